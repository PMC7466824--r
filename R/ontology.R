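#' Construct an ontology from a term table and a parent relation
#'
#' An ontology is a directed acyclic graph of terms in which an edge
#' `child -> parent` states that the parent is *more general than* the child.
#' The reflexive-transitive closure of this relation is the partial order
#' used everywhere else in the package: annotation propagation, the
#' Redundant Generalization reduction, and feature selection all query it.
#'
#' Ancestor sets are materialized once at construction time so that
#' [is_more_general()] and [ancestors()] are O(1) lookups.
#'
#' @param id Identifier of the ontology (e.g. `"GO"`).
#' @param terms Character vector of term identifiers, or a data frame with
#'   columns `term` and (optionally) `name`.
#' @param parents Named list mapping a term id to the character vector of its
#'   direct parents (terms it `is_a`). Terms absent from the list are roots.
#' @return An object of class `ontology`: a list with elements `id`,
#'   `terms` (tibble with columns `term`, `name`), `parents`, `children`,
#'   `ancestors` (strict, i.e. excluding the term itself), `roots` and
#'   `n_edges`.
#' @examples
#' o <- ontology("toy", c("a", "b"), parents = list(b = "a"))
#' is_more_general(o, "a", "b")
#' @export
ontology <- function(id, terms, parents = list()) {
  if (is.data.frame(terms)) {
    term_ids <- as.character(terms$term)
    nm <- if ("name" %in% names(terms)) as.character(terms$name) else term_ids
  } else {
    term_ids <- as.character(terms)
    nm <- term_ids
  }
  if (anyDuplicated(term_ids)) {
    stop("duplicated term ids in ontology '", id, "': ",
         paste(unique(term_ids[duplicated(term_ids)]), collapse = ", "))
  }
  parents <- lapply(parents, function(p) unique(as.character(p)))
  bad_child <- setdiff(names(parents), term_ids)
  if (length(bad_child)) {
    stop("parent map refers to unknown terms: ", paste(bad_child, collapse = ", "))
  }
  bad_parent <- setdiff(unique(unlist(parents, use.names = FALSE)), term_ids)
  if (length(bad_parent)) {
    stop("unknown parent term ids: ", paste(bad_parent, collapse = ", "))
  }
  full_parents <- stats::setNames(vector("list", length(term_ids)), term_ids)
  for (t in term_ids) full_parents[[t]] <- character(0)
  for (t in names(parents)) full_parents[[t]] <- setdiff(parents[[t]], t)

  edges <- data.frame(
    child  = rep(names(full_parents), lengths(full_parents)),
    parent = unlist(full_parents, use.names = FALSE),
    stringsAsFactors = FALSE
  )

  # acyclicity check and parents-first ordering delegated to igraph
  order <- term_ids
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = term_ids))
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership ==
                                      which(comp$csize > 1)[1]]
      stop("cycle detected in ontology '", id, "' involving terms: ",
           paste(cyc, collapse = " -> "))
    }
    # topo_sort(mode = "out") puts every child before its parents; reverse it
    order <- rev(names(igraph::topo_sort(g, mode = "out")))
  }

  anc <- stats::setNames(vector("list", length(term_ids)), term_ids)
  for (t in order) {
    p <- full_parents[[t]]
    anc[[t]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
  }

  children <- stats::setNames(vector("list", length(term_ids)), term_ids)
  for (t in term_ids) children[[t]] <- character(0)
  if (nrow(edges)) {
    sp <- split(edges$child, edges$parent)
    for (p in names(sp)) children[[p]] <- unique(sp[[p]])
  }

  structure(
    list(
      id = id,
      terms = tibble::tibble(term = term_ids, name = nm),
      parents = full_parents,
      children = children,
      ancestors = anc,
      roots = term_ids[lengths(full_parents) == 0],
      n_edges = nrow(edges)
    ),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology '", x$id, "': ", nrow(x$terms), " terms, ",
      x$n_edges, " is_a edges, ", length(x$roots), " root(s)>\n", sep = "")
  invisible(x)
}

#' Parse an OBO flat file into an ontology
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 file. `is_a` lines always
#' contribute edges; `relationship: part_of` lines are included only when
#' `include_part_of = TRUE` (`is_a` is the only universally safe subsumption
#' relation, so it is the default). Terms flagged `is_obsolete: true` are
#' dropped, together with edges pointing at them. Other stanza types
#' (`[Typedef]`, ...) are ignored.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines
#'   (anything containing a newline is treated as literal text).
#' @param id Identifier for the resulting ontology; defaults to the
#'   `ontology:` header if present, else the file name.
#' @param include_part_of Also treat `part_of` relationships as subsumption.
#' @return An [ontology] object.
#' @export
parse_obo <- function(file, id = NULL, include_part_of = FALSE) {
  if (length(file) == 1L && !grepl("\n", file)) {
    if (!file.exists(file)) stop("OBO file not found: ", file)
    lines <- readLines(file, warn = FALSE)
    default_id <- basename(file)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
    default_id <- "obo"
  }
  lines <- sub("\\s+$", "", lines)

  header_ont <- grep("^ontology:", lines, value = TRUE)
  if (is.null(id)) {
    id <- if (length(header_ont)) sub("^ontology:\\s*", "", header_ont[1]) else default_id
  }

  stanza_at <- grep("^\\[", lines)
  term_at <- which(lines == "[Term]")
  out <- list()
  for (s in term_at) {
    end <- stanza_at[stanza_at > s]
    end <- if (length(end)) end[1] - 1L else length(lines)
    body <- lines[seq(s + 1L, length.out = max(0L, end - s))]
    body <- body[nzchar(body) & !grepl("^!", body)]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    bad <- which(lengths(kv) != 3L)
    if (length(bad)) {
      stop("malformed OBO stanza line ", s + bad[1], ": '", body[bad[1]], "'")
    }
    keys <- vapply(kv, `[`, "", 2L)
    vals <- vapply(kv, `[`, "", 3L)
    tid <- vals[keys == "id"]
    if (length(tid) != 1L) {
      stop("malformed OBO [Term] stanza starting at line ", s,
           ": expected exactly one 'id' line")
    }
    obsolete <- any(keys == "is_obsolete" & grepl("^true", vals))
    strip <- function(v) sub("\\s*!.*$", "", v)
    isa <- strip(vals[keys == "is_a"])
    if (include_part_of) {
      rel <- vals[keys == "relationship"]
      po <- grep("^part_of\\s+", rel, value = TRUE)
      isa <- c(isa, strip(sub("^part_of\\s+", "", po)))
    }
    nm <- vals[keys == "name"]
    out[[tid]] <- list(
      id = tid,
      name = if (length(nm)) nm[1] else tid,
      parents = unique(isa),
      obsolete = obsolete
    )
  }
  out <- out[!vapply(out, `[[`, TRUE, "obsolete")]
  ids <- names(out)
  parents <- lapply(out, function(t) intersect(t$parents, ids))
  dropped_edges <- sum(vapply(out, function(t) length(setdiff(t$parents, ids)),
                              0L))
  if (dropped_edges > 0) {
    warning(dropped_edges,
            " is_a edge(s) pointing at unknown/obsolete terms were dropped")
  }
  ontology(
    id = id,
    terms = data.frame(term = ids,
                       name = vapply(out, `[[`, "", "name"),
                       stringsAsFactors = FALSE),
    parents = parents
  )
}

#' Query the "more general than" partial order
#'
#' `is_more_general(o, t1, t2)` is `TRUE` iff `t1` subsumes `t2` under the
#' reflexive-transitive closure of the ontology's `is_a` edges (every term is
#' more general than itself). Terms of different ontologies are never
#' comparable.
#'
#' @param o An [ontology], or a list of ontologies.
#' @param t1,t2 Term identifiers.
#' @return Logical scalar.
#' @export
is_more_general <- function(o, t1, t2) {
  lk <- ontology_lookup(o)
  for (t in c(t1, t2)) {
    if (!t %in% names(lk$anc)) stop("unknown term id: ", t)
  }
  if (lk$ont_of[[t1]] != lk$ont_of[[t2]]) return(FALSE)
  t1 == t2 || t1 %in% lk$anc[[t2]]
}

#' Ancestors and descendants of a term
#'
#' `ancestors(o, t)` returns every term strictly more general than `t`;
#' `descendants(o, t)` every term strictly less general. Both exclude `t`
#' itself.
#'
#' @inheritParams is_more_general
#' @param t Term identifier.
#' @return Character vector of term ids (possibly empty).
#' @export
ancestors <- function(o, t) {
  lk <- ontology_lookup(o)
  if (!t %in% names(lk$anc)) stop("unknown term id: ", t)
  lk$anc[[t]]
}

#' @rdname ancestors
#' @export
descendants <- function(o, t) {
  lk <- ontology_lookup(o)
  if (!t %in% names(lk$anc)) stop("unknown term id: ", t)
  names(lk$anc)[vapply(lk$anc, function(a) t %in% a, TRUE)]
}

# Normalize one ontology or a list of them into combined lookup tables:
# anc (term -> strict ancestors), ont_of (term -> owning ontology id),
# name_of (term -> label). Term ids must be globally unique.
ontology_lookup <- function(o) {
  if (inherits(o, "ontology_lookup")) return(o)
  onts <- as_ontology_list(o)
  anc <- list()
  ont_of <- list()
  name_of <- list()
  for (ont in onts) {
    dup <- intersect(names(anc), names(ont$ancestors))
    if (length(dup)) {
      stop("term id(s) present in more than one ontology: ",
           paste(utils::head(dup, 5), collapse = ", "))
    }
    anc <- c(anc, ont$ancestors)
    ont_of <- c(ont_of, stats::setNames(as.list(rep(ont$id, nrow(ont$terms))),
                                        ont$terms$term))
    name_of <- c(name_of, stats::setNames(as.list(ont$terms$name),
                                          ont$terms$term))
  }
  structure(list(anc = anc, ont_of = ont_of, name_of = name_of,
                 ontologies = onts),
            class = "ontology_lookup")
}

as_ontology_list <- function(o) {
  if (inherits(o, "ontology")) return(list(o))
  if (is.list(o) && all(vapply(o, inherits, TRUE, "ontology"))) return(o)
  stop("expected an ontology or a list of ontologies")
}

# TRUE iff t1 and t2 are comparable under the reflexive partial order
# (same ontology and t1 == t2, or one is an ancestor of the other).
terms_comparable <- function(lk, t1, t2) {
  if (lk$ont_of[[t1]] != lk$ont_of[[t2]]) return(FALSE)
  t1 == t2 || t1 %in% lk$anc[[t2]] || t2 %in% lk$anc[[t1]]
}
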