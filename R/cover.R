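#' Propagate annotations into per-term semantic covers
#'
#' The semantic cover S(t) of a term is the set of examples annotated by `t`
#' *or any term less general than* `t`: direct annotations are propagated
#' upwards along the ontology DAG (the "true path rule"). For a row-axis
#' term, an example (r, c) is in S(t) when some term at or below `t`
#' directly annotates row r; column-axis terms work dually. Terms never
#' annotated on either axis get an empty cover.
#'
#' Annotation terms that do not occur in any supplied ontology are dropped
#' with a warning; the dropped ids are recorded in the result.
#'
#' @param ontologies An [ontology] or list of ontologies.
#' @param maps An [annotation_map] or list of annotation maps (each carries
#'   its axis).
#' @param examples An `example_set` defining the examples in scope.
#' @return A `semantic_cover`: list with `cover` (named list term id ->
#'   sorted integer vector of example indices), `n`, and `dropped_terms`.
#' @export
build_semantic_cover <- function(ontologies, maps, examples) {
  lk <- ontology_lookup(ontologies)
  if (inherits(maps, "annotation_map")) maps <- list(maps)
  stopifnot(all(vapply(maps, inherits, TRUE, "annotation_map")))

  scope <- example_scope(examples)
  ids <- examples$ids
  all_terms <- names(lk$anc)
  cover <- stats::setNames(vector("list", length(all_terms)), all_terms)
  for (t in all_terms) cover[[t]] <- integer(0)

  dropped <- character(0)
  for (mp in maps) {
    axis <- attr(mp, "axis")
    known <- mp$term %in% all_terms
    dropped <- c(dropped, unique(mp$term[!known]))
    mp <- mp[known, , drop = FALSE]
    if (!nrow(mp)) next
    # entities directly annotated per term, then upward closure:
    # entities(t) = direct(t) U direct(all descendants of t)
    direct <- split(mp$id, mp$term)
    ent_of_example <- if (axis == "rows") ids$row_id else ids$col_id
    annotated_terms <- names(direct)
    touch <- unique(c(annotated_terms,
                      unlist(lk$anc[annotated_terms], use.names = FALSE)))
    desc <- descendants_table(lk, touch)
    for (t in touch) {
      ents <- unique(unlist(direct[c(t, desc[[t]])], use.names = FALSE))
      if (!length(ents)) next
      ex <- scope[ent_of_example[scope] %in% ents]
      cover[[t]] <- sort(unique(c(cover[[t]], ex)))
    }
  }
  if (length(dropped)) {
    warning(length(unique(dropped)),
            " annotation term(s) not found in any ontology were dropped")
  }
  structure(
    list(cover = cover, n = examples$n, dropped_terms = unique(dropped)),
    class = "semantic_cover"
  )
}

# strict descendants for a set of terms, via one pass over the ancestor lists
descendants_table <- function(lk, terms) {
  out <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) out[[t]] <- character(0)
  for (child in names(lk$anc)) {
    for (a in intersect(lk$anc[[child]], terms)) {
      out[[a]] <- c(out[[a]], child)
    }
  }
  out
}

#' @export
print.semantic_cover <- function(x, ...) {
  nonempty <- sum(lengths(x$cover) > 0)
  cat("<semantic_cover: ", length(x$cover), " terms (", nonempty,
      " with non-empty cover) over ", x$n, " examples>\n", sep = "")
  invisible(x)
}

#' Examples covered by a conjunctive rule
#'
#' A rule is a set of ontology terms read as a conjunction; its cover is the
#' intersection of the member terms' semantic covers. The empty rule is the
#' empty conjunction and covers every example in scope. Terms without a
#' cover entry contribute the empty set.
#'
#' @param rule Character vector of term ids (possibly empty).
#' @param s A `semantic_cover` from [build_semantic_cover()].
#' @param all_examples Integer vector of the example indices in scope;
#'   defaults to all examples the cover was built over.
#' @return Sorted integer vector of covered example indices.
#' @export
rule_cover <- function(rule, s, all_examples = seq_len(s$n)) {
  rule <- unique(as.character(rule))
  if (!length(rule)) return(sort(all_examples))
  covers <- lapply(rule, function(t) {
    ct <- s$cover[[t]]
    if (is.null(ct)) integer(0) else ct
  })
  sort(Reduce(intersect, covers, accumulate = FALSE), method = "radix") |>
    intersect(all_examples) |>
    sort()
}

#' Generality of one rule over another
#'
#' Rule R1 is more general than rule R2 when it covers a superset of R2's
#' examples. This is the rule-level counterpart of the term order and is
#' reflexive.
#'
#' @param r1,r2 Character vectors of term ids.
#' @inheritParams rule_cover
#' @return Logical scalar.
#' @export
is_more_general_rule <- function(r1, r2, s, all_examples = seq_len(s$n)) {
  c1 <- rule_cover(r1, s, all_examples)
  c2 <- rule_cover(r2, s, all_examples)
  all(c2 %in% c1)
}
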