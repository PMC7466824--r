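# The committed reconstruction of the toy ontology's Hasse diagram:
# parent -> children. Any edge set reproducing the propagated covers below
# is equivalent; tests assert the covers, not the edges.
toy_edges <- list(
  t0 = c("t1", "t2", "t3"),
  t1 = "t4",
  t2 = c("t4", "t5"),
  t3 = c("t5", "t6")
)

#' The packaged toy world
#'
#' A seven-term ontology (t0 most general; t4, t5, t6 leaves), three
#' examples e1, e2, e3 arranged as a 3x1 binary matrix, and direct
#' annotations M(e1) = \{t4\}, M(e2) = \{t5, t6\}, M(e3) = \{t2\}. After
#' propagation the semantic covers are S(t0) = S(t2) = \{e1, e2, e3\},
#' S(t1) = S(t4) = \{e1\}, S(t3) = S(t5) = S(t6) = \{e2\}. The labels make
#' e1 and e3 positive and e2 negative, which is the smallest world in which
#' every scoring and pruning behaviour of the learner can be traced by
#' hand. The same world ships as plain files under
#' `inst/extdata/` (`toy.obo`, `toy_annotations.tsv`, `toy_matrix.tsv`) for
#' end-to-end round trips through the parsers.
#'
#' @return List with elements `ontology`, `matrix` (3x1 binary),
#'   `annotations` (row-axis [annotation_map]), `examples` (an
#'   `example_set`: e1, e3 positive, e2 negative) and `cover` (the
#'   propagated `semantic_cover`).
#' @examples
#' toy <- build_toy_fixture()
#' rule_cover(c("t0", "t2"), toy$cover)  # examples 1, 2, 3
#' @export
build_toy_fixture <- function() {
  parents <- list()
  for (p in names(toy_edges)) {
    for (ch in toy_edges[[p]]) parents[[ch]] <- c(parents[[ch]], p)
  }
  ont <- ontology("toy", paste0("t", 0:6), parents = parents)
  m <- matrix(c(1L, 0L, 1L), ncol = 1,
              dimnames = list(c("e1", "e2", "e3"), "c1"))
  ann <- annotation_map(
    data.frame(id = c("e1", "e2", "e2", "e3"),
               term = c("t4", "t5", "t6", "t2")),
    axis = "rows"
  )
  ex <- cells_to_examples(m)
  list(
    ontology = ont,
    matrix = m,
    annotations = ann,
    examples = ex,
    cover = suppressWarnings(build_semantic_cover(ont, ann, ex))
  )
}

#' Generate a random single-rooted ontology DAG
#'
#' Term 1 is the unique root; every later term draws between one and
#' `max_parents` parents uniformly from the earlier terms, which guarantees
#' a connected acyclic graph. Output is bit-reproducible for a fixed seed.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per non-root term (>= 1).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @param id Ontology identifier used to prefix term ids.
#' @return An [ontology].
#' @export
random_ontology <- function(n_terms, max_parents = 2, seed = NULL, id = "RND") {
  if (n_terms < 1 || max_parents < 1) {
    stop("n_terms and max_parents must both be at least 1")
  }
  gen <- function() {
    ids <- sprintf("%s:%03d", id, seq_len(n_terms) - 1L)
    parents <- list()
    for (i in seq_len(n_terms)[-1]) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      parents[[ids[i]]] <- ids[sample.int(i - 1L, k)]
    }
    ontology(id, ids, parents = parents)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a planted-rule binary dataset
#'
#' Emulates the learner's intended use: rows and (optionally) columns get
#' random direct annotations, a pairwise-incomparable conjunction of
#' `rule_length` annotated terms with a non-trivial cover is planted, cells
#' covered by that conjunction are set to 1 and all others to 0, and
#' finally every cell is flipped independently with probability
#' `noise_rate`. At `noise_rate = 0` the positive examples are exactly the
#' planted cover, which is what the recovery tests assert.
#'
#' @param row_ontology [ontology] annotating the rows.
#' @param n_rows,n_cols Matrix dimensions.
#' @param rule_length Number of terms in the planted conjunction (>= 1).
#' @param noise_rate Independent cell-flip probability in `[0, 0.5)`.
#' @param seed Optional integer seed (restores the global RNG state).
#' @param col_ontology Optional second [ontology] annotating the columns;
#'   the planted rule may then mix row- and column-axis terms.
#' @param terms_per_entity Direct annotations drawn per row/column.
#' @param min_cover Minimum number of cells the planted cover must contain.
#' @param max_tries Resampling budget for finding a valid conjunction.
#' @return List of class `planted_instance` with `matrix`, `ontologies`,
#'   `maps`, `examples`, `cover`, `planted_rule`, `planted_cover` (integer
#'   example indices) and `seed`.
#' @export
planted_rule_dataset <- function(row_ontology, n_rows, n_cols,
                                 rule_length = 2, noise_rate = 0,
                                 seed = NULL, col_ontology = NULL,
                                 terms_per_entity = 2, min_cover = 4,
                                 max_tries = 200) {
  if (rule_length < 1) stop("rule_length must be at least 1")
  if (noise_rate < 0 || noise_rate >= 0.5) stop("noise_rate must lie in [0, 0.5)")
  gen <- function() {
    row_ids <- sprintf("g%03d", seq_len(n_rows))
    col_ids <- sprintf("s%02d", seq_len(n_cols))
    onts <- c(list(row_ontology),
              if (!is.null(col_ontology)) list(col_ontology))
    lk <- ontology_lookup(onts)

    annotate <- function(entities, ont) {
      terms <- ont$terms$term
      data.frame(
        id = rep(entities, each = terms_per_entity),
        term = unlist(lapply(entities, function(e) {
          sample(terms, min(terms_per_entity, length(terms)))
        }), use.names = FALSE),
        stringsAsFactors = FALSE
      )
    }
    maps <- list(annotation_map(annotate(row_ids, row_ontology), "rows"))
    if (!is.null(col_ontology)) {
      maps <- c(maps, list(annotation_map(annotate(col_ids, col_ontology),
                                          "columns")))
    }

    blank <- matrix(0L, n_rows, n_cols, dimnames = list(row_ids, col_ids))
    ex <- cells_to_examples(blank)  # placeholder labels; covers ignore them
    s <- build_semantic_cover(onts, maps, ex)
    pool <- names(s$cover)[lengths(s$cover) > 0]
    if (length(pool) < rule_length) stop("too few annotated terms to plant a rule")

    valid <- function(cand) {
      if (rule_length > 1 && rule_has_comparable_pair(lk, cand)) return(FALSE)
      cov <- rule_cover(cand, s)
      length(cov) >= min_cover && length(cov) < ex$n
    }
    planted <- NULL
    for (try in seq_len(max_tries)) {
      cand <- sort(sample(pool, rule_length))
      if (valid(cand)) {
        planted <- cand
        break
      }
    }
    if (is.null(planted) && choose(length(pool), rule_length) <= 20000) {
      # sampling missed; fall back to enumerating every conjunction
      all_sets <- utils::combn(pool, rule_length, simplify = FALSE)
      ok <- all_sets[vapply(all_sets, valid, TRUE)]
      if (length(ok)) planted <- sort(ok[[sample.int(length(ok), 1L)]])
    }
    if (is.null(planted)) {
      stop("no pairwise-incomparable conjunction of length ", rule_length,
           " with a non-trivial cover exists; relax the parameters")
    }
    cov <- rule_cover(planted, s)

    values <- integer(ex$n)
    values[cov] <- 1L
    if (noise_rate > 0) {
      flip <- stats::runif(ex$n) < noise_rate
      values[flip] <- 1L - values[flip]
    }
    m <- matrix(0L, n_rows, n_cols, dimnames = list(row_ids, col_ids))
    # examples are row-major: example k is cell (row (k-1) %/% n_cols + 1, ...)
    m[cbind((ex$ids$example - 1L) %/% n_cols + 1L,
            (ex$ids$example - 1L) %% n_cols + 1L)] <- values
    examples <- cells_to_examples(m)

    structure(
      list(matrix = m, ontologies = onts, maps = maps,
           examples = examples, cover = s,
           planted_rule = planted, planted_cover = cov, seed = seed),
      class = "planted_instance"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' @export
print.planted_instance <- function(x, ...) {
  cat("<planted_instance: ", nrow(x$matrix), "x", ncol(x$matrix),
      " matrix, planted rule {", paste(x$planted_rule, collapse = ", "),
      "} covering ", length(x$planted_cover), " cells>\n", sep = "")
  invisible(x)
}
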