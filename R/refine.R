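# A candidate rule as carried through the search: term set plus cached
# cover and scores. `key` is the canonical identity of the term set.
new_rule <- function(terms, cover = NULL, counts = NULL, quality = NA_real_,
                     potential = NA_real_, lrs = NA_real_, significant = NA) {
  terms <- sort(unique(as.character(terms)))
  structure(
    list(terms = terms, key = paste(terms, collapse = " "),
         cover = cover, counts = counts, quality = quality,
         potential = potential, lrs = lrs, significant = significant),
    class = "sem1r_rule"
  )
}

#' @export
print.sem1r_rule <- function(x, ...) {
  lab <- if (length(x$terms)) paste(x$terms, collapse = " AND ") else "<empty rule>"
  cat(lab, "\n", sep = "")
  if (!is.null(x$counts)) {
    cat(sprintf("  TP=%d FP=%d FN=%d TN=%d  quality=%.4f  potential=%.4f  LRS=%.3f\n",
                x$counts[["tp"]], x$counts[["fp"]], x$counts[["fn"]],
                x$counts[["tn"]], x$quality, x$potential, x$lrs))
  }
  invisible(x)
}

as_rule_list <- function(candidates) {
  if (inherits(candidates, "sem1r_rule")) return(list(candidates))
  lapply(candidates, function(r) {
    if (inherits(r, "sem1r_rule")) r else new_rule(r)
  })
}

# evaluate a rule's cover and scores against an example set
evaluate_rule <- function(terms, parent_cover, feature_cover, e, evaluator,
                          alpha, lrs_variant) {
  cov <- intersect(parent_cover, feature_cover)
  cts <- confusion_counts(cov, e)
  l <- lrs(cts, variant = lrs_variant)
  new_rule(terms,
           cover = cov,
           counts = cts,
           quality = rule_quality(cts, evaluator),
           potential = rule_potential(cts, evaluator),
           lrs = l,
           significant = is_significant(l, alpha))
}

#' Drop candidate rules that are Redundant Generalizations
#'
#' A rule containing two comparable terms (one more general than the other,
#' including duplicates, which are comparable by reflexivity) covers exactly
#' the same examples as the rule without the more general term, so it is
#' redundant and can be removed without losing any cover. Only candidates in
#' which **no** pair of terms is comparable under the ontology order are
#' retained.
#'
#' @param candidates List of candidate rules (term-id character vectors or
#'   `sem1r_rule` objects).
#' @param ontologies An [ontology] or list of ontologies.
#' @return Filtered list of rules, in input order.
#' @export
remove_redundant_generalizations <- function(candidates, ontologies) {
  lk <- ontology_lookup(ontologies)
  rules <- as_rule_list(candidates)
  keep <- vapply(rules, function(r) !rule_has_comparable_pair(lk, r$terms), TRUE)
  rules[keep]
}

rule_has_comparable_pair <- function(lk, terms) {
  n <- length(terms)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (terms_comparable(lk, terms[i], terms[j])) return(TRUE)
    }
  }
  FALSE
}

#' Drop candidate rules that are Redundant Non-potentials
#'
#' A candidate whose potential quality (the admissible upper bound on the
#' quality of any of its specializations) is *strictly* below the best
#' quality found so far can never improve on the current best rule, and
#' neither can any of its refinements; such candidates are pruned together
#' with their whole specialization subtree. Ties with the bound survive, so
#' an equal-quality rule is never lost.
#'
#' @param candidates List of evaluated `sem1r_rule` objects (each carrying
#'   `potential`).
#' @param best_quality Quality of the best rule found so far.
#' @param evaluator Evaluator name; used to (re)compute missing potentials.
#' @return Filtered list of rules, in input order.
#' @export
remove_redundant_nonpotentials <- function(candidates, best_quality,
                                           evaluator = c("acc", "f1", "auc")) {
  evaluator <- match.arg(evaluator)
  rules <- as_rule_list(candidates)
  pot <- vapply(rules, function(r) {
    if (!is.na(r$potential)) r$potential else rule_potential(r$counts, evaluator)
  }, 0)
  rules[pot >= best_quality]
}

#' Ontology-based refinement of a single rule
#'
#' Appends each admissible feature to the rule, skips Redundant
#' Generalizations (the appended term comparable with a term already in the
#' rule — their covers would not change), evaluates the survivors, and
#' removes Redundant Non-potentials against `best_quality`. With
#' `prune = FALSE` both reductions are disabled and every appended candidate
#' is generated and evaluated (the exhaustive CN2-style operator).
#'
#' @param rule A `sem1r_rule` (or character vector of term ids) to refine;
#'   must itself be free of comparable term pairs.
#' @param features Character vector of admissible term ids, from
#'   [select_features()].
#' @param ontologies An [ontology] or list of ontologies.
#' @param best_quality Quality of the best rule found so far (the pruning
#'   bound, held fixed for the duration of this call).
#' @param examples The current `example_set`.
#' @param s A `semantic_cover`.
#' @param evaluator One of `"acc"`, `"f1"`, `"auc"`.
#' @param alpha Significance level used to annotate candidates.
#' @param prune Apply the two reductions (`TRUE`) or behave as the
#'   exhaustive refinement operator (`FALSE`).
#' @param lrs_variant LRS convention, `"printed"` or `"cn2"`.
#' @return List of evaluated surviving `sem1r_rule`s, deduplicated by term
#'   set, in deterministic (lexicographic feature) order. The attribute
#'   `evaluated_keys` records the term-set keys whose cover/score was
#'   actually computed (Redundant Generalizations are rejected *before*
#'   evaluation and do not appear there).
#' @export
refine_rule <- function(rule, features, ontologies, best_quality, examples, s,
                        evaluator = c("acc", "f1", "auc"), alpha = 0.01,
                        prune = TRUE, lrs_variant = c("printed", "cn2")) {
  evaluator <- match.arg(evaluator)
  lrs_variant <- match.arg(lrs_variant)
  lk <- ontology_lookup(ontologies)
  if (!inherits(rule, "sem1r_rule")) rule <- new_rule(rule)
  if (is.null(rule$cover)) {
    rule$cover <- rule_cover(rule$terms, s, example_scope(examples))
  }
  features <- sort(unique(as.character(features)))
  scope <- example_scope(examples)

  out <- list()
  evaluated <- character(0)
  for (f in features) {
    if (f %in% rule$terms) next
    if (prune && any(vapply(rule$terms, terms_comparable, TRUE, lk = lk, t2 = f))) {
      next  # Redundant Generalization: never generated, never evaluated
    }
    terms_new <- c(rule$terms, f)
    fc <- s$cover[[f]]
    if (is.null(fc)) fc <- integer(0)
    cand <- evaluate_rule(terms_new, rule$cover, intersect(fc, scope),
                          examples, evaluator, alpha, lrs_variant)
    evaluated <- c(evaluated, cand$key)
    if (prune && cand$potential < best_quality) next  # Redundant Non-potential
    if (!is.null(out[[cand$key]])) next
    out[[cand$key]] <- cand
  }
  res <- unname(out)
  attr(res, "evaluated_keys") <- evaluated
  res
}
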