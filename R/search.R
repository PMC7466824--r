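#' Search configuration for the rule learner
#'
#' Bundles every tunable of the covering search. Defaults follow common
#' practice for this learner: a beam of the 100 best rules, rules of at most
#' 10 terms, at most 10 rules per run, and a 99% significance level for the
#' likelihood-ratio gate.
#'
#' @param evaluator Rule quality function: `"acc"`, `"f1"` or `"auc"`.
#' @param feature_selection `"atLeastOne"` (terms covering at least one
#'   example), `"onlySig"` (significant terms only) or `"sigAtLeastOne"`
#'   (covering terms that are, or generalize, a significant term).
#' @param beam_width Number of candidate rules kept per refinement level;
#'   may be `Inf` for exhaustive breadth.
#' @param max_rule_length Maximum number of terms in a rule.
#' @param max_rules Maximum number of rules induced by the covering loop.
#' @param significance Confidence level of the chi-square significance gate
#'   (0.99 means rules must exceed the 99% quantile); the corresponding
#'   alpha is `1 - significance`.
#' @param covering_removal After accepting a rule, remove `"all-covered"`
#'   examples (positives and negatives) or `"positives-only"` from the
#'   working set.
#' @param pruning Apply the Redundant Generalization and Redundant
#'   Non-potential reductions (`TRUE`) or run the exhaustive refinement
#'   operator (`FALSE`).
#' @param lrs_variant Likelihood-ratio convention, see [lrs()].
#' @param seed Reserved for tie-shuffling strategies; the default
#'   deterministic tie-breaking ignores it.
#' @return A list of class `sem1r_control`.
#' @export
sem1r_control <- function(evaluator = c("acc", "f1", "auc"),
                          feature_selection = c("atLeastOne", "onlySig",
                                                "sigAtLeastOne"),
                          beam_width = 100,
                          max_rule_length = 10,
                          max_rules = 10,
                          significance = 0.99,
                          covering_removal = c("all-covered", "positives-only"),
                          pruning = TRUE,
                          lrs_variant = c("printed", "cn2"),
                          seed = NULL) {
  stopifnot(beam_width >= 1, max_rule_length >= 1, max_rules >= 1,
            significance > 0, significance < 1)
  structure(
    list(evaluator = match.arg(evaluator),
         feature_selection = match.arg(feature_selection),
         beam_width = beam_width,
         max_rule_length = max_rule_length,
         max_rules = max_rules,
         significance = significance,
         covering_removal = match.arg(covering_removal),
         pruning = isTRUE(pruning),
         lrs_variant = match.arg(lrs_variant),
         seed = seed),
    class = "sem1r_control"
  )
}

#' Select the admissible features for rule construction
#'
#' Every ontology term is a potential feature; feature selection trims the
#' set before search:
#'
#' * `atLeastOne` keeps terms whose semantic cover contains at least one
#'   example in scope — terms covering nothing can never improve a rule.
#' * `onlySig` keeps covering terms whose singleton rule is significant
#'   under the LRS gate.
#' * `sigAtLeastOne` keeps covering terms that are significant themselves or
#'   are a generalization of some significant term.
#'
#' All three methods require a non-empty cover, so the selections are nested:
#' `onlySig` is contained in `sigAtLeastOne` (significance is reflexive
#' generalization), which is contained in `atLeastOne`.
#'
#' @param method Feature-selection method name.
#' @param s A `semantic_cover`.
#' @param examples The current `example_set`.
#' @param ontologies An [ontology] or list of ontologies.
#' @param alpha Significance level for the LRS gate.
#' @param lrs_variant LRS convention, see [lrs()].
#' @return Character vector of term ids, sorted lexicographically (the
#'   deterministic refinement order).
#' @export
select_features <- function(method = c("atLeastOne", "onlySig", "sigAtLeastOne"),
                            s, examples, ontologies, alpha = 0.01,
                            lrs_variant = c("printed", "cn2")) {
  method <- match.arg(method)
  lrs_variant <- match.arg(lrs_variant)
  scope <- example_scope(examples)
  covers <- lapply(s$cover, intersect, scope)
  nonempty <- names(covers)[lengths(covers) > 0]
  if (method == "atLeastOne") return(sort(nonempty))

  sig <- nonempty[vapply(nonempty, function(t) {
    is_significant(lrs(confusion_counts(covers[[t]], examples),
                       variant = lrs_variant), alpha)
  }, TRUE)]
  if (method == "onlySig") return(sort(sig))

  lk <- ontology_lookup(ontologies)
  gen_of_sig <- unique(c(sig, unlist(lk$anc[sig], use.names = FALSE)))
  sort(intersect(nonempty, gen_of_sig))
}

#' Keep the best candidates of a refinement level (the beam filter)
#'
#' Sorts candidates by quality (descending) and truncates to the beam
#' width. Ties are broken deterministically: larger cover first, then the
#' lexicographically smallest sorted term tuple.
#'
#' @param candidates List of evaluated `sem1r_rule`s.
#' @param beam_width Maximum number of rules to keep; may be `Inf`.
#' @return List of at most `beam_width` rules in beam order.
#' @export
filter_rules <- function(candidates, beam_width) {
  stopifnot(beam_width >= 1)
  if (!length(candidates)) return(candidates)
  q <- vapply(candidates, `[[`, 0, "quality")
  csize <- vapply(candidates, function(r) length(r$cover), 0L)
  key <- vapply(candidates, `[[`, "", "key")
  ord <- order(-q, -csize, key, method = "radix")
  candidates[ord[seq_len(min(length(ord), beam_width))]]
}

#' Induce the single best rule by ontology-aware beam search
#'
#' Starting from the empty rule, candidates are iteratively refined by
#' appending features, with the Redundant Generalization and Redundant
#' Non-potential reductions pruning the candidate stream (unless
#' `control$pruning` is off). After each refinement level only the
#' `beam_width` best candidates are expanded further. A candidate becomes
#' the running best when its quality strictly exceeds the best score so far
#' *and* it passes the LRS significance gate; the gate applies to becoming
#' best, not to beam membership. The best score is initialized to 0 for
#' every call.
#'
#' @param examples The current `example_set`; needs at least one positive
#'   and one negative example.
#' @param ontologies An [ontology] or list of ontologies.
#' @param s A `semantic_cover` built over the same example universe.
#' @param control A [sem1r_control()] configuration.
#' @return List with `rule` (a `sem1r_rule`, or `NULL` when no significant
#'   rule exists) and `stats` (list with `explored_rules` and `runtime`
#'   seconds).
#' @export
induce_single_rule <- function(examples, ontologies, s,
                               control = sem1r_control()) {
  t0 <- proc.time()[["elapsed"]]
  stats <- list(explored_rules = 0L, runtime = 0)
  done <- function(rule) {
    stats$runtime <- proc.time()[["elapsed"]] - t0
    list(rule = rule, stats = stats)
  }
  if (!length(examples$positives) || !length(examples$negatives)) {
    warning("degenerate example set: need at least one positive and one negative")
    return(done(NULL))
  }
  alpha <- 1 - control$significance
  features <- select_features(control$feature_selection, s, examples,
                              ontologies, alpha, control$lrs_variant)
  if (!length(features)) {
    warning("no features survive feature selection; no rule induced")
    return(done(NULL))
  }
  scope <- example_scope(examples)
  s_scoped <- s
  s_scoped$cover <- lapply(s$cover, intersect, scope)

  empty <- new_rule(character(0), cover = scope)
  beam <- list(empty)
  best <- NULL
  best_score <- 0

  for (l in seq_len(control$max_rule_length)) {
    pool <- list()
    seen <- character(0)
    for (parent in beam) {
      cands <- refine_rule(parent, features, ontologies, best_score, examples,
                           s_scoped, control$evaluator, alpha,
                           prune = control$pruning, control$lrs_variant)
      new_keys <- setdiff(unique(attr(cands, "evaluated_keys")), seen)
      stats$explored_rules <- stats$explored_rules + length(new_keys)
      seen <- c(seen, new_keys)
      for (cand in cands) {
        if (cand$quality > best_score && cand$significant) {
          best <- cand
          best_score <- cand$quality
        }
        if (is.null(pool[[cand$key]])) pool[[cand$key]] <- cand
      }
    }
    if (!length(pool)) break
    beam <- filter_rules(unname(pool), control$beam_width)
  }
  done(best)
}

#' Induce a rule set by separate-and-conquer covering
#'
#' Repeatedly induces the best single rule on the current example set and
#' removes the examples that rule covers (all covered examples by default,
#' or only the covered positives), until every positive example is covered,
#' the rule budget is exhausted, or no significant rule can be found. Each
#' accepted rule is reported with the confusion counts, quality and LRS it
#' had on the example set it was induced from.
#'
#' @inheritParams induce_single_rule
#' @return An object of class `sem1r_ruleset`; see [tidy.sem1r_ruleset()],
#'   [glance.sem1r_ruleset()] and [autoplot.sem1r_ruleset()].
#' @examples
#' toy <- build_toy_fixture()
#' fit <- sem1r(toy$examples, toy$ontology, toy$cover,
#'              sem1r_control(significance = 0.5, max_rule_length = 2))
#' tidy(fit)
#' @export
sem1r <- function(examples, ontologies, s, control = sem1r_control()) {
  t0 <- proc.time()[["elapsed"]]
  lk <- ontology_lookup(ontologies)
  cur <- examples
  rules <- list()
  per_rule <- integer(0)
  explored <- 0L

  while (length(rules) < control$max_rules &&
         length(cur$positives) > 0 && length(cur$negatives) > 0) {
    res <- induce_single_rule(cur, ontologies, s, control)
    explored <- explored + res$stats$explored_rules
    per_rule <- c(per_rule, res$stats$explored_rules)
    if (is.null(res$rule)) break
    rules[[length(rules) + 1L]] <- res$rule
    covered <- res$rule$cover
    remove <- if (control$covering_removal == "all-covered") covered
              else intersect(covered, cur$positives)
    if (!length(intersect(covered, cur$positives))) break  # no progress
    keep <- setdiff(example_scope(cur), remove)
    cur <- subset_examples(cur, keep)
  }

  structure(
    list(
      rules = rules,
      uncovered_positives = examples$ids[examples$ids$example %in% cur$positives, ],
      stats = list(explored_rules = explored,
                   runtime = proc.time()[["elapsed"]] - t0,
                   per_rule_breakdown = per_rule),
      control = control,
      examples = examples,
      term_names = lk$name_of
    ),
    class = "sem1r_ruleset"
  )
}

#' Exhaustive-refinement baseline
#'
#' Runs the identical covering search with both reduction procedures
#' disabled (the beam filter still applies): the traditional CN2-style
#' refinement operator. Used to verify that pruning changes neither rule
#' qualities nor covers while exploring far fewer candidates.
#'
#' @inheritParams induce_single_rule
#' @return A `sem1r_ruleset`, as [sem1r()].
#' @export
run_exhaustive_baseline <- function(examples, ontologies, s,
                                    control = sem1r_control()) {
  control$pruning <- FALSE
  sem1r(examples, ontologies, s, control)
}
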