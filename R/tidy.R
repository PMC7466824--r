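#' Tidy a fitted rule set
#'
#' One row per induced rule, in induction order, with the confusion counts,
#' quality, potential quality and LRS each rule had on the example set it
#' was induced from (the working set shrinks across covering iterations).
#'
#' @param x A `sem1r_ruleset` from [sem1r()].
#' @param ... Unused.
#' @return A tibble with columns `rule`, `terms` (list column), `label`,
#'   `length`, `n_covered`, `tp`, `fp`, `fn`, `tn`, `quality`, `potential`,
#'   `lrs`, `significant`.
#' @method tidy sem1r_ruleset
#' @export
tidy.sem1r_ruleset <- function(x, ...) {
  if (!length(x$rules)) {
    return(tibble::tibble(
      rule = integer(0), terms = list(), label = character(0),
      length = integer(0), n_covered = integer(0),
      tp = integer(0), fp = integer(0), fn = integer(0), tn = integer(0),
      quality = numeric(0), potential = numeric(0), lrs = numeric(0),
      significant = logical(0)
    ))
  }
  tibble::tibble(
    rule = seq_along(x$rules),
    terms = lapply(x$rules, `[[`, "terms"),
    label = vapply(x$rules, function(r) paste(r$terms, collapse = " AND "), ""),
    length = vapply(x$rules, function(r) length(r$terms), 0L),
    n_covered = vapply(x$rules, function(r) length(r$cover), 0L),
    tp = vapply(x$rules, function(r) r$counts[["tp"]], 0L),
    fp = vapply(x$rules, function(r) r$counts[["fp"]], 0L),
    fn = vapply(x$rules, function(r) r$counts[["fn"]], 0L),
    tn = vapply(x$rules, function(r) r$counts[["tn"]], 0L),
    quality = vapply(x$rules, `[[`, 0, "quality"),
    potential = vapply(x$rules, `[[`, 0, "potential"),
    lrs = vapply(x$rules, `[[`, 0, "lrs"),
    significant = vapply(x$rules, `[[`, TRUE, "significant")
  )
}

#' One-row summary of a fitted rule set
#'
#' @inheritParams tidy.sem1r_ruleset
#' @return A tibble with the number of rules, search effort, and the
#'   configuration that produced them.
#' @method glance sem1r_ruleset
#' @export
glance.sem1r_ruleset <- function(x, ...) {
  tibble::tibble(
    n_rules = length(x$rules),
    n_uncovered_positives = nrow(x$uncovered_positives),
    explored_rules = x$stats$explored_rules,
    runtime = x$stats$runtime,
    evaluator = x$control$evaluator,
    feature_selection = x$control$feature_selection,
    beam_width = x$control$beam_width,
    pruning = x$control$pruning
  )
}

#' Plot a fitted rule set
#'
#' `aspect = "quality"` draws each rule's quality with its admissible
#' potential as reference; `aspect = "coverage"` stacks the covered true
#' and false positives per rule.
#'
#' @param object A `sem1r_ruleset`.
#' @param aspect `"quality"` or `"coverage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sem1r_ruleset
#' @export
autoplot.sem1r_ruleset <- function(object, aspect = c("quality", "coverage"),
                                   ...) {
  aspect <- match.arg(aspect)
  td <- tidy.sem1r_ruleset(object)
  if (!nrow(td)) stop("no rules to plot")
  td$rule <- factor(td$rule)
  if (aspect == "quality") {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$rule)) +
      ggplot2::geom_col(ggplot2::aes(y = .data$quality), fill = "steelblue") +
      ggplot2::geom_point(ggplot2::aes(y = .data$potential), shape = 4) +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "rule (induction order)",
                    y = paste0("quality (", object$control$evaluator, ")"),
                    title = "Rule quality (x = potential upper bound)") +
      ggplot2::theme_minimal()
  } else {
    long <- tibble::tibble(
      rule = rep(td$rule, 2),
      class = rep(c("true positives", "false positives"), each = nrow(td)),
      n = c(td$tp, td$fp)
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$rule, y = .data$n,
                                       fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "rule (induction order)", y = "covered examples",
                    title = "Covered examples per rule") +
      ggplot2::theme_minimal()
  }
}

#' @export
print.sem1r_ruleset <- function(x, ...) {
  cat("Ontology-guided rule set (", x$control$evaluator, " evaluator, ",
      ifelse(x$control$pruning, "pruned", "exhaustive"), " refinement)\n",
      sep = "")
  if (!length(x$rules)) {
    cat("  no significant rule found\n")
  }
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    nms <- unlist(x$term_names[r$terms], use.names = FALSE)
    lab <- paste(sprintf("%s [%s]", r$terms, nms), collapse = " AND ")
    cat(sprintf("Rule %d: %s\n", i, lab))
    cat(sprintf("  TP=%d FP=%d FN=%d TN=%d  quality=%.4f  LRS=%.3f%s\n",
                r$counts[["tp"]], r$counts[["fp"]], r$counts[["fn"]],
                r$counts[["tn"]], r$quality, r$lrs,
                ifelse(r$significant, "", "  (not significant)")))
  }
  cat(sprintf("Uncovered positives: %d | explored rules: %d | %.2fs\n",
              nrow(x$uncovered_positives), x$stats$explored_rules,
              x$stats$runtime))
  invisible(x)
}

#' Write a machine-readable rule report
#'
#' Serializes the rule set (terms, confusion counts, quality, LRS), the
#' uncovered positives and the search statistics to JSON.
#'
#' @param x A `sem1r_ruleset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules_json <- function(x, path) {
  report <- list(
    evaluator = x$control$evaluator,
    feature_selection = x$control$feature_selection,
    pruning = x$control$pruning,
    rules = lapply(x$rules, function(r) {
      list(terms = as.list(r$terms),
           names = as.list(unlist(x$term_names[r$terms], use.names = FALSE)),
           tp = r$counts[["tp"]], fp = r$counts[["fp"]],
           fn = r$counts[["fn"]], tn = r$counts[["tn"]],
           quality = r$quality, potential = r$potential,
           lrs = r$lrs, significant = r$significant)
    }),
    uncovered_positives = nrow(x$uncovered_positives),
    stats = x$stats
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
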