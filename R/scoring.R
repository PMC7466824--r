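#' Confusion counts of a rule cover
#'
#' Classifying every covered example as positive yields the usual confusion
#' matrix against the example labels: TP are covered positives, FP covered
#' negatives, FN uncovered positives and TN uncovered negatives.
#'
#' @param cover Integer vector of covered example indices.
#' @param e An `example_set` (possibly restricted by a covering step).
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(cover, e) {
  tp <- length(intersect(cover, e$positives))
  fp <- length(intersect(cover, e$negatives))
  c(tp = tp, fp = fp,
    fn = length(e$positives) - tp,
    tn = length(e$negatives) - fp)
}

counts_ok <- function(c) {
  stopifnot(length(c) == 4L, all(c >= 0))
  invisible(c)
}

#' Rule quality functions and their admissible upper bounds
#'
#' Three quality measures for a rule with confusion counts
#' `c = c(tp, fp, fn, tn)`:
#' accuracy `q_acc = (TP+TN)/(TP+TN+FP+FN)`, F1 `q_f1 = 2TP/(2TP+FP+FN)`,
#' and a single-point AUC
#' `q_auc = FPR*TPR + (1-FPR)*TPR + (1-FPR)(1-TPR)/2` with
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`.
#'
#' Each measure is paired with a *potential quality* `q_p_*`: the best value
#' any specialization of the rule could reach. Refinement can only shrink
#' the cover, so at best every currently covered negative (FP) becomes
#' uncovered (TN) while all covered positives are kept:
#' `q_p_acc = (TP+TN+FP)/(TP+TN+FP+FN)`, `q_p_f1 = 2TP/(2TP+FN)`, and
#' `q_p_auc = TPR + (1-TPR)/2` (FPR driven to zero). These bounds are what
#' makes the Redundant Non-potential reduction sound.
#'
#' F1 with a zero denominator (an empty cover over no positives) is defined
#' as 0 so that worthless candidates remain comparable during search.
#'
#' @param c Named or positional integer vector `c(tp, fp, fn, tn)`.
#' @return Quality value in `[0, 1]`.
#' @examples
#' q_acc(c(tp = 2, fp = 1, fn = 0, tn = 0))   # 2/3
#' q_p_acc(c(tp = 0, fp = 1, fn = 2, tn = 0)) # 1/3
#' @export
q_acc <- function(c) {
  counts_ok(c)
  tot <- sum(c)
  if (tot == 0) stop("accuracy undefined for zero total examples")
  (c[["tp"]] + c[["tn"]]) / tot
}

#' @rdname q_acc
#' @export
q_p_acc <- function(c) {
  counts_ok(c)
  tot <- sum(c)
  if (tot == 0) stop("accuracy undefined for zero total examples")
  (c[["tp"]] + c[["tn"]] + c[["fp"]]) / tot
}

#' @rdname q_acc
#' @export
q_f1 <- function(c) {
  counts_ok(c)
  den <- 2 * c[["tp"]] + c[["fp"]] + c[["fn"]]
  if (den == 0) return(0)
  2 * c[["tp"]] / den
}

#' @rdname q_acc
#' @export
q_p_f1 <- function(c) {
  counts_ok(c)
  den <- 2 * c[["tp"]] + c[["fn"]]
  if (den == 0) return(0)
  2 * c[["tp"]] / den
}

rates <- function(c) {
  if (c[["tp"]] + c[["fn"]] == 0 || c[["fp"]] + c[["tn"]] == 0) {
    stop("AUC undefined: one of the classes is empty")
  }
  c(tpr = c[["tp"]] / (c[["tp"]] + c[["fn"]]),
    fpr = c[["fp"]] / (c[["fp"]] + c[["tn"]]))
}

#' @rdname q_acc
#' @export
q_auc <- function(c) {
  counts_ok(c)
  r <- rates(c)
  r[["fpr"]] * r[["tpr"]] + (1 - r[["fpr"]]) * r[["tpr"]] +
    (1 - r[["fpr"]]) * (1 - r[["tpr"]]) / 2
}

#' @rdname q_acc
#' @export
q_p_auc <- function(c) {
  counts_ok(c)
  r <- rates(c)
  r[["tpr"]] + (1 - r[["tpr"]]) / 2
}

#' Evaluate a quality (or potential-quality) function by name
#'
#' @param c Confusion counts `c(tp, fp, fn, tn)`.
#' @param evaluator One of `"acc"`, `"f1"`, `"auc"`.
#' @return Quality value in `[0, 1]`.
#' @export
rule_quality <- function(c, evaluator = c("acc", "f1", "auc")) {
  switch(match.arg(evaluator), acc = q_acc(c), f1 = q_f1(c), auc = q_auc(c))
}

#' @rdname rule_quality
#' @export
rule_potential <- function(c, evaluator = c("acc", "f1", "auc")) {
  switch(match.arg(evaluator), acc = q_p_acc(c), f1 = q_p_f1(c), auc = q_p_auc(c))
}

#' Likelihood-ratio statistic for rule significance
#'
#' Measures how much the class mix associated with a rule deviates from the
#' global class mix; approximately chi-square distributed with one degree of
#' freedom. Two conventions are provided:
#'
#' * `"printed"` (default):
#'   `2 * (TP*log2((TP/(TP+TN)) / ((TP+FN)/|E|)) +
#'         TN*log2((TN/(TP+TN)) / ((FP+TN)/|E|)))`.
#' * `"cn2"`: the classical CN2 form with the covered set TP+FP, i.e. FP in
#'   place of TN throughout:
#'   `2 * (TP*log2((TP/(TP+FP)) / ((TP+FN)/|E|)) +
#'         FP*log2((FP/(TP+FP)) / ((FP+TN)/|E|)))`.
#'
#' The two differ in which pair of counts they treat as "the covered set";
#' under `"printed"` a perfect rule (FP = FN = 0) scores 0, under `"cn2"`
#' it scores its maximum, so the choice matters for the significance gate
#' (see the package vignette). Terms with a zero count or an undefined
#' ratio contribute 0 (the standard `0 * log = 0` convention); both forms
#' are nonnegative.
#'
#' @param c Confusion counts `c(tp, fp, fn, tn)`.
#' @param n_total Total number of examples |E|; defaults to `sum(c)`.
#' @param variant `"printed"` or `"cn2"`.
#' @return Nonnegative statistic.
#' @export
lrs <- function(c, n_total = sum(c), variant = c("printed", "cn2")) {
  counts_ok(c)
  variant <- match.arg(variant)
  tp <- c[["tp"]]; fp <- c[["fp"]]; fn <- c[["fn"]]; tn <- c[["tn"]]
  e <- n_total
  term <- function(x, num, den) {
    if (x == 0 || den == 0 || num == 0) return(0)
    r <- num / den
    if (!is.finite(r) || r <= 0) return(0)
    x * log2(r)
  }
  if (variant == "printed") {
    covered <- tp + tn
    t1 <- if (covered == 0) 0 else term(tp, tp / covered, (tp + fn) / e)
    t2 <- if (covered == 0) 0 else term(tn, tn / covered, (fp + tn) / e)
  } else {
    covered <- tp + fp
    t1 <- if (covered == 0) 0 else term(tp, tp / covered, (tp + fn) / e)
    t2 <- if (covered == 0) 0 else term(fp, fp / covered, (fp + tn) / e)
  }
  2 * (t1 + t2)
}

#' Chi-square significance gate for the LRS
#'
#' A rule (or single term) is significant when its likelihood-ratio
#' statistic exceeds the `1 - alpha` quantile of the chi-square distribution
#' with one degree of freedom; at `alpha = 0.01` the critical value is
#' 6.635.
#'
#' @param lrs_value Likelihood-ratio statistic.
#' @param alpha Significance level in (0, 1), e.g. 0.01 for the 99% level.
#' @return Logical scalar.
#' @export
is_significant <- function(lrs_value, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  lrs_value > stats::qchisq(1 - alpha, df = 1)
}
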