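#' Pool an ultrasound acquisition to its median SWV
#'
#' Collapses the sub-sampled SWV values of one shear-wave image to a single
#' per-acquisition value, its median, after dropping out-of-plane
#' sub-samples. Acquisitions with fewer than `min_subsamples` usable
#' datapoints are discarded as poor quality; a discard is a result, not an
#' error.
#'
#' @param swv Numeric vector of sub-sample SWV values in m/s.
#' @param in_plane Logical vector (recycled) marking sub-samples whose
#'   imaging section showed the central canal; out-of-plane values are
#'   dropped before counting.
#' @param min_subsamples Minimum usable sub-samples to retain the image
#'   (default 30; an image with exactly 30 is retained).
#' @return List with `median` (m/s, `NA` if discarded), `n` (usable
#'   sub-samples), `discarded` (logical) and `reason`.
#' @export
pool_acquisition <- function(swv, in_plane = TRUE, min_subsamples = 30) {
  stopifnot(is.numeric(swv))
  keep <- swv[rep_len(as.logical(in_plane), length(swv))]
  if (length(keep) < min_subsamples)
    return(list(median = NA_real_, n = length(keep), discarded = TRUE,
                reason = sprintf("fewer than %d sub-samples (%d usable)",
                                 min_subsamples, length(keep))))
  list(median = stats::median(keep), n = length(keep), discarded = FALSE,
       reason = NA_character_)
}

#' Classify an image SWV against a tension threshold
#'
#' An image indicates a stretched cord iff its median SWV lies strictly
#' above the threshold; ties go to relaxed.
#'
#' @param median_swv Per-image median SWV in m/s (vectorised).
#' @param threshold Diagnosis threshold in m/s (default 1.76, the
#'   simulation-derived zero-tension baseline).
#' @return Character vector, `"stretched"` or `"relaxed"`.
#' @export
classify_image <- function(median_swv, threshold = 1.76) {
  check_scalar(threshold, "threshold", lower = 0, strict_lower = TRUE)
  ifelse(median_swv > threshold, "stretched", "relaxed")
}

#' Confusion-matrix diagnostic rates
#'
#' Accuracy, sensitivity and specificity (percent, one decimal) of
#' predicted stretched/relaxed labels against ground truth, with
#' `"stretched"` as the positive class (tension present).
#'
#' @param predicted,truth Character vectors of `"stretched"`/`"relaxed"`
#'   labels of equal length.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the `confusion` counts (tp, fp, fn, tn).
#' @examples
#' truth <- rep(c("stretched", "relaxed"), c(28, 27))
#' pred <- truth; pred[c(1, 2, 3, 30, 31, 32, 33)] <- # 7 discordant of 55
#'   ifelse(truth[c(1, 2, 3, 30, 31, 32, 33)] == "stretched",
#'          "relaxed", "stretched")
#' diagnostic_accuracy(pred, truth)$accuracy  # 87.3
#' @export
diagnostic_accuracy <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth))
    stop("predicted and truth must be nonempty and of equal length")
  lv <- c("stretched", "relaxed")
  stopifnot(all(predicted %in% lv), all(truth %in% lv))
  tp <- sum(predicted == "stretched" & truth == "stretched")
  fp <- sum(predicted == "stretched" & truth == "relaxed")
  fn <- sum(predicted == "relaxed" & truth == "stretched")
  tn <- sum(predicted == "relaxed" & truth == "relaxed")
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: no %s cases", what,
                      if (what == "sensitivity") "positive" else "negative"))
      return(NaN)
    }
    round(100 * num / den, 1)
  }
  list(accuracy = round(100 * (tp + tn) / length(truth), 1),
       sensitivity = rate(tp, tp + fn, "sensitivity"),
       specificity = rate(tn, tn + fp, "specificity"),
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

taut_test_result <- function(statistic, df, p_value, alpha, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), alpha = alpha, method = method),
            class = "taut_test")
}

#' @export
print.taut_test <- function(x, ...) {
  df <- if (length(x$df) == 2)
    sprintf("df = (%g, %g)", x$df[1], x$df[2]) else sprintf("df = %.2f", x$df)
  cat(sprintf("%s: statistic = %.4g, %s, p = %.3g (alpha = %g)\n",
              x$method, x$statistic, df, x$p_value, x$alpha))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Student's t-test for unequal sample sizes and unequal variances
#' (Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param a,b Numeric samples, each with at least 2 values and nonzero
#'   variance.
#' @param alpha Significance level recorded with the result (default 0.001,
#'   the per-case criterion of the intraoperative analysis).
#' @return A `taut_test` with `statistic` (t), `df`, `p_value`, `alpha`.
#' @export
welch_t_test <- function(a, b, alpha = 0.001) {
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient data: each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(taut_test_result(0, length(a) + length(b) - 2, 1, alpha,
                            "Welch two-sample t-test"))
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("insufficient data: both samples are degenerate (zero variance)")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  taut_test_result(ht$statistic, ht$parameter, ht$p.value, alpha,
                   "Welch two-sample t-test")
}

#' One-way analysis of variance
#'
#' Classical single-factor ANOVA (equal-variance F test) across groups —
#' in the intraoperative pipeline the groups are the image acquisitions
#' within a case.
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 2).
#' @param alpha Significance level recorded with the result (default 0.05).
#' @return A `taut_test` with the F `statistic`, `df` (between, within),
#'   `p_value`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  check_groups(groups)
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  taut_test_result(ft$statistic, unname(ft$parameter), ft$p.value, alpha,
                   "One-way ANOVA")
}

#' Tukey-Kramer post hoc pairwise comparisons
#'
#' All-pairs comparisons after ANOVA using the studentized-range
#' distribution with the Tukey-Kramer unequal-sample-size standard error.
#'
#' @param groups List (optionally named) of numeric samples (>= 2 groups,
#'   each n >= 2).
#' @param alpha Family-wise significance level for the decisions
#'   (default 0.001).
#' @return Data frame of class `tukey_result`: one row per pair with `diff`
#'   (mean difference), `se`, `q` (studentized-range statistic), `p_adj`
#'   and the logical `significant` decision at `alpha`.
#' @export
tukey_kramer <- function(groups, alpha = 0.001) {
  check_groups(groups)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  df_w <- sum(n) - k
  mse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df_w
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))   # Tukey-Kramer SE
    q <- abs(m[i] - m[j]) / se
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = m[i] - m[j], se = se, q = q,
               p_adj = stats::ptukey(q, nmeans = k, df = df_w,
                                     lower.tail = FALSE))
  }))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_result", "data.frame")
  out
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("insufficient data: at least 2 groups are required")
  if (any(lengths(groups) < 2L))
    stop("insufficient data: every group needs at least 2 values")
  invisible(groups)
}
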