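# ROC/AUC evaluation, aggregation of repeated-validation ROC curves into a
# median curve with quartile bands, the Youden operating point, and the
# one-tailed Wilcoxon signed-rank test against chance.

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance probability (ties counted 1/2);
#' the curve is the usual threshold sweep over descending unique scores,
#' beginning at (0,0) and ending at (1,1).  The trapezoidal area under the
#' returned curve equals the concordance AUC.
#'
#' @param labels binary 0/1 vector (both classes required).
#' @param scores numeric prediction scores, higher = more positive.
#' @return list with `curve` (a `roc_curve`: data.frame of `fpr`, `tpr`) and
#'   `auc`.
#' @export
#' @examples
#' roc_and_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc  # 0.75
roc_and_auc <- function(labels, scores) {
  if (length(labels) != length(scores) || anyNA(labels) || anyNA(scores))
    stop_fracdem("labels and scores must be complete and of equal length",
                 class = "fracdem_eval_error")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L)
    stop_fracdem("both classes must be present", class = "fracdem_eval_error")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores)           # midranks handle ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1),
                     numeric(1)) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0),
                     numeric(1)) / n_neg)
  curve <- structure(data.frame(fpr = fpr, tpr = tpr),
                     class = c("roc_curve", "data.frame"))
  list(curve = curve, auc = auc)
}

#' Median ROC curve across repetitions with quartile bands
#'
#' Each repetition's ROC curve is interpolated onto a common
#' false-positive-rate grid as a step function (supremum of TPR over points
#' with FPR at most the grid value), then the pointwise median and 25th/75th
#' percentiles are taken.
#'
#' @param curves list of `roc_curve` objects (at least one).
#' @param grid_step FPR grid spacing (default 0.01).
#' @return an object of class `median_roc`: data.frame with `fpr`, `tpr`
#'   (median), `q25`, `q75`.
#' @export
median_roc <- function(curves, grid_step = 0.01) {
  if (!length(curves))
    stop_fracdem("need at least one ROC curve", class = "fracdem_eval_error")
  grid <- seq(0, 1, by = grid_step)
  mat <- vapply(curves, function(cv) {
    vapply(grid, function(g) max(cv$tpr[cv$fpr <= g + 1e-12]), numeric(1))
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  out <- data.frame(fpr = grid,
                    tpr = apply(mat, 1L, median),
                    q25 = apply(mat, 1L, quantile, probs = 0.25,
                                names = FALSE),
                    q75 = apply(mat, 1L, quantile, probs = 0.75,
                                names = FALSE))
  structure(out, class = c("median_roc", "data.frame"))
}

#' Youden-optimal operating point
#'
#' The point of a ROC curve maximizing Youden's index
#' J = sensitivity + specificity - 1 = TPR - FPR; ties are resolved in
#' favour of the lower false-positive rate.
#'
#' @param curve a `roc_curve` or `median_roc` (any data.frame with `fpr`,
#'   `tpr`).
#' @return list with `fpr`, `tpr`, `J`.
#' @export
youden_optimal <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("fpr", "tpr") %in% names(curve)))
  j <- curve$tpr - curve$fpr
  best <- order(-j, curve$fpr)[1L]
  list(fpr = curve$fpr[best], tpr = curve$tpr[best], J = j[best])
}

# One-tailed (greater) Wilcoxon signed-rank test of paired differences d
# against a zero median.  Exact null distribution when n <= 25 and the
# absolute differences are tie-free; otherwise normal approximation with
# tie and continuity corrections (exactness is impossible under ties).
signed_rank_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop_fracdem("all differences are zero; test undefined",
                 class = "fracdem_eval_error")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    # P(W >= w) on the integer-supported exact distribution
    p <- psignrank(w - 1, n, lower.tail = FALSE)
  } else {
    tie_sizes <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    p <- pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(statistic = w, n = n, p_value = as.numeric(p), exact = n <= 25L && !ties)
}

#' One-tailed Wilcoxon signed-rank test of AUCs against chance
#'
#' Tests whether the per-repetition AUCs exceed the chance level (0.5) in
#' median, discarding zero differences.
#'
#' @param aucs numeric vector of at least 5 repetition AUCs.
#' @param null chance level (default 0.5).
#' @return one-tailed p-value.
#' @export
#' @examples
#' wilcoxon_vs_chance(c(0.6, 0.7, 0.55, 0.65, 0.8))  # 1/32
wilcoxon_vs_chance <- function(aucs, null = 0.5) {
  if (length(aucs) < 5L)
    stop_fracdem("need at least 5 AUC values", class = "fracdem_eval_error")
  signed_rank_greater(aucs - null)$p_value
}

#' Mean AUC with empirical 90% confidence interval
#'
#' The interval is the empirical 5th-95th percentile range of the
#' repetition AUCs, matching the repeated-resampling design.
#'
#' @param aucs numeric vector of at least 2 AUC values.
#' @return list with `mean`, `ci` (length-2 vector).
#' @export
summarize_auc <- function(aucs) {
  if (length(aucs) < 2L)
    stop_fracdem("need at least 2 AUC values", class = "fracdem_eval_error")
  list(mean = mean(aucs),
       ci = unname(quantile(aucs, c(0.05, 0.95))))
}
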