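#' ROC curve with AUC, DeLong CI and Youden-optimal cut-off
#'
#' Builds the full ROC curve of a continuous score against a binary label
#' (higher score predicts positive).  Operating points are evaluated at
#' the midpoints between consecutive distinct scores plus `-Inf`/`+Inf`
#' sentinels, classifying positive at `score >= threshold`.  The AUC is
#' the trapezoidal integral of the curve, which equals the tie-corrected
#' rank statistic (concordant pairs + half ties) / (n1 * n0); its 95%
#' confidence interval uses the DeLong placement-variance estimator
#' (computed via midranks, O(n log n)).  The reported cut-off maximizes
#' the Youden index J = sensitivity + specificity - 1, ties broken toward
#' the smallest threshold.
#'
#' @param scores numeric vector, finite.
#' @param labels logical (or 0/1) vector; both classes must be present.
#' @param conf_level confidence level for the AUC interval.
#' @param ci_method `"delong"` (default) or `"bootstrap"` (2000 stratified
#'   resamples; uses the current RNG state).
#' @return object of class `roc_result`: `points` (data.frame of
#'   threshold, sensitivity, specificity), `auc`, `auc_ci`, `auc_se`,
#'   `best_cutoff`, `best_sensitivity`, `best_specificity`, `youden_j`,
#'   `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc           # 1
#' r$best_cutoff   # 2.5
roc_curve <- function(scores, labels, conf_level = 0.95,
                      ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("degenerate ROC: both classes required")

  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  # counts of cases/controls at or above each threshold, via cumulative
  # tabulation over the distinct score values
  band <- findInterval(scores, s)   # index of each score among distinct values
  pos_at <- tabulate(band[labels], nbins = length(s))
  neg_at <- tabulate(band[!labels], nbins = length(s))
  tp <- c(n1, rev(cumsum(rev(pos_at)))[-1], 0)
  fp <- c(n0, rev(cumsum(rev(neg_at)))[-1], 0)
  sens <- tp / n1
  spec <- 1 - fp / n0
  points <- data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec)

  # trapezoid over (FPR, TPR), curve traversed from (1,1) down to (0,0)
  fpr <- 1 - spec
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)

  if (ci_method == "delong") {
    v <- .delong_variance(scores, labels)
    se <- sqrt(v)
  } else {
    se <- .bootstrap_auc_se(scores, labels, reps = 2000L)
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))

  j <- sens + spec - 1
  best <- which.max(j)   # first index at the max: smallest threshold wins
  structure(list(points = points, auc = auc, auc_se = se, auc_ci = ci,
                 best_cutoff = thr[best], best_sensitivity = sens[best],
                 best_specificity = spec[best], youden_j = j[best],
                 n_pos = n1, n_neg = n0, ci_method = ci_method),
            class = "roc_result")
}

# DeLong placement variance via midranks (Sun & Xu fast formulation)
.delong_variance <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_x) / n0            # placements of cases
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_y) / n1   # placements of controls
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  s10 / n1 + s01 / n0
}

.bootstrap_auc_se <- function(scores, labels, reps = 2000L) {
  ip <- which(labels); ineg <- which(!labels)
  aucs <- vapply(seq_len(reps), function(i) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    .rank_auc(scores[idx], labels[idx])
  }, numeric(1))
  stats::sd(aucs)
}

# tie-corrected Mann-Whitney AUC
.rank_auc <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal operating point of a ROC result
#'
#' @param roc a `roc_result`.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  list(cutoff = roc$best_cutoff, sensitivity = roc$best_sensitivity,
       specificity = roc$best_specificity, youden_j = roc$youden_j)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d cases / %d controls; AUC %.3f (%s 95%% CI %.3f-%.3f)\n",
              x$n_pos, x$n_neg, x$auc, x$ci_method, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Youden cut-off %.3g: sensitivity %.3f, specificity %.3f, J %.3f\n",
              x$best_cutoff, x$best_sensitivity, x$best_specificity,
              x$youden_j))
  invisible(x)
}
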