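#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, computed by explicit pair counting:
#' `AUC = (concordant + 0.5 * tied) / (n_pos * n_neg)`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Class labels.
#' @param positive Label of the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = "AD") {
  lab <- as.character(labels) == positive
  if (!any(lab) || all(lab)) {
    stop_retispec("both classes must be present", "retispec_degenerate_label_error")
  }
  pos <- scores[lab]; neg <- scores[!lab]
  d <- outer(pos, neg, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(pos) * length(neg))
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the AUC from DeLong's structural
#' components: for each positive i, `V10_i` is the mean of the
#' placement indicators against all negatives (and `V01_j` symmetric),
#' `var(AUC) = S10/n_pos + S01/n_neg` with the sample variances of the
#' components, followed by a Wald interval clipped to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return List of class `auc_ci`: `auc`, `lo`, `hi`, `se`, `level`,
#'   `method`.
#' @export
delong_ci <- function(scores, labels, positive = "AD", level = 0.95) {
  lab <- as.character(labels) == positive
  if (sum(lab) < 2 || sum(!lab) < 2) {
    stop_retispec("need at least 2 subjects per class",
                  "retispec_degenerate_label_error")
  }
  pos <- scores[lab]; neg <- scores[!lab]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  va <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  se <- sqrt(max(va, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(auc = auc, lo = max(0, auc - z * se),
                 hi = min(1, auc + z * se), se = se, level = level,
                 method = "DeLong"),
            class = "auc_ci")
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified nonparametric bootstrap (resampling positives and
#' negatives separately), percentile interval.  Provided as an
#' alternative to [delong_ci()].
#'
#' @inheritParams delong_ci
#' @param B Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return List of class `auc_ci`.
#' @export
bootstrap_ci <- function(scores, labels, positive = "AD", level = 0.95,
                         B = 2000L, seed = 1L) {
  lab <- as.character(labels) == positive
  if (sum(lab) < 2 || sum(!lab) < 2) {
    stop_retispec("need at least 2 subjects per class",
                  "retispec_degenerate_label_error")
  }
  pos <- scores[lab]; neg <- scores[!lab]
  auc_fast <- function(p, n) {
    r <- rank(c(p, n))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(n))
  }
  reps <- with_seed(seed, vapply(seq_len(B), function(i) {
    auc_fast(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
  }, numeric(1)))
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(auc = auc_fast(pos, neg), lo = qs[1], hi = qs[2],
                 se = stats::sd(reps), level = level,
                 method = sprintf("bootstrap (B = %d)", B)),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f, %d%% CI [%.3f, %.3f] (%s)\n", x$auc,
              round(100 * x$level), x$lo, x$hi, x$method))
  invisible(x)
}
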