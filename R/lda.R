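# Linear discriminant analysis with a small diagonal shrinkage term.
# Authored from first principles: class means, pooled within-class
# covariance (divisor n - 2), effective covariance Sigma + eps I with
# eps = shrinkage * trace(Sigma) / p, empirical priors, Gaussian
# discriminants.  The shrinkage is the only departure from textbook LDA
# and exists to keep p ~ n fits (19 features on 38 samples) well posed.

# Lean fitter used by the cross-validation engines: x numeric matrix,
# y01 logical (TRUE = positive class).  No validation, no dispatch.
.lda_fit <- function(x, y01, shrinkage = 1e-6) {
  x1 <- x[y01, , drop = FALSE]; x0 <- x[!y01, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0); p <- ncol(x)
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  S <- (crossprod(sweep(x1, 2, mu1, "-")) +
        crossprod(sweep(x0, 2, mu0, "-"))) / (n1 + n0 - 2)
  eps <- max(shrinkage * sum(diag(S)) / p, 1e-300)
  diag(S) <- diag(S) + eps
  a <- solve(S, mu1 - mu0)                      # discriminant direction
  list(a = a,
       b = -0.5 * sum((mu1 + mu0) * a) + log(n1 / n0),
       mu1 = mu1, mu0 = mu0, eps = eps)
}

.lda_prob <- function(fit, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stats::plogis(drop(x %*% fit$a) + fit$b)
}

# Standardization helper: z-score columns by training-fold statistics.
.zstats <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
.zapply <- function(x, z) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(sweep(x, 2, z$center, "-"), 2, z$scale, "/")
}

#' Fit a linear discriminant classifier
#'
#' Two-class Gaussian classifier with shared covariance: class means,
#' pooled within-class covariance with divisor `n - 2`, empirical class
#' priors, and an effective covariance `Sigma + eps I` with
#' `eps = shrinkage * trace(Sigma) / p` so that near-collinear or
#' `p ~ n` designs remain well posed.
#'
#' @param x Numeric feature matrix (n x p).
#' @param y Class labels with exactly two levels present.
#' @param positive Label of the positive class whose posterior
#'   [predict_proba()] reports (default `"AD"`, falling back to the
#'   second factor level when absent).
#' @param shrinkage Relative ridge `eps / (trace(Sigma)/p)`.
#' @param standardize Z-score each feature using the training data
#'   (stored in the model and applied to new data).  Keeps um-scale RNFL
#'   features from dominating the pooled covariance.
#' @return Object of class `retispec_lda`.
#' @export
fit_lda <- function(x, y, positive = "AD", shrinkage = 1e-6,
                    standardize = FALSE) {
  x <- as.matrix(x)
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2L) {
    stop_retispec("y must contain exactly two classes",
                  "retispec_degenerate_label_error")
  }
  if (!positive %in% lev) positive <- lev[2]
  y01 <- y == positive
  z <- NULL
  if (standardize) {
    z <- .zstats(x)
    x <- .zapply(x, z)
  }
  fit <- .lda_fit(x, y01, shrinkage)
  structure(list(fit = fit, positive = positive,
                 negative = setdiff(lev, positive),
                 priors = c(mean(y01), 1 - mean(y01)),
                 p = ncol(x), z = z, shrinkage = shrinkage),
            class = "retispec_lda")
}

#' Posterior probability of the positive class
#'
#' Evaluates the two Gaussian discriminants
#' `delta_k(x) = x' (Sigma + eps I)^-1 mu_k - 1/2 mu_k' (Sigma + eps I)^-1 mu_k + log pi_k`
#' and returns the softmax posterior of the positive (AD) class.
#'
#' @param model A [fit_lda()] model.
#' @param x Feature vector or matrix with matching dimensionality.
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "retispec_lda"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$p) {
    stop_retispec("feature dimensionality does not match the model",
                  "retispec_shape_error")
  }
  if (!is.null(model$z)) x <- .zapply(x, model$z)
  .lda_prob(model$fit, x)
}

#' @export
predict.retispec_lda <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p
  else ifelse(p >= 0.5, object$positive, object$negative)
}

#' @export
print.retispec_lda <- function(x, ...) {
  cat(sprintf("LDA classifier: %d features, positive class '%s', priors %.2f/%.2f%s\n",
              x$p, x$positive, x$priors[1], x$priors[2],
              if (!is.null(x$z)) ", z-scored features" else ""))
  invisible(x)
}
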