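# Nested leave-one-out cross-validation with inner-loop configuration
# selection.  The outer loop estimates performance on subjects never seen
# by the selection step; the inner loop, run on each outer training set,
# scores every candidate feature configuration by its own LOOCV AUC.

# Held-out probabilities for every leave-one-out fold.  The compiled
# kernel carries the n * (fit + predict) hot loop; the R route is the
# reference implementation the unit tests pin it against.
.loocv_probs <- function(x, y01, shrinkage, standardize,
                         engine = "cpp") {
  if (engine == "cpp") {
    return(as.numeric(lda_loocv_probs_cpp(x, as.integer(y01), shrinkage,
                                          standardize)))
  }
  n <- nrow(x)
  probs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr01 <- y01[-i]
    if (all(tr01) || !any(tr01)) next
    xt <- x[-i, , drop = FALSE]
    xi <- x[i, , drop = FALSE]
    if (standardize) {
      z <- .zstats(xt)
      xt <- .zapply(xt, z); xi <- .zapply(xi, z)
    }
    probs[i] <- .lda_prob(.lda_fit(xt, tr01, shrinkage), xi)
  }
  probs
}

#' Leave-one-out cross-validated AUC for one configuration
#'
#' For each subject i, fits the LDA on the remaining n - 1 subjects
#' (z-scoring features on that training fold when `standardize = TRUE`)
#' and records the held-out posterior probability; returns the AUC over
#' the n held-out probabilities.  A fold whose training set loses one
#' class entirely (a class of size 1 being held out) is skipped with a
#' warning.
#'
#' @param x Feature matrix (n x p).
#' @param y Class labels (two levels).
#' @param positive Positive class label.
#' @param shrinkage,standardize Passed to the LDA (see [fit_lda()]).
#' @param engine `"cpp"` (compiled hot loop, default) or `"r"` (reference
#'   implementation); both produce identical probabilities.
#' @return List of class `loocv_result`: `auc`, `probs` (held-out
#'   probability per subject, `NA` for skipped folds), `n_skipped`.
#' @export
inner_loocv_auc <- function(x, y, positive = "AD", shrinkage = 1e-6,
                            standardize = TRUE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (n < 4L || length(unique(y)) != 2L) {
    stop_retispec("need n >= 4 with both classes present",
                  "retispec_degenerate_label_error")
  }
  if (!positive %in% y) positive <- unique(y)[2]
  y01 <- y == positive
  probs <- .loocv_probs(x, y01, shrinkage, standardize, engine)
  skipped <- sum(is.na(probs))
  if (skipped > 0L) {
    warning("degenerate inner fold (single class in training set); skipped")
  }
  ok <- !is.na(probs)
  auc <- if (length(unique(y[ok])) == 2L) {
    roc_auc(probs[ok], y[ok], positive)
  } else {
    warning("scored folds contain a single class; AUC undefined")
    NA_real_
  }
  structure(list(auc = auc, probs = probs, n_skipped = skipped),
            class = "loocv_result")
}

#' Nested leave-one-out cross-validation with configuration selection
#'
#' Outer loop: hold out one subject at a time (n folds for n subjects).
#' Inner loop: on the remaining n - 1 subjects, score every candidate
#' feature configuration by [inner_loocv_auc()] and select the one with
#' the maximal inner AUC (ties broken towards fewer features, then the
#' fixed order in which `features` is supplied).  The selected
#' configuration is refit on the full outer training set and the held-out
#' subject's AD probability recorded.  After all folds, the outer AUC
#' over the n held-out probabilities is reported with its confidence
#' interval.  Because selection happens inside each outer fold, the outer
#' AUC is an unbiased performance estimate (no selection leakage).
#'
#' @param features Named list of feature matrices (one per candidate
#'   configuration, e.g. `S1`, `I2`, `S1+RNFL`, `I2+RNFL`), all with the
#'   same subject order.
#' @param y Class labels (two levels).
#' @param positive Positive class label.
#' @param shrinkage,standardize Passed to the LDA.
#' @param ci `"delong"` (default) or `"bootstrap"`.
#' @param level Confidence level.
#' @param config_filter Optional `function(train_idx)` returning the
#'   names of the configurations admissible in that outer fold (used for
#'   strict in-fold SEM screening); `NULL` admits all.
#' @return Object of class `nested_cv`: per-fold held-out probability and
#'   selected configuration, the fold x configuration inner-AUC table,
#'   outer AUC with CI, and a selection tally.
#' @export
nested_loocv <- function(features, y, positive = "AD", shrinkage = 1e-6,
                         standardize = TRUE, ci = c("delong", "bootstrap"),
                         level = 0.95, config_filter = NULL) {
  ci <- match.arg(ci)
  stopifnot(is.list(features), length(features) >= 1L,
            !is.null(names(features)))
  features <- lapply(features, as.matrix)
  n <- nrow(features[[1]])
  if (!all(vapply(features, nrow, integer(1)) == n)) {
    stop_retispec("all configurations must share the subject order",
                  "retispec_shape_error")
  }
  if (n < 5L) {
    stop_retispec("need at least 5 subjects", "retispec_parameter_error")
  }
  y <- as.character(y)
  cfg_names <- names(features)
  n_feat <- vapply(features, ncol, integer(1))
  inner_auc <- matrix(NA_real_, n, length(cfg_names),
                      dimnames = list(NULL, cfg_names))
  selected <- character(n)
  probs <- rep(NA_real_, n)
  screened <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    cand <- cfg_names
    if (!is.null(config_filter)) {
      cand <- intersect(cfg_names, config_filter(tr))
      screened[[i]] <- cand
      if (!length(cand)) {
        selected[i] <- NA_character_
        warning(sprintf("fold %d: no configuration passed screening", i))
        next
      }
    }
    for (cfg in cand) {
      inner_auc[i, cfg] <- inner_loocv_auc(
        features[[cfg]][tr, , drop = FALSE], y[tr], positive,
        shrinkage, standardize)$auc
    }
    aucs <- inner_auc[i, cand]
    best <- cand[aucs >= max(aucs) - 1e-12]
    best <- best[order(n_feat[best], match(best, cfg_names))][1]
    selected[i] <- best
    xt <- features[[best]][tr, , drop = FALSE]
    xi <- features[[best]][i, , drop = FALSE]
    if (standardize) {
      z <- .zstats(xt)
      xt <- .zapply(xt, z); xi <- .zapply(xi, z)
    }
    probs[i] <- .lda_prob(.lda_fit(xt, y[tr] == positive, shrinkage), xi)
  }
  ok <- !is.na(probs)
  ci_fun <- if (ci == "delong") delong_ci else bootstrap_ci
  outer_ci <- ci_fun(probs[ok], y[ok], positive, level)
  structure(list(
    probs = probs, y = y, positive = positive,
    selected = selected,
    selection_tally = table(factor(selected, levels = cfg_names)),
    inner_auc = inner_auc,
    auc = outer_ci$auc, ci = c(outer_ci$lo, outer_ci$hi),
    ci_method = outer_ci$method, level = level,
    screened = if (!is.null(config_filter)) screened else NULL,
    n_folds = n
  ), class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("Nested LOOCV over %d folds\n", x$n_folds))
  cat(sprintf("  outer AUC %.3f, %d%% CI [%.3f, %.3f] (%s)\n",
              x$auc, round(100 * x$level), x$ci[1], x$ci[2], x$ci_method))
  tally <- x$selection_tally
  cat("  configuration selections:",
      paste(sprintf("%s %d/%d", names(tally), as.integer(tally), x$n_folds),
            collapse = ", "), "\n")
  invisible(x)
}

#' Single-level LOOCV with post-hoc configuration selection
#'
#' The optimistically biased alternative to [nested_loocv()]: each
#' configuration's LOOCV AUC is computed once on the full data and the
#' best value reported.  Because the same data select the configuration
#' and estimate its performance, the resulting AUC is inflated on null
#' data; it exists for demonstrating that bias.
#'
#' @inheritParams nested_loocv
#' @return List with the winning configuration and its AUC.
#' @export
single_level_selection_auc <- function(features, y, positive = "AD",
                                       shrinkage = 1e-6, standardize = TRUE) {
  aucs <- vapply(features, function(x) {
    inner_loocv_auc(x, y, positive, shrinkage, standardize)$auc
  }, numeric(1))
  list(config = names(which.max(aucs)), auc = max(aucs), all_auc = aucs)
}
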