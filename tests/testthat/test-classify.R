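# LDA, ROC/AUC, DeLong and bootstrap CIs, LOOCV engines.

test_that("LDA posterior is 0.5 at the midpoint of symmetric classes", {
  x <- matrix(c(0, 2, -2, 0), ncol = 1)
  y <- c("AD", "AD", "CTRL", "CTRL")
  m <- fit_lda(x, y)
  expect_equal(predict_proba(m, matrix(0, 1, 1)), 0.5, tolerance = 1e-9)
  expect_gt(predict_proba(m, matrix(10, 1, 1)), 0.999)   # deep in AD territory
  expect_lt(predict_proba(m, matrix(-10, 1, 1)), 0.001)
  expect_error(fit_lda(x, rep("AD", 4)),
               class = "retispec_degenerate_label_error")
  expect_error(predict_proba(m, matrix(0, 1, 3)),
               class = "retispec_shape_error")
})

test_that("posteriors of the two classes are complementary", {
  d <- make_features(30, 4, shift = 1, seed = 3)
  m_ad <- fit_lda(d$x, d$y, positive = "AD")
  m_ctrl <- fit_lda(d$x, d$y, positive = "CTRL")
  p1 <- predict_proba(m_ad, d$x)
  p2 <- predict_proba(m_ctrl, d$x)
  expect_equal(p1 + p2, rep(1, 30), tolerance = 1e-9)
})

test_that("shrinkage keeps perfectly collinear designs fit-able", {
  d <- make_features(24, 1, shift = 2, seed = 9)
  m1 <- fit_lda(d$x, d$y)
  m2 <- fit_lda(cbind(d$x, d$x), d$y)   # duplicated feature
  p1 <- predict_proba(m1, d$x)
  p2 <- predict_proba(m2, cbind(d$x, d$x))
  expect_lt(max(abs(p1 - p2)), 1e-3)
})

test_that("posteriors match the reference LDA implementation within 1e-6", {
  skip_if_not_installed("MASS")
  for (s in 1:20) {
    d <- make_features(20, 5, shift = runif(1, 0, 2), seed = 100 + s)
    # shrinkage lowered to isolate the textbook LDA computation; the
    # default 1e-6 ridge perturbs posteriors by about its own magnitude
    m <- fit_lda(d$x, d$y, positive = "AD", standardize = FALSE,
                 shrinkage = 1e-10)
    ref <- MASS::lda(d$x, grouping = d$y)
    p_ref <- predict(ref, d$x)$posterior[, "AD"]
    expect_lt(max(abs(predict_proba(m, d$x) - p_ref)), 1e-6)
  }
})

test_that("predictions are invariant to affine feature transformations", {
  d <- make_features(30, 5, shift = 1.5, seed = 7)
  set.seed(11)
  A <- matrix(runif(25, -1, 1), 5, 5) + diag(5)
  b <- runif(5)
  xt <- d$x %*% A + matrix(b, 30, 5, byrow = TRUE)
  # invariance is exact for textbook LDA; the diagonal ridge is not
  # affine-equivariant, so it is scaled out of this comparison
  p0 <- predict_proba(fit_lda(d$x, d$y, standardize = FALSE,
                              shrinkage = 1e-12), d$x)
  p1 <- predict_proba(fit_lda(xt, d$y, standardize = FALSE,
                              shrinkage = 1e-12), xt)
  expect_lt(max(abs(p0 - p1)), 1e-6)
})

test_that("AUC counts concordant pairs (hand case) and handles degeneracies", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c("AD", "CTRL", "AD", "CTRL")),
               0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c("AD", "AD", "CTRL", "CTRL")), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("AD", "CTRL"), 5)), 0.5)
  expect_error(roc_auc(1:4, rep("AD", 4)),
               class = "retispec_degenerate_label_error")
})

test_that("AUC equals the Mann-Whitney U formula on tie-free data", {
  set.seed(21)
  for (r in 1:10) {
    pos <- rnorm(8, 0.5); neg <- rnorm(11)
    u <- unname(wilcox.test(pos, neg, exact = TRUE)$statistic)
    expect_equal(roc_auc(c(pos, neg), rep(c("AD", "CTRL"), c(8, 11))),
                 u / (8 * 11))
  }
})

test_that("DeLong CI collapses for perfect separation and always brackets the AUC", {
  ci <- delong_ci(c(3, 2, 1, -1, -2, -3), rep(c("AD", "CTRL"), each = 3))
  expect_equal(ci$auc, 1)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  set.seed(31)
  for (r in 1:20) {
    sc <- rnorm(30)
    lab <- rep(c("AD", "CTRL"), 15)
    ci <- delong_ci(sc, lab)
    expect_lte(ci$lo, ci$auc); expect_gte(ci$hi, ci$auc)
    expect_gte(ci$lo, 0); expect_lte(ci$hi, 1)
  }
})

test_that("DeLong interval width tracks the bootstrap width", {
  set.seed(41)
  widths <- t(sapply(1:100, function(r) {
    sc <- c(rnorm(20, 0.8), rnorm(25))
    lab <- rep(c("AD", "CTRL"), c(20, 25))
    d <- delong_ci(sc, lab)
    b <- bootstrap_ci(sc, lab, B = 1000, seed = r)
    c(d$hi - d$lo, b$hi - b$lo)
  }))
  expect_lt(abs(mean(widths[, 1]) / mean(widths[, 2]) - 1), 0.15)
})

test_that("compiled and reference LOOCV engines agree to machine precision", {
  for (s in 1:5) {
    d <- make_features(24, 6, shift = runif(1, 0, 2), seed = 900 + s)
    for (std in c(TRUE, FALSE)) {
      p_cpp <- inner_loocv_auc(d$x, d$y, standardize = std, engine = "cpp")
      p_r <- inner_loocv_auc(d$x, d$y, standardize = std, engine = "r")
      expect_equal(p_cpp$probs, p_r$probs, tolerance = 1e-12)
      expect_equal(p_cpp$auc, p_r$auc)
    }
  }
})

test_that("inner LOOCV is deterministic and detects a strong class separation", {
  d <- make_features(40, 5, shift = 3, seed = 17)
  r1 <- inner_loocv_auc(d$x, d$y)
  r2 <- inner_loocv_auc(d$x, d$y)
  expect_identical(r1, r2)
  expect_gte(r1$auc, 0.95)
  expect_equal(sum(is.na(r1$probs)), 0)
})

test_that("null-feature inner LOOCV AUC is centered near chance", {
  aucs <- vapply(1:60, function(r) {
    d <- make_features(40, 5, shift = 0, seed = 600 + r)
    inner_loocv_auc(d$x, d$y)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("degenerate folds are skipped with a warning", {
  set.seed(61)
  x <- matrix(rnorm(12), 6, 2)
  y <- c("AD", rep("CTRL", 5))  # single AD: its fold cannot be scored
  warns <- capture_warnings(r <- inner_loocv_auc(x, y))
  expect_true(any(grepl("degenerate inner fold", warns)))
  expect_true(is.na(r$probs[1]))
  expect_equal(r$n_skipped, 1)
  expect_true(is.na(r$auc))  # remaining scored folds are single-class here
})

test_that("nested LOOCV produces one fold and one selection per subject", {
  d1 <- make_features(14, 3, shift = 2, seed = 71)
  feats <- list(S1 = d1$x,
                I2 = matrix(rnorm(14 * 3), 14, 3),
                `S1+RNFL` = cbind(d1$x, matrix(rnorm(14 * 2), 14, 2)))
  res <- nested_loocv(feats, d1$y)
  expect_equal(res$n_folds, 14)
  expect_length(res$probs, 14)
  expect_length(res$selected, 14)
  expect_true(all(res$probs >= 0 & res$probs <= 1))
  expect_true(all(res$selected %in% names(feats)))
  expect_equal(sum(res$selection_tally), 14)
  expect_equal(dim(res$inner_auc), c(14, 3))
  # deterministic
  expect_identical(res$probs, nested_loocv(feats, d1$y)$probs)
  # ties break towards fewer features: identical configs, smaller one wins
  tie <- list(big = cbind(d1$x, d1$x), small = d1$x)
  res_tie <- nested_loocv(tie, d1$y)
  expect_true(all(res_tie$selected == "small" |
                  res_tie$inner_auc[, "big"] > res_tie$inner_auc[, "small"]))
})

test_that("the strongest configuration dominates selection", {
  d <- make_features(20, 5, shift = 3, seed = 81)
  feats <- list(noise1 = matrix(rnorm(100), 20, 5),
                signal = d$x,
                noise2 = matrix(rnorm(100), 20, 5))
  res <- nested_loocv(feats, d$y)
  expect_gte(mean(res$selected == "signal"), 0.9)
  expect_gte(res$auc, 0.9)
})
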