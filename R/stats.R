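#' Pooled two-sample t-test from summary statistics
#'
#' Independent-samples t-test with pooled variance, computed directly
#' from the group means, SDs and sizes (as printed in a demographics
#' table), with `df = n1 + n2 - 2` and a two-sided p-value.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return Object of class `stat_result` with `test`, `statistic`, `df`,
#'   `p`.
#' @examples
#' pooled_t_test_summary(71.9, 6.6, 17, 68.6, 8.4, 22)  # age, p ~ 0.19
#' @export
pooled_t_test_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2 || s1 <= 0 || s2 <= 0) {
    stop_retispec("need n >= 2 and SD > 0 in both groups",
                  "retispec_parameter_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  stat_result("pooled t", statistic = t, df = df,
              p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison.  The exact null distribution of U is
#' used when `n1 * n2 <= 400` and there are no ties; otherwise the normal
#' approximation with tie-corrected variance (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   distribution.
#' @return `stat_result` with the U statistic (number of (x, y) pairs
#'   with x > y, ties counting one half) and two-sided p.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) {
    stop_retispec("both samples must be non-empty", "retispec_parameter_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  stat_result(if (exact && !ties) "Mann-Whitney (exact)"
              else "Mann-Whitney (normal approx.)",
              statistic = unname(wt$statistic), df = NA_real_,
              p = min(wt$p.value, 1))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @return `stat_result`.
#' @examples
#' chi_square_2x2(matrix(c(10, 10, 7, 12), 2))  # eye laterality, p ~ 0.408
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table))) {
    stop_retispec("need a 2x2 table of non-negative integer counts",
                  "retispec_parameter_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_retispec("all margins must be positive", "retispec_parameter_error")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_result("Pearson chi-square", statistic = unname(ct$statistic),
              df = 1, p = ct$p.value)
}

#' Covariate-adjusted group effect by multivariate linear regression
#'
#' Ordinary least squares of the outcome on intercept + group + age +
#' gender + scan quality; returns the group coefficient (effect of the
#' second group level relative to the first), its t statistic with
#' `df = n - 5`, and the two-sided p-value.  Used for the RNFL
#' parameters, which are corrected for age, gender and scan quality.
#'
#' @param y Numeric outcome (e.g. RNFL thickness, um).
#' @param group Two-level factor or character; the reported coefficient
#'   is for the second level vs the first ("CTRL" is used as reference
#'   when present).
#' @param age,quality Numeric covariates.
#' @param gender Two-level factor/character or numeric covariate.
#' @return `stat_result` with extra field `coefficient`.
#' @export
adjusted_group_effect <- function(y, group, age, gender, quality) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop_retispec("group must have exactly two levels",
                  "retispec_parameter_error")
  }
  if ("CTRL" %in% levels(group)) group <- stats::relevel(group, "CTRL")
  n <- length(y)
  if (n <= 5L) {
    stop_retispec("need more observations than predictors + 1",
                  "retispec_parameter_error")
  }
  dat <- data.frame(y = y, group = group, age = age,
                    gender = as.factor(gender), quality = quality)
  fit <- stats::lm(y ~ group + age + gender + quality, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop_retispec("rank-deficient design (collinear covariates)",
                  "retispec_collinearity_error")
  }
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))
  res <- stat_result("adjusted OLS group effect",
                     statistic = sm[row, "t value"],
                     df = n - 5,
                     p = 2 * stats::pt(-abs(sm[row, "t value"]), n - 5))
  res$coefficient <- unname(sm[row, "Estimate"])
  res$se <- unname(sm[row, "Std. Error"])
  res
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m p)` for a family of `m` comparisons.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) {
    stop_retispec("family size m must be >= number of p-values",
                  "retispec_parameter_error")
  }
  pmin(m * p, 1)
}

stat_result <- function(test, statistic, df, p, p_adjusted = NULL) {
  structure(list(test = test, statistic = as.numeric(statistic),
                 df = as.numeric(df), p = as.numeric(p),
                 p_adjusted = p_adjusted),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g%s\n", x$test, x$statistic,
              if (is.finite(x$df)) sprintf(", df = %g", x$df) else "",
              x$p,
              if (!is.null(x$p_adjusted))
                sprintf(" (adjusted %.4g)", x$p_adjusted) else ""))
  invisible(x)
}

#' Per-group spectral summary (means and SEMs)
#'
#' For each ROI and band, the group mean spectrum and its standard error
#' of the mean `SEM_g = s_g / sqrt(n_g)`.
#'
#' @param spectra 3-d array `subject x ROI x band` (dimnames on the ROI
#'   axis identify the ROIs).
#' @param groups Group label per subject (two levels, e.g. AD/CTRL).
#' @return List of class `group_spectral_summary`, one element per ROI
#'   with matrices `mean` and `sem` (group x band).
#' @export
group_spectral_summary <- function(spectra, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) {
    stop_retispec("need at least 2 subjects per group",
                  "retispec_parameter_error")
  }
  rois <- dimnames(spectra)[[2]] %||% sprintf("ROI%d", seq_len(dim(spectra)[2]))
  out <- lapply(seq_along(rois), function(r) {
    m <- sapply(levels(groups), function(g) {
      colMeans(spectra[groups == g, r, , drop = FALSE][, 1, ])
    })
    s <- sapply(levels(groups), function(g) {
      x <- spectra[groups == g, r, , drop = FALSE][, 1, ]
      apply(x, 2, stats::sd) / sqrt(sum(groups == g))
    })
    list(roi_id = rois[r], mean = t(m), sem = t(s))
  })
  names(out) <- rois
  structure(out, class = "group_spectral_summary")
}

#' SEM-overlap screening of ROIs
#'
#' An ROI enters the model-selection procedure if, for at least one
#' wavelength, the `mean +/- 1 SEM` intervals of the two groups'
#' average spectra do not overlap, i.e. `|m_1 - m_2| > SEM_1 + SEM_2`.
#'
#' @inheritParams group_spectral_summary
#' @return Character vector of selected ROI ids (possibly empty).
#' @export
sem_screen <- function(spectra, groups) {
  gs <- group_spectral_summary(spectra, groups)
  sel <- vapply(gs, function(x) {
    any(abs(x$mean[1, ] - x$mean[2, ]) > x$sem[1, ] + x$sem[2, ])
  }, logical(1))
  names(gs)[sel]
}

#' Demographics and clinical comparison table
#'
#' Reproduces the standard cohort characteristics battery on a simulated
#' (or real) cohort data frame: pooled t-tests for continuous variables,
#' Mann-Whitney for MMSE (ordinal), chi-square for dichotomous variables,
#' and covariate-adjusted regression (age, gender, scan quality) with
#' Bonferroni correction (m = 5) for the five RNFL parameters.
#'
#' @param cohort Data frame from [generate_cohort()] (or same columns).
#' @return Data frame with one row per parameter: group summaries, test
#'   name, p, and adjusted p for the RNFL family.
#' @export
cohort_table <- function(cohort) {
  g <- factor(cohort$group, levels = c("AD", "CTRL"))
  msd <- function(v, grp) {
    x <- v[g == grp]
    sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  }
  cont_row <- function(name, v) {
    r <- pooled_t_test_summary(mean(v[g == "AD"]), stats::sd(v[g == "AD"]),
                               sum(g == "AD"),
                               mean(v[g == "CTRL"]), stats::sd(v[g == "CTRL"]),
                               sum(g == "CTRL"))
    data.frame(parameter = name, ad = msd(v, "AD"), ctrl = msd(v, "CTRL"),
               test = r$test, p = r$p, p_adjusted = NA_real_)
  }
  bin_row <- function(name, v, lev) {
    tab <- table(factor(v, levels = lev), g)
    r <- chi_square_2x2(t(tab))
    fmt <- function(grp) paste(tab[, grp], collapse = "/")
    data.frame(parameter = name, ad = fmt("AD"), ctrl = fmt("CTRL"),
               test = r$test, p = r$p, p_adjusted = NA_real_)
  }
  mw <- mann_whitney(cohort$mmse[g == "AD"], cohort$mmse[g == "CTRL"])
  rows <- rbind(
    cont_row("Age (years)", cohort$age),
    data.frame(parameter = "Sex (male/female)",
               ad = paste(sum(cohort$sex[g == "AD"] == "M"),
                          sum(cohort$sex[g == "AD"] == "F"), sep = "/"),
               ctrl = paste(sum(cohort$sex[g == "CTRL"] == "M"),
                            sum(cohort$sex[g == "CTRL"] == "F"), sep = "/"),
               test = "Pearson chi-square",
               p = chi_square_2x2(table(cohort$sex, g))$p,
               p_adjusted = NA_real_),
    cont_row("Body mass index (kg/m2)", cohort$bmi),
    bin_row("Eye (right/left)", cohort$eye, c("right", "left")),
    data.frame(parameter = "MMSE",
               ad = msd(cohort$mmse, "AD"), ctrl = msd(cohort$mmse, "CTRL"),
               test = mw$test, p = mw$p, p_adjusted = NA_real_),
    cont_row("BCVA (logMAR)", cohort$bcva),
    cont_row("IOP (mmHg)", cohort$iop),
    bin_row("Phakic (yes/no)", cohort$phakic, c("TRUE", "FALSE")),
    cont_row("Vertical cup/disc ratio", cohort$vcdr)
  )
  rnfl_cols <- c(`RNFL_AVG (um)` = "rnfl_avg", `RNFL_SUP (um)` = "rnfl_sup",
                 `RNFL_INF (um)` = "rnfl_inf", `RNFL_TEM (um)` = "rnfl_tem",
                 `RNFL_NAS (um)` = "rnfl_nas")
  rnfl_res <- lapply(rnfl_cols, function(cl) {
    adjusted_group_effect(cohort[[cl]], g, cohort$age, cohort$sex,
                          cohort$scan_quality)
  })
  p_rnfl <- vapply(rnfl_res, `[[`, numeric(1), "p")
  p_adj <- bonferroni(p_rnfl, m = 5)
  rnfl_rows <- do.call(rbind, lapply(seq_along(rnfl_cols), function(i) {
    data.frame(parameter = names(rnfl_cols)[i],
               ad = msd(cohort[[rnfl_cols[i]]], "AD"),
               ctrl = msd(cohort[[rnfl_cols[i]]], "CTRL"),
               test = "adjusted OLS group effect",
               p = p_rnfl[i], p_adjusted = p_adj[i])
  }))
  out <- rbind(rows, rnfl_rows)
  rownames(out) <- NULL
  out
}
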