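# Cohort generator: determinism, degenerate variance, calibration against
# the demographic/RNFL targets.

test_that("cohort generation is deterministic and reproduces group sizes", {
  spec <- cohort_spec(n_ad = 17, n_ctrl = 22, seed = 404)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(sum(a$group == "AD"), 17)
  expect_equal(sum(a$group == "CTRL"), 22)
  expect_true(all(a$mmse >= 0 & a$mmse <= 30))
  expect_true(all(a$rnfl_avg > 0))
  expect_true(all(a$amyloid_load[a$group == "CTRL"] == 0))
  expect_true(all(a$amyloid_load[a$group == "AD"] > 0))
})

test_that("default cohort RNFL means sit near the published group targets", {
  co <- generate_cohort(cohort_spec(n_ad = 17, n_ctrl = 22, seed = 11))
  m_ad <- mean(co$rnfl_avg[co$group == "AD"])
  m_c <- mean(co$rnfl_avg[co$group == "CTRL"])
  expect_lt(abs(m_ad - 84.8), 3 * 7.5 / sqrt(17))
  expect_lt(abs(m_c - 92.1), 3 * 7.3 / sqrt(22))
})

test_that("large-sample group means calibrate within 3 SE of their targets", {
  n <- 200L
  spec <- cohort_spec(n_ad = n, n_ctrl = n, seed = 42)
  co <- generate_cohort(spec)
  check <- function(var, ad_target, ctrl_target, ad_sd, ctrl_sd) {
    expect_lt(abs(mean(co[[var]][co$group == "AD"]) - ad_target),
              3 * ad_sd / sqrt(n))
    expect_lt(abs(mean(co[[var]][co$group == "CTRL"]) - ctrl_target),
              3 * ctrl_sd / sqrt(n))
  }
  check("age", 71.9, 68.6, 6.6, 8.4)
  check("bmi", 24.9, 26.0, 2.9, 4.4)
  check("iop", 14, 15, 3, 4)
  check("rnfl_avg", 84.8, 92.1, 7.5, 7.3)
  check("rnfl_inf", 104.3, 115.6, 11.1, 11.4)
  check("rnfl_tem", 63.3, 70.4, 8.1, 6.7)
  # MMSE in controls is clipped at the 30-point ceiling; the attainable
  # mean is that of the clipped normal, computed here in closed form
  z <- (30 - 29.3) / 0.9
  mmse_ctrl_target <- 29.3 - 0.9 * (dnorm(z) - z * (1 - pnorm(z)))
  expect_lt(abs(mean(co$mmse[co$group == "CTRL"]) - mmse_ctrl_target),
            3 * 0.9 / sqrt(n))
  expect_lt(abs(mean(co$mmse[co$group == "AD"]) - 17.6), 3 * 5.5 / sqrt(n))
  # proportions: binomial 3-SE bands
  p_band <- function(obs, p) expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  p_band(mean(co$sex[co$group == "AD"] == "M"), 7 / 17)
  p_band(mean(co$phakic[co$group == "CTRL"]), 12 / 22)
  p_band(mean(co$eye[co$group == "AD"] == "right"), 10 / 17)
})

test_that("zero-variance spec with null effect collapses each group to one record", {
  dp <- default_demographics_zero <- local({
    dp <- list(
      age = list(ad = c(70, 0), ctrl = c(65, 0)),
      sex_m = list(ad = 1, ctrl = 0),
      bmi = list(ad = c(25, 0), ctrl = c(26, 0)),
      eye_r = list(ad = 1, ctrl = 1),
      mmse = list(ad = c(18, 0), ctrl = c(29, 0)),
      bcva = list(ad = c(0.1, 0), ctrl = c(0.05, 0)),
      iop = list(ad = c(14, 0), ctrl = c(15, 0)),
      phakic = list(ad = 1, ctrl = 0),
      vcdr = list(ad = c(0.5, 0), ctrl = c(0.5, 0)),
      scan_quality = list(ad = c(50, 0), ctrl = c(60, 0))
    )
    dp
  })
  zero_sds <- c(AVG = 0, SUP = 0, INF = 0, TEM = 0, NAS = 0)
  spec <- cohort_spec(n_ad = 4, n_ctrl = 4, seed = 9, scatter_amplitude = 0,
                      rnfl_sds = list(AD = zero_sds, CTRL = zero_sds),
                      demographic_params = dp)
  co <- generate_cohort(spec)
  drop_id <- setdiff(names(co), "subject_id")
  for (g in c("AD", "CTRL")) {
    rows <- co[co$group == g, drop_id]
    expect_true(all(vapply(rows, function(col) length(unique(col)) == 1,
                           logical(1))))
  }
})

test_that("invalid cohort specs are refused", {
  expect_error(cohort_spec(n_ad = 0), class = "retispec_parameter_error")
  expect_error(cohort_spec(n_ad = 1, n_ctrl = 5),
               class = "retispec_parameter_error")
  expect_error(cohort_spec(scatter_amplitude = 1.5),
               class = "retispec_parameter_error")
})

# Phantom generator: null effect, wavelength^-4 monotonicity, vessel dip,
# coverage invariant.

test_that("phantoms are deterministic and satisfy their invariants", {
  cam <- small_camera(24, 48)
  sub <- manual_subject(load = 1)
  a <- generate_phantom(sub, cam, seed = 5)
  b <- generate_phantom(sub, cam, seed = 5)
  expect_identical(a$base_reflectance, b$base_reflectance)
  expect_identical(a$vessel_truth, b$vessel_truth)
  cov <- mean(a$vessel_truth)
  expect_gte(cov, 0.05); expect_lte(cov, 0.15)
  expect_true(all(is.finite(a$base_reflectance)))
  expect_true(all(a$base_reflectance >= 0))
  expect_false(all(a$od_center == a$fovea))
})

test_that("null effect makes AD and CTRL phantoms identically distributed", {
  cam <- small_camera(24, 48)
  ad <- manual_phantom_from <- generate_phantom(
    manual_subject("AD", load = 1.4), cam, seed = 7, scatter_amplitude = 0)
  ctrl <- generate_phantom(
    manual_subject("CTRL", load = 0), cam, seed = 7, scatter_amplitude = 0)
  expect_identical(ad$base_reflectance, ctrl$base_reflectance)
})

test_that("AD attenuation is strongest at short wavelengths and decays monotonically", {
  cam <- small_camera(32, 64)
  ad <- generate_phantom(manual_subject("AD", load = 1), cam, seed = 3,
                         scatter_amplitude = 0.1, pixel_noise_sd = 0)
  ctrl <- generate_phantom(manual_subject("CTRL", load = 0), cam, seed = 3,
                           scatter_amplitude = 0.1, pixel_noise_sd = 0)
  keep <- !ad$vessel_truth
  band_mean <- function(ph, b) mean(ph$base_reflectance[, , b][keep])
  ratio <- vapply(1:16, function(b) band_mean(ad, b) / band_mean(ctrl, b),
                  numeric(1))
  expect_lt(ratio[1], ratio[16])           # 465 nm dimmed more than 615 nm
  expect_true(all(diff(ratio) > 0))        # attenuation eases with wavelength
  diffs <- vapply(1:16, function(b) band_mean(ad, b) - band_mean(ctrl, b),
                  numeric(1))
  expect_true(all(diffs < 0))
  expect_true(all(diff(abs(diffs)) < 1e-12))  # |AD - CTRL| non-increasing
})

test_that("vessel pixels carry the configured hemoglobin dip", {
  cam <- small_camera(32, 64)
  ph <- generate_phantom(manual_subject("CTRL", load = 0), cam, seed = 13,
                         pixel_noise_sd = 0)
  lam <- cam$band_centers
  hb_bands <- which(lam >= 540 & lam <= 580)
  expected_factor <- mean(1 - 0.25 - 0.45 * exp(-((lam[hb_bands] - 560)^2) /
                                                  (2 * 18^2)))
  hb_img <- apply(ph$base_reflectance[, , hb_bands], c(1, 2), mean)
  measured <- mean(hb_img[ph$vessel_truth]) / mean(hb_img[!ph$vessel_truth])
  # gain-field inhomogeneity between vessel and background pixels adds a
  # few percent of slack around the spectral factor
  expect_lt(abs(measured - expected_factor), 0.05)
})
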