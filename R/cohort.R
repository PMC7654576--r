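#' Cohort simulation parameters
#'
#' Bundles everything needed to simulate a study cohort: group sizes, the
#' strength of the hypothesized short-wavelength scattering effect in the
#' AD group, per-group RNFL thickness means/SDs, and demographic/clinical
#' covariate distributions.  The defaults reproduce the demographic and
#' clinical profile of a memory-clinic cohort of 17 AD patients and 22
#' cognitively intact controls (age ~72 vs ~69 y, MMSE ~18 vs ~29, RNFL
#' average 84.8 vs 92.1 um, and so on).
#'
#' @param n_ad,n_ctrl Group sizes (each >= 2).
#' @param seed Integer seed; the whole simulated study is a deterministic
#'   function of the spec (including the seed).
#' @param scatter_amplitude Unitless effect strength `a` in \[0, 1\] of the
#'   amyloid-driven Rayleigh-scattering attenuation applied to AD retinas
#'   (reflectance multiplied by `1 - a * load * (460/lambda)^4`).  The
#'   magnitude of this effect in reflectance units is not an estimate from
#'   data; it is a free simulation parameter.
#' @param rnfl_ad_means,rnfl_ctrl_means Named numeric vectors (um) for
#'   parameters AVG, SUP, INF, TEM, NAS.
#' @param rnfl_sds List with elements `AD` and `CTRL`: per-parameter SDs (um).
#' @param demographic_params List of per-variable specifications; continuous
#'   variables as `list(ad = c(mean, sd), ctrl = c(mean, sd))`, dichotomous
#'   ones as `list(ad = prop, ctrl = prop)` (proportion of the first level).
#' @param pixel_noise_sd Per-pixel reflectance noise SD used by
#'   [generate_phantom()].
#' @return Object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_ad = 17L, n_ctrl = 22L, seed = 20201110L,
                        scatter_amplitude = 0.1,
                        rnfl_ad_means = c(AVG = 84.8, SUP = 104.2, INF = 104.3,
                                          TEM = 63.3, NAS = 66.3),
                        rnfl_ctrl_means = c(AVG = 92.1, SUP = 109.8, INF = 115.6,
                                            TEM = 70.4, NAS = 72.7),
                        rnfl_sds = list(
                          AD   = c(AVG = 7.5, SUP = 8.9, INF = 11.1,
                                   TEM = 8.1, NAS = 11.7),
                          CTRL = c(AVG = 7.3, SUP = 12.4, INF = 11.4,
                                   TEM = 6.7, NAS = 8.6)),
                        demographic_params = NULL,
                        pixel_noise_sd = 0.02) {
  if (is.null(demographic_params)) demographic_params <- default_demographics()
  spec <- structure(list(
    n_ad = as.integer(n_ad), n_ctrl = as.integer(n_ctrl),
    seed = as.integer(seed),
    scatter_amplitude = scatter_amplitude,
    rnfl_ad_means = rnfl_ad_means, rnfl_ctrl_means = rnfl_ctrl_means,
    rnfl_sds = rnfl_sds,
    demographic_params = demographic_params,
    pixel_noise_sd = pixel_noise_sd
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

# Demographic/clinical covariate distributions.  Continuous entries carry the
# group mean/SD; dichotomous entries the group proportion of the first level.
# scan_quality is the OCT image-quality index used as a regression covariate;
# its distribution (AD slightly worse) is a simulation choice.
default_demographics <- function() {
  list(
    age    = list(ad = c(71.9, 6.6),  ctrl = c(68.6, 8.4)),
    sex_m  = list(ad = 7 / 17,        ctrl = 12 / 22),
    bmi    = list(ad = c(24.9, 2.9),  ctrl = c(26.0, 4.4)),
    eye_r  = list(ad = 10 / 17,       ctrl = 10 / 22),
    mmse   = list(ad = c(17.6, 5.5),  ctrl = c(29.3, 0.9)),
    bcva   = list(ad = c(0.14, 0.11), ctrl = c(0.06, 0.08)),
    iop    = list(ad = c(14, 3),      ctrl = c(15, 4)),
    phakic = list(ad = 15 / 17,       ctrl = 12 / 22),
    vcdr   = list(ad = c(0.52, 0.15), ctrl = c(0.51, 0.21)),
    scan_quality = list(ad = c(52, 12), ctrl = c(60, 10))
  )
}

validate_cohort_spec <- function(spec) {
  ok_names <- c("AVG", "SUP", "INF", "TEM", "NAS")
  if (spec$n_ad < 2L || spec$n_ctrl < 2L) {
    stop_retispec("n_ad and n_ctrl must both be >= 2",
                  "retispec_parameter_error")
  }
  if (spec$scatter_amplitude < 0 || spec$scatter_amplitude > 1) {
    stop_retispec("scatter_amplitude must lie in [0, 1]",
                  "retispec_parameter_error")
  }
  if (!all(ok_names %in% names(spec$rnfl_ad_means)) ||
      !all(ok_names %in% names(spec$rnfl_ctrl_means)) ||
      !all(ok_names %in% names(spec$rnfl_sds$AD)) ||
      !all(ok_names %in% names(spec$rnfl_sds$CTRL))) {
    stop_retispec("RNFL parameters must be named AVG, SUP, INF, TEM, NAS",
                  "retispec_parameter_error")
  }
  if (any(unlist(spec$rnfl_sds) < 0) || spec$pixel_noise_sd < 0) {
    stop_retispec("standard deviations must be non-negative",
                  "retispec_parameter_error")
  }
  invisible(spec)
}

#' Simulate a study cohort
#'
#' Draws one subject record per participant: demographics and clinical
#' covariates from group-specific normals (clipped to their legal ranges)
#' or binomials, RNFL thickness (average + four quadrants) from the
#' group means/SDs, and a latent, strictly positive `amyloid_load` for AD
#' subjects (LogNormal(0, 0.25); zero for controls) that drives the
#' spectral effect in [generate_phantom()].  Deterministic given the spec
#' (which includes the seed).
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with one row per subject and columns
#'   `subject_id`, `group` ("AD"/"CTRL"), `age`, `sex`, `eye`, `bmi`,
#'   `mmse`, `bcva`, `iop`, `phakic`, `vcdr`, `rnfl_avg`, `rnfl_sup`,
#'   `rnfl_inf`, `rnfl_tem`, `rnfl_nas`, `scan_quality`, `amyloid_load`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_ad = 4, n_ctrl = 4, seed = 1))
#' table(cohort$group)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_ad + spec$n_ctrl
    group <- rep(c("AD", "CTRL"), c(spec$n_ad, spec$n_ctrl))
    dp <- spec$demographic_params
    draw_cont <- function(var, lo = -Inf, hi = Inf) {
      p <- dp[[var]]
      m <- ifelse(group == "AD", p$ad[1], p$ctrl[1])
      s <- ifelse(group == "AD", p$ad[2], p$ctrl[2])
      pmin(pmax(stats::rnorm(n, m, s), lo), hi)
    }
    draw_bin <- function(var, levels) {
      p <- ifelse(group == "AD", dp[[var]]$ad, dp[[var]]$ctrl)
      ifelse(stats::runif(n) < p, levels[1], levels[2])
    }
    rnfl <- sapply(c("AVG", "SUP", "INF", "TEM", "NAS"), function(q) {
      m <- ifelse(group == "AD", spec$rnfl_ad_means[q], spec$rnfl_ctrl_means[q])
      s <- ifelse(group == "AD", spec$rnfl_sds$AD[q], spec$rnfl_sds$CTRL[q])
      pmax(stats::rnorm(n, m, s), 1)
    })
    # latent amyloid severity: strictly positive and right-skewed for AD,
    # zero for controls; a null study (a = 0) carries no latent load at all
    load <- if (spec$scatter_amplitude == 0) numeric(n) else
      ifelse(group == "AD", stats::rlnorm(n, 0, 0.25), 0)
    data.frame(
      subject_id = sprintf("%s%03d", ifelse(group == "AD", "AD", "C"),
                           stats::ave(seq_len(n), group, FUN = seq_along)),
      group = group,
      age = draw_cont("age", 0),
      sex = draw_bin("sex_m", c("M", "F")),
      eye = draw_bin("eye_r", c("right", "left")),
      bmi = draw_cont("bmi", 10),
      mmse = as.integer(round(pmin(pmax(draw_cont("mmse"), 0), 30))),
      bcva = draw_cont("bcva", -0.3, 2),
      iop = draw_cont("iop", 5),
      phakic = draw_bin("phakic", c(TRUE, FALSE)) == "TRUE",
      vcdr = draw_cont("vcdr", 0, 1),
      rnfl_avg = rnfl[, "AVG"], rnfl_sup = rnfl[, "SUP"],
      rnfl_inf = rnfl[, "INF"], rnfl_tem = rnfl[, "TEM"],
      rnfl_nas = rnfl[, "NAS"],
      scan_quality = draw_cont("scan_quality", 10, 100),
      amyloid_load = load,
      stringsAsFactors = FALSE
    )
  })
}

#' Extract the five RNFL features of a subject
#'
#' Returns RNFL thickness in the feature order used by the classifier
#' configurations: AVG, SUP, NAS, INF, TEM.
#'
#' @param record One row of the cohort data frame.
#' @return Named numeric vector of length 5 (um).
#' @export
rnfl_features <- function(record) {
  c(AVG = record$rnfl_avg, SUP = record$rnfl_sup, NAS = record$rnfl_nas,
    INF = record$rnfl_inf, TEM = record$rnfl_tem)
}
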