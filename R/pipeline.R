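# End-to-end study drivers: simulate a synthetic study to disk, or run
# the full analysis (preprocess -> ROI features -> statistics -> SEM
# screen -> nested LOOCV) on synthetic or on-disk data.

#' Simulate a synthetic study to disk
#'
#' Generates a cohort and one retinal phantom + raw mosaic frame per
#' subject, and writes the study in the on-disk exchange formats: 16-bit
#' TIFF raw frames, PNG vessel-truth masks, JSON sidecars (landmarks,
#' seed, band centers), cohort/landmark/RNFL CSV tables, and a manifest
#' with the seed and per-file MD5 checksums.  Deterministic given
#' (spec, camera): rerunning with the same seed reproduces identical
#' files.
#'
#' @param out_dir Output directory (created; must not contain a previous
#'   run unless `overwrite = TRUE`).
#' @param spec A [cohort_spec()].
#' @param camera A [camera_model()].
#' @param overwrite Allow writing into an existing study directory.
#' @return The manifest, invisibly (list with seed, subjects, file MD5s).
#' @export
run_simulate <- function(out_dir, spec = cohort_spec(),
                         camera = camera_model(), overwrite = FALSE) {
  validate_cohort_spec(spec)
  if (dir.exists(file.path(out_dir, "subjects")) && !overwrite) {
    stop_retispec(sprintf("study already exists in '%s'", out_dir),
                  "retispec_io_error")
  }
  dir.create(file.path(out_dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  lm_rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sub <- cohort[i, ]
    sdir <- file.path(out_dir, "subjects", sub$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    ph_seed <- derive_seed(spec$seed, i)
    ph <- generate_phantom(sub, camera, seed = ph_seed,
                           scatter_amplitude = spec$scatter_amplitude,
                           pixel_noise_sd = spec$pixel_noise_sd)
    raw <- render_raw_mosaic(ph, camera, seed = derive_seed(ph_seed, 1L))
    write_raw_tiff(raw, file.path(sdir, "raw.tiff"))
    write_mask_png(ph$vessel_truth, file.path(sdir, "vessel_truth.png"))
    jsonlite::write_json(list(
      subject_id = sub$subject_id, eye = sub$eye, seed = ph_seed,
      od_center = unname(ph$od_center), fovea = unname(ph$fovea),
      band_centers = camera$band_centers
    ), file.path(sdir, "sidecar.json"), auto_unbox = TRUE, digits = NA)
    lm_rows[[i]] <- data.frame(subject_id = sub$subject_id,
                               od_x = ph$od_center[["x"]],
                               od_y = ph$od_center[["y"]],
                               fovea_x = ph$fovea[["x"]],
                               fovea_y = ph$fovea[["y"]],
                               eye = sub$eye)
  }
  lm_tab <- do.call(rbind, lm_rows)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(lm_tab, file.path(out_dir, "landmarks.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort[, c("subject_id", "rnfl_avg", "rnfl_sup",
                              "rnfl_inf", "rnfl_tem", "rnfl_nas")],
                   file.path(out_dir, "rnfl.csv"), row.names = FALSE)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = spec$seed,
                   n_ad = spec$n_ad, n_ctrl = spec$n_ctrl,
                   subjects = cohort$subject_id,
                   md5 = as.list(stats::setNames(
                     unname(tools::md5sum(files)),
                     sub(paste0("^", out_dir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Per-subject image processing: raw frame -> QC, vessel mask, four
# standardized ROI spectra.  `lm` is a landmarks() object.
process_subject_frame <- function(raw, camera, lm, subject_ref = NA,
                                  vessel_args = list(), roi_args = list()) {
  dn <- demosaic(raw, camera)
  cube <- to_relative_reflectance(dn, camera, subject_ref)
  qc <- check_saturation(raw, lm$od_center, camera)
  vessels <- do.call(segment_vessels, c(list(cube), vessel_args))
  rois <- do.call(place_rois,
                  c(list(lm, dim(cube$values)[1:2]), roi_args))
  spec14 <- sapply(c("S1", "S2", "I1", "I2"), function(id) {
    standardize_spectrum(mean_roi_spectrum(cube, id, rois, vessels))
  })
  list(qc = qc, vessels = vessels, rois = rois,
       spectra = t(spec14))  # 4 x 14, rows S1 S2 I1 I2
}

#' Run the full study analysis
#'
#' Executes the complete pipeline and returns a report bundle:
#' \enumerate{
#'   \item acquire data: either simulate phantoms in memory from `spec`
#'     (default) or read a study directory written by [run_simulate()];
#'   \item per subject: demosaic, convert to relative reflectance,
#'     saturation QC, vessel segmentation, ROI placement and averaging,
#'     spectral standardization;
#'   \item cohort statistics ([cohort_table()]) and the per-ROI group
#'     spectral summary;
#'   \item SEM-overlap screening of the four ROIs; if no ROI passes, the
#'     run stops here with outcome `"no ROI passed SEM screen"`;
#'   \item nested LOOCV over the screened configurations (each screened
#'     ROI with and without the 5 RNFL features).
#' }
#'
#' @param spec A [cohort_spec()] (ignored when `input_dir` is given,
#'   except for `scatter_amplitude`/noise which are baked into the files).
#' @param camera A [camera_model()].
#' @param input_dir Optional study directory from [run_simulate()].
#' @param out_dir Optional directory to write the report files (CSV/JSON).
#' @param strict_screening Re-run the SEM screen inside each outer
#'   training fold (no selection leakage) instead of once on the full
#'   cohort.
#' @param ci `"delong"` or `"bootstrap"` confidence interval for the
#'   outer AUC.
#' @param standardize,shrinkage Passed to the LDA/CV engine.
#' @param vessel_args,roi_args Optional parameter overrides for
#'   [segment_vessels()] and [place_rois()].
#' @return Object of class `retispec_report`.
#' @export
run_full <- function(spec = cohort_spec(), camera = camera_model(),
                     input_dir = NULL, out_dir = NULL,
                     strict_screening = FALSE,
                     ci = c("delong", "bootstrap"),
                     standardize = TRUE, shrinkage = 1e-6,
                     vessel_args = list(), roi_args = list()) {
  ci <- match.arg(ci)
  t0 <- Sys.time()
  timing <- list()
  tick <- function(stage, t_prev) {
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t_prev, units = "secs"))
    Sys.time()
  }

  if (is.null(input_dir)) {
    cohort <- generate_cohort(spec)
  } else {
    cohort <- utils::read.csv(file.path(input_dir, "cohort.csv"),
                              stringsAsFactors = FALSE)
    lm_tab <- utils::read.csv(file.path(input_dir, "landmarks.csv"),
                              stringsAsFactors = FALSE)
  }
  n <- nrow(cohort)
  tk <- tick("cohort", t0)

  spectra <- array(NA_real_, dim = c(n, 4, 14),
                   dimnames = list(cohort$subject_id,
                                   c("S1", "S2", "I1", "I2"), NULL))
  qc <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- cohort[i, ]
    if (is.null(input_dir)) {
      ph_seed <- derive_seed(spec$seed, i)
      ph <- generate_phantom(sub, camera, seed = ph_seed,
                             scatter_amplitude = spec$scatter_amplitude,
                             pixel_noise_sd = spec$pixel_noise_sd)
      raw <- render_raw_mosaic(ph, camera, seed = derive_seed(ph_seed, 1L))
      lm <- landmarks(ph$od_center, ph$fovea, sub$eye)
    } else {
      raw <- read_raw_tiff(file.path(input_dir, "subjects", sub$subject_id,
                                     "raw.tiff"))
      r <- lm_tab[lm_tab$subject_id == sub$subject_id, ]
      lm <- landmarks(c(r$od_x, r$od_y), c(r$fovea_x, r$fovea_y), r$eye)
    }
    res <- tryCatch(
      process_subject_frame(raw, camera, lm, sub$subject_id,
                            vessel_args, roi_args),
      error = function(e) {
        stop_retispec(sprintf("stage 'preprocess', subject %s: %s",
                              sub$subject_id, conditionMessage(e)),
                      "retispec_stage_error")
      })
    spectra[i, , ] <- res$spectra
    qc[[i]] <- res$qc
  }
  tk <- tick("preprocess", tk)

  stats_table <- cohort_table(cohort)
  summary_gs <- group_spectral_summary(spectra, cohort$group)
  screened <- sem_screen(spectra, cohort$group)
  tk <- tick("statistics", tk)

  report <- list(
    cohort = cohort, stats_table = stats_table,
    spectral_summary = summary_gs, screened_rois = screened,
    qc = qc, seed = spec$seed
  )

  if (!length(screened)) {
    report$outcome <- "no ROI passed SEM screen"
    report$cv <- NULL
    report$timing <- timing
    class(report) <- "retispec_report"
    if (!is.null(out_dir)) write_report(report, out_dir)
    return(report)
  }

  roi_order <- intersect(c("S1", "S2", "I1", "I2"), screened)
  rnfl_mat <- t(sapply(seq_len(n), function(i) rnfl_features(cohort[i, ])))
  features <- c(
    stats::setNames(lapply(roi_order, function(r) {
      m <- spectra[, r, ]; colnames(m) <- sprintf("b%02d", 1:14); m
    }), roi_order),
    stats::setNames(lapply(roi_order, function(r) {
      cbind(spectra[, r, ], rnfl_mat)
    }), paste0(roi_order, "+RNFL"))
  )
  config_filter <- NULL
  if (strict_screening) {
    config_filter <- function(tr) {
      sel <- sem_screen(spectra[tr, , , drop = FALSE], cohort$group[tr])
      names(features)[sub("\\+RNFL$", "", names(features)) %in% sel]
    }
  }
  cv <- nested_loocv(features, cohort$group, positive = "AD",
                     shrinkage = shrinkage, standardize = standardize,
                     ci = ci, config_filter = config_filter)
  tk <- tick("nested_loocv", tk)

  report$configs <- names(features)
  report$cv <- cv
  report$outcome <- "completed"
  report$timing <- timing
  class(report) <- "retispec_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$stats_table,
                   file.path(out_dir, "statistics.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    outcome = report$outcome,
    screened_rois = report$screened_rois,
    configs = report$configs,
    auc = report$cv$auc %||% NA,
    ci = report$cv$ci %||% NA,
    selection_tally = as.list(report$cv$selection_tally %||% list()),
    timing = report$timing
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
     null = "null")
  if (!is.null(report$cv)) {
    utils::write.csv(data.frame(subject_id = report$cohort$subject_id,
                                group = report$cohort$group,
                                probability = report$cv$probs,
                                selected_config = report$cv$selected),
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.retispec_report <- function(x, ...) {
  cat(sprintf("Study report: %d AD / %d CTRL subjects\n",
              sum(x$cohort$group == "AD"), sum(x$cohort$group == "CTRL")))
  cat(sprintf("  SEM screen: %s\n",
              if (length(x$screened_rois))
                paste(x$screened_rois, collapse = ", ") else "none"))
  cat(sprintf("  outcome: %s\n", x$outcome))
  if (!is.null(x$cv)) {
    cat(sprintf("  outer AUC %.3f, CI [%.3f, %.3f]\n",
                x$cv$auc, x$cv$ci[1], x$cv$ci[2]))
  }
  invisible(x)
}
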