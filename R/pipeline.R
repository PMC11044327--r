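# End-to-end session pipeline: io -> preprocessing -> parameters -> epochs,
# with tidy CSV outputs and a QC report.

#' Analysis options for a session run
#'
#' Collects every tunable preprocessing and analysis threshold in one
#' place. Defaults match the documented stable-period contract.
#'
#' @param mad_k Spike threshold, robust SDs (default 6).
#' @param cv_max Stability threshold on the coefficient of variation of
#'   tidal swing and breath duration (default 0.25).
#' @param min_breaths Minimum breaths per stable period (default 5).
#' @param prominence_frac Extremum prominence as a fraction of the local
#'   tidal amplitude (default 0.3).
#' @param breath_min_s,breath_max_s Breath duration bounds, s (1-15).
#' @param artifact_frac_max Maximum unrepaired artifact fraction per
#'   stable period (default 0.01).
#' @param step_thresh_au Step detector threshold, AU (`NULL` = automatic).
#' @param hr_estimate Optional cardiac frequency, Hz.
#' @param gi_mode `"per_breath"` or `"period_image"` (see
#'   [period_parameters()]).
#' @param epoch_mode `"duration"` or `"count"` (see [divide_epochs()]).
#' @param n_epochs Number of within-SBT epochs (default 5).
#' @param calibration_method `"mean_of_points"` or `"single_point"`.
#' @return A list of class `eit_options`.
#' @export
eit_options <- function(mad_k = 6, cv_max = 0.25, min_breaths = 5L,
                        prominence_frac = 0.3, breath_min_s = 1,
                        breath_max_s = 15, artifact_frac_max = 0.01,
                        step_thresh_au = NULL, hr_estimate = NULL,
                        gi_mode = c("per_breath", "period_image"),
                        epoch_mode = c("duration", "count"),
                        n_epochs = 5L,
                        calibration_method = c("mean_of_points", "single_point")) {
  structure(
    list(
      mad_k = mad_k, cv_max = cv_max, min_breaths = as.integer(min_breaths),
      prominence_frac = prominence_frac, breath_min_s = breath_min_s,
      breath_max_s = breath_max_s, artifact_frac_max = artifact_frac_max,
      step_thresh_au = step_thresh_au, hr_estimate = hr_estimate,
      gi_mode = match.arg(gi_mode), epoch_mode = match.arg(epoch_mode),
      n_epochs = as.integer(n_epochs),
      calibration_method = match.arg(calibration_method)
    ),
    class = "eit_options"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)), parent = e)
  })
}

#' Run the full analysis on in-memory session objects
#'
#' Executes alignment, artifact removal, cardiac filtering, breath
#' segmentation, stable-period selection, volume calibration, per-breath
#' parameter computation and epoch summarization.
#'
#' @param seq An `eit_sequence`.
#' @param mask A `lung_mask`.
#' @param vent A `vent_log`.
#' @param ann An `sbt_annotation`.
#' @param options An [eit_options()] list.
#' @param patient_id Identifier carried into outputs.
#' @return An object of class `eit_session`: fields `patient_id`,
#'   `outcome`, `calibration`, `breaths` (per-breath parameters of stable
#'   breaths, with epochs), `all_breaths`, `periods`, `epochs`, `qc`
#'   (artifact report), `options`, `ann`, `filter` (frequency estimates).
#' @export
run_session <- function(seq, mask, vent, ann, options = eit_options(),
                        patient_id = "session") {
  aligned <- stage("io", align_channels(seq, vent, ann))

  clean <- stage("preprocessing", remove_artifacts(
    aligned$seq, mask,
    mad_k = options$mad_k, step_thresh_au = options$step_thresh_au
  ))
  gs <- stage("preprocessing", global_signal(clean$seq, mask))
  gsf <- stage("preprocessing", filter_cardiac(gs, hr_estimate = options$hr_estimate))
  breaths <- stage("preprocessing", segment_breaths(
    gsf,
    prominence_frac = options$prominence_frac,
    breath_min_s = options$breath_min_s, breath_max_s = options$breath_max_s
  ))
  periods <- stage("preprocessing", select_stable_periods(
    breaths, clean, ann,
    min_breaths = options$min_breaths, cv_max = options$cv_max,
    artifact_frac_max = options$artifact_frac_max
  ))
  stable <- stage("preprocessing", stable_breaths(breaths, periods))

  cal <- stage("parameters", calibrate_volume(
    stable[stable$phase == "pre", , drop = FALSE], aligned$vent,
    method = options$calibration_method
  ))
  params <- stage("parameters", breath_parameters(stable, clean$seq, mask, cal))
  if (options$gi_mode == "period_image" && nrow(params) > 0) {
    # replace per-breath image indices by the ones of the period-averaged
    # tidal image (less noise-sensitive; every breath of a period carries
    # its period's value into the epoch means)
    params <- stage("parameters", {
      for (pid in unique(params$period_id)) {
        sel <- params$period_id == pid
        img <- image_parameters(period_tidal_image(
          clean$seq, params[sel, ], mask,
          source = pid
        ))
        for (col in names(img)) params[[col]][sel] <- img[[col]]
      }
      params
    })
  }
  params <- stage("trend", divide_epochs(params, ann,
    n_epochs = options$n_epochs, epoch_mode = options$epoch_mode
  ))
  epochs <- stage("trend", summarize_epochs(params, n_epochs = options$n_epochs))

  structure(
    list(
      patient_id = patient_id, outcome = ann$outcome,
      calibration = cal, breaths = params, all_breaths = breaths,
      periods = periods, epochs = epochs, qc = clean$report,
      segments = clean$segments, options = options, ann = ann,
      filter = list(
        resp_freq = attr(gsf, "resp_freq"),
        cardiac_freq = attr(gsf, "cardiac_freq"),
        cutoff = attr(gsf, "cutoff")
      ),
      signal = gsf
    ),
    class = "eit_session"
  )
}

#' @export
print.eit_session <- function(x, ...) {
  cat(sprintf(
    "<eit_session> %s (outcome: %s)\n  %d stable breaths in %d periods; c = %.4g ml/AU\n",
    x$patient_id, x$outcome, nrow(x$breaths), nrow(x$periods), x$calibration$c
  ))
  cat(sprintf(
    "  epoch EELI %% change: %s\n",
    paste(sprintf("%.1f", x$epochs$pct_change_eeli), collapse = ", ")
  ))
  invisible(x)
}

valid_config_keys <- c(
  "session", "frames", "mask", "vent", "annotation", "outdir", "patient_id",
  "mad_k", "cv_max", "min_breaths", "prominence_frac", "breath_min_s",
  "breath_max_s", "artifact_frac_max", "step_thresh_au", "hr_estimate",
  "gi_mode", "epoch_mode", "n_epochs", "calibration_method"
)

#' Run the pipeline from a configuration
#'
#' The configuration (a named list or a YAML file path) points either at a
#' session container (`session:`) or at individual files (`frames:`,
#' `mask:`, `vent:`, `annotation:`), optionally an output directory
#' (`outdir:`), a `patient_id`, and any [eit_options()] threshold. When
#' `outdir` is set, writes `breaths.csv`, `periods.csv`, `epochs.csv`,
#' `qc_report.csv` and `session.log` there. Any stage failure aborts with
#' a stage-named message; unknown configuration keys are rejected with
#' the list of valid keys.
#'
#' @param config Named list or path to a YAML file.
#' @return An `eit_session`, invisibly when `outdir` is written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- stage("io", yaml::read_yaml(config))
  }
  bad <- setdiff(names(config), valid_config_keys)
  if (length(bad)) {
    abort(sprintf(
      "Unknown config key(s): %s. Valid keys: %s.",
      paste(bad, collapse = ", "), paste(valid_config_keys, collapse = ", ")
    ))
  }
  opt_keys <- intersect(names(config), names(formals(eit_options)))
  options <- do.call(eit_options, config[opt_keys])

  if (!is.null(config$session)) {
    cont <- stage("io", read_eit_container(config$session))
    seq <- cont$seq
    mask <- cont$mask
    vent <- cont$vent
    ann <- cont$annotation
    if (is.null(mask) || is.null(vent) || is.null(ann)) {
      stage("io", abort("Container lacks mask, ventilator log or annotation."))
    }
  } else {
    for (k in c("frames", "mask", "vent", "annotation")) {
      if (is.null(config[[k]])) stage("io", abort(sprintf("Missing `%s` in config.", k)))
    }
    seq <- stage("io", read_eit_sequence(config$frames))
    mask <- stage("io", read_lung_mask(config$mask))
    vent <- stage("io", read_vent_log(config$vent))
    ann <- stage("io", read_sbt_annotation(config$annotation))
  }

  res <- run_session(seq, mask, vent, ann,
    options = options,
    patient_id = config$patient_id %||% "session"
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    readr::write_csv(res$breaths, out("breaths.csv"))
    readr::write_csv(res$periods, out("periods.csv"))
    readr::write_csv(res$epochs, out("epochs.csv"))
    readr::write_csv(res$qc, out("qc_report.csv"))
    writeLines(c(
      sprintf("patient: %s", res$patient_id),
      sprintf("outcome: %s", res$outcome),
      sprintf("breaths detected: %d", nrow(res$all_breaths)),
      sprintf("stable breaths: %d in %d periods", nrow(res$breaths), nrow(res$periods)),
      sprintf("calibration: %.6g ml/AU (%s, %d points)", res$calibration$c,
        res$calibration$method, res$calibration$n_points),
      sprintf("resp/cardiac/cutoff Hz: %.4g / %.4g / %.4g",
        res$filter$resp_freq, res$filter$cardiac_freq %||% NA, res$filter$cutoff),
      sprintf("qc flags: %d", nrow(res$qc))
    ), out("session.log"))
    return(invisible(res))
  }
  res
}

#' @method tidy eit_session
#' @export
tidy.eit_session <- function(x, ...) {
  ep <- x$epochs
  stems <- sub("_mean$", "", grep("_mean$", names(ep), value = TRUE))
  means <- ep |>
    dplyr::select(phase = "epoch", "n_breaths", dplyr::ends_with("_mean")) |>
    tidyr::pivot_longer(dplyr::ends_with("_mean"),
      names_to = "parameter", values_to = "estimate",
      names_pattern = "(.*)_mean"
    )
  sds <- ep |>
    dplyr::select(phase = "epoch", dplyr::ends_with("_sd")) |>
    tidyr::pivot_longer(dplyr::ends_with("_sd"),
      names_to = "parameter", values_to = "std_dev",
      names_pattern = "(.*)_sd"
    )
  dplyr::left_join(means, sds, by = c("phase", "parameter")) |>
    dplyr::mutate(patient = x$patient_id, outcome = x$outcome, .before = 1)
}

#' @method glance eit_session
#' @export
glance.eit_session <- function(x, ...) {
  pre <- x$epochs[x$epochs$epoch == "pre", ]
  tibble(
    patient = x$patient_id,
    outcome = x$outcome,
    n_breaths_detected = nrow(x$all_breaths),
    n_breaths_stable = nrow(x$breaths),
    n_periods = nrow(x$periods),
    n_qc_flags = nrow(x$qc),
    calibration_ml_per_au = x$calibration$c,
    rr_baseline = pre$rr_mean,
    gi_baseline = pre$gi_mean,
    pct_change_eeli_post = x$epochs$pct_change_eeli[x$epochs$epoch == "post"],
    pct_change_dz_post = x$epochs$pct_change_dz[x$epochs$epoch == "post"]
  )
}
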