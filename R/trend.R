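# SBT trend assembly: epoch division, baseline normalization and cohort
# tables.

#' Epoch boundaries of an annotated SBT
#'
#' The SBT span is cut into `n_epochs` equal-duration, half-open intervals;
#' the pre-SBT and post-SBT phases are single epochs.
#'
#' @param ann An `sbt_annotation`.
#' @param n_epochs Number of within-SBT epochs (default 5).
#' @return A tibble with columns `phase`, `t_start`, `t_end`; the SBT
#'   intervals are pairwise disjoint and cover the SBT span exactly.
#' @export
epoch_bounds <- function(ann, n_epochs = 5L) {
  if (ann$t_sbt_end <= ann$t_sbt_start) {
    abort("SBT end must come after SBT start.")
  }
  cuts <- seq(ann$t_sbt_start, ann$t_sbt_end, length.out = n_epochs + 1L)
  tibble(
    phase = c("pre", paste0("sbt_", seq_len(n_epochs)), "post"),
    t_start = c(ann$t_pre_start, cuts[-length(cuts)], ann$t_sbt_end),
    t_end = c(ann$t_sbt_start, cuts[-1L], ann$t_post_end)
  )
}

epoch_levels <- function(n_epochs = 5L) {
  c("pre", paste0("sbt_", seq_len(n_epochs)), "post")
}

#' Assign breaths to SBT epochs
#'
#' Each breath is assigned to the epoch containing its end-expiration
#' start time; interval membership is half-open, so a breath exactly on a
#' boundary goes to the later interval. With `epoch_mode = "count"` the
#' SBT breaths are instead split into `n_epochs` groups of (nearly) equal
#' breath count in time order. Post-SBT breaths starting within
#' `post_early_s` of reconnection are flagged in a `post_early` column
#' (the tidal swing typically restores within about half a minute, so
#' those breaths mix the transient with the recovered state).
#'
#' @param breaths Breath or parameter table with a `t_start` column.
#' @param ann An `sbt_annotation`.
#' @param n_epochs Number of within-SBT epochs (default 5).
#' @param epoch_mode `"duration"` (equal-duration cuts, default) or
#'   `"count"` (equal breath counts).
#' @param post_early_s Early post-SBT flagging window, seconds.
#' @return `breaths` with added `epoch` (factor `pre`, `sbt_1` ...
#'   `post`; `NA` outside the annotated window) and `post_early` columns.
#' @export
divide_epochs <- function(breaths, ann, n_epochs = 5L,
                          epoch_mode = c("duration", "count"),
                          post_early_s = 30) {
  epoch_mode <- match.arg(epoch_mode)
  bounds <- epoch_bounds(ann, n_epochs)
  lv <- epoch_levels(n_epochs)
  t <- breaths$t_start
  epoch <- rep(NA_character_, length(t))
  if (epoch_mode == "duration") {
    for (k in seq_len(nrow(bounds))) {
      sel <- t >= bounds$t_start[k] & t < bounds$t_end[k]
      epoch[sel] <- bounds$phase[k]
    }
  } else {
    epoch[t >= ann$t_pre_start & t < ann$t_sbt_start] <- "pre"
    epoch[t >= ann$t_sbt_end & t < ann$t_post_end] <- "post"
    in_sbt <- which(t >= ann$t_sbt_start & t < ann$t_sbt_end)
    if (length(in_sbt)) {
      ord <- in_sbt[order(t[in_sbt])]
      grp <- ceiling(seq_along(ord) * n_epochs / length(ord))
      epoch[ord] <- paste0("sbt_", grp)
    }
  }
  breaths$epoch <- factor(epoch, levels = lv)
  breaths$post_early <- !is.na(epoch) & epoch == "post" &
    t < ann$t_sbt_end + post_early_s
  breaths
}

#' Per-epoch parameter summary with baseline-normalized trends
#'
#' Means and standard deviations of every parameter over the stable
#' breaths of each epoch, plus the percent change from the pre-SBT
#' baseline for EELI and the tidal swing:
#' `pct_change = 100 * (mean_epoch - mean_pre) / |mean_pre|` (the absolute
#' value keeps the sign meaningful if the baseline is negative). All
#' epochs are reported even when empty (`n_breaths = 0`, values `NA`); an
#' empty pre-SBT baseline is an error. Missing parameter values propagate
#' as `NA` with a per-epoch missing count for the GI.
#'
#' @param params Per-breath parameter table with an `epoch` column from
#'   [divide_epochs()].
#' @param n_epochs Number of within-SBT epochs (default 5).
#' @return A tibble of class `eit_epochs`: one row per epoch with
#'   `<parameter>_mean` / `<parameter>_sd` columns, `n_breaths`,
#'   `n_gi_missing`, `pct_change_eeli`, `pct_change_dz`.
#' @export
summarize_epochs <- function(params, n_epochs = 5L) {
  if (!"epoch" %in% names(params)) {
    abort("`params` lacks an `epoch` column; call divide_epochs() first.")
  }
  lv <- epoch_levels(n_epochs)
  num_cols <- intersect(
    c(
      "eeli", "dz", "rr", "vt_ml", "mv_l_min", "rsbi", "gi", "cov_x", "cov_y",
      "nss", "dss", "fls", "frac_left", "frac_right", "frac_ventral", "frac_dorsal"
    ),
    names(params)
  )
  dat <- params[!is.na(params$epoch), , drop = FALSE]
  if (!any(dat$epoch == "pre")) {
    abort("Empty pre-SBT baseline: no stable breath in the pre epoch.")
  }
  sm <- dat |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(
      n_breaths = dplyr::n(),
      n_gi_missing = if ("gi" %in% num_cols) sum(is.na(.data$gi)) else 0L,
      dplyr::across(
        dplyr::all_of(num_cols),
        list(
          mean = ~ mean(.x, na.rm = TRUE),
          sd = ~ stats::sd(.x, na.rm = TRUE)
        ),
        .names = "{.col}_{.fn}"
      ),
      .groups = "drop"
    )
  full <- tibble(epoch = factor(lv, levels = lv))
  out <- dplyr::left_join(full, sm, by = "epoch")
  out$n_breaths[is.na(out$n_breaths)] <- 0L
  base_eeli <- out$eeli_mean[out$epoch == "pre"]
  base_dz <- out$dz_mean[out$epoch == "pre"]
  out$pct_change_eeli <- 100 * (out$eeli_mean - base_eeli) / abs(base_eeli)
  out$pct_change_dz <- 100 * (out$dz_mean - base_dz) / abs(base_dz)
  class(out) <- c("eit_epochs", class(out))
  out
}

#' Per-epoch ground-truth summary for a synthetic scenario
#'
#' Applies the same epoch division and baseline normalization to the
#' generator's true per-breath record, yielding the reference against
#' which pipeline recovery is measured.
#'
#' @param truth Ground-truth object from [generate_scenario()].
#' @param ann The scenario's `sbt_annotation`.
#' @param n_epochs Number of within-SBT epochs (default 5).
#' @return A tibble with per-epoch true means of EELI, tidal swing, rate,
#'   volume and minute ventilation plus `pct_change_eeli`,
#'   `pct_change_dz`.
#' @export
ground_truth_epochs <- function(truth, ann, n_epochs = 5L) {
  b <- divide_epochs(truth$breaths, ann, n_epochs)
  b <- b[!is.na(b$epoch), , drop = FALSE]
  lv <- epoch_levels(n_epochs)
  out <- b |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(
      n_breaths = dplyr::n(),
      dplyr::across(
        dplyr::all_of(c("eeli", "dz", "rr", "vt_ml", "mv_l_min")),
        ~ mean(.x),
        .names = "{.col}_mean"
      ),
      .groups = "drop"
    )
  out <- dplyr::left_join(tibble(epoch = factor(lv, levels = lv)), out, by = "epoch")
  base_eeli <- out$eeli_mean[out$epoch == "pre"]
  base_dz <- out$dz_mean[out$epoch == "pre"]
  out$pct_change_eeli <- 100 * (out$eeli_mean - base_eeli) / abs(base_eeli)
  out$pct_change_dz <- 100 * (out$dz_mean - base_dz) / abs(base_dz)
  out
}

#' Long-format cohort table across sessions
#'
#' Stacks the epoch summaries of several sessions into a tidy long table
#' (`patient`, `outcome`, `phase`, `parameter`, `value`) ready for
#' external mixed-model fitting, with per-phase and per-outcome group
#' means joined in. Empty epochs yield rows with `missing = TRUE` rather
#' than being dropped.
#'
#' @param sessions List of `eit_session` objects from [run_session()].
#' @param parameters Parameter (column stem) names to include.
#' @return A tibble with one row per session, phase and parameter.
#' @export
cohort_table <- function(sessions,
                         parameters = c(
                           "eeli", "dz", "rr", "vt_ml", "mv_l_min", "rsbi",
                           "gi", "cov_x", "cov_y", "nss", "dss", "fls"
                         )) {
  if (!length(sessions)) abort("Need at least one session.")
  long <- purrr::map_dfr(sessions, function(s) {
    ep <- s$epochs
    cols <- paste0(parameters, "_mean")
    cols <- cols[cols %in% names(ep)]
    ep |>
      dplyr::select(phase = "epoch", dplyr::all_of(cols)) |>
      tidyr::pivot_longer(-"phase",
        names_to = "parameter", values_to = "value",
        names_pattern = "(.*)_mean"
      ) |>
      dplyr::mutate(patient = s$patient_id, outcome = s$outcome, .before = 1)
  })
  long$missing <- is.na(long$value)
  gm <- long |>
    dplyr::group_by(.data$outcome, .data$phase, .data$parameter) |>
    dplyr::summarise(group_mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  dplyr::left_join(long, gm, by = c("outcome", "phase", "parameter"))
}
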