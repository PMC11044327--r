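# Per-breath and per-period EIT parameters: tidal images, global
# inhomogeneity index, center of ventilation, silent spaces, volume
# calibration, rate/volume indices and regional ventilation fractions.

#' Construct a tidal image
#'
#' Per-pixel inspiratory impedance change (end-inspiration minus
#' end-expiration, AU), defined on lung pixels only. Negative pixel values
#' are retained (not clipped).
#'
#' @param di Numeric matrix of per-pixel impedance change on the full
#'   grid; values outside the lung are ignored.
#' @param mask A `lung_mask` with the same dimensions.
#' @param source Identifier of the breath or period the image comes from.
#' @param n_breaths Number of breaths averaged into the image.
#' @return An object of class `eit_tidal_image`.
#' @export
new_tidal_image <- function(di, mask, source = NA, n_breaths = 1L) {
  di <- as.matrix(di)
  if (!identical(dim(di), dim(mask$mask))) {
    abort("Tidal image and mask dimensions differ.")
  }
  di[!mask$mask] <- NA_real_
  structure(
    list(di = di, mask = mask, source = source, n_breaths = n_breaths),
    class = "eit_tidal_image"
  )
}

#' @export
print.eit_tidal_image <- function(x, ...) {
  v <- lung_values(x)
  cat(sprintf(
    "<eit_tidal_image> %d x %d grid, %d lung pixels, sum(di) = %.4g AU (%d breath%s)\n",
    nrow(x$di), ncol(x$di), x$mask$n_lung_pixels, sum(v),
    x$n_breaths, if (x$n_breaths == 1) "" else "s"
  ))
  invisible(x)
}

lung_values <- function(ti) ti$di[ti$mask$mask]

#' Tidal image of one breath
#'
#' `di(x, y)` is the pixel-wise difference between the end-inspiratory and
#' the end-expiratory frame of the breath, computed from the cleaned (but
#' not cardiac-filtered) frames so pixel indices are free of filter
#' ringing. By construction the sum of `di` over lung pixels equals the
#' global tidal swing between those two frames.
#'
#' @param seq Cleaned `eit_sequence`.
#' @param breath One row of a breath table (or any list with
#'   `i_exp_start`, `i_insp_peak`).
#' @param mask A `lung_mask`.
#' @return An `eit_tidal_image`.
#' @export
tidal_image <- function(seq, breath, mask) {
  check_mask_matches(seq, mask)
  i0 <- breath$i_exp_start
  i1 <- breath$i_insp_peak
  if (any(c(i0, i1) < 1L) || any(c(i0, i1) > n_frames(seq))) {
    abort("Breath frame indices fall outside the sequence.")
  }
  di <- frame_matrix(seq, i1) - frame_matrix(seq, i0)
  new_tidal_image(di, mask,
    source = breath$breath %||% NA, n_breaths = 1L
  )
}

#' Mean tidal image over several breaths
#'
#' @param seq Cleaned `eit_sequence`.
#' @param breaths Breath table (several rows).
#' @param mask A `lung_mask`.
#' @param source Identifier recorded on the image.
#' @return An `eit_tidal_image` averaging the per-breath images.
#' @export
period_tidal_image <- function(seq, breaths, mask, source = NA) {
  if (nrow(breaths) == 0) abort("No breaths to average.")
  acc <- NULL
  for (k in seq_len(nrow(breaths))) {
    di <- frame_matrix(seq, breaths$i_insp_peak[k]) -
      frame_matrix(seq, breaths$i_exp_start[k])
    acc <- if (is.null(acc)) di else acc + di
  }
  new_tidal_image(acc / nrow(breaths), mask,
    source = source, n_breaths = nrow(breaths)
  )
}

#' Global inhomogeneity (GI) index
#'
#' Sum over lung pixels of the absolute deviation of the pixel tidal
#' impedance change from the lung-pixel median, divided by the total tidal
#' impedance change. Zero for perfectly homogeneous ventilation; larger
#' values mean a more inhomogeneous distribution. Negative pixels are used
#' as-is. The even-count median is the mean of the two central order
#' statistics.
#'
#' @param ti An `eit_tidal_image`.
#' @return GI value, or `NA` (with a warning) when the total tidal
#'   impedance is non-positive so the index is undefined.
#' @export
compute_gi <- function(ti) {
  v <- lung_values(ti)
  s <- sum(v)
  if (s <= 0) {
    warn(sprintf(
      "GI undefined: total tidal impedance change is non-positive (%.4g AU).", s
    ))
    return(NA_real_)
  }
  sum(abs(v - median(v))) / s
}

# lung_values() and lung_coords() both enumerate lung pixels in
# column-major mask order, so their elements line up.
lung_coords <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  list(
    r = idx[, 1], c = idx[, 2],
    rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2])
  )
}

#' Center of ventilation (CoV)
#'
#' Impedance-weighted centroid of the tidal image over lung pixels,
#' expressed as a percentage of the lung-pixel bounding box along each
#' axis: 0% at the ventral (respectively left) edge, 100% at the dorsal
#' (right) edge. Negative pixels are clipped to zero for weighting only.
#'
#' @param ti An `eit_tidal_image`.
#' @return A tibble with columns `cov_x`, `cov_y` (percent), `NA` when no
#'   positive tidal signal exists.
#' @export
compute_cov <- function(ti) {
  v <- lung_values(ti)
  w <- pmax(v, 0)
  sw <- sum(w)
  if (sw <= 0) {
    return(tibble(cov_x = NA_real_, cov_y = NA_real_))
  }
  co <- lung_coords(ti$mask)
  frac <- function(centroid, lo, hi) {
    if (hi == lo) {
      return(50)
    }
    100 * (centroid - lo) / (hi - lo)
  }
  tibble(
    cov_x = frac(sum(w * co$c) / sw, co$cmin, co$cmax),
    cov_y = frac(sum(w * co$r) / sw, co$rmin, co$rmax)
  )
}

#' Silent spaces and functional lung space
#'
#' Lung pixels whose tidal impedance change is below 10% of the maximum
#' change are silent. A silent pixel gravitationally below the CoV line
#' (dorsal, in supine position) is dependent silent space (DSS), above it
#' nondependent (NSS); pixels exactly on the CoV row are split evenly with
#' the remainder going to DSS. The functional lung space (FLS) is 100%
#' minus the silent-space percentage, so `nss + dss + fls == 100` exactly.
#'
#' @param ti An `eit_tidal_image`.
#' @param cov_y Gravity-axis CoV in percent; computed from `ti` when
#'   omitted.
#' @param silent_frac Silent-space threshold as a fraction of the maximum
#'   pixel change (default 0.10).
#' @return A tibble with columns `nss`, `dss`, `fls` (percent of lung
#'   pixels).
#' @export
compute_silent_spaces <- function(ti, cov_y = NULL, silent_frac = 0.10) {
  v <- lung_values(ti)
  n <- length(v)
  vmax <- max(pmax(v, 0))
  if (vmax <= 0) {
    warn("No positive tidal signal: all lung pixels are silent, FLS = 0.")
    silent <- rep(TRUE, n)
  } else {
    silent <- v < silent_frac * vmax
  }
  if (is.null(cov_y)) cov_y <- compute_cov(ti)$cov_y
  if (is.na(cov_y)) cov_y <- 50
  co <- lung_coords(ti$mask)
  y_cov <- co$rmin + cov_y / 100 * (co$rmax - co$rmin)
  rs <- co$r[silent]
  n_dss <- sum(rs > y_cov)
  n_nss <- sum(rs < y_cov)
  n_on <- sum(rs == y_cov)
  n_nss <- n_nss + n_on %/% 2L
  n_dss <- n_dss + (n_on - n_on %/% 2L)
  nss <- 100 * n_nss / n
  dss <- 100 * n_dss / n
  tibble(nss = nss, dss = dss, fls = 100 - (nss + dss))
}

#' Ventilator volume calibration
#'
#' One-point (or averaged multi-point) calibration between the ventilator
#' tidal volume (ml) and the EIT tidal swing (AU), individualized per
#' session and derived only from stable pre-SBT breaths. Each breath is
#' matched to the ventilator samples overlapping its interval (padded by
#' `window_s` on both sides); the calibration factor is the mean over
#' calibration points of `vt_ml / dz`.
#'
#' @param breaths Stable pre-SBT breath table.
#' @param vent A `vent_log`.
#' @param method `"mean_of_points"` (all breaths) or `"single_point"`
#'   (first matched breath only).
#' @param window_s Matching window padding, seconds.
#' @return A list of class `eit_calibration` with fields `c` (ml per AU),
#'   `method`, `n_points` and the per-point table `points`.
#' @export
calibrate_volume <- function(breaths, vent,
                             method = c("mean_of_points", "single_point"),
                             window_s = 1) {
  method <- match.arg(method)
  if (nrow(breaths) == 0) abort("No pre-SBT stable breaths to calibrate from.")
  pts <- purrr::map_dfr(seq_len(nrow(breaths)), function(k) {
    a <- breaths$t_start[k] - window_s
    b <- breaths$t_start[k] + breaths$duration[k] + window_s
    m <- vent$vt_ml[vent$t_s >= a & vent$t_s <= b]
    if (!length(m)) {
      return(tibble())
    }
    tibble(breath = breaths$breath[k], vt_ml = mean(m), dz = breaths$dz[k])
  })
  if (nrow(pts) == 0) {
    abort("No breath could be matched to a ventilator sample.")
  }
  bad <- pts$vt_ml <= 0
  if (any(bad)) {
    warn(sprintf("%d calibration point(s) with non-positive tidal volume excluded.", sum(bad)))
    pts <- pts[!bad, , drop = FALSE]
    if (nrow(pts) == 0) abort("All matched calibration points had non-positive volume.")
  }
  if (method == "single_point") pts <- pts[1, , drop = FALSE]
  pts$c <- pts$vt_ml / pts$dz
  structure(
    list(c = mean(pts$c), method = method, n_points = nrow(pts), points = pts),
    class = "eit_calibration"
  )
}

#' @export
print.eit_calibration <- function(x, ...) {
  cat(sprintf(
    "<eit_calibration> c = %.4g ml/AU (%s, %d point%s)\n",
    x$c, x$method, x$n_points, if (x$n_points == 1) "" else "s"
  ))
  invisible(x)
}

regional_fractions <- function(ti) {
  v <- lung_values(ti)
  w <- pmax(v, 0)
  sw <- sum(w)
  if (sw <= 0) {
    return(tibble(
      frac_left = NA_real_, frac_right = NA_real_,
      frac_ventral = NA_real_, frac_dorsal = NA_real_
    ))
  }
  co <- lung_coords(ti$mask)
  half <- function(pos, lo, hi) {
    mid <- (lo + hi) / 2
    (sum(w[pos < mid]) + 0.5 * sum(w[pos == mid])) / sw
  }
  fl <- half(co$c, co$cmin, co$cmax)
  fv <- half(co$r, co$rmin, co$rmax)
  tibble(
    frac_left = fl, frac_right = 1 - fl,
    frac_ventral = fv, frac_dorsal = 1 - fv
  )
}

image_parameters <- function(ti) {
  cov <- compute_cov(ti)
  ss <- compute_silent_spaces(ti, cov_y = cov$cov_y)
  dplyr::bind_cols(tibble(gi = compute_gi(ti)), cov, ss, regional_fractions(ti))
}

#' Full per-breath EIT parameter table
#'
#' Augments a breath table with the calibrated and image-derived
#' parameters: tidal volume `vt_ml = c * dz`, minute ventilation
#' `mv_l_min`, rapid shallow breathing index `rsbi = rr / (vt_ml/1000)`
#' (missing when the volume is non-positive), and per-breath GI, CoV,
#' silent spaces and regional ventilation fractions from the breath's
#' tidal image.
#'
#' @param breaths Breath table (typically [stable_breaths()]).
#' @param seq Cleaned `eit_sequence` (artifact-repaired, unfiltered).
#' @param mask A `lung_mask`.
#' @param cal An `eit_calibration`.
#' @return The breath tibble with added parameter columns.
#' @export
breath_parameters <- function(breaths, seq, mask, cal) {
  if (nrow(breaths) == 0) {
    return(breaths)
  }
  img <- purrr::map_dfr(seq_len(nrow(breaths)), function(k) {
    image_parameters(tidal_image(seq, breaths[k, ], mask))
  })
  out <- dplyr::bind_cols(breaths, img)
  out$vt_ml <- cal$c * out$dz
  out$mv_l_min <- out$rr * out$vt_ml / 1000
  out$rsbi <- ifelse(out$vt_ml > 0, out$rr / (out$vt_ml / 1000), NA_real_)
  out
}

#' Per-period parameter summary
#'
#' Mean of per-breath parameters across each stable period. With
#' `gi_mode = "period_image"` the image indices (GI, CoV, silent spaces,
#' regional fractions) are instead computed once on the period-averaged
#' tidal image, which is less noise-sensitive.
#'
#' @param params Per-breath parameter table from [breath_parameters()]
#'   with a `period_id` column (see [stable_breaths()]).
#' @param seq,mask,cal As in [breath_parameters()]; needed for
#'   `gi_mode = "period_image"`.
#' @param gi_mode `"per_breath"` (average per-breath indices) or
#'   `"period_image"`.
#' @return One row per period with parameter means.
#' @export
period_parameters <- function(params, seq = NULL, mask = NULL, cal = NULL,
                              gi_mode = c("per_breath", "period_image")) {
  gi_mode <- match.arg(gi_mode)
  num_cols <- c(
    "eeli", "dz", "rr", "vt_ml", "mv_l_min", "rsbi", "gi", "cov_x", "cov_y",
    "nss", "dss", "fls", "frac_left", "frac_right", "frac_ventral", "frac_dorsal"
  )
  num_cols <- intersect(num_cols, names(params))
  out <- params |>
    dplyr::group_by(.data$period_id, .data$phase) |>
    dplyr::summarise(
      n_breaths = dplyr::n(),
      t_start = min(.data$t_start),
      dplyr::across(dplyr::all_of(num_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  if (gi_mode == "period_image") {
    if (is.null(seq) || is.null(mask)) {
      abort("`seq` and `mask` are required for gi_mode = 'period_image'.")
    }
    img <- purrr::map_dfr(out$period_id, function(pid) {
      ti <- period_tidal_image(seq, params[params$period_id == pid, ], mask,
        source = pid
      )
      image_parameters(ti)
    })
    for (col in names(img)) out[[col]] <- img[[col]]
  }
  out
}
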