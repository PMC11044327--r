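# Preprocessing: global lung signal extraction, spike/step artifact
# handling, cardiac-frequency filtering, breath segmentation and automated
# selection of stable tidal-breathing periods.

odd_window <- function(x, n) {
  w <- max(3L, as.integer(round(x)))
  w <- min(w, if (n %% 2L == 1L) n else n - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  max(w, 3L)
}

#' Global lung impedance signal
#'
#' Sum of lung-pixel impedance per frame, the carrier of EELI and the tidal
#' swing.
#'
#' @param seq An `eit_sequence`.
#' @param mask A `lung_mask` on the same grid.
#' @return A tibble with columns `frame`, `t`, `z` and attribute `fs`.
#' @export
global_signal <- function(seq, mask) {
  check_mask_matches(seq, mask)
  z <- rowSums(seq$frames[, mask_pixel_index(mask), drop = FALSE])
  gs <- tibble(frame = seq_len(n_frames(seq)), t = frame_times(seq), z = z)
  attr(gs, "fs") <- seq$fs
  gs
}

gs_fs <- function(gs, fs = NULL) {
  fs <- fs %||% attr(gs, "fs")
  if (is.null(fs)) {
    abort("Global signal has no `fs` attribute; pass `fs` explicitly.")
  }
  fs
}

#' Remove spike and step artifacts from an EIT sequence
#'
#' Spike frames are frames whose global lung signal deviates from a short
#' rolling median by more than `mad_k` robust standard deviations; runs of
#' up to `max_interp` flagged frames are replaced by temporal interpolation
#' of every pixel (longer runs are flagged as unrepaired). Step events --
#' sustained shifts of the rolling median larger than `step_thresh_au` --
#' are not corrected: they are recorded as segment boundaries across which
#' end-expiratory levels must not be compared.
#'
#' @param seq An `eit_sequence`.
#' @param mask A `lung_mask`.
#' @param mad_k Spike threshold in robust standard deviations (default 6).
#'   The residual scale is estimated from the 98th percentile of absolute
#'   residuals rather than the raw MAD: on monotone signal stretches the
#'   rolling median reproduces the signal exactly, so the plain MAD
#'   collapses toward zero, while the upper-quantile scale stays calibrated
#'   and tolerates spike contamination up to 2% of frames.
#' @param spike_win_s Rolling-median window for spike detection, seconds.
#' @param max_interp Longest flagged run (frames) that is repaired by
#'   interpolation.
#' @param step_win_s Half-window for the step detector's before/after
#'   median comparison, seconds.
#' @param step_thresh_au Step detection threshold in AU; default
#'   (`NULL`) is 3 times the robust tidal amplitude estimate, so
#'   physiological end-expiratory level changes are not mistaken for belt
#'   artifacts.
#' @return A list of class `eit_clean` with elements `seq` (repaired
#'   sequence), `report` (tibble `frame`, `kind`, `magnitude` with kinds
#'   `spike`, `unrepaired`, `nonfinite`, `step`), and `segments` (tibble of
#'   step-free segments with `i_start`, `i_end`).
#' @export
remove_artifacts <- function(seq, mask, mad_k = 6, spike_win_s = 0.1,
                             max_interp = 5L, step_win_s = 5,
                             step_thresh_au = NULL) {
  check_mask_matches(seq, mask)
  n <- n_frames(seq)
  lung <- mask_pixel_index(mask)
  z <- rowSums(seq$frames[, lung, drop = FALSE])

  report <- attr(seq, "nonfinite") %||% tibble(frame = integer(), pixel = integer())
  report <- tibble(
    frame = unique(report$frame),
    kind = rep("nonfinite", length(unique(report$frame))),
    magnitude = NA_real_
  )

  # --- spikes -----------------------------------------------------------
  w <- odd_window(spike_win_s * seq$fs, n)
  rm_short <- stats::runmed(z, w, endrule = "median")
  resid <- z - rm_short
  sigma <- as.numeric(quantile(abs(resid), 0.98)) / stats::qnorm(0.99)
  flagged <- if (sigma > 0) abs(resid) > mad_k * sigma else rep(FALSE, n)

  frames <- seq$frames
  if (any(flagged)) {
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]
      b <- ends[k]
      len <- b - a + 1L
      if (len <= max_interp && a > 1L && b < n) {
        lam <- (seq_len(len)) / (len + 1)
        frames[a:b, ] <- (1 - lam) %o% frames[a - 1L, ] + lam %o% frames[b + 1L, ]
        kind <- "spike"
      } else if (len <= max_interp) {
        src <- if (a == 1L) min(b + 1L, n) else max(a - 1L, 1L)
        frames[a:b, ] <- rep(frames[src, ], each = len)
        kind <- "spike"
      } else {
        kind <- "unrepaired"
      }
      report <- dplyr::bind_rows(report, tibble(
        frame = a:b, kind = kind, magnitude = resid[a:b]
      ))
    }
    z <- rowSums(frames[, lung, drop = FALSE])
  }

  n_bad <- length(unique(report$frame[report$kind %in% c("spike", "unrepaired", "nonfinite")]))
  if (n_bad > 0.5 * n) {
    abort(sprintf(
      "Unusable recording: %d of %d frames flagged as artifacts.",
      n_bad, n
    ))
  }

  # --- steps ------------------------------------------------------------
  long_w <- odd_window(15 * seq$fs, n)
  zc <- z - stats::runmed(z, long_w, endrule = "median")
  est_dz <- as.numeric(quantile(zc, 0.95) - quantile(zc, 0.05))
  thresh <- step_thresh_au %||% (3 * est_dz)

  W <- max(3L, as.integer(round(step_win_s * seq$fs)))
  step_frames <- integer(0)
  step_mags <- numeric(0)
  if (n > 4L * W) {
    k2 <- odd_window(2 * W, n)
    h <- (k2 - 1L) %/% 2L
    rm2 <- stats::runmed(z, k2, endrule = "median")
    idx <- (h + 2L):(n - h)
    d <- rm2[idx + h] - rm2[idx - h - 1L]
    cand <- abs(d) > thresh
    if (any(cand)) {
      r <- rle(cand)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        seg <- starts[k]:ends[k]
        coarse <- idx[seg[which.max(abs(d[seg]))]]
        lo <- max(2L, coarse - W)
        hi <- min(n, coarse + W)
        jump <- diff(z[(lo - 1L):hi])
        refined <- lo - 1L + which.max(abs(jump))
        step_frames <- c(step_frames, refined)
        step_mags <- c(step_mags, jump[which.max(abs(jump))])
      }
    }
  }
  # merge detections closer than one detector window
  if (length(step_frames) > 1) {
    ord <- order(step_frames)
    step_frames <- step_frames[ord]
    step_mags <- step_mags[ord]
    keep <- c(TRUE, diff(step_frames) > W)
    step_frames <- step_frames[keep]
    step_mags <- step_mags[keep]
  }
  if (length(step_frames)) {
    report <- dplyr::bind_rows(report, tibble(
      frame = step_frames, kind = "step", magnitude = step_mags
    ))
  }
  bounds <- c(1L, step_frames, n + 1L)
  segments <- tibble(
    segment = seq_len(length(bounds) - 1L),
    i_start = bounds[-length(bounds)],
    i_end = bounds[-1L] - 1L
  )

  cleaned <- eit_sequence(frames,
    fs = seq$fs, nrow = seq$nrow, ncol = seq$ncol,
    t0 = seq$t0, channels = seq$channels
  )
  structure(
    list(seq = cleaned, report = dplyr::arrange(report, .data$frame), segments = segments),
    class = "eit_clean"
  )
}

#' @export
print.eit_clean <- function(x, ...) {
  counts <- table(x$report$kind)
  cat(sprintf(
    "<eit_clean> %d frames; flagged: %s; %d segment(s)\n",
    n_frames(x$seq),
    if (length(counts)) paste(names(counts), counts, sep = "=", collapse = ", ") else "none",
    nrow(x$segments)
  ))
  invisible(x)
}

# Smoothed periodogram of the detrended, Hann-windowed signal.
signal_spectrum <- function(z, fs) {
  n <- length(z)
  zd <- z - mean(z)
  tt <- seq_len(n)
  zd <- zd - stats::lm.fit(cbind(1, tt), zd)$fitted.values
  hann <- 0.5 * (1 - cos(2 * pi * (tt - 1) / (n - 1)))
  p <- Mod(fft(zd * hann))^2
  m <- floor(n / 2)
  tibble(freq = (seq_len(m) - 1) * fs / n, power = p[seq_len(m)])
}

#' Estimate respiratory and cardiac fundamental frequencies
#'
#' Spectral-peak estimation on the global signal: the respiratory
#' fundamental is the periodogram peak in 0.08-0.8 Hz; the cardiac
#' fundamental is the peak between roughly twice the respiratory rate and
#' 3.5 Hz, reported only when clearly above the respiratory-band floor.
#'
#' @param gs Global signal tibble from [global_signal()].
#' @param fs Sampling rate (defaults to the `fs` attribute of `gs`).
#' @return List with `f_resp` and `f_card` (Hz; `f_card` is `NA` when no
#'   cardiac peak is detected).
#' @export
estimate_rates <- function(gs, fs = NULL) {
  fs <- gs_fs(gs, fs)
  sp <- signal_spectrum(gs$z, fs)
  resp_band <- sp$freq >= 0.08 & sp$freq <= 0.8
  if (!any(resp_band)) abort("Recording too short for spectral rate estimation.")
  f_resp <- sp$freq[resp_band][which.max(sp$power[resp_band])]
  p_resp <- max(sp$power[resp_band])
  lo <- max(0.8, 2.2 * f_resp)
  card_band <- sp$freq > lo & sp$freq <= min(3.5, 0.45 * fs)
  f_card <- NA_real_
  if (any(card_band)) {
    p_card <- max(sp$power[card_band])
    if (p_card > 0.002 * p_resp) {
      f_card <- sp$freq[card_band][which.max(sp$power[card_band])]
    }
  }
  list(f_resp = f_resp, f_card = f_card)
}

# Zero-phase low-pass via FFT with a raised-cosine transition band and
# mirror padding. Exactly unit gain below the transition, zero above it.
fft_lowpass <- function(z, fs, f_lo, f_hi) {
  n <- length(z)
  pad <- min(n - 1L, as.integer(round(10 * fs)))
  zp <- c(rev(z[2:(pad + 1L)]), z, rev(z[(n - pad):(n - 1L)]))
  m <- length(zp)
  fr <- c(0, seq_len(m - 1)) * fs / m
  fr <- pmin(fr, fs - fr) # two-sided frequency magnitude
  H <- ifelse(fr <= f_lo, 1,
    ifelse(fr >= f_hi, 0, 0.5 * (1 + cos(pi * (fr - f_lo) / (f_hi - f_lo))))
  )
  zf <- Re(fft(fft(zp) * H, inverse = TRUE)) / m
  zf[(pad + 1L):(pad + n)]
}

#' Filter the cardiac component out of the global signal
#'
#' Zero-phase low-pass with cutoff midway between the respiratory and
#' cardiac fundamental frequencies. The filter has exactly unit gain in the
#' passband (a raised-cosine transition band of half-width one quarter of
#' the smaller cutoff-to-fundamental distance), so respiratory amplitude is
#' preserved. When the two fundamentals are closer than 0.2 Hz a warning is
#' issued and the cutoff is placed at their geometric mean. When no cardiac
#' component is detected and no estimate is supplied, the signal is
#' returned unchanged.
#'
#' @param gs Global signal tibble from [global_signal()].
#' @param hr_estimate Optional cardiac fundamental frequency, Hz.
#' @param fs Sampling rate (defaults to the `fs` attribute of `gs`).
#' @return The global signal tibble with `z` replaced; attributes
#'   `resp_freq`, `cardiac_freq` and `cutoff` record the estimates.
#' @export
filter_cardiac <- function(gs, hr_estimate = NULL, fs = NULL) {
  fs <- gs_fs(gs, fs)
  est <- estimate_rates(gs, fs)
  f_resp <- est$f_resp
  f_card <- hr_estimate %||% est$f_card
  if (!is.na(f_card) && f_card <= f_resp) {
    abort(sprintf(
      "Cardiac frequency (%.3g Hz) must exceed the respiratory frequency (%.3g Hz).",
      f_card, f_resp
    ))
  }
  if (!is.na(f_card) && fs <= 2 * f_card) {
    abort("Sampling rate must exceed twice the cardiac frequency.")
  }
  attr(gs, "fs") <- fs
  attr(gs, "resp_freq") <- f_resp
  attr(gs, "cardiac_freq") <- f_card
  if (is.na(f_card)) {
    attr(gs, "cutoff") <- NA_real_
    return(gs)
  }
  if (f_card - f_resp < 0.2) {
    warn(sprintf(
      "Respiratory (%.3g Hz) and cardiac (%.3g Hz) peaks are closer than 0.2 Hz; cutoff at geometric mean.",
      f_resp, f_card
    ))
    fc <- sqrt(f_resp * f_card)
  } else {
    fc <- (f_resp + f_card) / 2
  }
  hw <- 0.25 * min(f_card - fc, fc - f_resp)
  hw <- max(hw, 0.01)
  gs$z <- fft_lowpass(gs$z, fs, fc - hw, fc + hw)
  attr(gs, "cutoff") <- fc
  gs
}

# Collapse runs of equal values to their center index, then return strict
# local extrema of the collapsed series as (index, type) with type +1 for
# peaks and -1 for troughs. Plateau extrema are reported at the plateau
# center.
local_extrema <- function(z) {
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centers <- as.integer(floor((starts + ends) / 2))
  v <- r$values
  m <- length(v)
  if (m < 3L) {
    return(tibble(i = integer(), type = integer()))
  }
  core <- 2:(m - 1)
  is_pk <- v[core] > v[core - 1] & v[core] > v[core + 1]
  is_tr <- v[core] < v[core - 1] & v[core] < v[core + 1]
  tibble(
    i = centers[core][is_pk | is_tr],
    type = ifelse(is_pk[is_pk | is_tr], 1L, -1L)
  )
}

# Prune an alternating extrema sequence: repeatedly drop the adjacent
# peak/trough pair with the smallest swing that falls below the local
# prominence requirement. Preserves alternation.
prune_extrema <- function(idx, type, z, prom_at) {
  repeat {
    m <- length(idx)
    if (m < 2L) {
      return(list(i = idx, type = type))
    }
    swings <- abs(z[idx[-1]] - z[idx[-m]])
    req <- prom_at((idx[-m] + idx[-1]) / 2)
    ratio <- swings / req
    k <- which.min(ratio)
    if (ratio[k] >= 1) {
      return(list(i = idx, type = type))
    }
    idx <- idx[-c(k, k + 1L)]
    type <- type[-c(k, k + 1L)]
  }
}

#' Segment breaths from the global impedance signal
#'
#' Alternating troughs (end-expiration) and peaks (end-inspiration) are
#' detected by prominence-gated extremum detection: a swing counts only if
#' it exceeds `prominence_frac` times the local rolling tidal-amplitude
#' estimate. Each trough-peak-trough triple is one breath; breaths shorter
#' than `breath_min_s` or longer than `breath_max_s` are discarded.
#'
#' The tidal swing `dz` is drift-compensated: it is the peak value minus
#' the straight line connecting the two flanking end-expiratory troughs,
#' evaluated at the peak time. When the end-expiratory level is steady the
#' two definitions coincide; when it drifts (e.g. right after ventilator
#' disconnection or reconnection) the line-referenced swing removes the
#' first-order baseline contamination from the volume surrogate.
#'
#' @param gs Global signal tibble, normally cardiac-filtered.
#' @param prominence_frac Fraction of the local tidal amplitude required as
#'   extremum prominence (default 0.3).
#' @param breath_min_s,breath_max_s Admissible breath duration bounds, s.
#' @param amp_win_s Window length for the rolling amplitude estimate, s.
#' @param fs Sampling rate (defaults to the `fs` attribute of `gs`).
#' @return A tibble of class `eit_breaths`, one row per breath, in time
#'   order: `breath`, `i_exp_start`, `i_insp_peak`, `i_exp_end`, `t_start`,
#'   `duration`, `rr`, `eeli` (signal at the end-expiratory trough), `dz`
#'   (drift-compensated peak-to-trough swing). Empty when no breath is
#'   found.
#' @export
segment_breaths <- function(gs, prominence_frac = 0.3, breath_min_s = 1,
                            breath_max_s = 15, amp_win_s = 30, fs = NULL) {
  fs <- gs_fs(gs, fs)
  z <- gs$z
  n <- length(z)
  t0 <- gs$t[1] %||% 0

  empty <- tibble(
    breath = integer(), i_exp_start = integer(), i_insp_peak = integer(),
    i_exp_end = integer(), t_start = numeric(), duration = numeric(),
    rr = numeric(), eeli = numeric(), dz = numeric()
  )
  class(empty) <- c("eit_breaths", class(empty))
  if (n < 3L || diff(range(z)) == 0) {
    return(empty)
  }

  # Rolling tidal-amplitude estimate: baseline-detrended signal, windowed
  # 5%-95% spread, interpolated across window centers.
  base <- stats::runmed(z, odd_window(15 * fs, n), endrule = "median")
  zc <- z - base
  wlen <- max(8L, as.integer(round(amp_win_s * fs)))
  centers <- unique(pmin(seq(1L, n, by = max(1L, wlen %/% 2L)), n))
  amp <- vapply(centers, function(ci) {
    a <- max(1L, ci - wlen %/% 2L)
    b <- min(n, ci + wlen %/% 2L)
    as.numeric(quantile(zc[a:b], 0.95) - quantile(zc[a:b], 0.05))
  }, numeric(1))
  amp_floor <- 0.05 * max(amp)
  prom_at <- function(i) {
    prominence_frac * pmax(approx(centers, amp, xout = i, rule = 2)$y, amp_floor)
  }

  ext <- local_extrema(z)
  if (nrow(ext) < 3L) {
    return(empty)
  }
  pruned <- prune_extrema(ext$i, ext$type, z, prom_at)
  idx <- pruned$i
  type <- pruned$type
  if (length(idx) < 3L) {
    return(empty)
  }

  tr <- which(type == -1L)
  rows <- list()
  for (k in tr) {
    if (k + 2L > length(idx)) break
    if (type[k + 1L] != 1L || type[k + 2L] != -1L) next
    a <- idx[k]
    p <- idx[k + 1L]
    b <- idx[k + 2L]
    dur <- (b - a) / fs
    if (dur < breath_min_s || dur > breath_max_s) next
    rows[[length(rows) + 1L]] <- tibble(
      i_exp_start = a, i_insp_peak = p, i_exp_end = b,
      t_start = t0 + (a - 1L) / fs, duration = dur, rr = 60 / dur,
      eeli = z[a],
      dz = z[p] - (z[a] + (z[b] - z[a]) * (p - a) / (b - a))
    )
  }
  if (!length(rows)) {
    return(empty)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, breath = dplyr::row_number(), .before = 1)
  class(out) <- c("eit_breaths", class(out))
  out
}

window_cv <- function(x) {
  if (length(x) < 2L) {
    return(0)
  }
  m <- mean(x)
  if (m == 0) {
    return(Inf)
  }
  stats::sd(x) / abs(m)
}

#' Automatically select stable tidal-breathing periods
#'
#' Maximal runs of consecutive breaths whose tidal swing and duration both
#' have a coefficient of variation at most `cv_max`, containing at least
#' `min_breaths` breaths, not spanning any step-event segment boundary or
#' SBT phase boundary, and containing at most `artifact_frac_max` unrepaired
#' artifact frames (repaired spike frames are tracked separately and
#' limited by `spike_frac_max`). Runs are returned longest-first within
#' each phase.
#'
#' @param breaths Breath table from [segment_breaths()].
#' @param clean Optional `eit_clean` result; supplies the artifact report
#'   and step segments.
#' @param ann Optional `sbt_annotation`; runs never cross phase boundaries
#'   and periods carry a `phase` column (`pre`/`sbt`/`post`).
#' @param min_breaths Minimum breaths per period (default 5).
#' @param cv_max Maximum coefficient of variation of tidal swing and of
#'   breath duration (default 0.25).
#' @param artifact_frac_max Maximum fraction of unrepaired artifact frames
#'   in a period (default 0.01).
#' @param spike_frac_max Maximum fraction of repaired spike frames (default
#'   0.05).
#' @param max_gap_frames Largest frame gap between consecutive breaths
#'   still treated as contiguous.
#' @return A tibble of class `eit_periods`: `period_id`, `phase`,
#'   `breath_first`, `breath_last` (row ranges into `breaths`), frame and
#'   time extents, `n_breaths`, `cv_dz`, `cv_duration`,
#'   `artifact_fraction`, `spike_fraction`. Empty tibble when nothing
#'   qualifies.
#' @export
select_stable_periods <- function(breaths, clean = NULL, ann = NULL,
                                  min_breaths = 5L, cv_max = 0.25,
                                  artifact_frac_max = 0.01,
                                  spike_frac_max = 0.05,
                                  max_gap_frames = 3L) {
  empty <- tibble(
    period_id = integer(), phase = character(), breath_first = integer(),
    breath_last = integer(), i_start = integer(), i_end = integer(),
    t_start = numeric(), t_end = numeric(), n_breaths = integer(),
    cv_dz = numeric(), cv_duration = numeric(),
    artifact_fraction = numeric(), spike_fraction = numeric()
  )
  class(empty) <- c("eit_periods", class(empty))
  m <- nrow(breaths)
  if (m == 0) {
    return(empty)
  }

  phase <- rep("all", m)
  if (!is.null(ann)) {
    phase <- dplyr::case_when(
      breaths$t_start < ann$t_sbt_start ~ "pre",
      breaths$t_start < ann$t_sbt_end ~ "sbt",
      TRUE ~ "post"
    )
  }
  step_frames <- integer(0)
  unrepaired <- integer(0)
  spikes <- integer(0)
  if (!is.null(clean)) {
    step_frames <- clean$report$frame[clean$report$kind == "step"]
    unrepaired <- clean$report$frame[clean$report$kind %in% c("unrepaired", "nonfinite")]
    spikes <- clean$report$frame[clean$report$kind == "spike"]
  }

  has_step <- vapply(seq_len(m), function(k) {
    any(step_frames >= breaths$i_exp_start[k] & step_frames <= breaths$i_exp_end[k])
  }, logical(1))

  break_after <- rep(FALSE, m)
  if (m > 1) {
    gap <- breaths$i_exp_start[-1] - breaths$i_exp_end[-m]
    break_after[-m] <- gap > max_gap_frames | phase[-1] != phase[-m]
  }
  # step-containing breaths act as hard breaks and are excluded themselves
  chunk <- cumsum(c(0L, as.integer(break_after[-m]))) + cumsum(as.integer(has_step)) * m
  chunk[has_step] <- NA_integer_

  periods <- list()
  for (ch in unique(stats::na.omit(chunk))) {
    rows <- which(!is.na(chunk) & chunk == ch)
    mm <- length(rows)
    i <- 1L
    while (i <= mm) {
      j <- i
      while (j < mm) {
        win <- rows[i:(j + 1L)]
        if (window_cv(breaths$dz[win]) <= cv_max &&
          window_cv(breaths$duration[win]) <= cv_max) {
          j <- j + 1L
        } else {
          break
        }
      }
      if (j - i + 1L >= min_breaths) {
        win <- rows[i:j]
        fa <- breaths$i_exp_start[win[1]]
        fb <- breaths$i_exp_end[win[length(win)]]
        nfr <- fb - fa + 1L
        periods[[length(periods) + 1L]] <- tibble(
          phase = phase[win[1]],
          breath_first = win[1], breath_last = win[length(win)],
          i_start = fa, i_end = fb,
          t_start = breaths$t_start[win[1]],
          t_end = breaths$t_start[win[length(win)]] +
            breaths$duration[win[length(win)]],
          n_breaths = length(win),
          cv_dz = window_cv(breaths$dz[win]),
          cv_duration = window_cv(breaths$duration[win]),
          artifact_fraction = sum(unrepaired >= fa & unrepaired <= fb) / nfr,
          spike_fraction = sum(spikes >= fa & spikes <= fb) / nfr
        )
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(periods)) {
    return(empty)
  }
  out <- dplyr::bind_rows(periods)
  out <- out[out$artifact_fraction <= artifact_frac_max &
    out$spike_fraction <= spike_frac_max, , drop = FALSE]
  if (nrow(out) == 0) {
    return(empty)
  }
  out$phase <- factor(out$phase, levels = intersect(
    c("pre", "sbt", "post", "all"), unique(out$phase)
  ))
  out <- dplyr::arrange(out, .data$phase, dplyr::desc(.data$n_breaths), .data$t_start)
  out$phase <- as.character(out$phase)
  out <- dplyr::mutate(out, period_id = dplyr::row_number(), .before = 1)
  class(out) <- c("eit_periods", class(out))
  out
}

#' Breaths belonging to stable periods
#'
#' @param breaths Breath table from [segment_breaths()].
#' @param periods Period table from [select_stable_periods()].
#' @return The subset of `breaths` inside a stable period, with added
#'   `period_id` and `phase` columns.
#' @export
stable_breaths <- function(breaths, periods) {
  if (nrow(periods) == 0 || nrow(breaths) == 0) {
    out <- breaths[integer(0), , drop = FALSE]
    out$period_id <- integer(0)
    out$phase <- character(0)
    return(out)
  }
  picks <- purrr::map(seq_len(nrow(periods)), function(k) {
    rows <- periods$breath_first[k]:periods$breath_last[k]
    out <- breaths[rows, , drop = FALSE]
    out$period_id <- periods$period_id[k]
    out$phase <- periods$phase[k]
    out
  })
  dplyr::arrange(dplyr::bind_rows(picks), .data$t_start)
}
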