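# Synthetic EIT scenario generator with full ground truth. Emulates tidal
# breathing inside a two-lobe lung mask, a cardiac-frequency oscillation,
# end-expiratory level (EELI) shifts around a spontaneous breathing trial,
# pixel noise and spike/step artifacts, so every downstream stage has a
# parameter-recovery test bed.

#' Scenario configuration for the synthetic EIT generator
#'
#' All knobs of the generator in one flat list. The defaults encode the
#' reference SBT scenario used throughout the test suite: a 2-minute
#' pre-SBT baseline, a 5-minute T-piece trial and a 2-minute
#' post-reconnection phase; respiratory rate rising from 15 to
#' 25 breaths/min at SBT start; a 20% EELI drop during the SBT with
#' incomplete (-10%) recovery afterwards; a 15% tidal impedance drop with
#' full recovery; a cardiac oscillation at 90 beats/min with amplitude 20%
#' of the tidal swing; and spike artifacts on 1% of frames.
#'
#' @param nrow,ncol Reconstruction grid size (pixels).
#' @param fs Frame rate, Hz.
#' @param pre_s,sbt_s,post_s Phase durations, seconds.
#' @param rr_pre,rr_sbt,rr_post Respiratory rate per phase, breaths/min.
#' @param vt_au Global tidal impedance amplitude, AU; the per-pixel
#'   amplitude map sums to this value over lung pixels.
#' @param vt_scale_sbt,vt_scale_post Multiplicative tidal amplitude scaling
#'   during and after the SBT.
#' @param eeli_au Baseline end-expiratory lung impedance, AU.
#' @param eeli_frac_sbt,eeli_frac_post Fractional EELI offset (relative to
#'   baseline) targeted during and after the SBT; transitions are
#'   exponential with time constant `transition_tau_s`.
#' @param transition_tau_s Time constant of EELI phase transitions, s.
#' @param drift_au_per_min Slow linear EELI drift superimposed on the
#'   whole recording, AU/min.
#' @param gamma,gamma_sbt,gamma_post Ventilation inhomogeneity exponent per
#'   phase (`NULL` = same as `gamma`). The amplitude map is a smooth
#'   log-normal random field raised to this power and renormalized;
#'   `gamma = 0` gives perfectly uniform amplitudes (GI = 0) and larger
#'   values give heavier-tailed spatial spread (larger GI).
#' @param smooth_sd Spatial smoothing of the random field, pixels.
#' @param hr Cardiac rate, beats/min (must exceed every respiratory rate).
#' @param cardiac_amp Cardiac oscillation amplitude in the global lung
#'   signal, as a fraction of `vt_au`.
#' @param noise_sd Per-pixel white noise standard deviation, AU.
#' @param spike_rate Fraction of frames receiving a single-pixel spike
#'   artifact.
#' @param spike_mag Spike magnitude as a multiple of `vt_au`.
#' @param step_times,step_mag Times (s) and global magnitudes (AU) of
#'   sudden baseline step artifacts (e.g. belt contact changes).
#' @param insp_frac Inspiratory fraction of the breath cycle.
#' @param ml_per_au True ventilator calibration factor, ml per AU.
#' @param tco2_baseline,tco2_rise Transcutaneous CO2 auxiliary channel:
#'   baseline (mmHg) and linear rise reached at SBT end (mmHg).
#' @param outcome SBT outcome recorded in the annotation.
#' @param seed Integer seed; the whole scenario is deterministic given it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(nrow = 32, ncol = 32, fs = 50.2,
                            pre_s = 120, sbt_s = 300, post_s = 120,
                            rr_pre = 15, rr_sbt = 25, rr_post = 15,
                            vt_au = 100, vt_scale_sbt = 0.85, vt_scale_post = 1,
                            eeli_au = 1000, eeli_frac_sbt = -0.20,
                            eeli_frac_post = -0.10, transition_tau_s = 8,
                            drift_au_per_min = 0,
                            gamma = 0.5, gamma_sbt = NULL, gamma_post = NULL,
                            smooth_sd = 2,
                            hr = 90, cardiac_amp = 0.2,
                            noise_sd = 0.1,
                            spike_rate = 0.01, spike_mag = 3,
                            step_times = numeric(0), step_mag = numeric(0),
                            insp_frac = 0.4, ml_per_au = 4,
                            tco2_baseline = 40, tco2_rise = 0,
                            outcome = "unknown", seed = 1L) {
  cfg <- list(
    nrow = nrow, ncol = ncol, fs = fs,
    pre_s = pre_s, sbt_s = sbt_s, post_s = post_s,
    rr_pre = rr_pre, rr_sbt = rr_sbt, rr_post = rr_post,
    vt_au = vt_au, vt_scale_sbt = vt_scale_sbt, vt_scale_post = vt_scale_post,
    eeli_au = eeli_au, eeli_frac_sbt = eeli_frac_sbt,
    eeli_frac_post = eeli_frac_post, transition_tau_s = transition_tau_s,
    drift_au_per_min = drift_au_per_min,
    gamma = gamma, gamma_sbt = gamma_sbt %||% gamma,
    gamma_post = gamma_post %||% gamma, smooth_sd = smooth_sd,
    hr = hr, cardiac_amp = cardiac_amp, noise_sd = noise_sd,
    spike_rate = spike_rate, spike_mag = spike_mag,
    step_times = as.numeric(unlist(step_times)),
    step_mag = as.numeric(unlist(step_mag)),
    insp_frac = insp_frac, ml_per_au = ml_per_au,
    tco2_baseline = tco2_baseline, tco2_rise = tco2_rise,
    outcome = outcome, seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  rr <- c(cfg$rr_pre, cfg$rr_sbt, cfg$rr_post)
  if (any(rr <= 0)) abort("Respiratory rates must be positive.")
  if (cfg$hr <= max(rr)) {
    abort("Cardiac rate `hr` must exceed every respiratory rate.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (any(c(cfg$pre_s, cfg$sbt_s, cfg$post_s) <= 0)) {
    abort("Phase durations must be positive.")
  }
  if (any(c(cfg$gamma, cfg$gamma_sbt, cfg$gamma_post) < 0)) {
    abort("Inhomogeneity exponents must be >= 0.")
  }
  if (length(cfg$step_times) != length(cfg$step_mag)) {
    abort("`step_times` and `step_mag` must have the same length.")
  }
  if (!(cfg$insp_frac > 0 && cfg$insp_frac < 1)) {
    abort("`insp_frac` must be in (0, 1).")
  }
  invisible(cfg)
}

#' Read/write a scenario configuration (YAML, flat keys)
#' @param path Path to the YAML file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), names(formals(scenario_config)))
  if (length(bad)) {
    abort(sprintf(
      "Unknown scenario key(s): %s. Valid keys: %s.",
      paste(bad, collapse = ", "),
      paste(names(formals(scenario_config)), collapse = ", ")
    ))
  }
  do.call(scenario_config, y)
}

#' @rdname read_scenario_config
#' @param cfg A `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Packaged SBT scenario presets
#'
#' `scenario_success()` emulates a successful T-piece trial: moderate
#' ventilation inhomogeneity that increases somewhat during the trial, a
#' tidal swing that recovers fully on reconnection while EELI does not, and
#' a flat transcutaneous CO2 channel. `scenario_failure()` emulates a
#' failing trial: markedly higher inhomogeneity in every phase, faster and
#' shallower breathing during the trial, and a rising CO2 channel.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_success <- function(seed = 1L, ...) {
  args <- modifyList(
    list(
      gamma = 0.4, gamma_sbt = 0.7, gamma_post = 0.45,
      tco2_rise = 2, outcome = "success", seed = seed
    ),
    list(...)
  )
  do.call(scenario_config, args)
}

#' @rdname scenario_success
#' @export
scenario_failure <- function(seed = 2L, ...) {
  args <- modifyList(
    list(
      gamma = 1.5, gamma_sbt = 1.5, gamma_post = 1.5,
      rr_sbt = 30, vt_scale_sbt = 0.8,
      tco2_baseline = 45, tco2_rise = 15, outcome = "failure", seed = seed
    ),
    list(...)
  )
  do.call(scenario_config, args)
}

#' Two-lobe elliptical lung mask
#'
#' Convenience mask builder: two elliptical lung fields on the grid, the
#' standard stand-in for patient-specific lung contours.
#'
#' @param nrow,ncol Grid size.
#' @return A `lung_mask`.
#' @export
make_lung_mask <- function(nrow = 32, ncol = 32) {
  r <- base::row(matrix(0, nrow, ncol))
  c <- base::col(matrix(0, nrow, ncol))
  in_ellipse <- function(cr, cc, ar, ac) {
    ((r - cr) / ar)^2 + ((c - cc) / ac)^2 <= 1
  }
  m <- in_ellipse(0.52 * nrow, 0.30 * ncol, 0.30 * nrow, 0.16 * ncol) |
    in_ellipse(0.52 * nrow, 0.70 * ncol, 0.30 * nrow, 0.16 * ncol)
  lung_mask(m * 1)
}

# Separable Gaussian smoothing with replicated edges.
gauss_smooth <- function(m, sd) {
  if (sd <= 0) {
    return(m)
  }
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-((-half:half)^2) / (2 * sd^2))
  k <- k / sum(k)
  smooth_vec <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(m, 1, smooth_vec))
}

# Smooth log-normal amplitude field raised to power gamma, renormalized so
# lung pixels sum to vt_au. gamma = 0 gives uniform amplitudes.
amplitude_map <- function(field_z, gamma, mask, vt_au) {
  amp <- exp(gamma * field_z)
  amp[!mask$mask] <- 0
  amp * (vt_au / sum(amp[mask$mask]))
}

# Raised-cosine breath cycle: 0 at end-expiration, 1 at end-inspiration,
# inspiration occupying `insp_frac` of the cycle. Smooth with zero slope at
# both extrema, giving flattened end-expiratory troughs.
resp_wave <- function(u, insp_frac) {
  ifelse(
    u < insp_frac,
    (1 - cos(pi * u / insp_frac)) / 2,
    (1 + cos(pi * (u - insp_frac) / (1 - insp_frac))) / 2
  )
}

#' Global inhomogeneity index of a noiseless amplitude map
#'
#' Direct evaluation of the GI definition on a known per-pixel amplitude
#' map: the sum over lung pixels of absolute deviations from the lung-pixel
#' median, divided by the sum of amplitudes. Serves as the independent
#' oracle for [compute_gi()].
#'
#' @param amp Numeric matrix of per-pixel tidal amplitudes.
#' @param mask A `lung_mask`.
#' @return GI value (dimensionless, >= 0; 0 for a uniform map).
#' @export
true_gi_of_map <- function(amp, mask) {
  if (!identical(dim(amp), dim(mask$mask))) {
    abort("Amplitude map and mask dimensions differ.")
  }
  v <- amp[mask$mask]
  sum(abs(v - median(v))) / sum(v)
}

#' Generate a synthetic SBT session
#'
#' Builds an EIT frame sequence, lung mask, ventilator log, SBT annotation
#' and a full ground-truth record from a [scenario_config()]. The pixel
#' signal is the sum of (i) the EELI track distributed over lung pixels,
#' (ii) the phase-specific amplitude map driven by a raised-cosine breath
#' cycle, (iii) a cardiac-frequency oscillation concentrated in a medial
#' heart region, (iv) white pixel noise, and (v) spike/step artifacts. The
#' ventilator log reports exactly `ml_per_au` times the true per-breath
#' tidal impedance swing. Deterministic for a fixed seed.
#'
#' @param cfg A `scenario_config`.
#' @return A list of class `eit_scenario` with elements `seq`, `mask`,
#'   `vent`, `ann`, `truth`. `truth` holds the per-frame EELI track, the
#'   per-breath table (boundary frames, tidal swing, rate, volume, phase),
#'   the per-phase amplitude maps and their GI, the calibration factor
#'   `c_true`, and the injected artifact logs.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed, generate_scenario_impl(cfg))
}

generate_scenario_impl <- function(cfg) {
  nr <- cfg$nrow
  nc <- cfg$ncol
  npix <- nr * nc
  mask <- make_lung_mask(nr, nc)
  lung_idx <- mask_pixel_index(mask)

  total <- cfg$pre_s + cfg$sbt_s + cfg$post_s
  n <- floor(total * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  t_sbt <- cfg$pre_s
  t_post <- cfg$pre_s + cfg$sbt_s

  # Smooth standardized random field shared by all phases.
  raw <- matrix(rnorm(npix), nr, nc)
  f <- gauss_smooth(raw, cfg$smooth_sd)
  fz <- (f - mean(f[mask$mask])) / stats::sd(f[mask$mask])

  gammas <- c(pre = cfg$gamma, sbt = cfg$gamma_sbt, post = cfg$gamma_post)
  amp_maps <- lapply(gammas, function(g) amplitude_map(fz, g, mask, cfg$vt_au))
  names(amp_maps) <- names(gammas)

  phase_rr <- c(pre = cfg$rr_pre, sbt = cfg$rr_sbt, post = cfg$rr_post)
  phase_vts <- c(pre = 1, sbt = cfg$vt_scale_sbt, post = cfg$vt_scale_post)
  phase_start <- c(pre = 0, sbt = t_sbt, post = t_post)

  # Breath-by-breath timeline: parameters switch at breath boundaries.
  b_start <- numeric(0)
  b_T <- numeric(0)
  b_phase <- character(0)
  cursor <- 0
  while (cursor < total - 1e-9) {
    ph <- names(phase_start)[max(which(cursor >= phase_start - 1e-9))]
    Tk <- 60 / phase_rr[[ph]]
    b_start <- c(b_start, cursor)
    b_T <- c(b_T, Tk)
    b_phase <- c(b_phase, ph)
    cursor <- cursor + Tk
  }
  n_b <- length(b_start)
  breath_of_frame <- findInterval(t, b_start)
  u <- (t - b_start[breath_of_frame]) / b_T[breath_of_frame]
  u <- pmin(u, 1)
  w <- resp_wave(u, cfg$insp_frac) * phase_vts[b_phase[breath_of_frame]]

  # EELI track: exponential approach to per-phase targets + linear drift.
  eeli <- rep(cfg$eeli_au, n)
  e_at <- cfg$eeli_au
  for (ph in c("sbt", "post")) {
    tp <- phase_start[[ph]]
    frac <- if (ph == "sbt") cfg$eeli_frac_sbt else cfg$eeli_frac_post
    target <- cfg$eeli_au * (1 + frac)
    sel <- t >= tp
    eeli[sel] <- target + (e_at - target) * exp(-(t[sel] - tp) / cfg$transition_tau_s)
    nxt <- if (ph == "sbt") t_post else total
    e_at <- target + (e_at - target) * exp(-(nxt - tp) / cfg$transition_tau_s)
  }
  eeli <- eeli + cfg$drift_au_per_min * t / 60

  # Spatial weights: EELI share (pre-phase amplitude shape, sums to 1) and
  # cardiac weights (medial gaussian restricted to the lung, sums to 1).
  share <- amp_maps$pre[mask$mask] / cfg$vt_au
  r <- base::row(matrix(0, nr, nc))
  c <- base::col(matrix(0, nr, nc))
  hw <- exp(-(((r - 0.40 * nr)^2 + (c - 0.50 * nc)^2)) / (2 * (0.12 * (nr + nc) / 2)^2))
  hw_l <- hw[mask$mask]
  hw_l <- hw_l / sum(hw_l)
  card <- cfg$cardiac_amp * cfg$vt_au * sin(2 * pi * cfg$hr / 60 * t)

  frames <- matrix(0, n, npix)
  lung_cols <- lung_idx
  lung_rc <- which(t(mask$mask), arr.ind = FALSE) # row-major order positions
  # amp map values in row-major pixel order for lung pixels:
  amp_l <- lapply(amp_maps, function(m) as.vector(t(m))[lung_cols])
  block <- eeli %o% share + card %o% hw_l
  for (ph in names(amp_maps)) {
    sel <- b_phase[breath_of_frame] == ph
    if (any(sel)) block[sel, ] <- block[sel, ] + w[sel] %o% amp_l[[ph]]
  }
  frames[, lung_cols] <- block
  rm(block)
  if (cfg$noise_sd > 0) {
    frames <- frames + matrix(rnorm(n * npix, sd = cfg$noise_sd), n, npix)
  }

  # Spike artifacts: single-frame additive outliers on one lung pixel.
  n_spk <- round(cfg$spike_rate * n)
  spikes <- tibble(frame = integer(), pixel = integer(), magnitude = numeric())
  if (n_spk > 0) {
    sf <- sort(sample.int(n, n_spk))
    sp <- sample(lung_cols, n_spk, replace = TRUE)
    sm <- cfg$spike_mag * cfg$vt_au * sample(c(-1, 1), n_spk, replace = TRUE)
    frames[cbind(sf, sp)] <- frames[cbind(sf, sp)] + sm
    spikes <- tibble(frame = sf, pixel = sp, magnitude = sm)
  }

  # Step artifacts: sustained global baseline shifts distributed over lung.
  steps <- tibble(time_s = numeric(), frame = integer(), magnitude = numeric())
  if (length(cfg$step_times)) {
    for (k in seq_along(cfg$step_times)) {
      sel <- t >= cfg$step_times[k]
      frames[sel, lung_cols] <- frames[sel, lung_cols] +
        rep(cfg$step_mag[k] * share, each = sum(sel))
    }
    steps <- tibble(
      time_s = cfg$step_times,
      frame = pmin(pmax(ceiling(cfg$step_times * cfg$fs - 0.5), 0), n - 1L) + 1L,
      magnitude = cfg$step_mag
    )
  }

  # Per-breath ground truth. True tidal swing is the continuous-time
  # peak-to-trough amplitude of the breath.
  b_dz <- cfg$vt_au * phase_vts[b_phase]
  b_frame <- pmin(pmax(ceiling(b_start * cfg$fs - 0.5), 0), n - 1L) + 1L
  truth_breaths <- tibble(
    breath = seq_len(n_b),
    t_start = b_start,
    frame_start = as.integer(b_frame),
    duration = b_T,
    rr = 60 / b_T,
    phase = b_phase,
    dz = as.numeric(b_dz),
    eeli = eeli[b_frame],
    vt_ml = cfg$ml_per_au * as.numeric(b_dz)
  )
  truth_breaths$mv_l_min <- truth_breaths$rr * truth_breaths$vt_ml / 1000

  # Ventilator log at 1 Hz, exactly c_true * true per-breath tidal swing.
  vt_t <- seq(0, floor(total) - 1)
  vb <- findInterval(vt_t, b_start)
  vent <- vent_log(tibble(
    t_s = vt_t,
    vt_ml = cfg$ml_per_au * as.numeric(b_dz[vb]),
    rr_bpm = 60 / b_T[vb]
  ))

  # Transcutaneous CO2 channel at 1 Hz.
  tco2 <- cfg$tco2_baseline +
    cfg$tco2_rise * pmax(0, pmin(1, (vt_t - t_sbt) / cfg$sbt_s)) *
      ifelse(vt_t < t_post, 1, NA)
  post_sel <- vt_t >= t_post
  tco2[post_sel] <- cfg$tco2_baseline +
    cfg$tco2_rise * exp(-(vt_t[post_sel] - t_post) / 60)
  channels <- list(tco2 = tibble(t = vt_t, value = tco2))

  seq <- eit_sequence(frames,
    fs = cfg$fs, nrow = nr, ncol = nc, t0 = 0,
    channels = channels
  )
  ann <- sbt_annotation(0, t_sbt, t_post, total, outcome = cfg$outcome)

  truth <- structure(
    list(
      eeli = tibble(frame = seq_len(n), t = t, eeli = eeli),
      breaths = truth_breaths,
      amp_maps = amp_maps,
      gi = vapply(amp_maps, true_gi_of_map, numeric(1), mask = mask),
      c_true = cfg$ml_per_au,
      spikes = spikes,
      steps = steps,
      config = cfg
    ),
    class = "eit_ground_truth"
  )

  structure(
    list(seq = seq, mask = mask, vent = vent, ann = ann, truth = truth),
    class = "eit_scenario"
  )
}

#' @export
print.eit_scenario <- function(x, ...) {
  cat("<eit_scenario>\n")
  print(x$seq)
  print(x$ann)
  cat(sprintf(
    "  truth: %d breaths, c_true = %g ml/AU, GI(pre/sbt/post) = %.3f/%.3f/%.3f\n",
    nrow(x$truth$breaths), x$truth$c_true,
    x$truth$gi[["pre"]], x$truth$gi[["sbt"]], x$truth$gi[["post"]]
  ))
  invisible(x)
}
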