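# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Short, completely clean recording: no noise, cardiac, spikes or phase
# changes. 60 s pre / 100 s SBT / 60 s post at a constant rate and volume.
flat_scenario <- function() {
  cached("flat", generate_scenario(scenario_config(
    pre_s = 60, sbt_s = 100, post_s = 60,
    rr_pre = 15, rr_sbt = 15, rr_post = 15,
    vt_scale_sbt = 1, vt_scale_post = 1,
    eeli_frac_sbt = 0, eeli_frac_post = 0,
    cardiac_amp = 0, noise_sd = 0, spike_rate = 0,
    gamma = 0.5, seed = 42
  )))
}

# Same physiology but with cardiac oscillation, pixel noise and spikes.
noisy_flat_scenario <- function() {
  cached("noisy_flat", generate_scenario(scenario_config(
    pre_s = 60, sbt_s = 100, post_s = 60,
    rr_pre = 15, rr_sbt = 15, rr_post = 15,
    vt_scale_sbt = 1, vt_scale_post = 1,
    eeli_frac_sbt = 0, eeli_frac_post = 0,
    seed = 42
  )))
}

# The reference SBT scenario at full default conditions.
sbt_scenario <- function() {
  cached("sbt", generate_scenario(scenario_config(seed = 7)))
}

# Small lung mask + uniform tidal image helpers for parameter tests.
tiny_mask <- function(nrow = 8, ncol = 8) {
  m <- matrix(0, nrow, ncol)
  m[2:(nrow - 1), 2:(ncol - 1)] <- 1
  lung_mask(m)
}

# Tidal image with specified lung-pixel values (column-major fill order,
# matching lung_values()).
image_with_values <- function(values, mask) {
  di <- matrix(0, nrow(mask$mask), ncol(mask$mask))
  di[mask$mask] <- values
  new_tidal_image(di, mask)
}

# Random tidal image on a random elliptical mask; mixed-sign pixel values.
random_tidal_image <- function() {
  nr <- sample(10:32, 1)
  nc <- sample(10:32, 1)
  r <- row(matrix(0, nr, nc))
  c <- col(matrix(0, nr, nc))
  cr <- runif(1, 0.35, 0.65) * nr
  cc <- runif(1, 0.35, 0.65) * nc
  m <- ((r - cr) / (0.4 * nr))^2 + ((c - cc) / (0.4 * nc))^2 <= 1
  if (sum(m) < 4) m[cr, cc] <- TRUE
  mask <- lung_mask(m * 1)
  v <- stats::rlnorm(mask$n_lung_pixels) - 0.2 # a few negative pixels
  image_with_values(v, mask)
}

# Minimal hand-built breath table for calibration/parameter arithmetic.
manual_breaths <- function(dz, t_start, duration = 3, fs = 50) {
  n <- length(dz)
  tibble::tibble(
    breath = seq_len(n),
    i_exp_start = as.integer(round(t_start * fs)) + 1L,
    i_insp_peak = as.integer(round((t_start + duration * 0.4) * fs)) + 1L,
    i_exp_end = as.integer(round((t_start + duration) * fs)) + 1L,
    t_start = t_start,
    duration = duration,
    rr = 60 / duration,
    eeli = 1000,
    dz = dz
  )
}
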