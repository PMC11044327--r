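# Artifact handling, cardiac filtering, breath segmentation and
# stable-period selection, validated against generator ground truth.

test_that("a clean recording yields zero flagged frames", {
  sc <- noisy_flat_scenario() # noise + cardiac, but no artifacts
  cl <- remove_artifacts(generate_scenario(scenario_config(
    pre_s = 60, sbt_s = 100, post_s = 60,
    rr_pre = 15, rr_sbt = 15, rr_post = 15,
    vt_scale_sbt = 1, vt_scale_post = 1,
    eeli_frac_sbt = 0, eeli_frac_post = 0,
    spike_rate = 0, seed = 42
  ))$seq, sc$mask)
  expect_identical(nrow(cl$report), 0L)
  expect_identical(nrow(cl$segments), 1L)
})

test_that("injected spikes are found and repaired without losing breaths", {
  cfg <- scenario_config(
    pre_s = 60, sbt_s = 100, post_s = 60,
    rr_pre = 15, rr_sbt = 15, rr_post = 15,
    vt_scale_sbt = 1, vt_scale_post = 1,
    eeli_frac_sbt = 0, eeli_frac_post = 0,
    spike_rate = 10 / floor(220 * 50.2), # exactly 10 spike frames
    seed = 13
  )
  sc <- generate_scenario(cfg)
  expect_identical(nrow(sc$truth$spikes), 10L)
  cl <- remove_artifacts(sc$seq, sc$mask)
  found <- cl$report$frame[cl$report$kind == "spike"]
  expect_gte(sum(sc$truth$spikes$frame %in% found), 9L)

  gs <- filter_cardiac(global_signal(cl$seq, sc$mask))
  br <- segment_breaths(gs)
  n_true <- nrow(sc$truth$breaths)
  expect_gte(nrow(br), n_true - 2L) # edge breaths may be partial
})

test_that("a large step is flagged once, within one second of the truth", {
  cfg <- scenario_config(
    pre_s = 60, sbt_s = 100, post_s = 60,
    rr_pre = 15, rr_sbt = 15, rr_post = 15,
    vt_scale_sbt = 1, vt_scale_post = 1,
    eeli_frac_sbt = 0, eeli_frac_post = 0,
    spike_rate = 0,
    step_times = 111, step_mag = 5 * 100, # 5 x tidal amplitude
    seed = 8
  )
  sc <- generate_scenario(cfg)
  cl <- remove_artifacts(sc$seq, sc$mask)
  steps <- cl$report[cl$report$kind == "step", ]
  expect_identical(nrow(steps), 1L)
  expect_lt(abs(steps$frame - sc$truth$steps$frame) / 50.2, 1)
  expect_identical(nrow(cl$segments), 2L)
})

test_that("an almost entirely corrupted recording is rejected", {
  m <- matrix(rep(sin((1:100) / 5), 4), 100, 4)
  m[sample(c(rep(TRUE, 60), rep(FALSE, 40))), ] <- NaN # 60% bad frames
  s <- eit_sequence(m, fs = 10, nrow = 2, ncol = 2)
  msk <- lung_mask(matrix(1, 2, 2))
  expect_error(remove_artifacts(s, msk), "Unusable")
})

test_that("cardiac filtering preserves the tidal swing within 5%", {
  sc <- noisy_flat_scenario() # cardiac at 90/min, amplitude 20% of swing
  cl <- remove_artifacts(sc$seq, sc$mask)
  gs <- global_signal(cl$seq, sc$mask)
  gsf <- filter_cardiac(gs)
  expect_equal(attr(gsf, "cardiac_freq"), 1.5, tolerance = 0.05)
  br <- segment_breaths(gsf)
  mid <- br[br$t_start > 10 & br$t_start < 200, ]
  true_dz <- sc$truth$config$vt_au
  expect_true(all(abs(mid$dz - true_dz) / true_dz < 0.05))
})

test_that("without a cardiac component the filter is a near-identity", {
  sc <- flat_scenario()
  gs <- global_signal(sc$seq, sc$mask)
  gsf <- filter_cardiac(gs)
  expect_true(is.na(attr(gsf, "cutoff")))
  expect_lt(max(abs(gsf$z - gs$z)), 0.01 * sc$truth$config$vt_au)
})

test_that("a cardiac estimate at or below the respiratory rate is rejected", {
  sc <- flat_scenario()
  gs <- global_signal(sc$seq, sc$mask)
  expect_error(filter_cardiac(gs, hr_estimate = 0.2), "exceed")
})

test_that("close respiratory and cardiac peaks trigger the geometric-mean fallback", {
  sc <- flat_scenario() # resp at 0.25 Hz
  gs <- global_signal(sc$seq, sc$mask)
  expect_warning(gsf <- filter_cardiac(gs, hr_estimate = 0.40), "geometric mean")
  expect_equal(attr(gsf, "cutoff"), sqrt(0.25 * 0.40), tolerance = 0.05)
})

test_that("noiseless breath segmentation recovers count, boundaries and rate", {
  sc <- flat_scenario()
  gs <- global_signal(sc$seq, sc$mask)
  br <- segment_breaths(gs)
  tb <- sc$truth$breaths
  # every fully contained true breath is found
  expect_gte(nrow(br), nrow(tb) - 2L)
  for (k in seq_len(nrow(br))) {
    j <- which.min(abs(tb$frame_start - br$i_exp_start[k]))
    expect_lte(abs(tb$frame_start[j] - br$i_exp_start[k]), 2L)
  }
  expect_lt(abs(mean(br$rr) - 15), 0.5)
  expect_true(all(abs(br$dz - 100) / 100 < 0.02))
})

test_that("a constant signal yields an empty breath list", {
  gs <- tibble::tibble(frame = 1:500, t = (0:499) / 50, z = rep(7, 500))
  attr(gs, "fs") <- 50
  expect_identical(nrow(segment_breaths(gs)), 0L)
})

test_that("rapid shallow breathing at 35/min is fully segmented", {
  sc <- generate_scenario(scenario_config(
    pre_s = 30, sbt_s = 60, post_s = 30,
    rr_pre = 35, rr_sbt = 35, rr_post = 35,
    vt_scale_sbt = 1, vt_scale_post = 1,
    eeli_frac_sbt = 0, eeli_frac_post = 0,
    cardiac_amp = 0, noise_sd = 0, spike_rate = 0, hr = 110, seed = 4
  ))
  br <- segment_breaths(global_signal(sc$seq, sc$mask))
  expect_gte(nrow(br), nrow(sc$truth$breaths) - 2L)
  expect_equal(mean(br$duration), 60 / 35, tolerance = 0.02)
})

test_that("detected breaths never overlap and fit the recording", {
  sc <- sbt_scenario()
  cl <- remove_artifacts(sc$seq, sc$mask)
  br <- segment_breaths(filter_cardiac(global_signal(cl$seq, sc$mask)))
  expect_true(all(diff(br$i_exp_start) > 0))
  expect_true(all(br$i_exp_start[-1] >= br$i_exp_end[-nrow(br)]))
  expect_lte(sum(br$duration), n_frames(sc$seq) / sc$seq$fs)
})

test_that("spikes at up to 1% of frames barely perturb per-breath swings", {
  for (seed in c(31, 32, 33)) {
    base_cfg <- scenario_config(
      pre_s = 40, sbt_s = 40, post_s = 40,
      rr_pre = 15, rr_sbt = 15, rr_post = 15,
      vt_scale_sbt = 1, vt_scale_post = 1,
      eeli_frac_sbt = 0, eeli_frac_post = 0,
      spike_rate = 0, noise_sd = 0, cardiac_amp = 0, seed = seed
    )
    spiky_cfg <- scenario_config(
      pre_s = 40, sbt_s = 40, post_s = 40,
      rr_pre = 15, rr_sbt = 15, rr_post = 15,
      vt_scale_sbt = 1, vt_scale_post = 1,
      eeli_frac_sbt = 0, eeli_frac_post = 0,
      spike_rate = 0.01, noise_sd = 0, cardiac_amp = 0, seed = seed
    )
    clean <- generate_scenario(base_cfg)
    spiky <- generate_scenario(spiky_cfg)
    br0 <- segment_breaths(global_signal(clean$seq, clean$mask))
    cl <- remove_artifacts(spiky$seq, spiky$mask)
    br1 <- segment_breaths(global_signal(cl$seq, spiky$mask))
    shared <- min(nrow(br0), nrow(br1))
    expect_true(all(
      abs(br1$dz[1:shared] - br0$dz[1:shared]) / br0$dz[1:shared] < 0.05
    ))
  }
})

test_that("a clean constant-rate recording yields one all-covering stable period per phase", {
  sc <- flat_scenario()
  cl <- remove_artifacts(sc$seq, sc$mask)
  br <- segment_breaths(global_signal(cl$seq, sc$mask))
  per <- select_stable_periods(br, cl)
  expect_identical(nrow(per), 1L)
  expect_identical(per$n_breaths, nrow(br))
  # with phase annotations, one period per phase instead
  per3 <- select_stable_periods(br, cl, sc$ann)
  expect_identical(nrow(per3), 3L)
  expect_identical(sum(per3$n_breaths), nrow(br))
})

test_that("no stable period spans a step event", {
  cfg <- scenario_config(
    pre_s = 60, sbt_s = 100, post_s = 60,
    rr_pre = 15, rr_sbt = 15, rr_post = 15,
    vt_scale_sbt = 1, vt_scale_post = 1,
    eeli_frac_sbt = 0, eeli_frac_post = 0,
    spike_rate = 0, step_times = 111, step_mag = 500, seed = 8
  )
  sc <- generate_scenario(cfg)
  cl <- remove_artifacts(sc$seq, sc$mask)
  br <- segment_breaths(filter_cardiac(global_signal(cl$seq, sc$mask)))
  per <- select_stable_periods(br, cl)
  step_frame <- cl$report$frame[cl$report$kind == "step"]
  expect_true(all(per$i_end < step_frame | per$i_start > step_frame))
})

test_that("alternating tidal volumes above the CV limit yield no stable period", {
  dz <- rep(c(1, 2), 10)
  br <- manual_breaths(dz, t_start = seq(0, by = 3, length.out = 20))
  expect_gt(sd(dz) / mean(dz), 0.25)
  per <- select_stable_periods(br)
  expect_identical(nrow(per), 0L)
})

test_that("the stability screen is scale invariant", {
  sc <- noisy_flat_scenario()
  cl <- remove_artifacts(sc$seq, sc$mask)
  gs <- filter_cardiac(global_signal(cl$seq, sc$mask))
  br1 <- segment_breaths(gs)
  gs2 <- gs
  gs2$z <- gs$z * 37.5
  br2 <- segment_breaths(gs2)
  expect_identical(br1$i_exp_start, br2$i_exp_start)
  p1 <- select_stable_periods(br1, cl, sc$ann)
  p2 <- select_stable_periods(br2, cl, sc$ann)
  expect_identical(p1$i_start, p2$i_start)
  expect_identical(p1$i_end, p2$i_end)
})
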