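# GI, CoV, silent spaces, calibration and the per-breath parameter table.

test_that("a noiseless tidal image reproduces the amplitude map", {
  sc <- flat_scenario()
  gs <- global_signal(sc$seq, sc$mask)
  br <- segment_breaths(gs)
  ti <- tidal_image(sc$seq, br[3, ], sc$mask)
  amp <- sc$truth$amp_maps$pre
  rel <- abs(ti$di[sc$mask$mask] - amp[sc$mask$mask]) / amp[sc$mask$mask]
  expect_lt(max(rel), 0.01)
  # the image sums to the global swing between its two frames
  z <- gs$z
  swing <- z[br$i_insp_peak[3]] - z[br$i_exp_start[3]]
  expect_lt(abs(sum(ti$di[sc$mask$mask]) - swing) / swing, 1e-9)
})

test_that("degenerate tidal images behave predictably", {
  msk <- tiny_mask()
  zero <- image_with_values(rep(0, msk$n_lung_pixels), msk)
  expect_true(all(zero$di[msk$mask] == 0))
  s <- flat_scenario()$seq
  expect_error(
    tidal_image(s, list(i_exp_start = 1L, i_insp_peak = n_frames(s) + 5L), flat_scenario()$mask),
    "outside"
  )
})

test_that("GI matches hand-evaluated examples", {
  msk3 <- lung_mask(matrix(c(1, 1, 1, 0), 2, 2))
  expect_equal(compute_gi(image_with_values(c(1, 2, 3), msk3)), 1 / 3)
  msk4 <- lung_mask(matrix(1, 2, 2))
  expect_equal(compute_gi(image_with_values(c(0, 0, 10, 10), msk4)), 1)
  uni <- image_with_values(rep(4.2, 36), tiny_mask())
  expect_identical(compute_gi(uni), 0)
})

test_that("GI is undefined for non-positive total tidal change", {
  msk <- tiny_mask()
  neg <- image_with_values(rep(-1, msk$n_lung_pixels), msk)
  expect_warning(gi <- compute_gi(neg), "non-positive")
  expect_true(is.na(gi))
})

test_that("GI is invariant under positive rescaling", {
  withr::with_seed(2, {
    for (rep in 1:25) {
      ti <- random_tidal_image()
      gi <- compute_gi(ti)
      k <- runif(1, 0.01, 100)
      ti2 <- new_tidal_image(ti$di * k, ti$mask)
      expect_equal(compute_gi(ti2), gi, tolerance = 1e-12)
    }
  })
})

test_that("GI agrees with the direct amplitude-map oracle", {
  sc <- flat_scenario()
  br <- segment_breaths(global_signal(sc$seq, sc$mask))
  ti <- tidal_image(sc$seq, br[2, ], sc$mask)
  gi_est <- compute_gi(ti)
  gi_true <- true_gi_of_map(sc$truth$amp_maps$pre, sc$mask)
  expect_equal(gi_est, gi_true, tolerance = 1e-12)
})

test_that("CoV matches symmetry and boundary cases", {
  msk <- tiny_mask(8, 8) # lung rows/cols 2..7
  uni <- image_with_values(rep(1, msk$n_lung_pixels), msk)
  cov <- compute_cov(uni)
  expect_equal(cov$cov_x, 50)
  expect_equal(cov$cov_y, 50)

  co <- which(msk$mask, arr.ind = TRUE)
  vals <- rep(0, msk$n_lung_pixels)
  vals[co[, 1] == max(co[, 1])] <- 1 # all weight in the most dorsal row
  expect_equal(compute_cov(image_with_values(vals, msk))$cov_y, 100)

  vals2 <- rep(0, msk$n_lung_pixels)
  vals2[co[, 1] == min(co[, 1]) & co[, 2] == min(co[, 2])] <- 1
  vals2[co[, 1] == max(co[, 1]) & co[, 2] == min(co[, 2])] <- 1
  expect_equal(compute_cov(image_with_values(vals2, msk))$cov_y, 50)

  # negative pixels carry no weight
  vals3 <- vals
  vals3[co[, 1] == min(co[, 1])] <- -5
  expect_equal(compute_cov(image_with_values(vals3, msk))$cov_y, 100)
})

test_that("silent spaces match the worked threshold example", {
  msk4 <- lung_mask(matrix(1, 2, 2))
  ss <- compute_silent_spaces(image_with_values(c(10, 5, 0.5, 0.9), msk4))
  expect_equal(ss$nss + ss$dss, 50)
  expect_equal(ss$fls, 50)

  uni <- image_with_values(rep(3, 36), tiny_mask())
  ss2 <- compute_silent_spaces(uni)
  expect_equal(ss2$fls, 100)
  expect_equal(ss2$nss + ss2$dss, 0)
})

test_that("an all-nonpositive image is entirely silent with a warning", {
  msk <- tiny_mask()
  expect_warning(
    ss <- compute_silent_spaces(image_with_values(rep(-2, msk$n_lung_pixels), msk)),
    "silent"
  )
  expect_equal(ss$fls, 0)
  expect_equal(ss$nss + ss$dss, 100)
})

test_that("NSS + DSS + FLS is exactly 100 for random images", {
  withr::with_seed(14, {
    for (rep in 1:200) {
      ss <- compute_silent_spaces(random_tidal_image())
      expect_identical(ss$nss + ss$dss + ss$fls, 100)
    }
  })
})

test_that("volume calibration arithmetic matches hand-worked points", {
  br <- manual_breaths(dz = 8, t_start = 10)
  vent <- vent_log(tibble::tibble(t_s = c(10, 11, 12), vt_ml = rep(400, 3)))
  cal <- calibrate_volume(br, vent, method = "single_point")
  expect_equal(cal$c, 50)
  expect_identical(cal$method, "single_point")

  br3 <- manual_breaths(dz = c(8, 8, 8), t_start = c(0, 10, 20))
  vent3 <- vent_log(tibble::tibble(
    t_s = c(1, 11, 21),
    vt_ml = 8 * c(50, 50, 56)
  ))
  cal3 <- calibrate_volume(br3, vent3)
  expect_equal(cal3$c, 52)
  expect_identical(cal3$n_points, 3L)
})

test_that("calibration recovers the generator's true factor within 2%", {
  sc <- sbt_scenario()
  cl <- remove_artifacts(sc$seq, sc$mask)
  br <- segment_breaths(filter_cardiac(global_signal(cl$seq, sc$mask)))
  per <- select_stable_periods(br, cl, sc$ann)
  stab <- stable_breaths(br, per)
  cal <- calibrate_volume(stab[stab$phase == "pre", ], sc$vent)
  expect_lt(abs(cal$c / sc$truth$c_true - 1), 0.02)
})

test_that("calibration rejects unmatched or non-positive points", {
  br <- manual_breaths(dz = 8, t_start = 100)
  vent <- vent_log(tibble::tibble(t_s = c(1, 2), vt_ml = c(400, 400)))
  expect_error(calibrate_volume(br, vent), "matched")

  br2 <- manual_breaths(dz = c(8, 8), t_start = c(0, 10))
  vent2 <- vent_log(tibble::tibble(t_s = c(1, 11), vt_ml = c(0, 400)))
  expect_warning(cal <- calibrate_volume(br2, vent2), "excluded")
  expect_identical(cal$n_points, 1L)
})

test_that("rate and volume indices follow their definitions", {
  br <- manual_breaths(dz = 8, t_start = 10, duration = 3) # rr = 20
  sc <- flat_scenario()
  cal <- structure(list(c = 50, method = "single_point", n_points = 1L),
    class = "eit_calibration"
  )
  # use a real breath from the scenario for the image part
  gs <- global_signal(sc$seq, sc$mask)
  real <- segment_breaths(gs)[2, ]
  real$duration <- 3
  real$rr <- 20
  real$dz <- 8
  p <- breath_parameters(real, sc$seq, sc$mask, cal)
  expect_equal(p$vt_ml, 400)
  expect_equal(p$rsbi, 50) # 20 breaths/min over 0.4 L
  expect_equal(p$mv_l_min, 8)
})

test_that("the RSBI identity holds to machine precision", {
  sc <- sbt_scenario()
  ses <- run_session(sc$seq, sc$mask, sc$vent, sc$ann)
  p <- ses$breaths
  c <- ses$calibration$c
  expect_equal(p$rsbi, p$rr^2 * 1000 / (c * p$dz * p$rr), tolerance = 1e-12)
})

test_that("a uniform image splits ventilation evenly between halves", {
  msk <- tiny_mask(8, 8)
  uni <- image_with_values(rep(1, msk$n_lung_pixels), msk)
  fr <- eitsbt:::regional_fractions(uni)
  expect_equal(fr$frac_left, 0.5)
  expect_equal(fr$frac_right, 0.5)
  expect_equal(fr$frac_ventral, 0.5)
  expect_equal(fr$frac_left + fr$frac_right, 1)
  expect_equal(fr$frac_ventral + fr$frac_dorsal, 1)
})

test_that("per-period parameters average their breaths", {
  sc <- flat_scenario()
  cl <- remove_artifacts(sc$seq, sc$mask)
  br <- segment_breaths(global_signal(cl$seq, sc$mask))
  per <- select_stable_periods(br, cl, sc$ann)
  stab <- stable_breaths(br, per)
  cal <- calibrate_volume(stab[stab$phase == "pre", ], sc$vent)
  p <- breath_parameters(stab, cl$seq, sc$mask, cal)
  pp <- period_parameters(p)
  expect_identical(nrow(pp), nrow(per))
  one <- p[p$period_id == pp$period_id[1], ]
  expect_equal(pp$dz[1], mean(one$dz))
  expect_equal(pp$gi[1], mean(one$gi))
  # on noiseless identical breaths the two GI modes coincide ...
  pp2 <- period_parameters(p, cl$seq, sc$mask, gi_mode = "period_image")
  expect_equal(pp2$dz, pp$dz)
  expect_equal(pp2$gi, pp$gi, tolerance = 1e-9)

  # ... while under pixel noise the period-image GI is distinct (and
  # smaller, since averaging suppresses the noise inflation)
  nsc <- noisy_flat_scenario()
  ncl <- remove_artifacts(nsc$seq, nsc$mask)
  nbr <- segment_breaths(filter_cardiac(global_signal(ncl$seq, nsc$mask)))
  nper <- select_stable_periods(nbr, ncl, nsc$ann)
  nstab <- stable_breaths(nbr, nper)
  ncal <- calibrate_volume(nstab[nstab$phase == "pre", ], nsc$vent)
  np <- breath_parameters(nstab, ncl$seq, nsc$mask, ncal)
  npp1 <- period_parameters(np)
  npp2 <- period_parameters(np, ncl$seq, nsc$mask, gi_mode = "period_image")
  expect_true(all(npp2$gi < npp1$gi))
})
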