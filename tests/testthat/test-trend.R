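# Epoch division, baseline-normalized summaries, cohort tables and the
# end-to-end pipeline.

test_that("a 30-minute SBT divides into five 6-minute epochs", {
  ann <- sbt_annotation(0, 600, 600 + 1800, 600 + 1800 + 300)
  eb <- epoch_bounds(ann)
  sbt <- eb[grepl("^sbt_", eb$phase), ]
  expect_identical(nrow(sbt), 5L)
  expect_equal(sbt$t_end - sbt$t_start, rep(360, 5))
  expect_equal(sbt$t_start[1], 600)
  expect_equal(sbt$t_end[5], 2400)
})

test_that("a 15-minute SBT divides into five 3-minute epochs", {
  ann <- sbt_annotation(0, 300, 300 + 900, 1500)
  eb <- epoch_bounds(ann)
  sbt <- eb[grepl("^sbt_", eb$phase), ]
  expect_equal(sbt$t_end - sbt$t_start, rep(180, 5))
})

test_that("the SBT epochs are disjoint, cover the span, and use half-open intervals", {
  ann <- sbt_annotation(0, 100, 400, 500)
  eb <- epoch_bounds(ann)
  sbt <- eb[grepl("^sbt_", eb$phase), ]
  expect_equal(sbt$t_start[-1], sbt$t_end[-5])
  expect_equal(sbt$t_start[1], ann$t_sbt_start)
  expect_equal(sbt$t_end[5], ann$t_sbt_end)

  # breath exactly on an interior boundary goes to the later interval
  br <- manual_breaths(dz = rep(1, 3), t_start = c(159.9, 160, 220))
  div <- divide_epochs(br, ann)
  expect_identical(as.character(div$epoch), c("sbt_1", "sbt_2", "sbt_3"))
  expect_error(sbt_annotation(0, 400, 400, 500), "strictly increasing")
})

test_that("every stable SBT breath lands in exactly one epoch", {
  sc <- sbt_scenario()
  ses <- run_session(sc$seq, sc$mask, sc$vent, sc$ann)
  b <- ses$breaths
  in_sbt <- b$t_start >= sc$ann$t_sbt_start & b$t_start < sc$ann$t_sbt_end
  expect_true(all(grepl("^sbt_", b$epoch[in_sbt])))
  expect_true(all(!grepl("^sbt_", b$epoch[!in_sbt])))
  expect_false(any(is.na(b$epoch)))
})

test_that("count-based epoching balances breath counts", {
  ann <- sbt_annotation(0, 10, 110, 120)
  br <- manual_breaths(dz = rep(1, 23), t_start = seq(12, 105, length.out = 23))
  div <- divide_epochs(br, ann, epoch_mode = "count")
  counts <- table(as.character(div$epoch[grepl("sbt", div$epoch)]))
  expect_lte(diff(range(counts)), 1)
})

test_that("epochs identical to baseline give zero percent change", {
  ann <- sbt_annotation(0, 60, 160, 220)
  br <- manual_breaths(dz = rep(2, 40), t_start = seq(1, 215, length.out = 40))
  br <- divide_epochs(br, ann)
  ep <- summarize_epochs(br)
  expect_identical(nrow(ep), 7L)
  expect_equal(ep$pct_change_eeli, rep(0, 7))
  expect_equal(ep$pct_change_dz, rep(0, 7))
  expect_identical(ep$pct_change_eeli[ep$epoch == "pre"], 0)
})

test_that("an empty pre-SBT baseline is an error", {
  ann <- sbt_annotation(0, 60, 160, 220)
  br <- manual_breaths(dz = rep(2, 10), t_start = seq(70, 150, length.out = 10))
  br <- divide_epochs(br, ann)
  expect_error(summarize_epochs(br), "baseline")
})

test_that("empty epochs are reported, not dropped", {
  ann <- sbt_annotation(0, 60, 160, 220)
  # no breaths in sbt_3 (span 100..120 s)
  t <- c(seq(1, 55, 5), seq(61, 99, 4), seq(121, 215, 6))
  br <- manual_breaths(dz = rep(2, length(t)), t_start = t)
  br <- divide_epochs(br, ann)
  ep <- summarize_epochs(br)
  expect_identical(nrow(ep), 7L)
  expect_identical(ep$n_breaths[ep$epoch == "sbt_3"], 0L)
  expect_true(is.na(ep$dz_mean[ep$epoch == "sbt_3"]))
})

test_that("the full SBT scenario reproduces its ground-truth trends", {
  sc <- sbt_scenario()
  ses <- run_session(sc$seq, sc$mask, sc$vent, sc$ann)
  gt <- ground_truth_epochs(sc$truth, sc$ann)
  expect_true(all(abs(ses$epochs$pct_change_eeli - gt$pct_change_eeli) < 2))
  expect_true(all(abs(ses$epochs$pct_change_dz - gt$pct_change_dz) < 2))
  # the signature pattern: swing restored after reconnection, EELI not
  post <- ses$epochs[ses$epochs$epoch == "post", ]
  expect_lt(abs(post$pct_change_dz), 2)
  expect_lt(post$pct_change_eeli, -5)
})

test_that("cohort tables are long, complete and carry group means", {
  sc <- sbt_scenario()
  ses <- run_session(sc$seq, sc$mask, sc$vent, sc$ann, patient_id = "p1")
  ses2 <- ses
  ses2$patient_id <- "p2"
  tab <- cohort_table(list(ses, ses2))
  expect_identical(nrow(tab), 2L * 7L * 12L)
  expect_setequal(unique(tab$patient), c("p1", "p2"))
  expect_true(all(c("outcome", "phase", "parameter", "value", "group_mean") %in% names(tab)))
  # single session: group means equal the session's own values
  tab1 <- cohort_table(list(ses))
  expect_equal(tab1$value, tab1$group_mean)
  expect_false(any(tab1$missing))
})

test_that("run_pipeline executes a container session end to end", {
  sc <- sbt_scenario()
  dir <- withr::local_tempdir()
  cont <- file.path(dir, "session.rds")
  write_eit_container(cont, sc$seq, sc$mask, sc$vent, sc$ann)
  res <- run_pipeline(list(
    session = cont, outdir = file.path(dir, "out"), patient_id = "demo"
  ))
  expect_s3_class(res, "eit_session")
  ep <- readr::read_csv(file.path(dir, "out", "epochs.csv"), show_col_types = FALSE)
  expect_identical(nrow(ep), 7L)
  expect_true(file.exists(file.path(dir, "out", "breaths.csv")))
  expect_true(file.exists(file.path(dir, "out", "qc_report.csv")))
  expect_true(file.exists(file.path(dir, "out", "session.log")))
})

test_that("pipeline failures name the failing stage", {
  dir <- withr::local_tempdir()
  expect_error(
    run_pipeline(list(
      frames = file.path(dir, "missing.csv"),
      mask = file.path(dir, "missing_mask.csv"),
      vent = file.path(dir, "v.csv"), annotation = file.path(dir, "a.yml")
    )),
    "\\[io\\]"
  )
  expect_error(run_pipeline(list(bogus = 1)), "Valid keys")
})

test_that("YAML configs drive the pipeline", {
  sc <- flat_scenario()
  dir <- withr::local_tempdir()
  cont <- file.path(dir, "session.rds")
  write_eit_container(cont, sc$seq, sc$mask, sc$vent, sc$ann)
  cfgf <- file.path(dir, "run.yml")
  yaml::write_yaml(list(session = cont, patient_id = "yml", min_breaths = 4), cfgf)
  res <- run_pipeline(cfgf)
  expect_identical(res$patient_id, "yml")
  expect_identical(res$options$min_breaths, 4L)
})

test_that("tidy and glance provide broom-style views of a session", {
  sc <- sbt_scenario()
  ses <- run_session(sc$seq, sc$mask, sc$vent, sc$ann, patient_id = "p1")
  td <- tidy(ses)
  expect_true(all(c("patient", "phase", "parameter", "estimate", "std_dev") %in% names(td)))
  expect_identical(nrow(td), 7L * length(unique(td$parameter)))
  gl <- glance(ses)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$calibration_ml_per_au, ses$calibration$c)
})

test_that("plot builders return ggplot objects", {
  sc <- flat_scenario()
  ses <- run_session(sc$seq, sc$mask, sc$vent, sc$ann)
  gs <- global_signal(sc$seq, sc$mask)
  expect_s3_class(plot_global_signal(gs, ses$all_breaths, sc$ann), "ggplot")
  br <- ses$all_breaths
  expect_s3_class(plot_tidal_image(tidal_image(sc$seq, br[1, ], sc$mask)), "ggplot")
  expect_s3_class(autoplot(ses$epochs), "ggplot")
})
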