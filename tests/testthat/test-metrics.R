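test_that("baseline stats count extrema with all ties included", {
  f0 <- mini_frame(matrix(c(30.0, 30.5, 31.0, 31.0), 2, 2))
  b <- baseline_stats(f0, full_mask(2, 2))
  expect_equal(b$t_min, 30.0)
  expect_equal(b$t_max, 31.0)
  expect_equal(b$a_roi, 4L)
  expect_equal(b$a_min_pct, 25)
  expect_equal(b$a_max_pct, 50)

  u <- baseline_stats(mini_frame(matrix(32.0, 3, 3)), full_mask(3, 3))
  expect_equal(u$t_min, u$t_max)
  expect_equal(u$a_min_pct, 100)
  expect_equal(u$a_max_pct, 100)

  m1 <- binary_mask(matrix(c(1L, 0L, 0L, 0L), 2, 2), "FOOT")
  s1 <- baseline_stats(f0, m1)
  expect_equal(s1$a_roi, 1L)
  expect_equal(s1$a_min_pct, 100)
  expect_equal(s1$a_max_pct, 100)
})

test_that("AURP band thresholds are inclusive and frozen at t0", {
  f0 <- mini_frame(matrix(c(30.0, 30.5, 31.0, 31.0), 2, 2))
  m <- full_mask(2, 2)
  b <- baseline_stats(f0, m)
  # at t0 the 1.5 band spans the whole 1.0 range: everything qualifies
  expect_equal(aurp_up(f0, m, b), 100)
  expect_equal(aurp_down(f0, m, b), 100)
  # uniformly warmed by +5: no pixel within 1.5 of the t0 minimum
  f5 <- mini_frame(f0$values + 5)
  expect_equal(aurp_down(f5, m, b), 0)
  expect_equal(aurp_up(f5, m, b), 100)
  # boundary: a pixel exactly at Tmax - 1.5 counts (inclusive >=)
  fb <- mini_frame(matrix(c(29.5, 29.4, 29.4, 29.4), 2, 2))
  expect_equal(aurp_up(fb, m, b), 25)
  # and exactly at Tmin + 1.5 counts for the down band
  fc <- mini_frame(matrix(c(31.5, 31.6, 31.6, 31.6), 2, 2))
  expect_equal(aurp_down(fc, m, b), 25)
})

test_that("aurp percentages match a 25-pixel hand count", {
  vals <- matrix(29.0, 5, 5)
  vals[1, 1:5] <- 33.0  # Tmax=33, threshold 31.5: exactly these 5 qualify
  f <- mini_frame(vals)
  m <- full_mask(5, 5)
  b <- baseline_stats(f, m)
  expect_equal(aurp_up(f, m, b), 20)
})

test_that("delta_tavr is the masked mean difference against t0", {
  f0 <- mini_frame(matrix(c(30.0, 31.0, 50.0, 50.0), 2, 2))
  m <- binary_mask(matrix(c(1L, 1L, 0L, 0L), 2, 2), "THIGH")
  expect_identical(delta_tavr(f0, f0, m), 0)
  ft <- mini_frame(matrix(c(30.4, 31.8, 10.0, 10.0), 2, 2))
  expect_equal(delta_tavr(ft, f0, m), 0.6)
  fshift <- mini_frame(f0$values + 0.5)
  expect_equal(delta_tavr(fshift, f0, m), 0.5)
  expect_error(delta_tavr(mini_frame(matrix(30, 3, 3)), f0, m), "shape")
})

test_that("per-pixel oracle equivalence on random small frames", {
  set.seed(42)
  for (i in 1:200) {
    fx <- random_frame_mask()
    f0 <- fx$frame; m <- fx$mask
    b <- baseline_stats(f0, m)
    o <- oracle_roi_stats(f0, m)
    expect_identical(b$t_min, o$t_min)
    expect_identical(b$t_max, o$t_max)
    expect_identical(b$a_roi, o$a_roi)
    expect_equal(b$a_min_pct, o$a_min_pct)
    expect_equal(b$a_max_pct, o$a_max_pct)
    expect_equal(aurp_up(f0, m, b), o$aurp_up)
    expect_equal(aurp_down(f0, m, b), o$aurp_down)
    ft <- mini_frame(round_temp(f0$values + matrix(rnorm(100, 0, 0.8), 10, 10)))
    ot <- oracle_roi_stats(ft, m)
    expect_equal(delta_tavr(ft, f0, m), ot$mean - o$mean)
  }
})

test_that("monotone warming never decreases AURP-up nor increases AURP-down", {
  set.seed(17)
  for (i in 1:50) {
    fx <- random_frame_mask()
    b <- baseline_stats(fx$frame, fx$mask)
    bump <- round_temp(matrix(runif(100, 0, 2), 10, 10))  # pointwise >= 0
    fw <- mini_frame(fx$frame$values + bump)
    expect_gte(aurp_up(fw, fx$mask, b), aurp_up(fx$frame, fx$mask, b))
    expect_lte(aurp_down(fw, fx$mask, b), aurp_down(fx$frame, fx$mask, b))
    # baseline floor: the band contains the extremum pixels at t0
    expect_gte(aurp_up(fx$frame, fx$mask, b), b$a_max_pct)
    expect_gte(aurp_down(fx$frame, fx$mask, b), b$a_min_pct)
  }
})

test_that("overlapping bands at t0 cover the ROI when the range is narrow", {
  set.seed(5)
  vals <- round_temp(matrix(runif(64, 30, 32.5), 8, 8))  # range <= 2.5 < 3.0
  f <- mini_frame(vals); m <- full_mask(8, 8)
  b <- baseline_stats(f, m)
  if (b$t_max - b$t_min <= 3.0) {
    expect_gte(aurp_up(f, m, b) + aurp_down(f, m, b), 100)
  }
})

test_that("metric series covers the native grid and the 30-s analysis view", {
  spec <- cohort_spec(n_pos = 1L, n_neg = 0L, frame_shape = c(16L, 20L),
                      duration_s = 900L, sensor_noise_sd_c = 0,
                      drift_sd_pos_c = 0, response = list(), seed = 3L)
  rec <- generate_subject(spec, "TRP_POSITIVE", 1L)
  s <- compute_metric_series(rec, "THIGH")
  expect_equal(nrow(s), 301L)                 # 0..900 every 3 s
  expect_equal(nrow(analysis_grid(s)), 31L)   # 0..900 every 30 s
  expect_equal(s$delta_tavr_c[1], 0)
  # constant frames: series flat at the baseline values
  expect_true(all(s$delta_tavr_c == 0))
  expect_equal(length(unique(s$aurp_up_pct)), 1L)
})

test_that("a planted linear ramp is recovered linearly in time", {
  spec <- cohort_spec(n_pos = 1L, n_neg = 0L, frame_shape = c(20L, 24L),
                      duration_s = 300L, sensor_noise_sd_c = 0,
                      drift_sd_pos_c = 0,
                      response = list(THIGH = list(onset_s = 0L, plateau_s = 300L,
                                                   peak_delta_c = 1.2,
                                                   blob_fraction = 0.3)),
                      seed = 21L)
  rec <- generate_subject(spec, "TRP_POSITIVE", 1L)
  s <- compute_metric_series(rec, "THIGH")
  fit <- lm(delta_tavr_c ~ time_s, data = s)
  expect_equal(unname(coef(fit)[2]) * 300, 1.2, tolerance = 0.08)
  # residuals bounded by blob-area granularity + rounding quantum
  expect_lt(max(abs(residuals(fit))), 0.1)
})

test_that("symmetry precheck fails only when the pain side is colder by more than 0.5", {
  f <- mini_frame(matrix(30.0, 4, 4)); m <- full_mask(4, 4)
  same <- symmetry_precheck(f, f, m, m)
  expect_true(same$pass); expect_equal(same$delta_c, 0)
  colder06 <- symmetry_precheck(mini_frame(matrix(29.4, 4, 4)), f, m, m)
  expect_false(colder06$pass)
  expect_equal(colder06$delta_c, -0.6)
  colder05 <- symmetry_precheck(mini_frame(matrix(29.5, 4, 4)), f, m, m)
  expect_true(colder05$pass)  # exactly at the threshold still passes
  warmer <- symmetry_precheck(mini_frame(matrix(31.0, 4, 4)), f, m, m)
  expect_true(warmer$pass)
})

test_that("motion score is 0 for static scenes and drift, high for translations", {
  spec <- cohort_spec(n_pos = 1L, n_neg = 0L, frame_shape = c(20L, 24L),
                      duration_s = 60L, sensor_noise_sd_c = 0,
                      drift_sd_pos_c = 0, response = list(), seed = 2L)
  rec <- generate_subject(spec, "TRP_POSITIVE", 1L)
  expect_equal(motion_score(rec, "THIGH"), 0)

  # uniform drift of +0.05 degC per frame stays under the 1.0 step
  drifted <- rec
  for (i in seq_along(drifted$frames)) {
    drifted$frames[[i]]$values <- round_temp(rec$frames[[i]]$values + 0.05 * i)
  }
  expect_equal(motion_score(drifted, "THIGH"), 0)

  # translate the thermal structure by half the ROI width mid-series
  shifted <- rec
  half <- floor(ncol(rec$frames[[1]]$values) / 2)
  last <- rec$frames[[length(rec$frames)]]$values
  shifted$frames[[length(rec$frames)]]$values <-
    cbind(last[, (half + 1):ncol(last)], last[, 1:half] + 3)
  expect_gt(motion_score(shifted, "THIGH"), 0.25)
})

test_that("cleaning excludes short and moved recordings with reasons, keeps static ones", {
  spec <- cohort_spec(n_pos = 2L, n_neg = 0L, frame_shape = c(20L, 24L),
                      duration_s = 960L, sensor_noise_sd_c = 0.02,
                      drift_sd_pos_c = 0, response = list(), seed = 6L)
  ok <- generate_subject(spec, "TRP_POSITIVE", 1L, subject_id = "ok",
                         times = seq(0, 960, by = 60))
  short_spec <- spec; short_spec$duration_s <- 840L  # 14 minutes
  short <- generate_subject(short_spec, "TRP_POSITIVE", 2L, subject_id = "short",
                            times = seq(0, 840, by = 60))
  moved <- generate_subject(spec, "TRP_POSITIVE", 3L, subject_id = "moved",
                            times = seq(0, 960, by = 60))
  mid <- 9L
  v <- moved$frames[[mid]]$values
  moved$frames[[mid]]$values <- v[, c(8:ncol(v), 1:7)] + 2  # 15-px translation
  for (j in (mid + 1L):length(moved$frames)) {
    moved$frames[[j]]$values <- moved$frames[[mid]]$values
  }
  manual <- generate_subject(spec, "TRP_POSITIVE", 4L, subject_id = "manual",
                             times = seq(0, 960, by = 60))
  manual$excluded <- TRUE; manual$exclusion_reason <- "operator note"

  res <- clean_recordings(list(ok, short, moved, manual))
  expect_equal(vapply(res$retained, function(r) r$subject_id, character(1)), "ok")
  expect_setequal(res$exclusions$subject_id, c("short", "moved", "manual"))
  expect_equal(res$exclusions$reason[res$exclusions$subject_id == "short"], "duration")
  expect_equal(res$exclusions$reason[res$exclusions$subject_id == "moved"], "motion")
  expect_equal(res$exclusions$reason[res$exclusions$subject_id == "manual"], "manual")
})
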