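test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(response = list(THIGH = list(
    onset_s = 100, plateau_s = 50, peak_delta_c = 1, blob_fraction = 0.2))),
    "onset_s < plateau_s")
  expect_error(cohort_spec(response = list(THIGH = list(
    onset_s = 0, plateau_s = 900, peak_delta_c = 1, blob_fraction = 1.4))),
    "blob_fraction")
  expect_error(cohort_spec(response = list(HAND = list(
    onset_s = 0, plateau_s = 900, peak_delta_c = 1, blob_fraction = 0.2))),
    "unknown response region")
  expect_error(cohort_spec(sensor_noise_sd_c = -1))
})

test_that("zero-noise zero-response subjects yield identically flat series", {
  spec <- cohort_spec(frame_shape = c(20L, 24L), duration_s = 60L,
                      sensor_noise_sd_c = 0, drift_sd_pos_c = 0,
                      drift_sd_neg_c = 0, response = list(), seed = 5L)
  rec <- generate_subject(spec, "TRP_POSITIVE", 1L)
  s <- compute_metric_series(rec, "THIGH")
  expect_true(all(s$delta_tavr_c == 0))
})

test_that("a planted final ROI-mean rise is recovered through the pipeline", {
  spec <- cohort_spec(frame_shape = c(24L, 32L), sensor_noise_sd_c = 0,
                      drift_sd_pos_c = 0, drift_sd_neg_c = 0, seed = 9L)
  rec <- generate_subject(spec, "TRP_POSITIVE", 1L, times = c(0L, 960L))
  d <- delta_tavr(rec$frames[[2]], rec$frames[[1]], rec$masks$THIGH)
  # 1.0 degC planted; granularity = blob pixel quantization + 0.1 rounding
  expect_equal(d, 1.0, tolerance = 0.05)
})

test_that("the planted blob drives AURP-up by about its area fraction", {
  spec <- cohort_spec(frame_shape = c(40L, 52L), sensor_noise_sd_c = 0,
                      drift_sd_pos_c = 0, seed = 13L)
  rec <- generate_subject(spec, "TRP_POSITIVE", 2L, times = c(0L, 960L))
  m <- rec$masks$THIGH
  b <- baseline_stats(rec$frames[[1]], m)
  up0 <- aurp_up(rec$frames[[1]], m, b)
  up1 <- aurp_up(rec$frames[[2]], m, b)
  # blob amplitude is 1.0/0.2 = 5 degC, far above the band threshold, so the
  # final AURP-up gains the planted 20% minus the blob/baseline-band overlap
  expect_gte(up1, 20)
  expect_gte(up1, up0)            # warming only adds band pixels
  expect_lte(up1, up0 + 20 + 1)   # at most the planted area on top of baseline
})

test_that("generation is deterministic and independent of cohort order", {
  spec <- cohort_spec(n_pos = 2L, n_neg = 2L, frame_shape = c(16L, 20L),
                      duration_s = 30L, seed = 77L,
                      response = list(THIGH = list(onset_s = 0L, plateau_s = 30L,
                                                   peak_delta_c = 1.0,
                                                   blob_fraction = 0.2)))
  a <- generate_subject(spec, "TRP_POSITIVE", 3L)
  b <- generate_subject(spec, "TRP_POSITIVE", 3L)
  expect_identical(lapply(a$frames, `[[`, "values"),
                   lapply(b$frames, `[[`, "values"))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  generate_cohort(spec, dir = dir1)
  generate_cohort(spec, dir = dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(f1, list.files(dir2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6),
                     info = f)
  }
})

test_that("cohort counts and empty-group handling", {
  resp30 <- list(THIGH = list(onset_s = 0L, plateau_s = 30L,
                              peak_delta_c = 1.0, blob_fraction = 0.2))
  spec <- cohort_spec(n_pos = 3L, n_neg = 2L, frame_shape = c(16L, 20L),
                      duration_s = 30L, seed = 1L, response = resp30)
  res <- generate_cohort(spec)
  expect_length(res$recordings, 5L)
  groups <- vapply(res$recordings, function(r) r$group, character(1))
  expect_equal(sum(groups == "TRP_POSITIVE"), 3L)

  spec0 <- cohort_spec(n_pos = 0L, n_neg = 2L, frame_shape = c(16L, 20L),
                       duration_s = 30L, seed = 1L, response = resp30)
  res0 <- generate_cohort(spec0)
  expect_length(res0$recordings, 2L)
  series <- do.call(rbind, lapply(res0$recordings, compute_metric_series,
                                  region = "THIGH"))
  expect_error(compare_groups(series, 0L, "THIGH"), "TRP_POSITIVE")
})

test_that("final-timepoint recovery is unbiased across noise replicates", {
  spec <- cohort_spec(frame_shape = c(24L, 32L), drift_sd_pos_c = 0,
                      sensor_noise_sd_c = 0.05, seed = 101L)
  err <- vapply(1:50, function(i) {
    rec <- generate_subject(spec, "TRP_POSITIVE", i, times = c(0L, 960L))
    delta_tavr(rec$frames[[2]], rec$frames[[1]], rec$masks$THIGH) - 1.0
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.05)  # within the one-decimal rounding quantum
})
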