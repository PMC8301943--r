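# Fully synthetic MIP cohorts with planted group structure. The generator
# targets the statistical structure the analysis assumes -- a smooth spatial
# baseline temperature field, per-frame sensor noise, a slow per-subject
# whole-limb drift, and (for trigger-point-positive subjects) a warm blob
# growing inside the thigh ROI whose area fraction and ROI-mean temperature
# rise follow a configured trajectory. It makes no biophysical (bioheat)
# claim.

#' Specification of a synthetic MIP cohort
#'
#' Defaults emulate the study conditions: 20 + 20 subjects, 16-minute
#' recordings sampled every 3 s on 240 x 320 frames, a thigh response
#' ramping to a 1.0 degC ROI-mean rise over a blob covering 20% of the ROI,
#' and between-subject final-drift SDs of 0.7 (positive) / 0.8 (negative)
#' degC matching the reported group dispersions.
#'
#' @param n_pos,n_neg subject counts per group.
#' @param frame_shape `c(rows, cols)` of every frame.
#' @param sampling_interval_s seconds between frames.
#' @param duration_s recording length in seconds.
#' @param baseline_temp_c mean skin temperature, degC.
#' @param spatial_noise_sd_c SD of the smooth spatial baseline field, degC.
#' @param sensor_noise_sd_c per-pixel per-frame sensor noise SD, degC.
#' @param response named list per responding region, each with `onset_s`,
#'   `plateau_s`, `peak_delta_c` (target final ROI-mean rise) and
#'   `blob_fraction` (target final blob area fraction of the ROI).
#' @param drift_sd_pos_c,drift_sd_neg_c SD of the per-subject whole-limb
#'   linear drift at the final frame, degC, by group.
#' @param seed master seed; per-subject streams are derived from it by a
#'   counter scheme, so a subject's data do not depend on cohort order.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pos = 20L, n_neg = 20L, frame_shape = c(240L, 320L),
                        sampling_interval_s = 3L, duration_s = 960L,
                        baseline_temp_c = 32, spatial_noise_sd_c = 1.0,
                        sensor_noise_sd_c = 0.05,
                        response = list(THIGH = list(onset_s = 0L,
                                                     plateau_s = 900L,
                                                     peak_delta_c = 1.0,
                                                     blob_fraction = 0.2)),
                        drift_sd_pos_c = 0.7, drift_sd_neg_c = 0.8,
                        seed = 1L) {
  stopifnot(n_pos >= 0L, n_neg >= 0L, length(frame_shape) == 2L,
            all(frame_shape >= 8L), sampling_interval_s >= 1L,
            duration_s >= sampling_interval_s, spatial_noise_sd_c >= 0,
            sensor_noise_sd_c >= 0, drift_sd_pos_c >= 0, drift_sd_neg_c >= 0)
  for (rg in names(response)) {
    r <- response[[rg]]
    if (!toupper(rg) %in% REGIONS) stop(sprintf("unknown response region %s", rg))
    if (r$blob_fraction < 0 || r$blob_fraction > 1) {
      stop("blob_fraction must lie in [0, 1]")
    }
    if (!(r$onset_s < r$plateau_s && r$plateau_s <= duration_s)) {
      stop("response must satisfy onset_s < plateau_s <= duration_s")
    }
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         frame_shape = as.integer(frame_shape),
         sampling_interval_s = as.integer(sampling_interval_s),
         duration_s = as.integer(duration_s),
         baseline_temp_c = baseline_temp_c,
         spatial_noise_sd_c = spatial_noise_sd_c,
         sensor_noise_sd_c = sensor_noise_sd_c,
         response = response, drift_sd_pos_c = drift_sd_pos_c,
         drift_sd_neg_c = drift_sd_neg_c, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

ellipse_mask <- function(shape, center_frac, semi_frac) {
  r <- matrix(seq_len(shape[1L]), nrow = shape[1L], ncol = shape[2L])
  c_ <- matrix(seq_len(shape[2L]), nrow = shape[1L], ncol = shape[2L],
               byrow = TRUE)
  cr <- center_frac[1L] * shape[1L]; cc <- center_frac[2L] * shape[2L]
  ar <- max(1, semi_frac[1L] * shape[1L]); ac <- max(1, semi_frac[2L] * shape[2L])
  (((r - cr) / ar)^2 + ((c_ - cc) / ac)^2 <= 1) * 1L
}

#' Standard region mask geometry of the synthetic limb
#'
#' Three disjoint ellipses (thigh, calf, foot) stacked down the frame.
#'
#' @param shape `c(rows, cols)`.
#' @param subject_id subject identifier stamped on the masks.
#' @return named list of [binary_mask()] objects.
#' @export
synthetic_region_masks <- function(shape, subject_id = NA_character_) {
  list(
    THIGH = binary_mask(ellipse_mask(shape, c(0.25, 0.5), c(0.16, 0.32)),
                        "THIGH", subject_id),
    CALF = binary_mask(ellipse_mask(shape, c(0.58, 0.5), c(0.13, 0.26)),
                       "CALF", subject_id),
    FOOT = binary_mask(ellipse_mask(shape, c(0.87, 0.5), c(0.08, 0.18)),
                       "FOOT", subject_id)
  )
}

# smooth baseline: coarse iid Gaussian grid (one knot per ~8 px, so the
# field's correlation length is fixed in pixels and the ROI always contains
# several independent warm/cool patches), bilinearly interpolated
smooth_field <- function(shape, sd, knot_pitch_px = 4L) {
  kr <- max(2L, ceiling(shape[1L] / knot_pitch_px))
  kc <- max(2L, ceiling(shape[2L] / knot_pitch_px))
  coarse <- matrix(stats::rnorm(kr * kc, 0, sd), kr, kc)
  ri <- seq(1, kr, length.out = shape[1L])
  ci <- seq(1, kc, length.out = shape[2L])
  r0 <- pmin(floor(ri), kr - 1L); c0 <- pmin(floor(ci), kc - 1L)
  fr <- ri - r0; fc <- ci - c0
  out <- matrix(0, shape[1L], shape[2L])
  for (i in seq_len(shape[1L])) {
    a <- coarse[r0[i], ] * (1 - fr[i]) + coarse[r0[i] + 1L, ] * fr[i]
    out[i, ] <- a[c0] * (1 - fc) + a[c0 + 1L] * fc
  }
  out
}

ramp_frac <- function(t, onset, plateau) {
  pmin(1, pmax(0, (t - onset) / (plateau - onset)))
}

subject_stream_seed <- function(spec, subject_seed) {
  as.integer((as.numeric(spec$seed) * 48271 + as.numeric(subject_seed) * 69621) %% 2147483647)
}

#' Generate one synthetic subject recording
#'
#' Deterministic given `(spec$seed, subject_seed, times)`. Positive subjects
#' receive, in each responding region, a warm blob of constant amplitude
#' `peak_delta_c / blob_fraction` whose area fraction ramps from 0 at
#' `onset_s` to `blob_fraction` at `plateau_s`, so the planted ROI-mean rise
#' follows `peak_delta_c * ramp(t)`. Both groups share the baseline field
#' model and a per-subject whole-limb linear drift.
#'
#' @param spec a [cohort_spec()].
#' @param group `"TRP_POSITIVE"` or `"TRP_NEGATIVE"`.
#' @param subject_seed integer counter identifying the subject's random
#'   stream.
#' @param subject_id identifier stamped on frames and masks.
#' @param times frame times in seconds (default: the full sampling grid).
#'   A sparse subset (e.g. `c(0, spec$duration_s)`) generates only those
#'   frames, for calibration experiments.
#' @return a [subject_recording()].
#' @export
generate_subject <- function(spec, group, subject_seed,
                             subject_id = sprintf("S%04d", subject_seed),
                             times = NULL) {
  group <- match.arg(toupper(group), GROUPS)
  if (is.null(times)) {
    times <- seq(0L, spec$duration_s, by = spec$sampling_interval_s)
  }
  times <- as.integer(sort(unique(times)))
  shape <- spec$frame_shape
  masks <- synthetic_region_masks(shape, subject_id)

  set.seed(subject_stream_seed(spec, subject_seed))
  base <- spec$baseline_temp_c + smooth_field(shape, spec$spatial_noise_sd_c)
  drift_sd <- if (group == "TRP_POSITIVE") spec$drift_sd_pos_c else spec$drift_sd_neg_c
  drift_final <- stats::rnorm(1L, 0, drift_sd)

  # per responding region: pixels ordered by distance from the ROI centroid,
  # so the blob grows outward from the center
  blobs <- list()
  if (group == "TRP_POSITIVE") {
    for (rg in names(spec$response)) {
      m <- masks[[toupper(rg)]]$values
      idx <- which(m == 1L, arr.ind = TRUE)
      ctr <- colMeans(idx)
      ord <- order((idx[, 1L] - ctr[1L])^2 + (idx[, 2L] - ctr[2L])^2)
      blobs[[toupper(rg)]] <- list(
        lin = which(m == 1L)[ord], a_roi = nrow(idx),
        par = spec$response[[rg]])
    }
  }

  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    vals <- base + drift_final * t / spec$duration_s
    for (b in blobs) {
      f <- b$par$blob_fraction * ramp_frac(t, b$par$onset_s, b$par$plateau_s)
      nblob <- round(f * b$a_roi)
      if (nblob > 0L) {
        amp <- b$par$peak_delta_c / b$par$blob_fraction
        vals[b$lin[seq_len(nblob)]] <- vals[b$lin[seq_len(nblob)]] + amp
      }
    }
    if (spec$sensor_noise_sd_c > 0) {
      vals <- vals + stats::rnorm(length(vals), 0, spec$sensor_noise_sd_c)
    }
    frames[[i]] <- temperature_frame(vals, time_s = t, subject_id = subject_id)
  }
  subject_recording(frames, masks, group = group, subject_id = subject_id,
                    sampling_interval_s = spec$sampling_interval_s,
                    duration_s = spec$duration_s)
}

#' Generate a full synthetic cohort
#'
#' `n_pos + n_neg` subjects; optionally writes frames (text), masks (BMP)
#' and a YAML manifest to `dir` in the formats the loader reads.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory; when NULL (default) the cohort is returned
#'   in memory only.
#' @param times frame times passed to [generate_subject()].
#' @return list with `recordings` (list of [subject_recording()]) and
#'   `manifest_path` (NULL when `dir` is NULL).
#' @export
generate_cohort <- function(spec, dir = NULL, times = NULL) {
  n <- spec$n_pos + spec$n_neg
  groups <- c(rep("TRP_POSITIVE", spec$n_pos), rep("TRP_NEGATIVE", spec$n_neg))
  ids <- sprintf("%s%02d", ifelse(groups == "TRP_POSITIVE", "P", "N"),
                 c(seq_len(spec$n_pos), seq_len(spec$n_neg)))
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    recordings[[i]] <- generate_subject(spec, groups[i], subject_seed = i,
                                        subject_id = ids[i], times = times)
  }
  manifest_path <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- recordings[[i]]
      sdir <- file.path(dir, rec$subject_id)
      dir.create(sdir, showWarnings = FALSE)
      frame_paths <- character(length(rec$frames))
      for (j in seq_along(rec$frames)) {
        frame_paths[j] <- file.path(rec$subject_id,
                                    sprintf("frame_%04d.txt", j - 1L))
        write_frame(rec$frames[[j]], file.path(dir, frame_paths[j]))
      }
      mask_paths <- list()
      for (rg in names(rec$masks)) {
        mp <- file.path(rec$subject_id, sprintf("mask_%s.bmp", tolower(rg)))
        # ROI pure white on mid-gray background, as a mask author would paint
        write_mask_bmp(rec$masks[[rg]]$values * 127L + 128L, file.path(dir, mp))
        mask_paths[[tolower(rg)]] <- mp
      }
      subjects[[i]] <- list(id = rec$subject_id, group = rec$group,
                            frames = as.list(frame_paths), masks = mask_paths)
    }
    manifest <- list(sampling_interval_s = spec$sampling_interval_s,
                     frame_shape = as.list(spec$frame_shape),
                     seed = spec$seed, subjects = subjects)
    manifest_path <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(manifest, manifest_path)
  }
  list(recordings = recordings, manifest_path = manifest_path)
}
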