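# Per-subject, per-ROI diagnostic parameters of the minimally invasive
# procedure (MIP): baseline extrema, the autonomic-referred-pain area
# percentages AURP-up / AURP-down, and the change in mean ROI temperature
# delta-Tavr, plus the pre-stimulation symmetry check and the
# recording-quality cleaning rules.

masked_values <- function(frame, mask) {
  if (!identical(dim(frame$values), dim(mask$values))) {
    stop(sprintf("frame shape %s does not match mask shape %s",
                 paste(dim(frame$values), collapse = "x"),
                 paste(dim(mask$values), collapse = "x")))
  }
  frame$values[mask$values == 1L]
}

#' Baseline statistics of a ROI at the first frame
#'
#' From the first thermogram (t0): the minimum and maximum ROI temperature
#' (Tmin, Tmax), the ROI area in pixels (AROI), and the percentage of ROI
#' pixels attaining Tmin (Amin) and Tmax (Amax). Every pixel tied at an
#' extremum counts. Tmin/Tmax are frozen here for the whole series: the
#' AURP thresholds at later timepoints always refer back to t0.
#'
#' @param frame0 the t0 [temperature_frame()].
#' @param mask the region's [binary_mask()].
#' @return list of class `baseline_stats` with `t_min`, `t_max` (degC),
#'   `a_roi` (pixel count), `a_min_pct`, `a_max_pct` (percent).
#' @export
baseline_stats <- function(frame0, mask) {
  v <- masked_values(frame0, mask)
  a_roi <- length(v)
  t_min <- min(v)
  t_max <- max(v)
  structure(
    list(t_min = t_min, t_max = t_max, a_roi = a_roi,
         a_min_pct = 100 * sum(v == t_min) / a_roi,
         a_max_pct = 100 * sum(v == t_max) / a_roi),
    class = "baseline_stats"
  )
}

#' Vasodilatation area percentage (AURP-up)
#'
#' Percentage of ROI pixels whose temperature is within the 1.5 degC band
#' below the baseline maximum, i.e. `T >= Tmax - band_c` with Tmax fixed at
#' t0. Nonzero at baseline by construction (the pixels attaining Tmax always
#' qualify).
#'
#' @param frame a [temperature_frame()] at any timepoint.
#' @param mask the region's [binary_mask()].
#' @param base [baseline_stats()] of the same subject/region at t0.
#' @param band_c band width in degC (default 1.5).
#' @return percentage in \[0, 100\].
#' @export
aurp_up <- function(frame, mask, base, band_c = 1.5) {
  v <- masked_values(frame, mask)
  100 * sum(v >= base$t_max - band_c) / base$a_roi
}

#' Vasoconstriction area percentage (AURP-down)
#'
#' Mirror of [aurp_up()]: percentage of ROI pixels with
#' `T <= Tmin + band_c`, Tmin fixed at t0.
#'
#' @inheritParams aurp_up
#' @return percentage in \[0, 100\].
#' @export
aurp_down <- function(frame, mask, base, band_c = 1.5) {
  v <- masked_values(frame, mask)
  100 * sum(v <= base$t_min + band_c) / base$a_roi
}

#' Change in mean ROI temperature relative to t0
#'
#' `delta_Tavr(t) = mean(T in ROI at t) - mean(T in ROI at t0)`.
#'
#' @param frame_t frame at time t.
#' @param frame_0 the t0 frame.
#' @param mask the region's [binary_mask()].
#' @return temperature change in degC (exactly 0 when `frame_t` is `frame_0`).
#' @export
delta_tavr <- function(frame_t, frame_0, mask) {
  mean(masked_values(frame_t, mask)) - mean(masked_values(frame_0, mask))
}

#' Compute the full metric series of one subject x region
#'
#' Evaluates AURP-up, AURP-down and delta-Tavr on every available frame
#' (native grid, typically every 3 s). Group statistics use the coarser
#' analysis grid (default every 30 s), obtainable with [analysis_grid()].
#'
#' @param rec a [subject_recording()] (not excluded).
#' @param region region name with a mask present in `rec`.
#' @param band_c AURP band width in degC (default 1.5).
#' @param analysis_interval_s analysis-grid spacing, stored as an attribute
#'   (default 30 s).
#' @return data.frame with columns `subject_id, group, region, time_s,
#'   aurp_up_pct, aurp_down_pct, delta_tavr_c`; attribute
#'   `analysis_interval_s`.
#' @export
compute_metric_series <- function(rec, region, band_c = 1.5,
                                  analysis_interval_s = 30L) {
  region <- toupper(region)
  if (rec$excluded) {
    stop(sprintf("recording %s is excluded (%s)", rec$subject_id,
                 rec$exclusion_reason))
  }
  mask <- rec$masks[[region]]
  if (is.null(mask)) {
    stop(sprintf("subject %s has no %s mask", rec$subject_id, region))
  }
  f0 <- rec$frames[[1L]]
  base <- baseline_stats(f0, mask)
  mean0 <- mean(masked_values(f0, mask))
  n <- length(rec$frames)
  out <- data.frame(
    subject_id = rep(rec$subject_id, n),
    group = rep(rec$group, n),
    region = rep(region, n),
    time_s = frame_times(rec),
    aurp_up_pct = numeric(n),
    aurp_down_pct = numeric(n),
    delta_tavr_c = numeric(n),
    stringsAsFactors = FALSE
  )
  idx <- mask$values == 1L
  lo <- base$t_min + band_c
  hi <- base$t_max - band_c
  for (i in seq_len(n)) {
    v <- rec$frames[[i]]$values[idx]
    out$aurp_up_pct[i] <- 100 * sum(v >= hi) / base$a_roi
    out$aurp_down_pct[i] <- 100 * sum(v <= lo) / base$a_roi
    out$delta_tavr_c[i] <- mean(v) - mean0
  }
  attr(out, "analysis_interval_s") <- as.integer(analysis_interval_s)
  attr(out, "baseline") <- base
  out
}

#' Restrict a metric series to the analysis grid
#'
#' Keeps the timepoints that fall on the analysis grid (multiples of
#' `interval_s`), on which the per-timepoint group tests are run.
#'
#' @param series output of [compute_metric_series()] (or several rbind-ed).
#' @param interval_s grid spacing in seconds (default: the series attribute,
#'   falling back to 30).
#' @return the filtered data.frame.
#' @export
analysis_grid <- function(series, interval_s = NULL) {
  if (is.null(interval_s)) {
    interval_s <- attr(series, "analysis_interval_s") %||% 30L
  }
  series[series$time_s %% interval_s == 0L, , drop = FALSE]
}

#' Pre-stimulation thermal symmetry check
#'
#' Compares the mean temperature of the pain region against its
#' contralateral counterpart. A pain side colder by strictly more than
#' `threshold_c` (default 0.5 degC) is a sign of neuropathic pain and fails
#' the check; a deficit of exactly `threshold_c` still passes.
#'
#' @param pain_frame,contra_frame frames of the pain side and the
#'   contralateral side.
#' @param pain_mask,contra_mask the corresponding ROI masks.
#' @param threshold_c exclusion threshold in degC.
#' @return list with `pass` (logical) and `delta_c`
#'   (pain minus contralateral mean, degC).
#' @export
symmetry_precheck <- function(pain_frame, contra_frame, pain_mask, contra_mask,
                              threshold_c = 0.5) {
  delta <- mean(masked_values(pain_frame, pain_mask)) -
    mean(masked_values(contra_frame, contra_mask))
  list(pass = !(delta < -threshold_c), delta_c = delta)
}

#' Motion score of a recording within one ROI
#'
#' Deterministic surrogate for "the limb was significantly moved": the
#' maximum, over consecutive frame pairs, of the fraction of masked pixels
#' whose absolute temperature change exceeds `step_c`. A static scene scores
#' 0; slow physiologic drift (well under `step_c` per frame) also scores 0;
#' a translation of the thermal structure flips many masked pixels at once
#' and scores high.
#'
#' @param rec a [subject_recording()] with at least 2 frames.
#' @param region region whose mask delimits the scored pixels.
#' @param step_c per-pixel change threshold in degC (default 1.0).
#' @return fraction in \[0, 1\].
#' @export
motion_score <- function(rec, region, step_c = 1.0) {
  mask <- rec$masks[[toupper(region)]]
  if (is.null(mask)) stop(sprintf("no %s mask for subject %s", region, rec$subject_id))
  if (length(rec$frames) < 2L) stop("motion score needs at least 2 frames")
  idx <- mask$values == 1L
  a <- sum(idx)
  worst <- 0
  prev <- rec$frames[[1L]]$values[idx]
  for (i in 2:length(rec$frames)) {
    cur <- rec$frames[[i]]$values[idx]
    worst <- max(worst, sum(abs(cur - prev) > step_c) / a)
    prev <- cur
  }
  worst
}

#' Apply the recording-quality cleaning rules
#'
#' Excludes recordings shorter than `min_duration_s` (reason `"duration"`,
#' the camera-recording-error rule: measurements of less than 15 min are
#' dropped), recordings whose [motion_score()] in any masked region exceeds
#' `motion_threshold` (reason `"motion"`), and recordings flagged in the
#' manifest (reason `"manual"`).
#'
#' @param recordings list of [subject_recording()] objects.
#' @param min_duration_s minimum duration in seconds (default 900).
#' @param motion_threshold maximum tolerated motion score (default 0.2).
#' @param motion_step_c per-pixel step for the motion score (default 1.0).
#' @return list with `retained` (list of recordings) and `exclusions`
#'   (data.frame `subject_id, reason, detail`; zero rows if none).
#' @export
clean_recordings <- function(recordings, min_duration_s = 900L,
                             motion_threshold = 0.2, motion_step_c = 1.0) {
  retained <- list()
  excl <- list()
  for (rec in recordings) {
    if (rec$excluded) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = rec$subject_id, reason = "manual",
        detail = as.character(rec$exclusion_reason), stringsAsFactors = FALSE)
      next
    }
    if (rec$duration_s < min_duration_s) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = rec$subject_id, reason = "duration",
        detail = sprintf("%d s < %d s", rec$duration_s, min_duration_s),
        stringsAsFactors = FALSE)
      next
    }
    scores <- if (length(rec$frames) >= 2L) {
      vapply(names(rec$masks), function(rg)
        motion_score(rec, rg, step_c = motion_step_c), numeric(1))
    } else numeric(0)
    if (length(scores) && max(scores) > motion_threshold) {
      worst <- names(scores)[which.max(scores)]
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = rec$subject_id, reason = "motion",
        detail = sprintf("%s score %.3f > %.3f", worst, max(scores),
                         motion_threshold),
        stringsAsFactors = FALSE)
      next
    }
    retained[[length(retained) + 1L]] <- rec
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), reason = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(retained = retained, exclusions = exclusions)
}
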