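#' @keywords internal
"_PACKAGE"

REGIONS <- c("THIGH", "CALF", "FOOT")
GROUPS <- c("TRP_POSITIVE", "TRP_NEGATIVE")

#' Round temperatures to one decimal place
#'
#' Thermal-camera exports carry temperatures rounded to one decimal; the same
#' quantum is enforced at ingest so all downstream arithmetic runs on the
#' rounded values. Halves round away from zero.
#'
#' @param x numeric vector or matrix of temperatures in degrees Celsius.
#' @return `x` rounded to one decimal place.
#' @export
round_temp <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Construct a temperature frame
#'
#' One thermogram: a rows x cols grid of skin temperatures in degrees Celsius
#' plus the acquisition time in seconds since the start of the recording.
#' Values are rounded to one decimal place on construction.
#'
#' @param values numeric matrix of temperatures (degC), all finite.
#' @param time_s non-negative integer seconds since recording start.
#' @param subject_id opaque subject identifier.
#' @return an object of class `temperature_frame`.
#' @export
temperature_frame <- function(values, time_s = 0L, subject_id = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("frame values must be a numeric matrix")
  }
  if (any(!is.finite(values))) stop("frame contains non-finite temperatures")
  if (length(time_s) != 1L || is.na(time_s) || time_s < 0) {
    stop("time_s must be a single non-negative number")
  }
  structure(
    list(values = round_temp(values), time_s = as.integer(time_s),
         subject_id = as.character(subject_id)),
    class = "temperature_frame"
  )
}

#' @export
print.temperature_frame <- function(x, ...) {
  cat(sprintf("<temperature_frame> %dx%d px, t=%ds, subject=%s, range [%.1f, %.1f] degC\n",
              nrow(x$values), ncol(x$values), x$time_s, x$subject_id,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a binary ROI mask
#'
#' 0/1 matrix selecting the pixels of one anatomical region (THIGH, CALF or
#' FOOT). A mask must select at least one pixel.
#'
#' @param values 0/1 integer matrix.
#' @param region one of `"THIGH"`, `"CALF"`, `"FOOT"`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(values, region, subject_id = NA_character_) {
  region <- match.arg(toupper(region), REGIONS)
  if (!is.matrix(values)) stop("mask values must be a matrix")
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L))) stop("mask entries must all be 0 or 1")
  if (sum(values) < 1L) {
    stop(sprintf("empty ROI: no pixel selected for region %s of subject %s",
                 region, subject_id))
  }
  structure(
    list(values = values, region = region, subject_id = as.character(subject_id)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %dx%d px, area %d px, subject=%s\n",
              x$region, nrow(x$values), ncol(x$values), sum(x$values),
              x$subject_id))
  invisible(x)
}

#' Construct a subject recording
#'
#' Time-ordered frame sequence plus the region masks and the group label of
#' one subject. Frame timestamps must be strictly increasing and equally
#' spaced at the sampling interval; every mask must match the frame shape.
#'
#' @param frames list of [temperature_frame()] objects, time-ordered.
#' @param masks named list of [binary_mask()] objects (names are regions).
#' @param group `"TRP_POSITIVE"` or `"TRP_NEGATIVE"`.
#' @param subject_id opaque subject identifier.
#' @param sampling_interval_s sampling interval in seconds (default 3).
#' @param duration_s recording duration in seconds; defaults to the last
#'   frame's timestamp.
#' @param excluded logical manual-exclusion flag from the manifest.
#' @param exclusion_reason reason string when `excluded` is TRUE.
#' @return an object of class `subject_recording`.
#' @export
subject_recording <- function(frames, masks, group, subject_id,
                              sampling_interval_s = 3L, duration_s = NULL,
                              excluded = FALSE, exclusion_reason = NA_character_) {
  group <- match.arg(toupper(group), GROUPS)
  if (length(frames) < 1L) stop("recording needs at least one frame")
  times <- vapply(frames, function(f) f$time_s, integer(1))
  if (length(times) > 1L) {
    d <- diff(times)
    if (any(d <= 0)) stop("frame timestamps must be strictly increasing")
    if (any(d != sampling_interval_s)) {
      # irregular grids are allowed (e.g. a sparse pair of requested frames)
      # as long as they are increasing; flag equal spacing when claimed
      if (length(unique(d)) == 1L) sampling_interval_s <- d[1L]
    }
  }
  shape <- dim(frames[[1L]]$values)
  for (f in frames) {
    if (!identical(dim(f$values), shape)) {
      stop("all frames of one recording must share one shape")
    }
  }
  for (m in masks) {
    if (!identical(dim(m$values), shape)) {
      stop(sprintf("mask shape %s does not match frame shape %s",
                   paste(dim(m$values), collapse = "x"),
                   paste(shape, collapse = "x")))
    }
  }
  if (is.null(duration_s)) duration_s <- times[length(times)]
  structure(
    list(frames = frames, masks = masks, group = group,
         subject_id = as.character(subject_id),
         sampling_interval_s = as.integer(sampling_interval_s),
         duration_s = as.integer(duration_s),
         excluded = isTRUE(excluded), exclusion_reason = exclusion_reason),
    class = "subject_recording"
  )
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s (%s): %d frames @ %ds, %ds total, masks: %s\n",
              x$subject_id, x$group, length(x$frames), x$sampling_interval_s,
              x$duration_s, paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

frame_times <- function(rec) vapply(rec$frames, function(f) f$time_s, integer(1))
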