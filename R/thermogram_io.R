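# Reading and writing the pipeline's external formats: temperature-matrix
# text files (one per frame), subject manifests (YAML), and the long-format
# metric-series CSV.

#' Read one thermogram exported as a text matrix
#'
#' Accepts whitespace-, comma- and semicolon-delimited matrices; a decimal
#' comma (European thermal-camera exports) is normalized to a decimal point.
#' Values are rounded to one decimal place at ingest and the grid shape is
#' validated against `shape`.
#'
#' @param path path to the frame text file.
#' @param time_s acquisition time in seconds since recording start.
#' @param shape expected `c(rows, cols)`; default 240 x 320.
#' @param subject_id opaque subject identifier.
#' @return a [temperature_frame()].
#' @export
read_frame <- function(path, time_s = 0L, shape = c(240L, 320L),
                       subject_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != shape[1L]) {
    stop(sprintf("frame shape error in %s: expected %d rows, found %d",
                 path, shape[1L], length(lines)))
  }
  vals <- matrix(NA_real_, nrow = shape[1L], ncol = shape[2L])
  for (r in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[[r]]), "[\t ;]+")[[1L]]
    tokens <- tokens[nzchar(tokens)]
    # a comma between digits with no dot present is a decimal comma;
    # otherwise commas delimit fields
    if (any(grepl(",", tokens, fixed = TRUE))) {
      if (all(grepl("^-?[0-9]+(,[0-9]+)?$", tokens[grepl(",", tokens)]))) {
        tokens <- gsub(",", ".", tokens, fixed = TRUE)
      } else {
        tokens <- unlist(strsplit(tokens, ","))
        tokens <- tokens[nzchar(tokens)]
      }
    }
    if (length(tokens) != shape[2L]) {
      stop(sprintf("frame shape error in %s row %d: expected %d columns, found %d",
                   path, r, shape[2L], length(tokens)))
    }
    row <- suppressWarnings(as.numeric(tokens))
    if (any(is.na(row))) {
      bad <- which(is.na(row))[1L]
      stop(sprintf("malformed number '%s' in %s at row %d, col %d",
                   tokens[bad], path, r, bad))
    }
    vals[r, ] <- row
  }
  temperature_frame(vals, time_s = time_s, subject_id = subject_id)
}

#' Write one thermogram as a text matrix
#'
#' One decimal place, space-delimited; inverse of [read_frame()].
#'
#' @param frame a [temperature_frame()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  lines <- apply(frame$values, 1L, function(r) paste(sprintf("%.1f", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject manifest
#'
#' YAML (or JSON) file listing, per subject: the ordered frame files, the
#' mask file per region, the group label, and an optional manual exclusion.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return list with elements `subjects` (list) and `root` (directory).
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$subjects) || length(man$subjects) == 0L) {
    stop(sprintf("manifest %s lists no subjects", path))
  }
  root <- dirname(normalizePath(path))
  for (s in man$subjects) {
    if (is.null(s$id) || is.null(s$group) || is.null(s$frames) || is.null(s$masks)) {
      stop("each manifest subject needs id, group, frames, masks")
    }
    if (!toupper(s$group) %in% GROUPS) {
      stop(sprintf("subject %s: group must be one of %s", s$id,
                   paste(GROUPS, collapse = ", ")))
    }
  }
  list(subjects = man$subjects, root = root,
       sampling_interval_s = man$sampling_interval_s %||% 3L,
       frame_shape = unlist(man$frame_shape %||% c(240L, 320L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_path <- function(p, root) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(root, p)
}

#' Load one subject's recording from a manifest entry
#'
#' Frame timestamps come from the manifest order and the sampling interval,
#' not from file names. Masks are built through the full mask pipeline
#' (BMP -> grayscale -> strict-255 binarization).
#'
#' @param entry one element of `read_manifest(...)$subjects`.
#' @param root directory against which relative paths resolve.
#' @param sampling_interval_s seconds between frames (default 3).
#' @param frame_shape expected `c(rows, cols)` of each frame.
#' @return a [subject_recording()].
#' @export
load_recording <- function(entry, root = ".", sampling_interval_s = 3L,
                           frame_shape = c(240L, 320L)) {
  frames <- vector("list", length(entry$frames))
  for (i in seq_along(entry$frames)) {
    frames[[i]] <- read_frame(resolve_path(entry$frames[[i]], root),
                              time_s = (i - 1L) * sampling_interval_s,
                              shape = frame_shape, subject_id = entry$id)
  }
  masks <- list()
  for (region in names(entry$masks)) {
    masks[[toupper(region)]] <- mask_from_bmp(
      resolve_path(entry$masks[[region]], root),
      region = toupper(region), subject_id = entry$id)
  }
  subject_recording(frames, masks, group = entry$group, subject_id = entry$id,
                    sampling_interval_s = sampling_interval_s,
                    excluded = isTRUE(entry$excluded),
                    exclusion_reason = entry$exclusion_reason %||% NA_character_)
}

#' Write metric series to CSV
#'
#' Long format: `subject_id, group, region, time_s, aurp_up_pct,
#' aurp_down_pct, delta_tavr_c`, ordered by subject, region, time.
#'
#' @param series data.frame of metric series (rows from
#'   [compute_metric_series()], possibly several subjects/regions bound).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_series <- function(series, path) {
  cols <- c("subject_id", "group", "region", "time_s",
            "aurp_up_pct", "aurp_down_pct", "delta_tavr_c")
  if (is.null(series) || nrow(series) == 0L) {
    stop("refusing to write an empty metric-series table")
  }
  missing <- setdiff(cols, names(series))
  if (length(missing)) {
    stop(sprintf("metric series lacks columns: %s", paste(missing, collapse = ", ")))
  }
  series <- series[order(series$subject_id, series$region, series$time_s), cols]
  utils::write.csv(series, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read metric series back from CSV
#' @param path CSV written by [write_metric_series()].
#' @return data.frame in the same long format.
#' @export
read_metric_series <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
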