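# End-to-end orchestration: ingest (manifest or synthetic spec) -> masks ->
# metric series -> cleaning -> group statistics -> output bundle.

#' Default pipeline configuration
#'
#' All thresholds at their documented defaults: 1.5 degC AURP band, 30-s
#' analysis grid, 900-s minimum duration, motion step 1.0 degC / threshold
#' 0.2, symmetry threshold 0.5 degC.
#'
#' @param ... named overrides.
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    frame_shape = c(240L, 320L),
    sampling_interval_s = 3L,
    band_c = 1.5,
    analysis_interval_s = 30L,
    min_duration_s = 900L,
    motion_threshold = 0.2,
    motion_step_c = 1.0,
    symmetry_threshold_c = 0.5,
    stimulation_end_s = 600L,
    n_mc = 1e4L,
    firth_components = NULL,
    regions = REGIONS,
    seed = 1L,
    manifest = NULL,   # path to a manifest, or
    synth = NULL,      # a cohort_spec for a synthetic run
    out_dir = NULL
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full MIP analysis pipeline
#'
#' Stages: (1) load the cohort from `config$manifest`, or generate it from
#' `config$synth`; (2) apply the cleaning rules; (3) compute the metric
#' series per retained subject x region; (4) run the group comparison and
#' Firth regression; (5) when `config$out_dir` is set, write the bundle:
#' `metrics.csv`, `comparison.csv`, `firth.json`, `exclusions.csv`,
#' `run_metadata.json` (each written atomically). Deterministic given the
#' configuration and inputs.
#'
#' @param config list from [default_config()].
#' @return list of class `mip_run`: `series`, `comparison`, `exclusions`,
#'   `retained_ids`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.null(config$manifest) && is.null(config$synth)) {
    stop("pipeline stage 'ingest': config needs either a manifest or a synth spec")
  }
  if (!is.null(config$manifest)) {
    man <- read_manifest(config$manifest)
    recordings <- lapply(man$subjects, function(entry)
      load_recording(entry, root = man$root,
                     sampling_interval_s = man$sampling_interval_s,
                     frame_shape = man$frame_shape))
    message(sprintf("[ingest] loaded %d subjects from %s",
                    length(recordings), config$manifest))
  } else {
    recordings <- generate_cohort(config$synth)$recordings
    message(sprintf("[ingest] generated %d synthetic subjects (seed %d)",
                    length(recordings), config$synth$seed))
  }

  cleaned <- clean_recordings(recordings,
                              min_duration_s = config$min_duration_s,
                              motion_threshold = config$motion_threshold,
                              motion_step_c = config$motion_step_c)
  message(sprintf("[clean] retained %d subjects, excluded %d",
                  length(cleaned$retained), nrow(cleaned$exclusions)))
  if (length(cleaned$retained) == 0L) {
    stop("pipeline stage 'clean': no recordings retained")
  }

  series_list <- list()
  for (rec in cleaned$retained) {
    for (rg in intersect(toupper(config$regions), names(rec$masks))) {
      series_list[[length(series_list) + 1L]] <-
        compute_metric_series(rec, rg, band_c = config$band_c,
                              analysis_interval_s = config$analysis_interval_s)
    }
  }
  series <- do.call(rbind, series_list)
  attr(series, "analysis_interval_s") <- config$analysis_interval_s
  message(sprintf("[metrics] %d series rows across %d subject x region series",
                  nrow(series), length(series_list)))

  comparison <- run_full_comparison(
    series, analysis_interval_s = config$analysis_interval_s,
    firth_components = config$firth_components, n_mc = config$n_mc,
    stimulation_end_s = config$stimulation_end_s, seed = config$seed)
  message(sprintf("[stats] %d timepoint tests, %d with p < 0.05",
                  nrow(comparison$tests), sum(comparison$tests$p < 0.05)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_atomic(function(p) write_metric_series(series, p), out("metrics.csv"))
    write_atomic(function(p) utils::write.csv(comparison$tests, p,
                                              row.names = FALSE), out("comparison.csv"))
    if (!is.null(comparison$firth)) {
      write_atomic(function(p) jsonlite::write_json(
        list(coefficients = comparison$firth$coefficients,
             components = comparison$firth_components,
             converged = comparison$firth$converged,
             iterations = comparison$firth$iter,
             seed = config$seed),
        p, auto_unbox = TRUE, digits = NA), out("firth.json"))
    }
    write_atomic(function(p) utils::write.csv(cleaned$exclusions, p,
                                              row.names = FALSE), out("exclusions.csv"))
    cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "synth")],
                                 auto_unbox = TRUE, null = "null")
    meta <- list(seed = config$seed,
                 config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("mipadt")),
                 n_subjects_in = length(recordings),
                 n_subjects_retained = length(cleaned$retained))
    write_atomic(function(p) jsonlite::write_json(meta, p, auto_unbox = TRUE),
                 out("run_metadata.json"))
    message(sprintf("[write] bundle in %s", config$out_dir))
  }

  structure(list(series = series, comparison = comparison,
                 exclusions = cleaned$exclusions,
                 retained_ids = vapply(cleaned$retained,
                                       function(r) r$subject_id, character(1)),
                 config = config),
            class = "mip_run")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp, auto_unbox = TRUE,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.mip_run <- function(x, ...) {
  cat(sprintf("<mip_run> %d subjects retained, %d excluded; %d metric rows\n",
              length(x$retained_ids), nrow(x$exclusions), nrow(x$series)))
  print(x$comparison)
  invisible(x)
}
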