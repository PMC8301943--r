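# Cohort-level statistics: the per-timepoint comparison table (one exact
# Mann-Whitney test per region x metric x analysis timepoint, in the layout
# of a clinical results table: phase, time, group mean +/- SD, Monte-Carlo
# p with 99% CI, exact p) and the Firth regression ranking the diagnostic
# components.

phase_label <- function(time_s, stimulation_end_s = 600L) {
  ifelse(time_s <= stimulation_end_s, "stimulation", "observation")
}

#' Subject-level summary features for the diagnostic regression
#'
#' Collapses each subject's metric series to scalar features: the maximum
#' delta-Tavr and maximum AURP-up per region (computed over the analysis
#' grid). Feature names are `<region>_<metric>_max`, e.g.
#' `THIGH_delta_tavr_max`.
#'
#' @param series long metric-series data.frame covering the cohort.
#' @return data.frame: one row per subject with `subject_id`, `group`, and
#'   one column per available region x feature.
#' @export
subject_features <- function(series) {
  subjects <- unique(series[, c("subject_id", "group")])
  subjects <- subjects[order(subjects$subject_id), , drop = FALSE]
  out <- subjects
  for (rg in intersect(REGIONS, unique(series$region))) {
    sub <- series[series$region == rg, , drop = FALSE]
    dt <- tapply(sub$delta_tavr_c, sub$subject_id, max)
    au <- tapply(sub$aurp_up_pct, sub$subject_id, max)
    out[[paste0(rg, "_delta_tavr_max")]] <- as.numeric(dt[out$subject_id])
    out[[paste0(rg, "_aurp_up_max")]] <- as.numeric(au[out$subject_id])
  }
  rownames(out) <- NULL
  out
}

default_firth_components <- function(available) {
  # five subject-level components: peak mean-temperature rise in thigh and
  # calf, peak vasodilatation area in all three regions
  want <- c("THIGH_delta_tavr_max", "THIGH_aurp_up_max",
            "CALF_delta_tavr_max", "CALF_aurp_up_max", "FOOT_aurp_up_max")
  intersect(want, available)
}

#' Run the full group comparison
#'
#' For every region x metric x analysis timepoint present in the series,
#' runs the exact Mann-Whitney U test (trigger-point-positive vs -negative)
#' and assembles the results-table layout: procedure phase, time, group mean
#' +/- SD, the Monte-Carlo p estimate with its 99% Clopper-Pearson CI, the
#' exact p, and a Holm-adjusted column (reported for transparency; the
#' per-timepoint p values are the primary read-out). Then fits the Firth
#' regression of group on the configured subject-level components.
#'
#' @param series long metric-series data.frame for the cleaned cohort
#'   (both groups present).
#' @param analysis_interval_s test-grid spacing in seconds (default 30).
#' @param metrics metrics to test (default all three).
#' @param firth_components character vector of feature names (see
#'   [subject_features()]); default: the five-component set restricted to
#'   available regions.
#' @param n_mc Monte-Carlo permutations behind the CI column (default 1e4).
#' @param stimulation_end_s end of the noxious-stimulation phase (default
#'   600 s; later timepoints are the observation phase).
#' @param seed integer seed for the Monte-Carlo permutations.
#' @return list of class `mip_comparison`: `tests` (data.frame), `firth`
#'   (a `firth_fit` or NULL when no components are available), `seed`.
#' @export
run_full_comparison <- function(series, analysis_interval_s = 30L,
                                metrics = c("delta_tavr_c", "aurp_up_pct",
                                            "aurp_down_pct"),
                                firth_components = NULL, n_mc = 1e4L,
                                stimulation_end_s = 600L, seed = 1L) {
  if (length(unique(series$group)) < 2L) {
    stop("both groups must be present in the series")
  }
  grid <- analysis_grid(series, analysis_interval_s)
  set.seed(seed)
  rows <- list()
  for (rg in intersect(REGIONS, unique(grid$region))) {
    for (metric in metrics) {
      for (t in sort(unique(grid$time_s[grid$region == rg]))) {
        sel <- grid$region == rg & grid$time_s == t
        pos <- grid[[metric]][sel & grid$group == "TRP_POSITIVE"]
        neg <- grid[[metric]][sel & grid$group == "TRP_NEGATIVE"]
        tst <- mann_whitney_exact(pos, neg, n_mc = n_mc, mc_also = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, metric = metric,
          phase = phase_label(t, stimulation_end_s), time_s = t,
          mean_pos = mean(pos), sd_pos = stats::sd(pos),
          mean_neg = mean(neg), sd_neg = stats::sd(neg),
          n_pos = tst$n_a, n_neg = tst$n_b,
          u_statistic = tst$u_statistic,
          p_mc = tst$p_mc, p_ci_low = tst$p_ci_low, p_ci_high = tst$p_ci_high,
          p = tst$p_two_sided, method = tst$method,
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_holm <- stats::p.adjust(tests$p, method = "holm")

  feats <- subject_features(grid)
  avail <- setdiff(names(feats), c("subject_id", "group"))
  if (is.null(firth_components)) {
    firth_components <- default_firth_components(avail)
  } else {
    missing <- setdiff(firth_components, avail)
    if (length(missing)) {
      stop(sprintf("unknown Firth component(s): %s", paste(missing, collapse = ", ")))
    }
  }
  firth <- NULL
  if (length(firth_components)) {
    outcome <- as.integer(feats$group == "TRP_POSITIVE")
    firth <- firth_logistic(feats[, firth_components, drop = FALSE], outcome)
  }
  structure(list(tests = tests, firth = firth, seed = seed,
                 firth_components = firth_components),
            class = "mip_comparison")
}

#' @export
print.mip_comparison <- function(x, ...) {
  cat(sprintf("<mip_comparison> %d tests (%s), seed %d\n",
              nrow(x$tests),
              paste(unique(x$tests$region), collapse = ", "), x$seed))
  sig <- x$tests[x$tests$p < 0.05, , drop = FALSE]
  cat(sprintf("  %d of %d timepoint tests with p < 0.05\n", nrow(sig), nrow(x$tests)))
  if (!is.null(x$firth)) print(x$firth)
  invisible(x)
}
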