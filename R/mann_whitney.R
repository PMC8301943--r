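# Exact two-tailed Mann-Whitney U test with midrank tie correction.
#
# The exact two-sided p is obtained from the permutation distribution of the
# rank sum over all C(n, n_a) group assignments. Midranks of tied
# observations are half-integers, so doubling them gives integer scores and
# the distribution can be built by convolution (a shift-algorithm dynamic
# program over subset size x score sum) -- exact for any tie pattern and
# cheap up to n of several dozen, which covers the study's 20 + 20 design.
# Beyond `exact_cap` total observations a Monte-Carlo permutation estimate
# with a 99% Clopper-Pearson CI takes over. The tie-corrected normal
# approximation is always reported as a diagnostic.

# distribution of the score sum over subsets of size na: matrix of counts,
# rows = subset size 0..na, cols = achievable sums (offset by 1)
rank_sum_counts <- function(scores, na) {
  smax <- sum(sort(scores, decreasing = TRUE)[seq_len(na)])
  counts <- matrix(0, nrow = na + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (s in scores) {
    # update subset sizes from high to low so each score is used once
    for (k in na:1L) {
      if (s == 0) {
        counts[k + 1L, ] <- counts[k + 1L, ] + counts[k, ]
      } else {
        cols <- (s + 1L):(smax + 1L)
        counts[k + 1L, cols] <- counts[k + 1L, cols] + counts[k, cols - s]
      }
    }
  }
  counts[na + 1L, ]
}

#' Exact two-tailed Mann-Whitney U test with tie correction
#'
#' Computes the U statistic from midranks and its exact two-sided p value by
#' full enumeration of the permutation distribution of the rank sum
#' (feasible because tied midranks are half-integers). For pooled samples
#' larger than `exact_cap` the p value is a Monte-Carlo permutation estimate
#' with a 99% Clopper-Pearson confidence interval. The permutation
#' distribution of U is symmetric about `n_a n_b / 2`, so the two-sided p is
#' the probability of a deviation from that center at least as large as the
#' observed one.
#'
#' @param a,b numeric vectors, the two samples (non-empty).
#' @param exact_cap maximum pooled sample size for the exact enumeration
#'   (default 60).
#' @param n_mc Monte-Carlo permutations when above the cap (default 1e5).
#' @param mc_also when TRUE also compute the Monte-Carlo estimate (with CI)
#'   even if the exact path was taken, e.g. to populate a CI column.
#' @return list with `u_statistic` (U of sample `a`), `p_two_sided`,
#'   `method` ("exact" or "monte-carlo"), `p_mc`, `p_ci_low`, `p_ci_high`
#'   (NA unless Monte-Carlo was run), `p_normal` (tie-corrected normal
#'   approximation), `n_a`, `n_b`, and `degenerate` (TRUE when the pooled
#'   data are constant, in which case p = 1 by convention).
#' @export
mann_whitney_exact <- function(a, b, exact_cap = 60L, n_mc = 1e5L,
                               mc_also = FALSE) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("samples must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks for ties
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  dev <- abs(u - mu)

  # tie-corrected normal approximation (diagnostic)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- na * nb / 12 * (n + 1 - tie_term)
  p_normal <- if (v > 0) 2 * stats::pnorm(-dev / sqrt(v)) else 1
  p_normal <- min(1, p_normal)

  if (length(unique(pooled)) == 1L) {
    return(list(u_statistic = u, p_two_sided = 1, method = "degenerate",
                p_mc = NA_real_, p_ci_low = NA_real_, p_ci_high = NA_real_,
                p_normal = 1, n_a = na, n_b = nb, degenerate = TRUE))
  }

  eps <- 1e-9
  res <- list(u_statistic = u, n_a = na, n_b = nb, degenerate = FALSE,
              p_normal = p_normal, p_mc = NA_real_,
              p_ci_low = NA_real_, p_ci_high = NA_real_)

  if (n <= exact_cap) {
    scores <- as.integer(round(2 * r))  # integer scores; ranks sum preserved
    counts <- rank_sum_counts(scores, na)
    sums <- seq_along(counts) - 1L      # achievable 2*rank-sum values
    # U for a subset with doubled rank sum S is S/2 - na(na+1)/2
    u_all <- sums / 2 - na * (na + 1) / 2
    total <- sum(counts)
    p <- sum(counts[abs(u_all - mu) >= dev - eps]) / total
    res$p_two_sided <- min(1, p)
    res$method <- "exact"
  } else {
    res$method <- "monte-carlo"
  }

  if (identical(res$method, "monte-carlo") || isTRUE(mc_also)) {
    k <- 0L
    for (i in seq_len(n_mc)) {
      rp <- sample(r)
      up <- sum(rp[seq_len(na)]) - na * (na + 1) / 2
      if (abs(up - mu) >= dev - eps) k <- k + 1L
    }
    res$p_mc <- (k + 1) / (n_mc + 1)
    res$p_ci_low <- if (k == 0L) 0 else stats::qbeta(0.005, k, n_mc - k + 1)
    res$p_ci_high <- if (k == n_mc) 1 else stats::qbeta(0.995, k + 1, n_mc - k)
    if (identical(res$method, "monte-carlo")) res$p_two_sided <- res$p_mc
  }
  res[c("u_statistic", "p_two_sided", "method", "p_mc", "p_ci_low",
        "p_ci_high", "p_normal", "n_a", "n_b", "degenerate")]
}

#' Compare the two groups at one timepoint
#'
#' Extracts each subject's value of one metric in one region at one
#' timepoint from a long metric-series table and runs the exact
#' Mann-Whitney U test, trigger-point-positive vs -negative.
#'
#' @param series long metric-series data.frame (see
#'   [compute_metric_series()]), several subjects bound together.
#' @param time_s the timepoint in seconds.
#' @param region region name.
#' @param metric one of `"delta_tavr_c"`, `"aurp_up_pct"`, `"aurp_down_pct"`.
#' @param ... passed to [mann_whitney_exact()].
#' @return one-row data.frame: `time_s, region, metric, n_pos, n_neg,
#'   u_statistic, p_two_sided, method, p_mc, p_ci_low, p_ci_high, p_normal`.
#' @export
compare_groups <- function(series, time_s, region, metric = "delta_tavr_c", ...) {
  metric <- match.arg(metric, c("delta_tavr_c", "aurp_up_pct", "aurp_down_pct"))
  sel <- series$time_s == time_s & series$region == toupper(region)
  sub <- series[sel, , drop = FALSE]
  pos <- sub[[metric]][sub$group == "TRP_POSITIVE"]
  neg <- sub[[metric]][sub$group == "TRP_NEGATIVE"]
  if (length(pos) == 0L) stop(sprintf("no TRP_POSITIVE subjects at t=%ds in %s",
                                      time_s, region))
  if (length(neg) == 0L) stop(sprintf("no TRP_NEGATIVE subjects at t=%ds in %s",
                                      time_s, region))
  t <- mann_whitney_exact(pos, neg, ...)
  data.frame(time_s = time_s, region = toupper(region), metric = metric,
             n_pos = t$n_a, n_neg = t$n_b, u_statistic = t$u_statistic,
             p_two_sided = t$p_two_sided, method = t$method, p_mc = t$p_mc,
             p_ci_low = t$p_ci_low, p_ci_high = t$p_ci_high,
             p_normal = t$p_normal, stringsAsFactors = FALSE)
}
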