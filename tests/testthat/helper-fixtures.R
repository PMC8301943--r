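# Fixture builders and independent oracles used across the suite. The
# oracles deliberately use a different computational route than the package
# (explicit per-pixel / per-subset loops, generic numerical optimization).

mini_frame <- function(vals, time_s = 0L, id = "s1") {
  temperature_frame(vals, time_s = time_s, subject_id = id)
}

full_mask <- function(nr, nc, region = "THIGH", id = "s1") {
  binary_mask(matrix(1L, nr, nc), region, id)
}

random_frame_mask <- function(nr = 10L, nc = 10L) {
  vals <- round_temp(matrix(runif(nr * nc, 28, 36), nr, nc))
  m <- matrix(0L, nr, nc)
  while (sum(m) == 0L) m <- matrix(rbinom(nr * nc, 1L, 0.4), nr, nc)
  list(frame = mini_frame(vals), mask = binary_mask(m, "THIGH"))
}

# brute-force per-pixel oracle for the baseline stats and AURP percentages
oracle_roi_stats <- function(frame, mask, band = 1.5) {
  v <- c()
  for (r in seq_len(nrow(mask$values))) {
    for (cc in seq_len(ncol(mask$values))) {
      if (mask$values[r, cc] == 1L) v <- c(v, frame$values[r, cc])
    }
  }
  tmin <- v[1]; tmax <- v[1]
  for (x in v) { if (x < tmin) tmin <- x; if (x > tmax) tmax <- x }
  n_min <- 0L; n_max <- 0L; n_up <- 0L; n_down <- 0L
  for (x in v) {
    if (x == tmin) n_min <- n_min + 1L
    if (x == tmax) n_max <- n_max + 1L
    if (x >= tmax - band) n_up <- n_up + 1L
    if (x <= tmin + band) n_down <- n_down + 1L
  }
  list(t_min = tmin, t_max = tmax, a_roi = length(v),
       a_min_pct = 100 * n_min / length(v), a_max_pct = 100 * n_max / length(v),
       aurp_up = 100 * n_up / length(v), aurp_down = 100 * n_down / length(v),
       mean = sum(v) / length(v))
}

# exhaustive enumeration oracle for the exact two-sided Mann-Whitney p:
# every C(n, na) assignment of the pooled values to group a
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  mu <- na * length(b) / 2
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  dev_obs <- abs(u_of(seq_len(na)) - mu)
  sets <- utils::combn(n, na)
  hits <- 0L
  for (j in seq_len(ncol(sets))) {
    if (abs(u_of(sets[, j]) - mu) >= dev_obs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(sets)
}

# independent Firth oracle: generic BFGS maximization of the Jeffreys-prior
# penalized log-likelihood (no modified-score Newton anywhere in here)
oracle_firth_beta <- function(X, y) {
  negpl <- function(beta) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    info <- t(X * w) %*% X
    ld <- determinant(info, logarithm = TRUE)
    -(sum(y * eta - log(1 + exp(eta))) + 0.5 * as.numeric(ld$modulus))
  }
  stats::optim(rep(0, ncol(X)), negpl, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# small static cohort for I/O and pipeline tests
tiny_cohort_spec <- function(...) {
  cohort_spec(n_pos = 3L, n_neg = 3L, frame_shape = c(20L, 24L),
              sampling_interval_s = 3L, duration_s = 30L,
              sensor_noise_sd_c = 0.02,
              response = list(THIGH = list(onset_s = 0L, plateau_s = 30L,
                                           peak_delta_c = 1.0,
                                           blob_fraction = 0.2)),
              seed = 11L, ...)
}
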