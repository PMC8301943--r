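# Firth's bias-reduced logistic regression: maximum penalized likelihood
# with the Jeffreys prior, l*(beta) = l(beta) + 0.5 log det I(beta).
# The penalty keeps estimates finite under complete separation, where
# ordinary maximum likelihood diverges. Fitting uses Newton scoring with
# Firth's modified score U*_j = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ij
# (h_i = hat diagonals) and step-halving on the penalized log-likelihood.
# Per-coefficient p values come from penalized likelihood-ratio tests: the
# model is refit with the coefficient fixed at zero (same design, so the
# penalty still uses the full information matrix) and twice the penalized
# log-likelihood drop is referred to chi-square with 1 df.

penalized_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  XtWX <- crossprod(X * w, X)
  ld <- determinant(XtWX, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld$modulus)
}

# Newton iterations over the coefficients indexed by `free` (others pinned
# at their current value, used for the likelihood-ratio refits)
firth_newton <- function(X, y, beta, free, max_iter = 100L, tol = 1e-10) {
  pl <- penalized_loglik(X, y, beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    XtWX <- crossprod(XW, X)
    XtWX_inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(XtWX_inv)) {
      stop("Firth fit failed: information matrix is singular (collinear predictors?)")
    }
    # hat diagonals of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
    h <- rowSums((X %*% XtWX_inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))[free]
    info <- XtWX[free, free, drop = FALSE]
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) stop("Firth fit failed: singular information sub-matrix")
    # step-halving: accept the largest step that improves the penalized loglik
    lambda <- 1
    repeat {
      cand <- beta
      cand[free] <- beta[free] + lambda * step
      pl_new <- penalized_loglik(X, y, cand)
      if (is.finite(pl_new) && pl_new >= pl - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    beta <- cand
    converged <- max(abs(lambda * step)) < tol || abs(pl_new - pl) < tol
    pl <- pl_new
    if (converged) {
      return(list(beta = beta, pl = pl, iter = iter, converged = TRUE,
                  vcov = XtWX_inv))
    }
  }
  list(beta = beta, pl = pl, iter = max_iter, converged = FALSE,
       vcov = XtWX_inv)
}

#' Firth's bias-reduced logistic regression
#'
#' Fits a binary-outcome logistic model by maximizing the Jeffreys-prior
#' penalized log-likelihood. Estimates stay finite under complete
#' separation. Constant (zero-variance) predictor columns are dropped with a
#' message. p values are penalized likelihood-ratio tests.
#'
#' @param design numeric matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @param outcome binary vector (0/1, logical, or 2-level factor); both
#'   classes must be present.
#' @param max_iter Newton iteration cap (default 100).
#' @param tol convergence tolerance (default 1e-10).
#' @return object of class `firth_fit`: data.frame `coefficients` with
#'   columns `term, beta, exp_beta, p`, plus `loglik_penalized`, `iter`,
#'   `converged`, `dropped` (names of constant columns removed), `vcov`.
#' @export
firth_logistic <- function(design, outcome, max_iter = 100L, tol = 1e-10) {
  design <- as.matrix(as.data.frame(design))
  storage.mode(design) <- "double"
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (length(unique(y)) < 2L) stop("outcome has a single class; cannot fit")
  if (nrow(design) != length(y)) stop("design and outcome lengths differ")
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  const <- apply(design, 2L, function(col) length(unique(col)) == 1L)
  dropped <- colnames(design)[const]
  if (any(const)) {
    message("dropping constant predictor(s): ", paste(dropped, collapse = ", "))
    design <- design[, !const, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, design)
  k <- ncol(X)
  if (k > length(y)) {
    stop(sprintf("Firth fit needs at least as many observations as coefficients (%d coefficients, %d observations)",
                 k, length(y)))
  }
  fit <- firth_newton(X, y, beta = rep(0, k), free = seq_len(k),
                      max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    stop(sprintf("Firth fit did not converge in %d iterations (penalized loglik %.6f)",
                 max_iter, fit$pl))
  }
  pvals <- rep(NA_real_, k)
  for (j in seq_len(k)[-1L]) {  # LR test per predictor (not the intercept)
    beta0 <- fit$beta
    beta0[j] <- 0
    restricted <- firth_newton(X, y, beta = beta0, free = seq_len(k)[-j],
                               max_iter = max_iter, tol = tol)
    lr <- 2 * (fit$pl - restricted$pl)
    pvals[j] <- stats::pchisq(max(0, lr), df = 1L, lower.tail = FALSE)
  }
  coef_tab <- data.frame(
    term = colnames(X), beta = unname(fit$beta),
    exp_beta = exp(unname(fit$beta)), p = pvals,
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coef_tab, loglik_penalized = fit$pl, iter = fit$iter,
         converged = fit$converged, dropped = dropped, vcov = fit$vcov,
         n = length(y)),
    class = "firth_fit"
  )
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("Firth bias-reduced logistic regression (n = %d, %d iterations)\n",
              x$n, x$iter))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (length(x$dropped)) {
    cat("dropped constant predictors:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
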