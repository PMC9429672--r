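# Shared weighted least-squares machinery around minpack.lm::nls.lm.

# Weighted Levenberg-Marquardt fit with box constraints.
# fn(pars) must return model values on the data grid.
.wls_fit <- function(par0, fn, data, err, lower = NULL, upper = NULL,
                     maxiter = 1000) {
  resid_fn <- function(p) (data - fn(p)) / err
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, maxfev = 100000,
                                     ftol = 1e-15, ptol = 1e-15)
  # optimizer chatter (e.g. hitting maxiter on unidentifiable corners) is
  # reported through the converged flag and message, not as warnings
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       lower = lower, upper = upper, control = ctrl))
  p <- stats::coef(fit)
  n <- length(data)
  k <- length(p)
  chi2 <- sum(resid_fn(p)^2)
  # covariance from J^T J of the weighted residuals
  covm <- tryCatch(solve(fit$hessian),
                   error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(p)
  at_lower <- if (is.null(lower)) rep(FALSE, k) else abs(p - lower) < 1e-10 * pmax(1, abs(lower))
  at_upper <- if (is.null(upper)) rep(FALSE, k) else abs(p - upper) < 1e-10 * pmax(1, abs(upper))
  list(par = p, se = se, cov = covm, chi2 = chi2,
       chi2_red = chi2 / max(1, n - k),
       converged = fit$info %in% 1:4,
       at_bound = at_lower | at_upper,
       info = fit$info, message = fit$message)
}

# Weighted linear least squares with optional non-negativity by clipping
# and refitting on the active set (2-column designs only).
.wls_linear_nonneg <- function(X, y, err) {
  w <- 1 / err
  Xw <- X * w
  yw <- y * w
  b <- tryCatch(qr.coef(qr(Xw), yw), error = function(e) rep(0, ncol(X)))
  b[is.na(b)] <- 0
  if (all(b >= 0)) return(b)
  # active-set for the tiny 2-parameter case
  k <- ncol(X)
  best <- NULL
  best_rss <- Inf
  for (mask in seq_len(2^k) - 1L) {
    on <- bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0
    bb <- rep(0, k)
    if (any(on)) {
      sol <- tryCatch(qr.coef(qr(Xw[, on, drop = FALSE]), yw),
                      error = function(e) NULL)
      if (is.null(sol) || any(is.na(sol)) || any(sol < 0)) next
      bb[on] <- sol
    }
    rss <- sum((yw - Xw %*% bb)^2)
    if (rss < best_rss) { best_rss <- rss; best <- bb }
  }
  if (is.null(best)) rep(0, k) else best
}

# Numeric Jacobian of fn at p (forward differences, relative step).
.num_jacobian <- function(fn, p, eps = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1e-8)
    pj <- p
    pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}
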