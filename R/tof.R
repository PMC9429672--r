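# Per-q fitting of time-of-flight spectra: pure-solvent model, protein
# model with the solvent fixed and scaled by (1 - phi), and jump-diffusion
# analysis of the extracted internal linewidths.

#' Evaluate the pure-solvent spectral model at one q
#'
#' Resolution-convolved sum of two Lorentzians and an elastic line plus a
#' linear background: R (x) [I1 L(sigma1) + I2 L(sigma2) + I_el delta] +
#' slope * omega + offset.  The background is not convolved.
#'
#' @param pars named vector: I1, I2, I_el, sigma1, sigma2, slope, offset
#' @param omega energy grid (micro-eV)
#' @param res_q resolution Gaussians at this q (data frame weight/center/sd)
#' @return model intensities
#' @export
solvent_model_eval <- function(pars, omega, res_q) {
  p <- as.list(pars)
  comps <- list(
    list(kind = "lorentzian", weight = p$I1, hwhm = p$sigma1, center = 0),
    list(kind = "lorentzian", weight = p$I2, hwhm = p$sigma2, center = 0),
    list(kind = "delta", weight = p$I_el, hwhm = 0, center = 0))
  convolve_model(comps, res_q)(omega) + p$slope * omega + p$offset
}

#' Evaluate the protein time-of-flight spectral model at one q
#'
#' Free part: apparent elastic line, slow internal Lorentzian (width
#' `gamma_slow`) and fast broad Lorentzian (width `gamma_fast`); fixed
#' part: the pure-solvent Lorentzians and background scaled by (1 - phi).
#' All scattering terms are resolution-convolved; the background is not.
#'
#' @param free named vector: I_el, I_slow, gamma_slow, I_fast, gamma_fast
#' @param omega energy grid (micro-eV)
#' @param res_q resolution Gaussians at this q
#' @param solvent_pars named vector I1, I2, sigma1, sigma2, slope, offset
#'   from the pure-solvent fit at the same q
#' @param phi protein volume fraction in [0, 1)
#' @return model intensities
#' @export
protein_tof_model_eval <- function(free, omega, res_q, solvent_pars, phi) {
  f <- as.list(free)
  s <- as.list(solvent_pars)
  comps <- list(
    list(kind = "delta", weight = f$I_el, hwhm = 0, center = 0),
    list(kind = "lorentzian", weight = f$I_slow, hwhm = f$gamma_slow, center = 0),
    list(kind = "lorentzian", weight = (1 - phi) * s$I1, hwhm = s$sigma1, center = 0),
    list(kind = "lorentzian", weight = (1 - phi) * s$I2, hwhm = s$sigma2, center = 0))
  if (f$I_fast > 0)
    comps <- c(comps, list(list(kind = "lorentzian", weight = f$I_fast,
                                hwhm = f$gamma_fast, center = 0)))
  convolve_model(comps, res_q)(omega) + (1 - phi) * (s$slope * omega + s$offset)
}

# Moment-based starting values for the solvent fit at one q.
.solvent_start <- function(omega, y, window) {
  n <- length(omega)
  edge <- unique(c(seq_len(max(3L, n %/% 10)),
                   seq(n - max(3L, n %/% 10) + 1L, n)))
  bg <- stats::lm.fit(cbind(1, omega[edge]), y[edge])$coefficients
  ycore <- pmax(y - bg[1] - bg[2] * omega, 0)
  total <- sum(ycore) * mean(diff(omega))
  c(I1 = 0.6 * total, I2 = 0.35 * total, I_el = 0.05 * total,
    sigma1 = 0.03 * window, sigma2 = 0.3 * window,
    slope = unname(bg[2]), offset = unname(bg[1]))
}

#' Fit the pure-solvent model at each q
#'
#' Independent weighted least-squares fit at every q of the two-Lorentzian
#' solvent model with an elastic line and linear background.  Lorentzian
#' widths are ordered sigma1 < sigma2 after the fit (amplitudes swapped
#' accordingly).  A q where the optimiser fails is flagged in the
#' `converged` column rather than aborting the set.
#'
#' @param spectra a [spectrum_set()] with sample "solvent"
#' @param resolution a [resolution_model()] sharing the q grid
#' @return a `solvent_fit` data frame: one row per q with parameter values,
#'   standard errors (`*_se`, from the covariance diagonal), `chi2_red`
#'   and `converged`
#' @export
fit_solvent <- function(spectra, resolution) {
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(resolution, "resolution_model"))
  if (spectra$sample != "solvent")
    warning("fit_solvent() called on a '", spectra$sample, "' sample")
  pnames <- c("I1", "I2", "I_el", "sigma1", "sigma2", "slope", "offset")
  rows <- lapply(seq_along(spectra$q), function(i) {
    q <- spectra$q[i]
    res_q <- resolution_at(resolution, q)
    omega <- spectra$omega
    y <- spectra$intensity[i, ]
    err <- spectra$error[i, ]
    p0 <- .solvent_start(omega, y, spectra$profile$window)
    lower <- c(0, 0, 0, 1e-3, 1e-3, -Inf, -Inf)
    upper <- c(Inf, Inf, Inf, 50 * spectra$profile$window,
               200 * spectra$profile$window, Inf, Inf)
    fit <- tryCatch(
      .wls_fit(p0, function(p) solvent_model_eval(p, omega, res_q),
               y, err, lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) {
      out <- as.list(rep(NA_real_, 2 * length(pnames)))
      names(out) <- c(pnames, paste0(pnames, "_se"))
      return(data.frame(q = q, out, chi2_red = NA_real_, converged = FALSE))
    }
    p <- fit$par
    se <- fit$se
    if (p[["sigma1"]] > p[["sigma2"]]) {   # enforce width ordering
      p[c("sigma1", "sigma2")] <- p[c("sigma2", "sigma1")]
      p[c("I1", "I2")] <- p[c("I2", "I1")]
      se[c("sigma1", "sigma2")] <- se[c("sigma2", "sigma1")]
      se[c("I1", "I2")] <- se[c("I2", "I1")]
    }
    out <- c(as.list(p[pnames]), as.list(stats::setNames(se[pnames],
                                                         paste0(pnames, "_se"))))
    data.frame(q = q, out, chi2_red = fit$chi2_red, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("solvent_fit", "data.frame")
  out
}

#' Fit the protein time-of-flight model at each q
#'
#' Weighted per-q fit with the solvent Lorentzian amplitudes and the
#' background fixed from the pure-solvent fit and scaled by (1 - phi).
#' Free parameters: apparent elastic amplitude, and amplitude + width of
#' the slow internal (jump-diffusion-bearing) and fast broad Lorentzians.
#' The slow internal width is reported as `gamma_in5`.
#'
#' @param spectra a [spectrum_set()] with a protein or ligand-only sample
#' @param resolution a [resolution_model()]
#' @param solvent a `solvent_fit` from [fit_solvent()] covering all q
#' @param phi protein volume fraction in [0, 1)
#' @return a `tof_fit` data frame: per q, `I_el`, `I_slow`, `gamma_in5`,
#'   `I_fast`, `gamma_fast`, standard errors, `chi2_red`, `converged` and
#'   `width_at_bound`
#' @export
fit_protein_tof <- function(spectra, resolution, solvent, phi) {
  stopifnot(inherits(spectra, "spectrum_set"), phi >= 0, phi < 1)
  if (spectra$sample == "solvent")
    stop("use fit_solvent() for a pure-solvent sample")
  pnames <- c("I_el", "I_slow", "gamma_slow", "I_fast", "gamma_fast")
  rows <- lapply(seq_along(spectra$q), function(i) {
    q <- spectra$q[i]
    j <- which(abs(solvent$q - q) <= 1e-8 * max(1, q))
    if (length(j) != 1L)
      stop("solvent fit has no entry for q = ", q)
    sp <- unlist(solvent[j, c("I1", "I2", "sigma1", "sigma2", "slope", "offset")])
    res_q <- resolution_at(resolution, q)
    omega <- spectra$omega
    y <- spectra$intensity[i, ]
    err <- spectra$error[i, ]
    # subtract the fixed part to seed the free amplitudes
    fixed <- protein_tof_model_eval(
      c(I_el = 0, I_slow = 0, gamma_slow = 1, I_fast = 0, gamma_fast = 1),
      omega, res_q, sp, phi)
    excess <- pmax(y - fixed, 0)
    total <- sum(excess) * mean(diff(omega))
    win <- spectra$profile$window
    p0 <- c(I_el = 0.1 * total, I_slow = 0.6 * total,
            gamma_slow = .hbar * 40 * q^2 / (1 + 40 * q^2 * 0.01),
            I_fast = 0.3 * total, gamma_fast = 0.15 * win)
    lower <- c(0, 0, 1e-4, 0, 1e-4)
    upper <- c(Inf, Inf, 20 * win, Inf, 200 * win)
    fit <- tryCatch(
      .wls_fit(p0, function(p) protein_tof_model_eval(p, omega, res_q, sp, phi),
               y, err, lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) {
      out <- as.list(rep(NA_real_, 2 * length(pnames)))
      names(out) <- c(pnames, paste0(pnames, "_se"))
      df <- data.frame(q = q, out, chi2_red = NA_real_, converged = FALSE,
                       width_at_bound = NA)
    } else {
      p <- fit$par
      se <- fit$se
      width_at_bound <- any(fit$at_bound[c(3L, 5L)] & p[c(3L, 5L)] > 1e-3)
      df <- data.frame(q = q, as.list(p[pnames]),
                       as.list(stats::setNames(se[pnames], paste0(pnames, "_se"))),
                       chi2_red = fit$chi2_red, converged = fit$converged,
                       width_at_bound = width_at_bound)
    }
    df
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "gamma_slow"] <- "gamma_in5"
  names(out)[names(out) == "gamma_slow_se"] <- "gamma_in5_se"
  class(out) <- c("tof_fit", "data.frame")
  out
}

#' Fit the jump-diffusion model to internal linewidths
#'
#' Weighted fit of gamma(q) = hbar D_i q^2 / (1 + D_i q^2 tau) to
#' quasi-elastic widths.  If the optimiser drives tau negative the fit is
#' repeated with tau fixed at zero and flagged Fickian-like.
#'
#' @param gamma HWHM values (micro-eV), > 0
#' @param q momentum transfers (1/Angstrom), >= 4 points
#' @param gamma_err uncertainties on `gamma` (micro-eV); equal weights if
#'   omitted
#' @return a `jump_diffusion_fit` list: `D_i` (Angstrom^2/ns), `tau` (ns),
#'   standard errors, covariance, `fickian` flag and the fitted curve
#'   function
#' @export
fit_jump_diffusion <- function(gamma, q, gamma_err = NULL) {
  keep <- is.finite(gamma) & gamma > 0 & is.finite(q)
  gamma <- gamma[keep]; q <- q[keep]
  if (!is.null(gamma_err)) gamma_err <- gamma_err[keep]
  if (length(q) < 4L) stop("jump-diffusion fit needs >= 4 usable q points")
  if (is.null(gamma_err) || !all(is.finite(gamma_err)) || !all(gamma_err > 0))
    gamma_err <- rep(1, length(gamma))
  model <- function(p) jump_diffusion_hwhm(q, p[["D_i"]], p[["tau"]])
  D0 <- max(gamma[1] / (.hbar * q[1]^2), 1e-3)
  p0 <- c(D_i = D0, tau = .hbar / (2 * max(gamma)))
  fit <- .wls_fit(p0, model, gamma, gamma_err,
                  lower = c(1e-6, 0), upper = c(Inf, Inf))
  fickian <- FALSE
  if (fit$at_bound[2L] || fit$par[["tau"]] < 1e-12) {
    # tau pinned at zero: refit the Fickian line gamma = hbar D q^2
    fickian <- TRUE
    w <- 1 / gamma_err^2
    x <- .hbar * q^2
    D_i <- sum(w * x * gamma) / sum(w * x^2)
    se <- sqrt(1 / sum(w * x^2))
    fit$par <- c(D_i = D_i, tau = 0)
    fit$se <- c(D_i = se, tau = 0)
    fit$cov <- diag(c(se^2, 0))
  }
  structure(list(D_i = unname(fit$par[["D_i"]]), tau = unname(fit$par[["tau"]]),
                 D_i_se = unname(fit$se[["D_i"]]), tau_se = unname(fit$se[["tau"]]),
                 cov = fit$cov, fickian = fickian,
                 chi2_red = fit$chi2_red, q = q, gamma = gamma,
                 curve = local({
                   Di <- unname(fit$par[["D_i"]]); tv <- unname(fit$par[["tau"]])
                   function(q) .hbar * Di * q^2 / (1 + Di * q^2 * tv)
                 })),
            class = "jump_diffusion_fit")
}

#' @export
print.jump_diffusion_fit <- function(x, ...) {
  cat(sprintf("Jump diffusion: D_i = %.4g +/- %.2g A^2/ns, tau = %.4g +/- %.2g ns%s\n",
              x$D_i, x$D_i_se, x$tau, x$tau_se,
              if (x$fickian) " (Fickian-like: tau fixed at 0)" else ""))
  invisible(x)
}
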