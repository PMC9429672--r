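# Global-in-q fit of backscattering spectra: Fickian centre-of-mass
# diffusion plus an internal Lorentzian whose width is fixed from the
# time-of-flight jump-diffusion result, and a fixed solvent line.

#' Evaluate the backscattering spectral model at one q
#'
#' beta [A0 L(hbar D q^2) + (1 - A0) L(hbar D q^2 + Gamma)] +
#' beta_d2o L(gamma_d2o), every Lorentzian resolution-convolved (i.e. a
#' Voigt sum).  The centre-of-mass line broadens the otherwise elastic
#' fraction A0, and the internal line carries the summed width because a
#' product of intermediate scattering functions convolves in energy.
#'
#' @param omega energy grid (micro-eV)
#' @param res_q resolution Gaussians at this q (data frame weight/center/sd)
#' @param D apparent centre-of-mass diffusion coefficient (Angstrom^2/ns)
#' @param q momentum transfer (1/Angstrom)
#' @param beta overall protein amplitude at this q
#' @param A0 elastic incoherent structure factor at this q, in [0, 1]
#' @param Gamma internal linewidth at this q (micro-eV), held fixed
#' @param beta_d2o solvent amplitude at this q (already rescaled if the
#'   (1 - phi) convention is in use)
#' @param gamma_d2o solvent Lorentzian HWHM at this q (micro-eV)
#' @return model intensities
#' @export
bs_model_eval <- function(omega, res_q, D, q, beta, A0, Gamma,
                          beta_d2o, gamma_d2o) {
  gam <- fickian_hwhm(q, D)
  as_line <- function(weight, hwhm)     # frozen motion: Lorentzian -> delta
    if (hwhm > 0) list(kind = "lorentzian", weight = weight, hwhm = hwhm,
                       center = 0)
    else list(kind = "delta", weight = weight, hwhm = 0, center = 0)
  comps <- list(
    as_line(beta * A0, gam),
    as_line(beta * (1 - A0), gam + Gamma),
    as_line(beta_d2o, gamma_d2o))
  comps <- Filter(function(cc) cc$weight > 0, comps)
  if (!length(comps)) return(numeric(length(omega)))
  convolve_model(comps, res_q)(omega)
}

# Resolution-convolved unit Lorentzian at one q (basis function).
.conv_lorentzian <- function(omega, res_q, hwhm) {
  out <- numeric(length(omega))
  for (i in seq_len(nrow(res_q)))
    out <- out + res_q$weight[i] * voigt(omega, hwhm, res_q$sd[i],
                                         center = res_q$center[i])
  out
}

#' Global fit of backscattering spectra over all q simultaneously
#'
#' Single weighted least-squares problem over every (q, omega) point with
#' one global apparent diffusion coefficient D (entering as Fickian width
#' hbar D q^2) and per-q amplitude beta(q) and EISF A0(q).  The internal
#' linewidth Gamma(q) is always supplied externally — from the
#' time-of-flight jump-diffusion parameters or an explicit override —
#' because freeing it on backscattering data alone is unstable when the
#' internal motions are faster than the accessible window.  The solvent
#' amplitude and width per q are fixed inputs.
#'
#' The joint problem is solved by variable projection: for each candidate
#' D the per-q amplitudes (beta A0, beta (1 - A0)) are the solution of a
#' non-negative weighted linear least squares, leaving a one-dimensional
#' profile objective in D that is minimised from five jittered starts.
#' The parameter covariance is evaluated from the joint Jacobian of all
#' 2 nq + 1 parameters at the optimum.
#'
#' @param spectra a [spectrum_set()] on a backscattering-like profile
#' @param resolution a [resolution_model()]
#' @param solvent_params data frame with columns `q`, `beta_d2o`,
#'   `gamma_d2o` (see [bs_solvent_truth_params()])
#' @param internal a [fit_jump_diffusion()] result or list with `D_i`
#'   (Angstrom^2/ns) and `tau` (ns); ignored if `Gamma_override` given
#' @param phi protein volume fraction; with `scale_solvent = TRUE` the
#'   solvent amplitude is rescaled by (1 - phi)
#' @param scale_solvent logical, default TRUE
#' @param Gamma_override optional per-q internal widths (micro-eV)
#' @param D_range search interval for D (Angstrom^2/ns)
#' @param n_starts jittered local starts around the grid-scan minimum
#' @param jitter_seed fixed seed for the start jitter
#' @return a `global_fit` list: `D`, `D_se`, per-q table `per_q` (beta,
#'   A0, standard errors, fixed Gamma and solvent inputs,
#'   `gamma_exceeds_window` flag), `chi2_red` and bookkeeping
#' @export
global_fit <- function(spectra, resolution, solvent_params, internal = NULL,
                       phi = 0.09, scale_solvent = TRUE,
                       Gamma_override = NULL, D_range = c(0.05, 50),
                       n_starts = 5L, jitter_seed = 421L) {
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(resolution, "resolution_model"))
  q <- spectra$q
  nq <- length(q)
  omega <- spectra$omega
  if (is.null(Gamma_override)) {
    if (is.null(internal))
      stop("global_fit() requires fixed internal dynamics: supply 'internal' ",
           "(jump-diffusion parameters from the time-of-flight analysis) or ",
           "an explicit 'Gamma_override'")
    Gamma <- jump_diffusion_hwhm(q, internal$D_i, internal$tau)
  } else {
    Gamma <- rep_len(Gamma_override, nq)
  }
  idx <- match(round(q, 10), round(solvent_params$q, 10))
  if (anyNA(idx)) stop("solvent_params must cover every q of the spectra")
  sol_scale <- if (scale_solvent) 1 - phi else 1
  beta_d2o <- sol_scale * solvent_params$beta_d2o[idx]
  gamma_d2o <- solvent_params$gamma_d2o[idx]
  res_list <- lapply(q, function(qi) resolution_at(resolution, qi))
  sol_term <- lapply(seq_len(nq), function(i)
    beta_d2o[i] * .conv_lorentzian(omega, res_list[[i]], gamma_d2o[i]))

  # profile objective: solve per-q linear amplitudes at fixed D
  profile_fit <- function(D) {
    chi2 <- 0
    b1 <- numeric(nq); b2 <- numeric(nq)
    for (i in seq_len(nq)) {
      gam <- fickian_hwhm(q[i], D)
      X <- cbind(.conv_lorentzian(omega, res_list[[i]], gam),
                 .conv_lorentzian(omega, res_list[[i]], gam + Gamma[i]))
      y <- spectra$intensity[i, ] - sol_term[[i]]
      err <- spectra$error[i, ]
      b <- .wls_linear_nonneg(X, y, err)
      b1[i] <- b[1]; b2[i] <- b[2]
      chi2 <- chi2 + sum(((y - X %*% b) / err)^2)
    }
    list(chi2 = chi2, b1 = b1, b2 = b2)
  }
  obj <- function(logD) profile_fit(exp(logD))$chi2

  grid <- seq(log(D_range[1]), log(D_range[2]), length.out = 15L)
  chi_grid <- vapply(grid, obj, numeric(1))
  best0 <- grid[which.min(chi_grid)]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(jitter_seed)
  starts <- c(best0, best0 + stats::rnorm(max(0L, n_starts - 1L), sd = 0.15))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  fits <- lapply(starts, function(s)
    stats::nlminb(s, obj, lower = log(D_range[1]), upper = log(D_range[2])))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  if (best$convergence != 0 && !is.finite(best$objective))
    stop("global fit did not converge; last objective = ", best$objective)
  D <- exp(best$par)
  pf <- profile_fit(D)
  beta <- pf$b1 + pf$b2
  A0 <- ifelse(beta > 0, pmin(pmax(pf$b1 / beta, 0), 1), NA_real_)

  # joint covariance at the optimum over theta = (D, beta_q, A0_q)
  theta <- c(D, beta, A0)
  resid_fn <- function(th) {
    Dv <- th[1]; bv <- th[2:(nq + 1)]; av <- th[(nq + 2):(2 * nq + 1)]
    unlist(lapply(seq_len(nq), function(i) {
      m <- bs_model_eval(omega, res_list[[i]], Dv, q[i], bv[i], av[i],
                         Gamma[i], beta_d2o[i], gamma_d2o[i])
      (spectra$intensity[i, ] - m) / spectra$error[i, ]
    }))
  }
  J <- .num_jacobian(resid_fn, theta)
  covm <- tryCatch(solve(crossprod(J)), error = function(e) {
    sv <- svd(crossprod(J))
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  se <- sqrt(pmax(diag(covm), 0))
  wide <- Gamma > spectra$profile$window
  A0_se <- se[(nq + 2):(2 * nq + 1)]
  if (any(wide))
    warning("fixed internal width Gamma exceeds the energy window at q = ",
            paste(signif(q[wide], 3), collapse = ", "),
            "; the internal line there is flat on the accessible window ",
            "and the EISF is weakly constrained")
  n_data <- length(omega) * nq
  out <- list(D = D, D_se = se[1],
              per_q = data.frame(q = q, beta = beta,
                                 beta_se = se[2:(nq + 1)],
                                 A0 = A0, A0_se = A0_se,
                                 Gamma = Gamma, beta_d2o = beta_d2o,
                                 gamma_d2o = gamma_d2o,
                                 gamma_exceeds_window = wide),
              chi2 = pf$chi2,
              chi2_red = pf$chi2 / max(1, n_data - (2 * nq + 1)),
              phi = phi, scale_solvent = scale_solvent,
              at_bound = any(A0 %in% c(0, 1)))
  class(out) <- "global_fit"
  out
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global backscattering fit: D = %.4g +/- %.2g A^2/ns over %d q points (chi2_red = %.3g)\n",
              x$D, x$D_se, nrow(x$per_q), x$chi2_red))
  invisible(x)
}
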