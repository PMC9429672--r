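# Time-of-flight pipeline: solvent fits, protein fits with fixed solvent,
# and the jump-diffusion analysis of the extracted widths.

test_that("noise-free solvent fit recovers all parameters", {
  setup <- default_tof_setup()
  sp <- with_cache("tof_solvent_clean",
                   simulate_solvent(setup$profile, setup$truth))
  fit <- with_cache("tof_solvent_fit", fit_solvent(sp, setup$resolution))
  truth <- solvent_truth_params(setup$truth, setup$profile$q)
  expect_true(all(fit$converged))
  for (p in c("I1", "I2", "I_el", "sigma1", "sigma2"))
    expect_lt(max(rel_err(fit[[p]], truth[[p]])), 1e-3)
  expect_equal(fit$slope, truth$slope, tolerance = 1e-3)
  expect_equal(fit$offset, truth$offset, tolerance = 1e-3)
  expect_true(all(fit$sigma1 < fit$sigma2))
})

test_that("doubling the intensities doubles amplitudes, not widths", {
  setup <- default_tof_setup()
  sp <- with_cache("tof_solvent_clean",
                   simulate_solvent(setup$profile, setup$truth))
  fit1 <- with_cache("tof_solvent_fit", fit_solvent(sp, setup$resolution))
  sp2 <- sp
  sp2$intensity <- 2 * sp$intensity
  sp2$error <- 2 * sp$error
  fit2 <- fit_solvent(sp2, setup$resolution)
  expect_equal(fit2$I1, 2 * fit1$I1, tolerance = 1e-6)
  expect_equal(fit2$I2, 2 * fit1$I2, tolerance = 1e-6)
  expect_equal(fit2$sigma1, fit1$sigma1, tolerance = 1e-6)
  expect_equal(fit2$sigma2, fit1$sigma2, tolerance = 1e-6)
})

test_that("a zero-amplitude broad solvent line is recovered as zero", {
  prof <- tiny_tof_profile(128L)
  tr <- ground_truth(solvent = list(I2 = 0), noise = 1e-3, seed = 21)
  sp <- simulate_solvent(prof, tr)
  res <- gaussian_resolution(prof$q, prof$fwhm)
  fit <- fit_solvent(sp, res)
  # with no broad line the two-Lorentzian split is degenerate: the fitted
  # I2 must be consistent with zero within its bound, where a singular
  # covariance (NA bound) marks exactly that unidentifiability
  defined <- is.finite(fit$I2_se) & fit$I2_se > 0
  expect_true(all(fit$I2[defined] <= 3 * fit$I2_se[defined] + 1e-8))
  # the identifiable content - the summed model - matches the truth
  truth_pars <- solvent_truth_params(tr, prof$q)
  for (i in seq_along(prof$q)) {
    m_true <- solvent_model_eval(
      unlist(truth_pars[i, c("I1", "I2", "I_el", "sigma1", "sigma2",
                             "slope", "offset")]),
      prof$omega, resolution_at(res, prof$q[i]))
    m_fit <- solvent_model_eval(
      unlist(fit[i, c("I1", "I2", "I_el", "sigma1", "sigma2",
                      "slope", "offset")]),
      prof$omega, resolution_at(res, prof$q[i]))
    # within a few noise standard deviations of the peak
    expect_lt(max(abs(m_fit - m_true)) / max(m_true),
              4 * 1e-3 / sqrt(max(m_true)))
  }
})

test_that("protein TOF fit recovers the internal widths without noise", {
  setup <- default_tof_setup()
  solvent_fit <- with_cache("tof_solvent_fit", {
    sp <- simulate_solvent(setup$profile, setup$truth)
    fit_solvent(sp, setup$resolution)
  })
  prot <- simulate_protein(setup$profile, setup$truth, "liganded")
  fit <- fit_protein_tof(prot, setup$resolution, solvent_fit,
                         setup$truth$phi)
  truth_g <- jump_diffusion_hwhm(setup$profile$q, setup$truth$protein$D_i,
                                 setup$truth$protein$tau)
  expect_true(all(fit$converged))
  expect_lt(max(rel_err(fit$gamma_in5, truth_g)), 5e-3)
  amps <- setup$truth$protein$tof_amplitudes$liganded
  expect_lt(max(rel_err(fit$I_slow, amps[["I_slow"]])), 1e-3)
  expect_lt(max(rel_err(fit$gamma_fast, setup$truth$protein$gamma_fast)),
            1e-2)
})

test_that("apo-like truth yields a vanishing broad component", {
  setup <- default_tof_setup()
  solvent_fit <- with_cache("tof_solvent_fit", {
    sp <- simulate_solvent(setup$profile, setup$truth)
    fit_solvent(sp, setup$resolution)
  })
  prot <- simulate_protein(setup$profile, setup$truth, "apo")
  fit <- fit_protein_tof(prot, setup$resolution, solvent_fit,
                         setup$truth$phi)
  expect_lt(max(fit$I_fast), 1e-4 * max(fit$I_slow))
})

test_that("protein model with phi = 0 and no protein terms equals the solvent model", {
  setup <- default_tof_setup()
  pars <- solvent_truth_params(setup$truth, setup$profile$q)
  i <- 4
  sp <- unlist(pars[i, c("I1", "I2", "sigma1", "sigma2", "slope", "offset")])
  res_q <- resolution_at(setup$resolution, setup$profile$q[i])
  omega <- setup$profile$omega
  m_protein <- protein_tof_model_eval(
    c(I_el = pars$I_el[i], I_slow = 0, gamma_slow = 1, I_fast = 0,
      gamma_fast = 1),
    omega, res_q, sp, phi = 0)
  m_solvent <- solvent_model_eval(
    unlist(pars[i, c("I1", "I2", "I_el", "sigma1", "sigma2", "slope",
                     "offset")]),
    omega, res_q)
  expect_equal(m_protein, m_solvent, tolerance = 1e-10)
})

test_that("pure-noise residuals give reduced chi-square near one", {
  prof <- tiny_tof_profile(256L)
  tr <- ground_truth(noise = 5e-3, seed = 31)
  sp <- simulate_solvent(prof, tr)
  fit <- fit_solvent(sp, gaussian_resolution(prof$q, prof$fwhm))
  expect_true(all(abs(fit$chi2_red - 1) < 0.25))
})

test_that("jump-diffusion fit is exact on exact data and in its limits", {
  q <- seq(0.3, 2.0, length.out = 18)
  g <- jump_diffusion_hwhm(q, 60, 0.01)
  jd <- fit_jump_diffusion(g, q)
  expect_lt(rel_err(jd$D_i, 60), 1e-6)
  expect_lt(rel_err(jd$tau, 0.01), 1e-6)
  expect_false(jd$fickian)
  # Fickian truth: fitted curve is linear in q^2
  gf <- fickian_hwhm(q, 30)
  jdf <- fit_jump_diffusion(gf, q)
  expect_lt(rel_err(jdf$D_i, 30), 1e-6)
  expect_true(jdf$fickian || jdf$tau < 1e-8)
  # high-q plateau of the fitted model is hbar / tau
  expect_equal(jd$curve(1e6), qens_constants$hbar_uev_ns / jd$tau,
               tolerance = 1e-6)
  expect_error(fit_jump_diffusion(g[1:3], q[1:3]), ">= 4")
})

test_that("fitted jump-diffusion curves are monotone and bounded by hbar/tau", {
  q <- seq(0.3, 2.0, length.out = 18)
  set.seed(17)
  for (rep in 1:5) {
    D_i <- runif(1, 20, 80)
    tau <- runif(1, 0.005, 0.02)
    g <- jump_diffusion_hwhm(q, D_i, tau) * (1 + rnorm(18, sd = 0.03))
    jd <- fit_jump_diffusion(pmax(g, 1e-3), q)
    dense <- jd$curve(seq(0.05, 10, length.out = 400))
    expect_true(all(diff(dense) > -1e-12))
    expect_true(all(dense <= qens_constants$hbar_uev_ns / max(jd$tau, 1e-12) +
                      1e-9))
  }
})

test_that("jump-diffusion 1-sigma intervals have sane coverage", {
  # 200 replicates of widths with known Gaussian errors: the D_i interval
  # should cover truth at roughly the nominal 68% rate
  q <- seq(0.3, 2.0, length.out = 18)
  g0 <- jump_diffusion_hwhm(q, 50, 0.01)
  se <- 0.05 * g0
  set.seed(99)
  hits <- 0L
  for (rep in 1:200) {
    g <- g0 + rnorm(18, sd = se)
    jd <- fit_jump_diffusion(pmax(g, 1e-4), q, se)
    if (abs(jd$D_i - 50) <= jd$D_i_se) hits <- hits + 1L
  }
  expect_gte(hits, 120)   # 60% of 200
  expect_lte(hits, 152)   # 76% of 200
})
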