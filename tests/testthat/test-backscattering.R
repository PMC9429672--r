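# EISF models and the global-in-q backscattering fit.

test_that("three-site jump EISF has the exact limits and values", {
  expect_equal(eisf_a3jump(0), 1, tolerance = 1e-14)
  expect_equal(eisf_a3jump(1.0, d = 1.715),
               (1 + 2 * sin(1.715) / 1.715) / 3, tolerance = 1e-12)
  expect_equal(eisf_a3jump(1.0, d = 1.715), 0.718, tolerance = 1e-4)
  # large-q limit: averages to 1/3
  qs <- seq(400, 500, length.out = 2000)
  expect_equal(mean(eisf_a3jump(qs, 1.715)), 1 / 3, tolerance = 1e-3)
  expect_error(eisf_a3jump(1, d = -1))
})

test_that("sphere EISF vanishes at the first j1 zero and decreases before it", {
  expect_equal(eisf_sphere(0, R = 8.5), 1, tolerance = 1e-12)
  # first zero of j1 at x = 4.493409...
  expect_lt(eisf_sphere(4.4934094579 / 8.5, R = 8.5), 1e-10)
  x <- seq(1e-3, 4.49, length.out = 500)
  vals <- eisf_sphere(x, R = 1)
  expect_true(all(diff(vals) < 0))
  # surface-of-sphere variant
  expect_equal(eisf_sphere(0.7, R = 2, model = "surface"),
               (sin(1.4) / 1.4)^2, tolerance = 1e-12)
})

test_that("composite EISF equals one at q = 0 and respects its bounds", {
  set.seed(5)
  q <- seq(0, 5, length.out = 300)
  # below the first zero of j0 (q d < pi) the methyl term stays >= 1/3;
  # globally it is bounded by its minimum (1 + 2 min j0) / 3
  q_low <- q[q * 1.715 < pi]
  xx <- seq(1e-4, 5 * 1.715, length.out = 20000)
  a3_min <- (1 + 2 * min(sin(xx) / xx)) / 3
  for (rep in 1:10) {
    a <- runif(1); b <- runif(1); R <- runif(1, 2, 15)
    A0 <- eisf_model(q, a, b, R)
    expect_equal(A0[1], 1, tolerance = 1e-12)
    expect_true(all(A0 <= 1 + 1e-12))
    expect_true(all(eisf_model(q_low, a, b, R) >=
                      a + (1 - a) * b / 3 - 1e-12))
    expect_true(all(A0 >= a + (1 - a) * b * a3_min - 1e-9))
  }
})

test_that("EISF fit recovers parameters and flags the immobile limit", {
  q <- seq(0.2, 1.9, length.out = 16)
  A0 <- eisf_model(q, 0.4, 0.3, 8.5)
  fit <- fit_eisf(A0, q)
  expect_lt(rel_err(fit$a, 0.4), 1e-3)
  expect_lt(rel_err(fit$b, 0.3), 1e-3)
  expect_lt(rel_err(fit$R, 8.5), 1e-3)
  # fully immobile protein: a -> 1, (b, R) unidentifiable
  fit1 <- fit_eisf(rep(1, 16), q)
  expect_gt(fit1$a, 0.999)
  expect_true("a" %in% fit1$unidentifiable ||
                length(fit1$unidentifiable) > 0)
  expect_error(fit_eisf(A0[1:4], q[1:4]), ">= 5")
  expect_error(fit_eisf(A0 + 0.3, q), "1.05")
})

test_that("global fit recovers D and the EISF without noise", {
  setup <- default_bs_setup()
  sp <- with_cache("bs_clean",
                   simulate_protein(setup$profile, setup$truth, "liganded"))
  gf <- with_cache("bs_gf_clean", suppressWarnings(
    global_fit(sp, setup$resolution, setup$solvent_params,
               internal = list(D_i = 50, tau = 0.01), phi = 0.09)))
  expect_lt(rel_err(gf$D, setup$truth$protein$D), 1e-3)
  A0_true <- eisf_model(setup$profile$q, 0.4, 0.3, 8.5)
  expect_lt(max(abs(gf$per_q$A0 - A0_true)), 1e-3)
  expect_lt(max(rel_err(gf$per_q$beta, setup$truth$protein$beta)), 1e-3)
  expect_true(all(gf$per_q$A0 >= 0 & gf$per_q$A0 <= 1))
})

test_that("the weakly constrained wide-Gamma region is flagged", {
  setup <- default_bs_setup()
  sp <- with_cache("bs_clean",
                   simulate_protein(setup$profile, setup$truth, "liganded"))
  expect_warning(
    global_fit(sp, setup$resolution, setup$solvent_params,
               internal = list(D_i = 50, tau = 0.01), phi = 0.09),
    "exceeds the energy window")
  gf <- with_cache("bs_gf_clean", suppressWarnings(
    global_fit(sp, setup$resolution, setup$solvent_params,
               internal = list(D_i = 50, tau = 0.01), phi = 0.09)))
  wide <- gf$per_q$gamma_exceeds_window
  expect_true(any(wide))
  expect_identical(wide, gf$per_q$Gamma > sp$profile$window)
})

test_that("D is insensitive to the fixed internal width when it exceeds the window", {
  # internal motions far faster than the accessible window: the internal
  # line is a flat background and D must not depend on its exact width
  profs <- default_profiles()
  tr <- ground_truth(protein = list(D_i = 5000, tau = 0.00022))
  sp <- simulate_protein(profs$backscattering, tr, "liganded")
  setup <- default_bs_setup()
  fit_with <- function(scale) {
    Gam <- jump_diffusion_hwhm(profs$backscattering$q, 5000, 0.00022) * scale
    suppressWarnings(global_fit(sp, setup$resolution, setup$solvent_params,
                                Gamma_override = Gam, phi = 0.09))$D
  }
  D_half <- fit_with(0.5)
  D_one <- fit_with(1)
  D_wide <- fit_with(1.5)
  expect_lt(rel_err(D_half, D_one), 0.02)
  expect_lt(rel_err(D_wide, D_one), 0.02)
})

test_that("D is invariant under doubling the per-q amplitude", {
  setup <- default_bs_setup()
  gf1 <- with_cache("bs_gf_clean", suppressWarnings(
    global_fit(with_cache("bs_clean",
                          simulate_protein(setup$profile, setup$truth,
                                           "liganded")),
               setup$resolution, setup$solvent_params,
               internal = list(D_i = 50, tau = 0.01), phi = 0.09)))
  tr2 <- ground_truth(protein = list(beta = 0.4))
  sp2 <- simulate_protein(setup$profile, tr2, "liganded")
  gf2 <- suppressWarnings(
    global_fit(sp2, setup$resolution, setup$solvent_params,
               internal = list(D_i = 50, tau = 0.01), phi = 0.09))
  expect_lt(rel_err(gf2$D, gf1$D), 5e-3)
  expect_equal(gf2$per_q$beta, 2 * gf1$per_q$beta, tolerance = 1e-3)
})

test_that("two samples with D differing by 1.3x are statistically separated", {
  setup <- default_bs_setup()
  ns <- noise_scale_for("bs", 30)
  tr_a <- ground_truth(noise = ns, seed = 41)
  tr_b <- ground_truth(protein = list(D = 3.9), noise = ns, seed = 42)
  gf_a <- suppressWarnings(global_fit(
    simulate_protein(setup$profile, tr_a, "liganded"),
    setup$resolution, setup$solvent_params,
    internal = list(D_i = 50, tau = 0.01), phi = 0.09))
  gf_b <- suppressWarnings(global_fit(
    simulate_protein(setup$profile, tr_b, "liganded"),
    setup$resolution, setup$solvent_params,
    internal = list(D_i = 50, tau = 0.01), phi = 0.09))
  sep <- abs(gf_b$D - gf_a$D) / sqrt(gf_a$D_se^2 + gf_b$D_se^2)
  expect_gt(sep, 3)
})

test_that("global fit refuses to run without fixed internal dynamics", {
  setup <- default_bs_setup()
  sp <- with_cache("bs_clean",
                   simulate_protein(setup$profile, setup$truth, "liganded"))
  expect_error(global_fit(sp, setup$resolution, setup$solvent_params),
               "fixed internal")
})
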