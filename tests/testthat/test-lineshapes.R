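# Analytic lineshapes: Lorentzian, Gaussian, Voigt and the resolution
# convolution that turns fit models into Voigt sums.

test_that("Lorentzian has the defining peak value, HWHM and tail mass", {
  g <- seq(-10, 10, by = 0.5)
  expect_equal(lorentzian(0, hwhm = 1), 1 / pi, tolerance = 1e-12)
  expect_equal(lorentzian(c(-1, 1), hwhm = 1),
               rep(lorentzian(0, 1) / 2, 2), tolerance = 1e-12)
  # mass on a finite window has the closed arctangent form
  mass <- stats::integrate(function(w) lorentzian(w, hwhm = 2.5),
                           -5000, 5000, rel.tol = 1e-12)$value
  expect_equal(mass, (2 / pi) * atan(5000 / 2.5), tolerance = 1e-9)
  expect_lt(mass, 1)
  expect_error(lorentzian(g, hwhm = 0), "positive")
  expect_error(lorentzian(g, hwhm = -1), "positive")
})

test_that("Gaussian density and FWHM conversions are consistent", {
  expect_equal(gaussian(0, sd = 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian(c(-1, 1), sd = 1),
               rep(exp(-0.5) / sqrt(2 * pi), 2), tolerance = 1e-12)
  expect_equal(fwhm_to_sd(0.75), 0.3185, tolerance = 1e-4)
  expect_equal(sd_to_fwhm(fwhm_to_sd(80)), 80, tolerance = 1e-12)
  # half maximum reached at +/- FWHM/2
  sd <- fwhm_to_sd(0.75)
  expect_equal(gaussian(0.75 / 2, sd), gaussian(0, sd) / 2, tolerance = 1e-12)
  expect_error(gaussian(0, sd = 0), "positive")
})

test_that("Faddeeva function matches frozen reference values", {
  # reference values computed with an independent erfcx-based
  # implementation, frozen to 15 digits
  expect_equal(faddeeva_w(0.5 + 0.5i),
               0.533156707912175 + 0.230488231384458i, tolerance = 1e-13)
  expect_equal(faddeeva_w(0 + 1i), 0.427583576155807 + 0i, tolerance = 1e-13)
  expect_equal(faddeeva_w(10 + 2i),
               0.011001556705734 + 0.054471817098657i, tolerance = 1e-12)
  expect_equal(faddeeva_w(0.2 + 0i),
               0.960789439152323 + 0.219753008822806i, tolerance = 1e-13)
  expect_error(faddeeva_w(1 - 1i), "Im")
})

test_that("Voigt reduces to its Gaussian and Lorentzian limits", {
  w <- seq(-10, 10, by = 0.05)
  expect_equal(voigt(w, lor_hwhm = 0, gauss_sd = 1.3),
               gaussian(w, sd = 1.3), tolerance = 1e-12)
  v <- voigt(w, lor_hwhm = 1, gauss_sd = 1e-6)
  expect_equal(v, lorentzian(w, hwhm = 1), tolerance = 1e-6)
  expect_error(voigt(w, lor_hwhm = 0, gauss_sd = 0), "both widths zero")
})

test_that("Voigt matches the brute-force numerical convolution", {
  # trapezoid convolution oracle on a +/-200 window, step 0.01
  x <- seq(-200, 200, by = 0.01)
  lor <- lorentzian(x, hwhm = 2)
  at <- function(w) sum(lor * gaussian(w - x, sd = 1.5)) * 0.01
  for (w in c(0, 1.7, -3.2)) {
    expect_equal(voigt(w, 2, 1.5), at(w), tolerance = 1e-5)
  }
})

test_that("Voigt is symmetric about its center on a symmetric grid", {
  w <- seq(-25, 25, by = 0.1)
  v <- voigt(w, 3, 0.8, center = 0)
  expect_equal(v, rev(v), tolerance = 1e-12)
  v2 <- voigt(w + 4, 3, 0.8, center = 4)
  expect_equal(v2, rev(v2), tolerance = 1e-12)
})

test_that("density primitives integrate to their weight on wide windows", {
  # Lorentzian tails dominate the truncation loss: on a half-window of
  # W x hwhm the missing mass is (2/pi) atan(hwhm/W-ish) ~ 2/(pi W),
  # so 0.5% accuracy needs W >= ~130
  for (hwhm in c(0.5, 2)) {
    W <- 150 * hwhm
    m <- stats::integrate(function(w) lorentzian(w, hwhm), -W, W,
                          rel.tol = 1e-10)$value
    expect_equal(m, (2 / pi) * atan(W / hwhm), tolerance = 1e-9)
    expect_equal(m, 1, tolerance = 5e-3)
  }
  # split at the peak so quadrature resolves the narrow core
  m <- stats::integrate(function(w) voigt(w, 1, 2), -150, -10,
                        rel.tol = 1e-10)$value +
    stats::integrate(function(w) voigt(w, 1, 2), -10, 10,
                     rel.tol = 1e-10)$value +
    stats::integrate(function(w) voigt(w, 1, 2), 10, 150,
                     rel.tol = 1e-10)$value
  expect_equal(m, 1, tolerance = 5e-3)
})

test_that("convolve_model realises deltas as the resolution profile", {
  res_q <- data.frame(weight = c(0.6, 0.4), center = c(-1, 2),
                      sd = c(0.5, 1.2))
  w <- seq(-20, 20, by = 0.1)
  m <- convolve_model(list(spectral_component("delta", weight = 1)), res_q)
  expect_equal(m(w), 0.6 * gaussian(w, 0.5, -1) + 0.4 * gaussian(w, 1.2, 2),
               tolerance = 1e-12)
  # weight scales linearly
  m2 <- convolve_model(list(spectral_component("delta", weight = 2.5)), res_q)
  expect_equal(m2(w), 2.5 * m(w), tolerance = 1e-12)
})

test_that("convolve_model is linear and matches Voigt sums", {
  res_q <- data.frame(weight = c(0.7, 0.3), center = c(0, 0),
                      sd = c(fwhm_to_sd(80), 60))
  w <- seq(-500, 500, by = 2)
  one <- convolve_model(list(
    spectral_component("lorentzian", weight = 1, hwhm = 3)), res_q)(w)
  halves <- convolve_model(list(
    spectral_component("lorentzian", weight = 0.5, hwhm = 3),
    spectral_component("lorentzian", weight = 0.5, hwhm = 3)), res_q)(w)
  expect_equal(one, halves, tolerance = 1e-12)
  direct <- 0.7 * voigt(w, 3, fwhm_to_sd(80)) + 0.3 * voigt(w, 3, 60)
  expect_equal(one, direct, tolerance = 1e-12)
  # and the brute-force convolution agrees at the peak
  x <- seq(-3000, 3000, by = 0.05)
  lor <- lorentzian(x, hwhm = 3)
  num <- sum(lor * (0.7 * gaussian(-x, fwhm_to_sd(80)) +
                      0.3 * gaussian(-x, 60))) * 0.05
  expect_equal(one[w == 0], num, tolerance = 1e-5)
})

test_that("convolve_model rejects unknown component kinds", {
  res_q <- data.frame(weight = 1, center = 0, sd = 1)
  expect_error(convolve_model(list(list(kind = "voigt", weight = 1,
                                        hwhm = 1, center = 0)), res_q),
               "unknown component kind")
  expect_error(spectral_component("lorentzian", weight = -1, hwhm = 1),
               ">= 0")
})
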