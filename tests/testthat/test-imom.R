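# Restricted inverse-moment prior: densities, normalizer, mode, sampler.

test_that("density matches the closed formula and vanishes at the null", {
  pr <- im_prior(0.1, 0.06)
  expect_equal(dimom(0.3, pr), 0.06 * 0.2^-3 * exp(-0.06 / 0.04),
               tolerance = 1e-12)
  expect_identical(dimom(0.1, pr), 0)
  expect_identical(drimom(0.05, pr), 0)   # outside the support
  expect_identical(drimom(1.0, pr), 0)
  expect_equal(drimom(0.3, pr), dimom(0.3, pr) / rimom_mass(pr),
               tolerance = 1e-12)
  # restricted density value from the spec's derived ratio
  expect_equal(drimom(0.3, pr), 1.673476 / 0.4643015, tolerance = 1e-4)
})

test_that("closed-form restricted normalizer agrees with quadrature on a (theta0, tau) grid", {
  for (theta0 in c(0, 0.3, 0.6, 0.9)) {
    for (tau in c(1e-4, 1e-2, 0.1, 1)) {
      pr <- im_prior(theta0, tau)
      peak <- theta0 + sqrt(2 * tau / 3)
      pieces <- sort(unique(pmin(pmax(c(theta0, peak, 1), theta0), 1)))
      q <- 0
      for (i in seq_len(length(pieces) - 1)) {
        q <- q + integrate(function(t) dimom(t, pr), pieces[i], pieces[i + 1],
                           rel.tol = 1e-13, abs.tol = 0)$value
      }
      expect_lt(abs(q - rimom_mass(pr)) / rimom_mass(pr), 1e-8)
    }
  }
  # spec's derived examples
  expect_equal(rimom_mass(im_prior(0.1, 0.06)), 0.5 * exp(-0.06 / 0.81),
               tolerance = 1e-12)
  expect_equal(rimom_mass(im_prior(0, 0.015)), 0.5 * exp(-0.015),
               tolerance = 1e-12)
  # tau -> 0 limit: half the mass sits above theta0
  expect_equal(rimom_mass(im_prior(0.5, 1e-10)), 0.5, tolerance = 1e-6)
})

test_that("restricted density integrates to one", {
  for (spec in list(c(0.1, 0.06), c(0, 0.015), c(0.2, 0.06))) {
    pr <- im_prior(spec[1], spec[2])
    peak <- spec[1] + sqrt(2 * spec[2] / 3)
    q <- integrate(function(t) drimom(t, pr), spec[1], peak,
                   rel.tol = 1e-10)$value +
      integrate(function(t) drimom(t, pr), peak, 1, rel.tol = 1e-10)$value
    expect_equal(q, 1, tolerance = 1e-6)
  }
})

test_that("mode matches dense grid search and the printed calibrations", {
  expect_equal(imom_mode(im_prior(0.1, 0.06)), 0.3, tolerance = 1e-12)
  expect_equal(imom_mode(im_prior(0, 0.015)), 0.1, tolerance = 1e-12)
  expect_equal(imom_mode(im_prior(0.2, 0.06)), 0.4, tolerance = 1e-12)
  for (spec in list(c(0.1, 0.06), c(0, 0.015), c(0.4, 0.02))) {
    pr <- im_prior(spec[1], spec[2])
    g <- seq(spec[1] + 1e-5, 1 - 1e-5, by = 1e-5)
    expect_equal(imom_mode(pr), g[which.max(dimom(g, pr))], tolerance = 2e-5)
  }
  expect_warning(imom_mode(im_prior(0.9, 1)), "mode")
})

test_that("inversion sampler matches the quadrature CDF and mean", {
  pr <- im_prior(0.1, 0.06)
  set.seed(42)
  s <- rrimom(1e5, pr)
  expect_true(all(s > 0.1 & s < 1))
  # KS against the analytic restricted CDF, 1% critical value
  ks <- max(abs(ecdf(s)(sort(s)) - primom(sort(s), pr)))
  expect_lt(ks, 1.63 / sqrt(1e5))
  # mean against quadrature within 3 standard errors
  peak <- 0.1 + sqrt(2 * 0.06 / 3)
  mu <- integrate(function(t) t * drimom(t, pr), 0.1, peak,
                  rel.tol = 1e-10)$value +
    integrate(function(t) t * drimom(t, pr), peak, 1, rel.tol = 1e-10)$value
  expect_lt(abs(mean(s) - mu), 3 * sd(s) / sqrt(1e5))
  # determinism under a fixed seed
  set.seed(7); a <- rrimom(10, pr)
  set.seed(7); b <- rrimom(10, pr)
  expect_identical(a, b)
})

test_that("invalid hyperparameters are rejected", {
  expect_error(im_prior(1, 0.06), "theta0")
  expect_error(im_prior(-0.1, 0.06), "theta0")
  expect_error(im_prior(0.1, 0), "tau")
  expect_error(im_prior(0.1, 0.06, k = 0), "k")
  expect_error(im_prior(0.1, 0.06, nu = -1), "nu")
})
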