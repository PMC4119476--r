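# Marginal likelihoods and posterior hypothesis probabilities.

theta0 <- 0.1
hyps <- bht_hypotheses(2, theta0, tau1 = 0.06, tau2 = 0.015)
models <- bma_models(2, tau2 = 0.015)

test_that("binomial likelihood and point-null marginal", {
  expect_equal(binom_lik(dose_data(c(0, 0), c(1, 1)), c(0.1, 0.1)), 0.81)
  expect_equal(binom_lik(dose_data(c(1, 1), c(1, 1)), c(1, 1)), 1)
  expect_equal(binom_lik(dose_data(c(2, 3), c(10, 10)), c(0.1, 0.3)),
               choose(10, 2) * 0.1^2 * 0.9^8 * choose(10, 3) * 0.3^3 * 0.7^7,
               tolerance = 1e-12)
  expect_error(binom_lik(dose_data(c(1, 1), c(2, 2)), c(0.5, 1.2)), "theta")
  expect_equal(marginal_likelihood(dose_data(c(0, 0), c(1, 1)), hyps$H0)$value,
               0.81, tolerance = 1e-12)
})

test_that("M1 closed form equals one-dimensional quadrature", {
  expect_equal(marginal_likelihood(dose_data(c(1, 1), c(2, 2)),
                                   models$M1)$value, 4 / 30,
               tolerance = 1e-12)
  for (x in list(c(0, 0), c(3, 2), c(9, 11))) {
    d <- dose_data(x, c(12, 12))
    closed <- marginal_likelihood(d, models$M1)$value
    oracle <- prod(choose(d$n, d$x)) *
      integrate(function(t) t^sum(d$x) * (1 - t)^(sum(d$n) - sum(d$x)),
                0, 1, rel.tol = 1e-12)$value
    expect_lt(abs(closed - oracle) / oracle, 1e-8)
  }
})

test_that("quadrature and Monte Carlo marginals agree on an (x1, x2) grid", {
  # scaled-down unit check (3x3 states, 2e5 draws); the acceptance suite runs
  # the full 5x5 grid at 1e6 draws
  for (x1 in c(0, 3, 6)) {
    for (x2 in c(0, 3, 6)) {
      d <- dose_data(c(x1, x2), c(12, 12))
      for (h in hyps[c("H1", "H2", "H3")]) {
        q <- marginal_likelihood(d, h)$value
        mc <- marginal_likelihood(d, h, method = "mc", ndraws = 2e5,
                                  seed = 1000 + 10 * x1 + x2)
        expect_lt(abs(q - mc$value), 3 * mc$mc_se + 1e-12)
      }
    }
  }
})

test_that("two-dose ordered-kernel marginal matches importance-sampling MC and the grid oracle", {
  for (x in list(c(2, 5), c(6, 6))) {
    d <- dose_data(x, c(12, 12))
    q <- marginal_likelihood(d, models$M2)$value
    mc <- marginal_likelihood(d, models$M2, method = "mc", ndraws = 5e5,
                              seed = 99)
    expect_lt(abs(q - mc$value), 3 * mc$mc_se)
    orc <- m2_grid_oracle(d$x, d$n, 0.015)$marginal
    expect_lt(abs(q - orc) / orc, 5e-3)
  }
})

test_that("posterior probabilities normalize, reduce to the prior without data, and match brute force", {
  p <- posterior_hyp_probs(dose_data(c(1, 6), c(12, 12)), hyps)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # no data: posterior equals prior
  p0 <- posterior_hyp_probs(dose_data(c(0, 0), c(0, 0)), hyps,
                            prior_probs = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(unname(p0), c(0.4, 0.3, 0.2, 0.1), tolerance = 1e-4)
  # merged H2* against independently computed MC marginals
  d <- dose_data(c(1, 6), c(12, 12))
  p <- posterior_hyp_probs(d, hyps, merge = list("H2*" = c("H2", "H3")))
  m <- vapply(hyps, function(h)
    marginal_likelihood(d, h, method = "mc", ndraws = 1e6, seed = 3)$value,
    numeric(1))
  brute <- c(m[1], m[2], m[3] + m[4]) / sum(m)
  expect_equal(unname(p), unname(brute), tolerance = 0.01)
  # BHT-B priors halve the H2* mass relative to variant A
  pB <- posterior_hyp_probs(d, hyps, prior_probs = c(1, 1, 0.5, 0.5) / 3,
                            merge = list("H2*" = c("H2", "H3")))
  mq <- vapply(hyps, function(h) marginal_likelihood(d, h)$value, numeric(1))
  expect_equal(unname(pB),
               unname(c(mq[1], mq[2], (mq[3] + mq[4]) / 2) /
                        (mq[1] + mq[2] + (mq[3] + mq[4]) / 2)),
               tolerance = 1e-10)
})

test_that("label-swap symmetry holds for dose-symmetric hypotheses", {
  a <- dose_data(c(2, 7), c(10, 14))
  b <- dose_data(c(7, 2), c(14, 10))
  for (h in list(hyps$H0, hyps$H2, models$M1)) {
    expect_equal(marginal_likelihood(a, h)$value,
                 marginal_likelihood(b, h)$value, tolerance = 1e-10)
  }
  # asymmetric hypotheses must notice the swap
  expect_false(isTRUE(all.equal(marginal_likelihood(a, hyps$H1)$value,
                                marginal_likelihood(b, hyps$H1)$value)))
})

test_that("three-dose hypothesis and model families integrate coherently", {
  h3 <- bht_hypotheses(3, theta0, 0.06, 0.015)
  expect_named(h3, paste0("H", 0:7))
  m3 <- bma_models(3, 0.015)
  expect_named(m3, paste0("M", 1:4))
  d <- dose_data(c(1, 3, 5), c(8, 8, 8))
  for (h in c(h3, m3)) {
    q <- marginal_likelihood(d, h, nodes = 48)$value
    mc <- marginal_likelihood(d, h, method = "mc", ndraws = 2e5, seed = 17)
    expect_gte(q, 0)
    expect_lt(abs(q - mc$value), 4 * mc$mc_se + 1e-10)
  }
  p <- posterior_hyp_probs(d, h3, nodes = 48)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("evidence accumulates toward a true null as the trial grows", {
  # nonlocal-prior property: average p(H0 | x) over simulated null paths is
  # non-decreasing in n (150 paths, checkpoints 24/34/44/54)
  set.seed(2024)
  checkpoints <- c(24, 34, 44, 54)
  avg <- matrix(NA_real_, 150, length(checkpoints))
  for (path in 1:150) {
    arm <- rbinom(54, 1, 0.5) + 1
    resp <- rbinom(54, 1, theta0)
    for (ci in seq_along(checkpoints)) {
      idx <- seq_len(checkpoints[ci])
      x <- c(sum(resp[idx][arm[idx] == 1]), sum(resp[idx][arm[idx] == 2]))
      n <- c(sum(arm[idx] == 1), sum(arm[idx] == 2))
      p <- posterior_hyp_probs(dose_data(x, n), hyps)
      avg[path, ci] <- p[["H0"]]
    }
  }
  expect_false(is.unsorted(colMeans(avg)))
})

test_that("the marginal cache is consistent and counts hits", {
  cache_clear()
  d <- dose_data(c(2, 3), c(13, 12))
  v1 <- marginal_likelihood(d, hyps$H3)$value
  v2 <- marginal_likelihood(d, hyps$H3)$value
  expect_identical(v1, v2)
  info <- cache_info()
  expect_gte(info$hits[info$cache == "ml"], 1L)
  v3 <- marginal_likelihood(d, hyps$H3, cache = FALSE)$value
  expect_equal(v1, v3, tolerance = 1e-14)
})
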