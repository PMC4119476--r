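# Interim decision rules of the monitoring designs.

test_that("joint BHT interim: burn-in, stopping, split and final analysis", {
  des <- bht_design()
  # below burn-in: always continue
  expect_equal(interim(des, dose_data(c(0, 0), c(12, 11)))$action, "continue")
  # all-zero data at burn-in: H0 dominates and stops
  dec <- interim(des, dose_data(c(0, 0), c(12, 12)))
  expect_equal(dec$action, "stop")
  expect_equal(dec$conclusion, "H0")
  expect_gt(dec$posterior[["H0"]], des$Pa)
  # intermediate data: continue
  expect_equal(interim(des, dose_data(c(2, 2), c(12, 12)))$action, "continue")
  # at the maximum sample size the same thresholds apply, else inconclusive
  dec54 <- interim(des, dose_data(c(5, 5), c(27, 27)))
  expect_equal(dec54$action, "stop")
  expect_true(dec54$conclusion %in% c("H0", "H1", "H2", "H3", "inconclusive"))
  # clear equal response: H2 via the ratio split
  dec2 <- interim(des, dose_data(c(4, 4), c(12, 12)))
  expect_equal(dec2$action, "stop")
  expect_equal(dec2$conclusion, "H2")
  # monotone increase: H2* split can go to H3
  expect_equal(bht_split(des, dose_data(c(4, 11), c(12, 12))), "H3")
})

test_that("H2/H3 split is strict and agrees between integrators", {
  des <- bht_design()
  d <- dose_data(c(8, 8), c(12, 12))
  m2 <- marginal_likelihood(d, des$hyps$H2)$value
  m3 <- marginal_likelihood(d, des$hyps$H3)$value
  m2mc <- marginal_likelihood(d, des$hyps$H2, method = "mc", ndraws = 1e6,
                              seed = 8)$value
  m3mc <- marginal_likelihood(d, des$hyps$H3, method = "mc", ndraws = 1e6,
                              seed = 9)$value
  expect_identical(m2 / m3 > des$Pb, m2mc / m3mc > des$Pb)
})

test_that("posteriors sum to one so at most one stop can fire at Pa > 0.5", {
  des <- bht_design()
  for (x in list(c(0, 0), c(3, 3), c(6, 2), c(9, 9))) {
    post <- maxed:::.bht_posterior(des, dose_data(x, c(13, 14)))
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_lte(sum(post > des$Pa), 1L)
  }
})

test_that("adding a response at the high dose never strengthens H0 on a scanned lattice", {
  des <- bht_design()
  viol <- 0L
  for (x1 in 0:6) {
    for (x2 in 0:6) {
      p <- maxed:::.bht_posterior(des, dose_data(c(x1, x2), c(13, 13)))
      p2 <- maxed:::.bht_posterior(des, dose_data(c(x1, x2 + 1), c(13, 14)))
      if (p2[["H0"]] > p[["H0"]] + 1e-12) viol <- viol + 1L
    }
  }
  expect_equal(viol, 0L)
})

test_that("futility-only variant: stop, close-lower and final claims", {
  des <- bht_futility_design()
  # below burn-in: continue
  expect_equal(interim(des, dose_data(c(0, 0), c(11, 11)))$action, "continue")
  # null data: terminate for futility with H0
  dec <- interim(des, dose_data(c(0, 0), c(14, 14)))
  expect_equal(dec$action, "stop")
  expect_equal(dec$conclusion, "H0")
  # lower null / higher active: close the lower arm, trial continues
  dec2 <- interim(des, dose_data(c(0, 10), c(14, 14)))
  expect_equal(dec2$action, "close_lower")
  # once closed, the same data no longer triggers closure
  dec3 <- interim(des, dose_data(c(0, 10), c(14, 14)), lower_closed = TRUE)
  expect_equal(dec3$action, "continue")
  # final analysis claims the hypothesis above 0.5, H2* split at 1.37
  fin <- interim(des, dose_data(c(18, 19), c(45, 45)), final = TRUE)
  expect_equal(fin$action, "stop")
  expect_true(fin$conclusion %in% c("H2", "H3"))
  # flat posteriors at the end: inconclusive
  finx <- interim(des, dose_data(c(4, 8), c(45, 45)), final = TRUE)
  expect_true(finx$conclusion %in%
                c("H0", "H1", "H2", "H3", "inconclusive"))
})

test_that("BMA interim follows the printed decision rules", {
  des <- bma_design()
  # no data: model posteriors are the equal priors
  expect_equal(unname(bma_model_posteriors(dose_data(c(0, 0), c(0, 0)), des)),
               c(0.5, 0.5), tolerance = 1e-12)
  # equal strong rates favor the equality model
  pm <- bma_model_posteriors(dose_data(c(6, 6), c(12, 12)), des)
  expect_gt(pm[["M1"]], pm[["M2"]])
  # the ordered prior is asymmetric in the arms
  p29 <- bma_model_posteriors(dose_data(c(2, 9), c(12, 12)), des)[["M2"]]
  p92 <- bma_model_posteriors(dose_data(c(9, 2), c(12, 12)), des)[["M2"]]
  expect_gt(p29, p92)
  # extreme data drive the tails to their limits
  t_all <- bma_tail_probs(dose_data(c(12, 12), c(12, 12)), des)
  expect_gt(t_all[["p1"]], 0.99)
  t_none <- bma_tail_probs(dose_data(c(0, 0), c(12, 12)), des)
  expect_gt(t_none[["p3"]], 0.95)
  expect_lt(t_none[["p1"]], 0.01)
  # decision rules
  expect_equal(interim(des, dose_data(c(9, 9), c(12, 12)))$conclusion, "H2")
  expect_equal(interim(des, dose_data(c(0, 0), c(12, 12)))$conclusion, "H0")
  expect_equal(interim(des, dose_data(c(0, 8), c(12, 12)))$conclusion, "H1")
  expect_equal(interim(des, dose_data(c(2, 3), c(12, 12)))$action, "continue")
})

test_that("BMA tails are disjoint and collapse to single-model values against the grid oracle", {
  des <- bma_design()
  for (x in list(c(2, 5), c(0, 0), c(5, 9))) {
    d <- dose_data(x, c(12, 12))
    p <- bma_tail_probs(d, des)
    expect_lte(sum(p), 1 + 1e-9)
    expect_true(all(p >= 0 & p <= 1))
    # M2-only values against the independent midpoint-grid oracle
    orc <- m2_grid_oracle(d$x, d$n, des$tau2, m = 2000)
    lo <- des$theta0 + des$delta; hi <- des$theta_star - des$delta
    key <- maxed:::.key_num("bmatail", des$tau2, des$grid_n, lo, hi,
                            maxed:::.key_num(d$x), maxed:::.key_num(d$n))
    tails <- maxed:::.cache_env("bmatail")$store[[key]]
    expect_close(tails["M2", "p1"],
                 orc$post_region(function(t) t > hi, function(t) t > hi), 1e-3)
    expect_close(tails["M2", "p3"],
                 orc$post_region(function(t) t < lo, function(t) t < lo), 1e-3)
    # M1-only values are exact beta tails
    a <- sum(d$x) + 1; b <- sum(d$n) - sum(d$x) + 1
    expect_equal(unname(tails["M1", "p1"]),
                 pbeta(hi, a, b, lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("independent BHT arms decide independently and combine as printed", {
  des <- indep_bht_design()
  # arm decisions do not depend on the other arm's data
  d_a <- dose_data(c(0, 3), c(12, 12))
  d_b <- dose_data(c(0, 9), c(12, 12))
  pa <- maxed:::.arm_h1_posterior(des, 0, 12)
  expect_identical(interim(des, d_a)$status[1], interim(des, d_b)$status[1])
  expect_gt(1 - pa, des$Pa_star)  # null arm is futile
  # both futile -> H0
  expect_equal(interim(des, dose_data(c(0, 0), c(12, 12)))$conclusion, "H0")
  # low futile, high effective -> H1
  expect_equal(interim(des, dose_data(c(0, 8), c(12, 12)))$conclusion, "H1")
  # low effective, high futile -> inconclusive
  expect_equal(interim(des, dose_data(c(8, 0), c(12, 12)))$conclusion,
               "inconclusive")
  # below per-arm burn-in nothing resolves
  expect_equal(interim(des, dose_data(c(0, 0), c(11, 11)))$action, "continue")
})

test_that("independent split probability agrees between grid quadrature and MC", {
  for (sp in c("nonlocal", "flat")) {
    des <- indep_bht_design(split_prior = sp)
    d <- dose_data(c(4, 8), c(14, 14))
    qd <- maxed:::.indep_diff_prob(des, d)
    mc <- maxed:::.with_seed(31, {
      draw <- function(x, n, m) {
        if (sp == "flat") return(rbeta(m, x + 1, n - x + 1))
        # posterior under the restricted inverse-moment prior by
        # sampling-importance-resampling from the prior
        th <- rrimom(m * 20, im_prior(des$theta0, des$tau1))
        w <- dbinom(x, n, th)
        sample(th, m, replace = TRUE, prob = w)
      }
      m <- 2e5
      mean(draw(d$x[2], d$n[2], m) - draw(d$x[1], d$n[1], m) > des$diff)
    })
    expect_lt(abs(qd - mc), 5e-3)
  }
})

test_that("BIT interim matches its extreme-data behavior and MC oracle", {
  des <- bit_design()
  # saturated data: immediate H2* stop with ordered draws untouched
  p <- bit_tail_probs(dose_data(c(12, 12), c(12, 12)), des, seed = 3)
  expect_gt(p[["p1"]], 0.99)
  dec <- interim(des, dose_data(c(12, 12), c(12, 12)), seed = 3)
  expect_equal(dec$action, "stop")
  expect_true(dec$conclusion %in% c("H2", "H3"))
  # null data: the H0 path, checked against a large-draw oracle
  p0 <- bit_tail_probs(dose_data(c(0, 0), c(12, 12)),
                       bit_design(ndraws = 1e5), seed = 4)
  expect_gt(p0[["p2"]] + p0[["p3"]], des$Pi)
  expect_lte(p0[["p2"]] - p0[["p3"]], des$Pj)
  expect_equal(interim(des, dose_data(c(0, 0), c(12, 12)), seed = 4)$conclusion,
               "H0")
  # clearly ordered rates leave few pooled draws
  ps <- bit_tail_probs(dose_data(c(1, 11), c(12, 12)), des, seed = 5)
  expect_lt(ps[["eq"]], 0.05)
})
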