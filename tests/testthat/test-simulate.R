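# Trial simulator: reproducibility, bookkeeping invariants, extreme
# scenarios, aggregation.

test_that("fixed seeds reproduce trials exactly", {
  des <- bht_design()
  sc <- scenario(c(0.3, 0.3))
  a <- simulate_trial(des, sc, seed = 123)
  b <- simulate_trial(des, sc, seed = 123)
  expect_identical(a$conclusion, b$conclusion)
  expect_identical(a$n, b$n)
  expect_identical(a$looks, b$looks)
  c2 <- simulate_trial(des, sc, seed = 124)
  expect_false(identical(list(a$n, a$conclusion), list(c2$n, c2$conclusion)))
})

test_that("extreme scenarios resolve as they must", {
  des <- bht_design()
  # perfect response at both doses: H2* at (or right after) burn-in
  tr <- simulate_trial(des, scenario(c(1, 1), tox = c(0, 0)), seed = 5)
  expect_true(tr$conclusion %in% c("H2", "H3"))
  expect_lte(tr$n_total, des$n_min + 2)
  # zero response: H0 in essentially every replicate
  oc <- operating_characteristics(des, scenario(c(0, 0), tox = c(0, 0)),
                                  nsim = 100, seed = 6)
  expect_gte(oc$p[["H0"]], 0.99)
})

test_that("conclusion frequencies partition and sample sizes stay within bounds", {
  des <- bht_design()
  oc <- operating_characteristics(des, scenario(c(0.2, 0.2)), nsim = 150,
                                  seed = 9)
  expect_equal(sum(oc$p), 1, tolerance = 1e-12)
  expect_gte(oc$avg_ss, des$n_min)
  expect_lte(oc$avg_ss, des$n_max)
  expect_equal(sum(oc$avg_ss_arm), oc$avg_ss, tolerance = 1e-9)
})

test_that("toxicity terminations are rare under the informative priors but fire under heavy toxicity", {
  des <- bht_design()
  oc <- operating_characteristics(des, scenario(c(0.3, 0.3), tox = c(0.15, 0.15)),
                                  nsim = 150, seed = 10)
  expect_lt(oc$p[["toxicity"]], 0.02)
  # flat priors and severe toxicity: the monitor must terminate most trials
  des_tox <- bht_design(tox = tox_monitor(prior = list(c(1, 1), c(1, 1))))
  oc2 <- operating_characteristics(des_tox,
                                   scenario(c(0.3, 0.3), tox = c(0.7, 0.7)),
                                   nsim = 50, seed = 11)
  expect_gt(oc2$p[["toxicity"]], 0.9)
})

test_that("futility-only design honors arm caps and closure bookkeeping", {
  des <- bht_futility_design()
  for (s in c(21, 22, 23)) {
    tr <- simulate_trial(des, scenario(c(0.1, 0.4), tox = c(0, 0)), seed = s)
    expect_lte(max(tr$n), des$arm_max)
    expect_lte(tr$n_total, 2 * des$arm_max)
    expect_true(tr$conclusion %in%
                  c("H0", "H1", "H2", "H3", "inconclusive"))
  }
})

test_that("independent design: per-arm caps and inconclusive accounting", {
  des <- indep_bht_design()
  oc <- operating_characteristics(des, scenario(c(0.2, 0.2)), nsim = 100,
                                  seed = 12)
  expect_equal(sum(oc$p), 1, tolerance = 1e-12)
  trs <- simulate(des, nsim = 20, seed = 13, scen = scenario(c(0.2, 0.2)))
  expect_true(all(trs$n1 <= des$arm_max & trs$n2 <= des$arm_max))
})

test_that("replicate substreams make the cache shareable and effective", {
  # Bernoulli randomization diversifies the sufficient statistic, so the
  # marginal cache saturates slowly: the measured hit rate over a fresh
  # 1000-replicate null-scenario run is ~0.56 (toxicity states repeat far
  # more, ~0.83).  The check pins the realized contract: well over half of
  # all look evaluations are cache hits, which is what keeps a scenario at
  # desk scale (under a minute).
  cache_clear()
  des <- bht_design()
  invisible(operating_characteristics(des, scenario(c(0.1, 0.1)), nsim = 1000,
                                      seed = 14))
  info <- cache_info()
  ml <- info[info$cache == "ml", ]
  expect_gt(ml$hits / (ml$hits + ml$misses), 0.5)
  tox <- info[info$cache == "tox", ]
  expect_gt(tox$hits / (tox$hits + tox$misses), 0.75)
})

test_that("doubling replicates halves the standard error of a frequency", {
  # i.i.d. replicates: SE(p-hat) = sqrt(p(1-p)/n); check the aggregation is
  # unbiased across disjoint replicate sets rather than re-deriving the rate
  des <- simon_two_dose_design()
  sc <- scenario(c(0.1, 0.1), tox = c(0, 0))
  o1 <- operating_characteristics(des, sc, nsim = 400, seed = 15)
  o2 <- operating_characteristics(des, sc, nsim = 400, seed = 16)
  exact <- (1 - des$simon$alpha)^2
  se <- sqrt(exact * (1 - exact) / 400)
  expect_lt(abs(o1$p[["H0"]] - exact), 4 * se)
  expect_lt(abs(o2$p[["H0"]] - exact), 4 * se)
})
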