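# Benchmark designs: independent per-arm Bayesian hypothesis tests with a
# nonlocal alternative prior, and the Bayesian isotonic regression
# transformation (BIT) efficacy design.

#' Independent per-arm BHT design
#'
#' Each dose runs its own single-arm Bayesian hypothesis test of
#' `H0i: theta_i = theta0` against `H1i: theta_i ~ pi_rI(theta_i; theta0,
#' tau1)` with equal prior probabilities.  An arm is terminated for efficacy
#' when `p(H1i|x) > Pa_star` and for futility when `p(H0i|x) > Pa_star`,
#' monitoring continuously after a per-arm burn-in.  Trial conclusions
#' combine the arm outcomes: both futile is H0, lower futile with higher
#' effective is H1, both effective is H2* (split to H2 when
#' `P(theta2 - theta1 > diff | x) <= Pd` under the independent posteriors),
#' and lower effective with higher futile -- or any arm unresolved at its
#' cap -- is inconclusive.
#'
#' @inheritParams bht_design
#' @param Pa_star Per-arm posterior stopping threshold (> 0.5).
#' @param Pd Threshold on the posterior probability of a between-dose
#'   difference larger than `diff` (H2 iff it is `<= Pd`).
#' @param diff Between-dose difference of interest.
#' @param arm_min Per-arm burn-in.
#' @param arm_max Per-arm maximum sample size.
#' @param split_prior Posterior used for the H2/H3 split probability:
#'   the nonlocal `H1i` posteriors (default, as in the arm-level tests) or
#'   flat `Beta(x+1, n-x+1)` posteriors.
#' @return An object of class `c("indep_bht_design", "med_design")`.
#' @export
indep_bht_design <- function(theta0 = 0.1, theta_star = 0.3, tau1 = 0.06,
                             Pa_star = 0.7, Pd = 0.11, diff = 0.1,
                             arm_min = 12, arm_max = 27, cadence = 1,
                             tox = tox_monitor(),
                             split_prior = c("nonlocal", "flat"),
                             nodes = 128) {
  if (Pa_star <= 0.5) stop("`Pa_star` must exceed 0.5")
  split_prior <- match.arg(split_prior)
  arm_hyps <- list(
    H0i = .new_hypothesis("H0i", theta0, list(.block(1L, "point"))),
    H1i = .new_hypothesis("H1i", theta0, list(.block(1L, "rim", 0L, tau1))))
  structure(list(
    name = "indep-bht",
    theta0 = theta0, theta_star = theta_star, tau1 = tau1,
    Pa_star = Pa_star, Pd = Pd, diff = diff, arm_min = arm_min,
    arm_max = arm_max, n_max = 2L * arm_max, cadence = cadence, tox = tox,
    tox_independent = TRUE, split_prior = split_prior, nodes = nodes,
    arm_hyps = arm_hyps),
    class = c("indep_bht_design", "med_design"))
}

#' @export
print.indep_bht_design <- function(x, ...) {
  cat("Independent per-arm BHT design\n")
  cat(sprintf("  theta0 = %.3g, tau1 = %.4g; arm stop when posterior > %.3g\n",
              x$theta0, x$tau1, x$Pa_star))
  cat(sprintf("  H2 iff P(theta2 - theta1 > %.3g | x) <= %.3g (%s posteriors)\n",
              x$diff, x$Pd, x$split_prior))
  cat(sprintf("  per-arm burn-in %d, cap %d\n", x$arm_min, x$arm_max))
  invisible(x)
}

# Posterior P(H1i | x) for one arm (equal prior odds), cached via the
# marginal machinery.
.arm_h1_posterior <- function(design, x, n) {
  d1 <- dose_data(x, n)
  m0 <- marginal_likelihood(d1, design$arm_hyps$H0i, nodes = design$nodes)$value
  m1 <- marginal_likelihood(d1, design$arm_hyps$H1i, nodes = design$nodes)$value
  m1 / (m0 + m1)
}

# P(theta2 - theta1 > diff | x) under independent per-arm posteriors,
# deterministic product quadrature.
.indep_diff_prob <- function(design, data) {
  nodes <- design$nodes
  post_nodes <- function(x, n) {
    if (design$split_prior == "nonlocal") {
      pr <- im_prior(design$theta0, design$tau1)
      peak <- design$theta0 + sqrt(2 * design$tau1 / 3)
      g <- .gl_split(design$theta0, 1, peak, nodes)
      f <- drimom(g$x, pr) * stats::dbinom(x, n, g$x)
    } else {
      g <- .gl_interval(0, 1, nodes)
      f <- stats::dbinom(x, n, g$x)
    }
    list(t = g$x, w = g$w * f / sum(g$w * f))
  }
  g1 <- post_nodes(data$x[1], data$n[1])
  g2 <- post_nodes(data$x[2], data$n[2])
  ind <- outer(g1$t, g2$t, function(a, b) b - a > design$diff)
  as.numeric(crossprod(g1$w, ind %*% g2$w))
}

#' @rdname interim
#' @export
interim.indep_bht_design <- function(design, data,
                                     status = c("open", "open"), ...) {
  p1 <- rep(NA_real_, 2)
  for (i in 1:2) {
    if (status[i] != "open") next
    if (data$n[i] < design$arm_min) next
    p1[i] <- .arm_h1_posterior(design, data$x[i], data$n[i])
    if (p1[i] > design$Pa_star) status[i] <- "effective"
    else if (1 - p1[i] > design$Pa_star) status[i] <- "futile"
    else if (data$n[i] >= design$arm_max) status[i] <- "capped"
  }
  post <- c(pH1_low = p1[1], pH1_high = p1[2])
  if (any(status == "open"))
    return(.decision("continue", posterior = post, extra = list(status = status)))
  concl <- if (any(status == "capped")) {
    "inconclusive"
  } else if (status[1] == "futile" && status[2] == "futile") {
    "H0"
  } else if (status[1] == "futile" && status[2] == "effective") {
    "H1"
  } else if (status[1] == "effective" && status[2] == "futile") {
    "inconclusive"
  } else {
    if (.indep_diff_prob(design, data) <= design$Pd) "H2" else "H3"
  }
  .decision("stop", concl, post, extra = list(status = status))
}

#' Bayesian isotonic transformation (BIT) design
#'
#' Uniform(0,1) priors give independent beta posteriors per dose; each joint
#' posterior draw is projected onto the ordered cone by precision-weighted
#' isotonic regression, and the three tail probabilities `p1`, `p2`, `p3`
#' (defined as in [bma_design()]) are computed from the projected draws.
#' The trial stops when `p1 > Ph` (conclude H2*; H2 iff the posterior mass
#' pooled to equality by the projection is at least the mass with
#' `theta1 < theta2`) or when `p2 + p3 > Pi` (H0 iff `p2 - p3 <= Pj`, else
#' H1); inconclusive at `n_max` otherwise.
#'
#' @inheritParams bma_design
#' @param Ph Stopping threshold on `p1`.
#' @param Pi_ Stopping threshold on `p2 + p3` (trailing underscore avoids
#'   masking `base::pi`).
#' @param Pj Cutoff on `p2 - p3` separating H0 from H1.
#' @param ndraws Posterior draws per evaluation.
#' @return An object of class `c("bit_design", "med_design")`.
#' @export
bit_design <- function(theta0 = 0.1, theta_star = 0.3, delta = 0.1,
                       Ph = 0.65, Pi_ = 0.65, Pj = 0.4, n_min = 24,
                       n_max = 54, cadence = 1, tox = tox_monitor(),
                       ndraws = 10000) {
  structure(list(
    name = "bit",
    theta0 = theta0, theta_star = theta_star, delta = delta,
    Ph = Ph, Pi = Pi_, Pj = Pj, n_min = n_min, n_max = n_max,
    cadence = cadence, tox = tox, ndraws = as.integer(ndraws)),
    class = c("bit_design", "med_design"))
}

#' @export
print.bit_design <- function(x, ...) {
  cat("Bayesian isotonic transformation design\n")
  cat(sprintf("  stop when p1 > %.3g or p2 + p3 > %.3g; H0 iff p2 - p3 <= %.3g\n",
              x$Ph, x$Pi, x$Pj))
  cat(sprintf("  burn-in %d, maximum %d patients, %d draws per look\n",
              x$n_min, x$n_max, x$ndraws))
  invisible(x)
}

#' Projected tail probabilities of the BIT design
#'
#' @param data A [dose_data()] object.
#' @param design A [bit_design()] object.
#' @param seed Optional seed (local RNG stream); when given, the result is
#'   memoised by sufficient statistic and seed.
#' @return Vector `c(p1, p2, p3, eq)` where `eq` is the posterior
#'   probability of exact equality, i.e. the fraction of projected draws in
#'   which the projection pooled the two doses.
#' @export
bit_tail_probs <- function(data, design, seed = NULL) {
  stopifnot(inherits(design, "bit_design"))
  lo <- design$theta0 + design$delta
  hi <- design$theta_star - design$delta
  compute <- function() {
    a <- data$x + 1
    b <- data$n - data$x + 1
    prec <- (a + b)^2 * (a + b + 1) / (a * b)
    run <- function() {
      d1 <- stats::rbeta(design$ndraws, a[1], b[1])
      d2 <- stats::rbeta(design$ndraws, a[2], b[2])
      pr <- .pava2(d1, d2, prec[1], prec[2])
      c(p1 = mean(pr$p1 > hi & pr$p2 > hi),
        p2 = mean(pr$p1 < lo & pr$p2 > hi),
        p3 = mean(pr$p1 < lo & pr$p2 < lo),
        eq = mean(pr$violated))
    }
    if (!is.null(seed)) .with_seed(seed, run()) else run()
  }
  if (is.null(seed)) return(compute())
  key <- .key_num("bit", design$delta, design$ndraws, lo, hi, seed,
                  .key_num(data$x), .key_num(data$n))
  .cache_get(.cache_env("bittail"), key, compute)
}

#' @rdname interim
#' @export
interim.bit_design <- function(design, data, seed = NULL, final = FALSE, ...) {
  n_tot <- sum(data$n)
  if (n_tot < design$n_min) return(.decision("continue"))
  p <- bit_tail_probs(data, design, seed = seed)
  if (p[["p1"]] > design$Ph) {
    concl <- if (p[["eq"]] >= 1 - p[["eq"]]) "H2" else "H3"
    return(.decision("stop", concl, p))
  }
  if (p[["p2"]] + p[["p3"]] > design$Pi) {
    concl <- if (p[["p2"]] - p[["p3"]] <= design$Pj) "H0" else "H1"
    return(.decision("stop", concl, p))
  }
  if (n_tot >= design$n_max || final)
    return(.decision("stop", "inconclusive", p))
  .decision("continue", posterior = p)
}
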