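# Marginal likelihoods under the hypothesis / model specifications, and
# posterior hypothesis probabilities.
#
# The default integrator is deterministic: nested Gauss-Legendre quadrature
# with the node set split at the inverse-moment prior mode (the integrand's
# only sharp feature), 128 nodes per dimension.  Monte Carlo integration --
# the estimator the design was originally described with -- is kept as a
# verification mode.  Values are memoised by sufficient statistic because
# continuous monitoring across simulated trials revisits a small lattice of
# data states.

# --- ordered-pair prior grid for the two-dose strictly ordered model -------

# Fixed product grid over the triangle 0 < theta1 < theta2 < 1 with
# trapezoid weights; the prior kernel ((d)^2)^(-3/2) exp(-(d^2/tau)^(-1)),
# d = theta2 - theta1, is normalized globally over the triangle.
.m2_grid <- function(tau, m) {
  cache <- .cache_env("m2grid")
  .cache_get(cache, .key_num(tau, m), function() {
    t <- seq(0, 1, length.out = m)
    h <- 1 / (m - 1)
    w <- rep(h, m); w[c(1L, m)] <- h / 2
    d <- outer(t, t, function(a, b) b - a)   # d[i, j] = t_j - t_i
    K <- matrix(0, m, m)
    pos <- d > 0
    K[pos] <- exp(-3 * log(d[pos]) - tau / d[pos]^2)
    S <- as.numeric(crossprod(w, K %*% w))
    list(t = t, w = w, K = K, S = S)
  })
}

# Posterior-weighted sums over the ordered grid.  `a`, `b` are the per-dose
# likelihood factors on the grid; masks select sub-regions.  Returns the
# unnormalized integral (divide by the full-region value for posterior
# probabilities, by grid$S for the marginal likelihood).
.m2_region <- function(grid, a, b, mask1 = NULL, mask2 = NULL) {
  wa <- grid$w * a
  wb <- grid$w * b
  if (!is.null(mask1)) wa <- wa * mask1
  if (!is.null(mask2)) wb <- wb * mask2
  as.numeric(crossprod(wa, grid$K %*% wb))
}

# --- quadrature over block specifications ----------------------------------

.marg_quad_blocks <- function(data, hyp, nodes) {
  blocks <- hyp$blocks
  theta0 <- hyp$theta0
  x <- data$x; n <- data$n
  blik <- function(b, th) {
    lik <- rep(1, length(th))
    for (d in b$doses) lik <- lik * stats::dbinom(x[d], n[d], th)
    lik
  }
  nb <- length(blocks)
  rec <- function(bi, anchors) {
    b <- blocks[[bi]]
    if (b$type == "point") {
      contrib <- blik(b, theta0)
      if (bi == nb) return(contrib)
      return(contrib * rec(bi + 1L, c(anchors, theta0)))
    }
    if (b$type == "unif") {
      g <- .gl_interval(0, 1, nodes)
      dens <- rep(1, nodes)
    } else {
      anc <- if (b$anchor == 0L) theta0 else anchors[b$anchor]
      pr <- im_prior(anc, b$tau)
      peak <- anc + (2 * pr$k / (pr$nu + 1))^(1 / (2 * pr$k)) * sqrt(b$tau)
      g <- .gl_split(anc, 1, peak, nodes)
      dens <- drimom(g$x, pr)
    }
    f <- dens * blik(b, g$x)
    if (bi == nb) return(sum(g$w * f))
    inner <- vapply(seq_along(g$x),
                    function(i) rec(bi + 1L, c(anchors, g$x[i])),
                    numeric(1))
    sum(g$w * f * inner)
  }
  rec(1L, numeric(0))
}

# --- Monte Carlo over block specifications ---------------------------------

.marg_mc_blocks <- function(data, hyp, ndraws) {
  blocks <- hyp$blocks
  theta0 <- hyp$theta0
  vals <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    vals[[bi]] <- switch(b$type,
      point = rep(theta0, ndraws),
      unif = stats::runif(ndraws),
      rim = {
        anc <- if (b$anchor == 0L) rep(theta0, ndraws) else vals[[b$anchor]]
        .rimom_inv(stats::runif(ndraws), anc, b$tau)
      })
  }
  L <- rep(1, ndraws)
  for (bi in seq_along(blocks)) {
    for (d in blocks[[bi]]$doses)
      L <- L * stats::dbinom(data$x[d], data$n[d], vals[[bi]])
  }
  list(value = mean(L), mc_se = stats::sd(L) / sqrt(ndraws))
}

.marg_mc_kernel2d <- function(data, hyp, ndraws) {
  # Importance sampling: draw theta1 ~ U(0,1), theta2 | theta1 from the
  # conditionally normalized restricted prior, and reweight by the dropped
  # restriction mass N(theta1) = exp(-tau (1-theta1)^-2)/2 to target the
  # globally normalized kernel.
  tau <- hyp$tau
  th1 <- stats::runif(ndraws)
  th2 <- .rimom_inv(stats::runif(ndraws), th1, tau)
  N <- 0.5 * exp(-tau * (1 - th1)^-2)
  L <- stats::dbinom(data$x[1], data$n[1], th1) *
    stats::dbinom(data$x[2], data$n[2], th2)
  r <- L * N
  est <- mean(r) / mean(N)
  se <- stats::sd(r - est * N) / (mean(N) * sqrt(ndraws))
  list(value = est, mc_se = se)
}

#' Marginal likelihood of the data under one hypothesis or model
#'
#' Integrates the joint binomial likelihood against the hypothesis's prior
#' over its free dimensions.  Point-null hypotheses are plain likelihood
#' evaluations; the equal-rates uniform model has the closed beta-function
#' form `prod(choose(n, x)) * B(sum(x) + 1, sum(n - x) + 1)`; all other
#' specifications are integrated by nested split Gauss-Legendre quadrature
#' (default) or Monte Carlo.
#'
#' @param data A [dose_data()] object.
#' @param hyp A hypothesis from [bht_hypotheses()] or [bma_models()].
#' @param method `"quadrature"` (deterministic, default) or `"mc"`.
#' @param nodes Quadrature nodes per dimension.
#' @param ndraws Monte Carlo sample size when `method = "mc"`.
#' @param grid_n Grid side length for the two-dose ordered-kernel model.
#' @param cache Memoise deterministic results by sufficient statistic?
#' @param seed Optional seed for `method = "mc"` (evaluated in a local RNG
#'   stream; the caller's stream is untouched).
#' @return A list of class `"marginal_result"` with elements `value`,
#'   `method`, `mc_se` (0 for deterministic methods) and `label`.
#' @export
marginal_likelihood <- function(data, hyp, method = c("quadrature", "mc"),
                                nodes = 128, ndraws = 1e5, grid_n = 2000,
                                cache = TRUE, seed = NULL) {
  stopifnot(inherits(data, "dose_data"), inherits(hyp, "med_hypothesis"))
  method <- match.arg(method)
  if (hyp$n_doses > length(data$n))
    stop("hypothesis refers to more doses than the data contain")
  out <- if (method == "quadrature") {
    compute <- function() {
      v <- switch(hyp$engine,
        beta = prod(choose(data$n, data$x)) *
          beta(sum(data$x) + 1, sum(data$n - data$x) + 1),
        kernel2d = {
          g <- .m2_grid(hyp$tau, grid_n)
          a <- stats::dbinom(data$x[1], data$n[1], g$t)
          b <- stats::dbinom(data$x[2], data$n[2], g$t)
          .m2_region(g, a, b) / g$S
        },
        blocks = .marg_quad_blocks(data, hyp, nodes))
      if (!is.finite(v) || v < 0)
        stop(sprintf("integration failed for %s at x=%s, n=%s", hyp$label,
                     paste(data$x, collapse = ","),
                     paste(data$n, collapse = ",")))
      v
    }
    v <- if (cache) {
      key <- .key_num(hyp$key, .key_num(data$x), .key_num(data$n), nodes, grid_n)
      .cache_get(.cache_env("ml"), key, compute)
    } else compute()
    list(value = v, mc_se = 0)
  } else {
    run <- function() switch(hyp$engine,
      kernel2d = .marg_mc_kernel2d(data, hyp, ndraws),
      .marg_mc_blocks(data, hyp, ndraws))
    if (!is.null(seed)) .with_seed(seed, run()) else run()
  }
  structure(list(value = out$value, method = method, mc_se = out$mc_se,
                 label = hyp$label), class = "marginal_result")
}

#' @export
print.marginal_result <- function(x, ...) {
  cat(sprintf("p(x | %s) = %.6g  [%s%s]\n", x$label, x$value, x$method,
              if (x$mc_se > 0) sprintf(", se %.3g", x$mc_se) else ""))
  invisible(x)
}

#' Posterior hypothesis (or model) probabilities
#'
#' Normalizes prior probability times marginal likelihood over a hypothesis
#' family, optionally merging hypotheses into composite conclusions (e.g.
#' \eqn{H_2^* = H_2 \cup H_3}, "both doses promising").  With equal priors
#' over H0-H3 the merged probability is proportional to
#' `p(x|H2) + p(x|H3)`; with priors (1/3, 1/3, 1/6, 1/6) it is proportional
#' to `(p(x|H2) + p(x|H3)) / 2`.
#'
#' @param data A [dose_data()] object.
#' @param hyps Named list of hypotheses.
#' @param prior_probs Prior probabilities (default equal); must sum to 1.
#' @param merge Optional named list mapping a merged label to the member
#'   hypothesis labels, e.g. `list("H2*" = c("H2", "H3"))`.
#' @param ... Passed to [marginal_likelihood()].
#' @return Named vector of posterior probabilities (summing to 1).
#' @export
posterior_hyp_probs <- function(data, hyps, prior_probs = NULL, merge = NULL,
                                ...) {
  labs <- vapply(hyps, `[[`, character(1), "label")
  names(hyps) <- labs
  if (is.null(prior_probs)) prior_probs <- rep(1 / length(hyps), length(hyps))
  if (length(prior_probs) != length(hyps))
    stop("`prior_probs` must match the number of hypotheses")
  if (abs(sum(prior_probs) - 1) > 1e-8) stop("`prior_probs` must sum to 1")
  m <- vapply(hyps, function(h) marginal_likelihood(data, h, ...)$value,
              numeric(1))
  w <- prior_probs * m
  if (all(w == 0)) stop("all marginal likelihoods are zero")
  post <- w / sum(w)
  names(post) <- labs
  if (!is.null(merge)) {
    for (new in names(merge)) {
      members <- merge[[new]]
      keep <- setdiff(labs, members)
      merged <- c(post[keep], sum(post[members]))
      names(merged) <- c(keep, new)
      post <- merged
      labs <- names(post)
    }
  }
  post
}
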