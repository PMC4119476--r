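# Independent oracles used across the suite.

# Exact weighted isotonic projection by enumeration over contiguous level-set
# partitions (J <= 3): the projection is piecewise constant on contiguous
# blocks with values the weighted block means; enumerate every contiguous
# partition, keep the monotone-feasible fits, take the weighted-SSE minimizer.
pava_oracle <- function(y, w) {
  n <- length(y)
  parts <- list()
  if (n == 1L) parts <- list(list(1L))
  if (n == 2L) parts <- list(list(1L, 2L), list(1:2))
  if (n == 3L) parts <- list(list(1L, 2L, 3L), list(1:2, 3L), list(1L, 2:3),
                             list(1:3))
  best <- NULL; best_sse <- Inf
  for (p in parts) {
    fit <- numeric(n)
    for (blk in p) fit[blk] <- sum(w[blk] * y[blk]) / sum(w[blk])
    if (is.unsorted(fit)) next
    sse <- sum(w * (fit - y)^2)
    if (sse < best_sse) { best <- fit; best_sse <- sse }
  }
  best
}

# Brute-force posterior on an independent midpoint grid for the two-dose
# ordered model: joint prior kernel ((d)^2)^(-3/2) exp(-tau/d^2) on the
# triangle, likelihood product of binomials.  Intentionally a different
# construction (midpoint rule, loop-free outer) from the package's
# trapezoid grid.
m2_grid_oracle <- function(x, n, tau, m = 1500) {
  t <- (seq_len(m) - 0.5) / m
  d <- outer(t, t, function(a, b) b - a)
  K <- matrix(0, m, m)
  pos <- d > 0
  K[pos] <- d[pos]^(-3) * exp(-tau / d[pos]^2)
  a <- dbinom(x[1], n[1], t)
  b <- dbinom(x[2], n[2], t)
  w <- rep(1 / m, m)
  list(
    marginal = as.numeric(crossprod(w * a, K %*% (w * b))) /
      as.numeric(crossprod(w, K %*% w)),
    post_region = function(mask1, mask2) {
      num <- as.numeric(crossprod(w * a * mask1(t), K %*% (w * b * mask2(t))))
      den <- as.numeric(crossprod(w * a, K %*% (w * b)))
      num / den
    },
    t = t)
}

expect_close <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
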