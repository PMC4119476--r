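# Continuous toxicity monitoring with order-constrained posteriors via the
# Bayesian isotonic regression transformation: independent beta posteriors
# per dose, each joint draw projected onto the non-decreasing cone by
# precision-weighted least-squares isotonic regression (pool-adjacent-
# violators), then compared against the toxicity limit.

#' Toxicity monitoring configuration
#'
#' Per-dose beta priors for the probability of dose-limiting toxicity, the
#' toxicity upper limit and the posterior threshold that declares a dose
#' toxic.  The defaults are the informative priors elicited from a phase I
#' study with no observed toxicities (see [phase1_tox_priors()]): Beta(0.5,
#' 16.5) at the lower and Beta(0.5, 8.5) at the higher dose, limit 0.3,
#' threshold 0.8.
#'
#' @param prior List with one `c(shape1, shape2)` pair per dose, low to high.
#' @param limit Toxicity upper limit \eqn{\bar p}.
#' @param Pc Posterior threshold: dose `i` is toxic when
#'   `P(p_i^* > limit | data) > Pc`.
#' @param ndraws Posterior draws per evaluation.
#' @return An object of class `"tox_monitor"`.
#' @export
tox_monitor <- function(prior = list(c(0.5, 16.5), c(0.5, 8.5)),
                        limit = 0.3, Pc = 0.8, ndraws = 10000) {
  if (!is.list(prior) || !all(vapply(prior, length, integer(1)) == 2L) ||
      any(unlist(prior) <= 0))
    stop("`prior` must be a list of positive c(shape1, shape2) pairs")
  if (limit <= 0 || limit >= 1 || Pc <= 0 || Pc >= 1)
    stop("`limit` and `Pc` must lie in (0, 1)")
  structure(list(prior = prior, limit = limit, Pc = Pc,
                 ndraws = as.integer(ndraws)),
            class = "tox_monitor")
}

#' @export
print.tox_monitor <- function(x, ...) {
  cat(sprintf("Toxicity monitor: limit %.2g, threshold Pc = %.2g, %d draws\n",
              x$limit, x$Pc, x$ndraws))
  for (i in seq_along(x$prior))
    cat(sprintf("  dose %d prior Beta(%.3g, %.3g)\n", i, x$prior[[i]][1],
                x$prior[[i]][2]))
  invisible(x)
}

#' Weighted pool-adjacent-violators
#'
#' Exact weighted least-squares isotonic projection: minimizes
#' \eqn{\sum_i w_i (z_i - y_i)^2} over non-decreasing `z`.  Each fitted value
#' is the weighted mean of a contiguous block of inputs.
#'
#' @param y Numeric vector.
#' @param w Positive weights (default equal).
#' @return Non-decreasing vector of the same length.
#' @examples
#' pava(c(0.3, 0.1))              # c(0.2, 0.2)
#' pava(c(0.3, 0.1), c(3, 1))     # c(0.25, 0.25)
#' @export
pava <- function(y, w = rep(1, length(y))) {
  if (length(w) != length(y)) stop("`y` and `w` must have equal length")
  if (any(w <= 0)) stop("weights must be positive")
  n <- length(y)
  if (n <= 1L) return(y)
  # block representation: value, weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      wsum <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) / wsum
      wt[nb - 1L] <- wsum
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], sz[seq_len(nb)])
}

# Vectorised two-dose projection of draw pairs (rows): pool when violated.
.pava2 <- function(p1, p2, w1, w2) {
  viol <- p1 > p2
  if (any(viol)) {
    pooled <- (w1 * p1[viol] + w2 * p2[viol]) / (w1 + w2)
    p1[viol] <- pooled
    p2[viol] <- pooled
  }
  list(p1 = p1, p2 = p2, violated = viol)
}

#' Posterior probability that each dose exceeds the toxicity limit
#'
#' Draws from the unconstrained independent beta posteriors, projects each
#' joint draw onto the ordered cone by [pava()] with weights equal to the
#' unconstrained posterior precisions (reciprocal beta posterior variances),
#' and reports the per-dose frequency with which the constrained draw
#' exceeds the limit.  A single dose needs no projection and its exceedance
#' probability is the exact beta tail.
#'
#' @param tox Integer vector of toxicity counts per dose.
#' @param n Integer vector of patient counts per dose.
#' @param monitor A [tox_monitor()] object.
#' @param seed Optional seed for the posterior draws (local RNG stream).
#' @return Vector of exceedance probabilities, non-decreasing across doses.
#' @export
tox_exceedance <- function(tox, n, monitor, seed = NULL) {
  stopifnot(inherits(monitor, "tox_monitor"))
  J <- length(n)
  if (length(tox) != J || J > length(monitor$prior))
    stop("`tox`/`n` length must match the monitored doses")
  a <- vapply(seq_len(J), function(i) monitor$prior[[i]][1] + tox[i], numeric(1))
  b <- vapply(seq_len(J), function(i) monitor$prior[[i]][2] + n[i] - tox[i],
              numeric(1))
  if (J == 1L)
    return(stats::pbeta(monitor$limit, a, b, lower.tail = FALSE))
  prec <- (a + b)^2 * (a + b + 1) / (a * b)  # 1 / Var(Beta(a, b))
  run <- function() {
    draws <- lapply(seq_len(J), function(i) stats::rbeta(monitor$ndraws, a[i], b[i]))
    if (J == 2L) {
      pr <- .pava2(draws[[1]], draws[[2]], prec[1], prec[2])
      cons <- cbind(pr$p1, pr$p2)
    } else {
      cons <- t(vapply(seq_len(monitor$ndraws), function(t) {
        pava(vapply(draws, `[[`, numeric(1), t), prec)
      }, numeric(J)))
    }
    colMeans(cons > monitor$limit)
  }
  if (!is.null(seed)) .with_seed(seed, run()) else run()
}

#' Toxicity action rule
#'
#' Terminate the trial if every dose is toxic; close the highest dose arms
#' if only an upper set of doses is toxic; otherwise continue.  Under the
#' order constraint the set of toxic doses is always an upper set (the
#' constrained exceedance probabilities are non-decreasing in dose).
#'
#' @param exceedance Per-dose exceedance probabilities from
#'   [tox_exceedance()].
#' @param monitor A [tox_monitor()] object.
#' @return `"none"`, `"close_high"` or `"terminate"`, with attribute
#'   `"toxic"` giving the logical per-dose toxicity calls.
#' @export
tox_action <- function(exceedance, monitor) {
  stopifnot(inherits(monitor, "tox_monitor"))
  toxic <- exceedance > monitor$Pc
  if (is.unsorted(exceedance))
    stop("constrained exceedance probabilities must be non-decreasing in dose")
  action <- if (all(toxic)) "terminate" else if (any(toxic)) "close_high" else "none"
  structure(action, toxic = toxic)
}

#' Elicit toxicity priors from phase I data with dose-level borrowing
#'
#' Reproduces the informative beta toxicity priors from a phase I escalation
#' with no observed dose-limiting toxicities, borrowing strength downwards:
#' every `exchange[1]` toxicity-free patients at a higher dose level count as
#' `exchange[2]` toxicity-free patients at the next lower level, compounding
#' per level gap; effective patient numbers are rounded to whole patients.
#' With the defaults (four phase I levels, three patients per level, no
#' DLTs, phase II doses equal to the two middle levels, a Beta(0.5, 0.5)
#' base) this yields Beta(0.5, 16.5) and Beta(0.5, 8.5) for the lower and
#' higher phase II dose.
#'
#' @param base Base prior `c(shape1, shape2)` before seeing phase I data.
#' @param n_levels Number of phase I dose levels.
#' @param n_per_level Toxicity-free patients per phase I level.
#' @param phase2_levels Indices of the phase I levels matching the phase II
#'   doses (low, high).
#' @param exchange `c(higher, lower)` patient exchange rate between adjacent
#'   levels.
#' @return List of beta parameter pairs, one per phase II dose.
#' @export
phase1_tox_priors <- function(base = c(0.5, 0.5), n_levels = 4,
                              n_per_level = 3, phase2_levels = c(2, 3),
                              exchange = c(3, 5)) {
  rate <- exchange[2] / exchange[1]
  lapply(phase2_levels, function(lev) {
    higher <- seq_len(n_levels)
    higher <- higher[higher >= lev]
    eff <- sum(round(n_per_level * rate^(higher - lev)))
    c(base[1], base[2] + eff)
  })
}
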