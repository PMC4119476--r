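# The Bayesian model-averaging (BMA) design: posterior probabilities of the
# equal-rates model M1 and the strictly ordered model M2, model-averaged
# tail probabilities p1/p2/p3, and the stopping / conclusion rules.

#' Bayesian model-averaging design
#'
#' Patients are equally randomized between two doses.  Two models are
#' entertained: M1 (`theta1 = theta2`, Uniform(0,1) prior on the common
#' rate) and M2 (`theta1 < theta2`, the joint prior proportional to the
#' inverse-moment kernel in the rate difference on the ordered triangle).
#' After burn-in, three model-averaged posterior probabilities are monitored
#' after every patient:
#' `p1 = P(theta1 > theta_star - delta, theta2 > theta_star - delta | data)`
#' (both doses promising),
#' `p2 = P(theta1 < theta0 + delta, theta2 > theta_star - delta | data)`
#' (only the higher dose promising), and
#' `p3 = P(theta1 < theta0 + delta, theta2 < theta0 + delta | data)`
#' (neither promising).  The trial stops when `p1 > Pe` (conclude H2*, split
#' to H2 iff `p(M1|x)/p(M2|x) > Pg`), when `p2 + p3 > Pf` (conclude H0 iff
#' `p2 - p3 <= Pk`, else H1), or at `n_max` (inconclusive if neither held).
#'
#' @inheritParams bht_design
#' @param delta Margin defining "promising" (`theta > theta_star - delta`)
#'   and "not promising" (`theta < theta0 + delta`).
#' @param Pe Stopping threshold on `p1`.
#' @param Pf Stopping threshold on `p2 + p3`.
#' @param Pg Model-odds cutoff for the H2/H3 split.
#' @param Pk Cutoff on `p2 - p3` separating H0 from H1.
#' @param grid_n Side length of the fixed posterior grid under M2.
#' @return An object of class `c("bma_design", "med_design")`.
#' @export
bma_design <- function(theta0 = 0.1, theta_star = 0.3, tau2 = 0.015,
                       delta = 0.1, Pe = 0.7, Pf = 0.65, Pg = 1.3,
                       Pk = 0.02, n_min = 24, n_max = 54, cadence = 1,
                       tox = tox_monitor(), grid_n = 2000) {
  if (delta <= 0 || delta >= theta_star - theta0)
    stop("`delta` must lie in (0, theta_star - theta0)")
  if (Pe <= 0 || Pe >= 1 || Pf <= 0 || Pf >= 1) stop("`Pe`, `Pf` must lie in (0, 1)")
  if (Pg <= 0) stop("`Pg` must be positive")
  if (Pk <= -1 || Pk >= 1) stop("`Pk` must lie in (-1, 1)")
  structure(list(
    name = "bma",
    theta0 = theta0, theta_star = theta_star, tau2 = tau2, delta = delta,
    Pe = Pe, Pf = Pf, Pg = Pg, Pk = Pk, n_min = n_min, n_max = n_max,
    cadence = cadence, tox = tox, grid_n = grid_n,
    models = bma_models(2, tau2, theta0),
    prior_model_probs = c(M1 = 0.5, M2 = 0.5)),
    class = c("bma_design", "med_design"))
}

#' @export
print.bma_design <- function(x, ...) {
  cat("Bayesian model-averaging design\n")
  cat(sprintf("  theta0 = %.3g, theta* = %.3g, tau2 = %.4g, delta = %.3g\n",
              x$theta0, x$theta_star, x$tau2, x$delta))
  cat(sprintf("  stop when p1 > Pe = %.3g or p2 + p3 > Pf = %.3g\n", x$Pe, x$Pf))
  cat(sprintf("  H2 iff model odds > Pg = %.3g; H0 iff p2 - p3 <= Pk = %.3g\n",
              x$Pg, x$Pk))
  cat(sprintf("  burn-in %d, maximum %d patients\n", x$n_min, x$n_max))
  invisible(x)
}

#' Posterior model probabilities under the BMA design
#'
#' `p(M1|x) : p(M2|x) = p(x|M1) : p(x|M2)` under equal prior model
#' probabilities; `p(x|M1)` has the closed beta-function form, `p(x|M2)` is
#' integrated on the design's fixed ordered grid.
#'
#' @param data A [dose_data()] object.
#' @param design A [bma_design()] object.
#' @return Named vector `c(M1, M2)` summing to 1.
#' @export
bma_model_posteriors <- function(data, design) {
  stopifnot(inherits(design, "bma_design"))
  posterior_hyp_probs(data, design$models, design$prior_model_probs,
                      grid_n = design$grid_n)
}

#' Model-averaged tail probabilities of the BMA design
#'
#' Each event probability is computed under the posterior of each model and
#' averaged with the posterior model probabilities.  Under M1 the events
#' collapse to beta tail probabilities of the common rate; under M2 they are
#' sums over the fixed posterior grid on the ordered triangle.
#'
#' @inheritParams bma_model_posteriors
#' @return Vector `c(p1, p2, p3)` (disjoint events; the sum is at most 1).
#' @export
bma_tail_probs <- function(data, design) {
  stopifnot(inherits(design, "bma_design"), inherits(data, "dose_data"))
  lo <- design$theta0 + design$delta      # "not promising" upper edge
  hi <- design$theta_star - design$delta  # "promising" lower edge
  pm <- bma_model_posteriors(data, design)
  key <- .key_num("bmatail", design$tau2, design$grid_n, lo, hi,
                  .key_num(data$x), .key_num(data$n))
  tails <- .cache_get(.cache_env("bmatail"), key, function() {
    # M1: common rate ~ Beta(x. + 1, n. - x. + 1)
    a <- sum(data$x) + 1
    b <- sum(data$n) - sum(data$x) + 1
    m1 <- c(p1 = stats::pbeta(hi, a, b, lower.tail = FALSE),
            p2 = max(0, stats::pbeta(lo, a, b) - stats::pbeta(hi, a, b)),
            p3 = stats::pbeta(lo, a, b))
    if (lo <= hi) m1["p2"] <- 0  # disjoint margins: impossible under M1
    # M2: posterior on the ordered grid
    g <- .m2_grid(design$tau2, design$grid_n)
    av <- stats::dbinom(data$x[1], data$n[1], g$t)
    bv <- stats::dbinom(data$x[2], data$n[2], g$t)
    z <- .m2_region(g, av, bv)
    m1lo <- g$t < lo; m1hi <- g$t > hi
    m2 <- c(p1 = .m2_region(g, av, bv, m1hi, m1hi) / z,
            p2 = .m2_region(g, av, bv, m1lo, m1hi) / z,
            p3 = .m2_region(g, av, bv, m1lo, m1lo) / z)
    rbind(M1 = m1, M2 = m2)
  })
  drop(pm %*% tails)
}

#' @rdname interim
#' @export
interim.bma_design <- function(design, data, final = FALSE, ...) {
  n_tot <- sum(data$n)
  if (n_tot < design$n_min) return(.decision("continue"))
  p <- bma_tail_probs(data, design)
  post <- c(p, p23 = unname(p[2] + p[3]))
  if (p[1] > design$Pe) {
    pm <- bma_model_posteriors(data, design)
    concl <- if (pm[["M1"]] / pm[["M2"]] > design$Pg) "H2" else "H3"
    return(.decision("stop", concl, post))
  }
  if (p[2] + p[3] > design$Pf) {
    concl <- if (p[2] - p[3] <= design$Pk) "H0" else "H1"
    return(.decision("stop", concl, post))
  }
  if (n_tot >= design$n_max || final)
    return(.decision("stop", "inconclusive", post))
  .decision("continue", posterior = post)
}
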