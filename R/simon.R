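# Simon optimal two-stage design: exact binomial enumeration, per-dose error
# splitting, and the two-dose extension's conclusion rule.

#' Split overall error rates across independent dose arms
#'
#' With `J` independent arms, per-dose levels `1 - (1 - overall)^(1/J)`
#' control the overall type I error at `overall_alpha` when every dose is
#' null and the overall type II error at `overall_beta` when every dose is
#' effective.  For (0.05, 0.2, 2) this gives per-dose errors (0.0253, 0.106).
#'
#' @param overall_alpha Overall type I error bound.
#' @param overall_beta Overall type II error bound.
#' @param J Number of dose arms.
#' @return Named vector `c(alpha, beta)` of per-dose error rates.
#' @export
split_errors <- function(overall_alpha, overall_beta, J = 2) {
  if (J < 2) stop("`J` must be at least 2")
  c(alpha = 1 - (1 - overall_alpha)^(1 / J),
    beta = 1 - (1 - overall_beta)^(1 / J))
}

# P(dose rejected) = P(X1 <= r1) + P(X1 > r1, X1 + X2 <= r), exact.
.simon_reject_prob <- function(n1, r1, n, r, p) {
  pet <- stats::pbinom(r1, n1, p)
  hi <- min(n1, r)
  if (r1 + 1L > hi) return(pet)
  x1 <- seq(r1 + 1L, hi)
  pet + sum(stats::dbinom(x1, n1, p) * stats::pbinom(r - x1, n - n1, p))
}

#' Simon optimal two-stage design
#'
#' Exhaustive search over `(n1, r1, n, r)` with `n <= n_max` for the design
#' minimizing the expected sample size under `p0` subject to exact binomial
#' attained error bounds: reject the dose (conclude it not promising) after
#' stage 1 if at most `r1` responses in `n1` patients, or finally if at most
#' `r` responses in `n`.  Ties in expected sample size are broken by smaller
#' `n`, then smaller `n1`.
#'
#' @param p0 Response rate not of interest (null).
#' @param p1 Target response rate.
#' @param alpha Type I error bound.
#' @param beta Type II error bound.
#' @param n_max Enumeration ceiling for the total sample size.
#' @return An object of class `"simon_design"`: `n1`, `r1`, `n`, `r`,
#'   attained `alpha` and `power`, `PET0` (probability of early termination
#'   under `p0`) and `EN0` (expected sample size under `p0`).
#' @examples
#' simon_optimal(0.1, 0.3, 0.0253, 0.106)   # 17/45
#' @export
simon_optimal <- function(p0, p1, alpha, beta, n_max = 100) {
  if (p0 >= p1) stop("`p0` must be smaller than `p1`")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("error bounds must lie in (0, 1)")
  best <- NULL
  for (n in 2:n_max) {
    for (n1 in 1:(n - 1L)) {
      n2 <- n - n1
      for (r1 in 0:n1) {
        # power can never exceed P(X1 > r1 | p1): prune and stop raising r1
        if (1 - stats::pbinom(r1, n1, p1) < 1 - beta) break
        # smallest r with attained alpha <= bound maximizes power
        lo <- r1; hi <- n
        if (1 - .simon_reject_prob(n1, r1, n, n, p0) > alpha) next
        while (lo < hi) {
          mid <- (lo + hi) %/% 2L
          if (1 - .simon_reject_prob(n1, r1, n, mid, p0) <= alpha) hi <- mid
          else lo <- mid + 1L
        }
        r <- lo
        pow <- 1 - .simon_reject_prob(n1, r1, n, r, p1)
        if (pow < 1 - beta) next
        pet0 <- stats::pbinom(r1, n1, p0)
        en0 <- n1 + (1 - pet0) * n2
        cand <- list(n1 = n1, r1 = r1, n = n, r = r,
                     alpha = 1 - .simon_reject_prob(n1, r1, n, r, p0),
                     power = pow, PET0 = pet0, EN0 = en0,
                     p0 = p0, p1 = p1,
                     alpha_nom = alpha, beta_nom = beta)
        if (is.null(best) || en0 < best$EN0 - 1e-12 ||
            (abs(en0 - best$EN0) <= 1e-12 &&
             (n < best$n || (n == best$n && n1 < best$n1)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best))
    stop(sprintf("no feasible two-stage design with n <= %d", n_max))
  structure(best, class = "simon_design")
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf("Simon optimal two-stage design (p0 = %.3g, p1 = %.3g):\n",
              x$p0, x$p1))
  cat(sprintf("  r1/n1 = %d/%d, r/n = %d/%d\n", x$r1, x$n1, x$r, x$n))
  cat(sprintf("  attained alpha %.4f (<= %.4f), power %.4f (>= %.4f)\n",
              x$alpha, x$alpha_nom, x$power, 1 - x$beta_nom))
  cat(sprintf("  PET(p0) = %.3f, EN(p0) = %.2f\n", x$PET0, x$EN0))
  invisible(x)
}

#' Conclusion rule of the two-dose Simon procedure
#'
#' Combines independent per-arm two-stage results: conclude `H0` if both
#' doses are rejected (neither promising), `H1` if only the lower dose is
#' rejected, inconclusive if only the higher dose is rejected.  If neither
#' is rejected (both promising) conclude `H2` when the observed rates
#' satisfy `RR1 >= RR2 - delta`, else `H3`.
#'
#' @param rejected Logical vector `c(low, high)`: was each dose rejected?
#' @param rr Observed per-dose response proportions `c(RR1, RR2)`.
#' @param delta Equality margin on observed rates.
#' @return One of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"inconclusive"`.
#' @export
simon_two_dose_conclusion <- function(rejected, rr, delta = 0.05) {
  stopifnot(length(rejected) == 2L)
  if (rejected[1] && rejected[2]) return("H0")
  if (rejected[1] && !rejected[2]) return("H1")
  if (!rejected[1] && rejected[2]) return("inconclusive")
  if (rr[1] >= rr[2] - delta) "H2" else "H3"
}

#' Two-dose extension of the Simon optimal two-stage design
#'
#' Applies the Simon optimal two-stage design independently at each of two
#' dose levels, with the overall error rates split across the doses by
#' [split_errors()], and combines the per-arm accept/reject outcomes by
#' [simon_two_dose_conclusion()].
#'
#' @param p0 Null response rate.
#' @param p1 Target response rate.
#' @param alpha Overall type I error when both doses are null.
#' @param beta Overall type II error when both doses are effective.
#' @param delta Equality margin on the observed rates for the H2/H3 split
#'   (0.05 for the primary analysis; 0.03 and 0.07 as sensitivity variants).
#' @param n_max Enumeration ceiling passed to [simon_optimal()].
#' @return An object of class `c("simon2_design", "med_design")` carrying
#'   the per-arm `simon_design` in `$simon`.
#' @export
simon_two_dose_design <- function(p0 = 0.1, p1 = 0.3, alpha = 0.05,
                                  beta = 0.2, delta = 0.05, n_max = 100) {
  per <- split_errors(alpha, beta, 2)
  # per-dose errors at the printed precision: 0.0253 and 0.106 for (0.05, 0.2)
  per_alpha <- round(per[["alpha"]], 4)
  per_beta <- round(per[["beta"]], 3)
  sd1 <- simon_optimal(p0, p1, per_alpha, per_beta, n_max = n_max)
  name <- switch(as.character(delta), "0.05" = "simon-i", "0.03" = "simon-ii",
                 "0.07" = "simon-iii", "simon")
  structure(list(name = name, p0 = p0, p1 = p1, alpha = alpha, beta = beta,
                 per_dose_alpha = per_alpha, per_dose_beta = per_beta,
                 delta = delta, simon = sd1, n_max = 2L * sd1$n, tox = NULL),
            class = c("simon2_design", "med_design"))
}

#' @export
print.simon2_design <- function(x, ...) {
  cat(sprintf("Independent two-dose Simon design (delta = %.2f)\n", x$delta))
  cat(sprintf("  overall alpha %.3g -> per dose %.4g; overall beta %.3g -> per dose %.4g\n",
              x$alpha, x$per_dose_alpha, x$beta, x$per_dose_beta))
  print(x$simon)
  invisible(x)
}
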