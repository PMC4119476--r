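# The joint Bayesian hypothesis-testing (BHT) design: continuous monitoring
# of posterior hypothesis probabilities over {H0, H1, H2* = H2 u H3}, the
# H2/H3 split on the marginal-likelihood ratio, and the futility-only
# variant used for comparison against the Simon two-stage procedure.

#' Interim decision for a design given current data
#'
#' Applies a design's monitoring rule to the current per-dose counts and
#' returns an interim decision: continue, stop with a conclusion, or (for
#' designs with arm-closure rules) a closure action.  Methods exist for all
#' design classes in the package.
#'
#' @param design A design object (e.g. [bht_design()], [bma_design()]).
#' @param data A [dose_data()] object.
#' @param ... Method-specific arguments (e.g. `final = TRUE` to force the
#'   end-of-trial analysis, or state flags such as `lower_closed`).
#' @return An object of class `"interim_decision"`: list with `action`
#'   (`"continue"`, `"stop"`, or a closure action), `conclusion` (`"none"`
#'   while the trial continues) and a `posterior` snapshot.
#' @export
interim <- function(design, data, ...) UseMethod("interim")

.decision <- function(action, conclusion = "none", posterior = NULL,
                      extra = NULL) {
  structure(c(list(action = action, conclusion = conclusion,
                   posterior = posterior), extra),
            class = "interim_decision")
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("action: %s", x$action))
  if (x$conclusion != "none") cat(sprintf("  conclusion: %s", x$conclusion))
  cat("\n")
  if (!is.null(x$posterior)) {
    cat("posterior probabilities:\n")
    print(round(x$posterior, 4))
  }
  invisible(x)
}

#' Joint Bayesian hypothesis-testing design
#'
#' The proposed MaxED design: patients are equally randomized between two
#' doses; once `n_min` total outcomes are observed the posterior
#' probabilities of H0 (neither dose promising), H1 (only the higher dose
#' promising) and H2* (both promising) are updated after every patient, and
#' the trial stops as soon as one exceeds `Pa` or the maximum sample size
#' `n_max` is reached.  A stop on H2* is refined to H2 (equal rates) when
#' `p(x|H2)/p(x|H3) > Pb`, else H3.  Variant `"A"` puts prior probability
#' 1/4 on each of H0-H3; variant `"B"` puts 1/3 on each of H0, H1, H2* (so
#' 1/6 on H2 and H3).
#'
#' @param theta0 Null response rate.
#' @param theta_star Target response rate (prior mode of the promising-rate
#'   prior; together with `theta0` it fixes `tau1`'s calibration).
#' @param tau1,tau2 Inverse-moment prior scales (defaults put the prior
#'   modes at `theta0 + 0.2` and at a between-dose difference of 0.1).
#' @param variant `"A"` or `"B"` (prior hypothesis probabilities), ignored
#'   when `prior_probs` is given.
#' @param prior_probs Optional explicit prior probabilities over H0-H3.
#' @param Pa Posterior stopping threshold (> 0.5).
#' @param Pb Marginal-ratio threshold for the H2/H3 split.
#' @param n_min Total burn-in before efficacy monitoring starts.
#' @param n_max Maximum total sample size.
#' @param cadence Monitor after every `cadence` patients once past burn-in
#'   (1 = after each patient, as in the motivating trial).
#' @param tox A [tox_monitor()] object, or `NULL` to disable toxicity
#'   monitoring.
#' @param nodes Quadrature nodes per dimension for marginal likelihoods.
#' @return An object of class `c("bht_design", "med_design")`.
#' @export
bht_design <- function(theta0 = 0.1, theta_star = 0.3, tau1 = 0.06,
                       tau2 = 0.015, variant = c("A", "B"),
                       prior_probs = NULL, Pa = 0.65, Pb = 1.2,
                       n_min = 24, n_max = 54, cadence = 1,
                       tox = tox_monitor(), nodes = 128) {
  variant <- match.arg(variant)
  if (is.null(prior_probs)) {
    prior_probs <- if (variant == "A") rep(1 / 4, 4) else c(1/3, 1/3, 1/6, 1/6)
  }
  if (length(prior_probs) != 4L || abs(sum(prior_probs) - 1) > 1e-8)
    stop("`prior_probs` must be 4 probabilities summing to 1")
  if (Pa <= 0.5) stop("`Pa` must exceed 0.5 (at most one stop can fire)")
  if (Pb <= 0) stop("`Pb` must be positive")
  if (n_min > n_max) stop("`n_min` must not exceed `n_max`")
  structure(list(
    name = paste0("bht-", tolower(variant)),
    theta0 = theta0, theta_star = theta_star, tau1 = tau1, tau2 = tau2,
    variant = variant, prior_probs = prior_probs, Pa = Pa, Pb = Pb,
    n_min = n_min, n_max = n_max, cadence = cadence, tox = tox,
    nodes = nodes,
    hyps = bht_hypotheses(2, theta0, tau1, tau2)),
    class = c("bht_design", "med_design"))
}

#' @export
print.bht_design <- function(x, ...) {
  cat(sprintf("Joint BHT design (variant %s)\n", x$variant))
  cat(sprintf("  theta0 = %.3g, theta* = %.3g, tau1 = %.4g, tau2 = %.4g\n",
              x$theta0, x$theta_star, x$tau1, x$tau2))
  cat(sprintf("  prior P(H0..H3) = %s\n",
              paste(sprintf("%.3g", x$prior_probs), collapse = ", ")))
  cat(sprintf("  stop when posterior > Pa = %.3g; H2 iff ratio > Pb = %.3g\n",
              x$Pa, x$Pb))
  cat(sprintf("  burn-in %d, maximum %d patients\n", x$n_min, x$n_max))
  if (!is.null(x$tox)) print(x$tox)
  invisible(x)
}

# Posterior over (H0, H1, H2*) under the design's priors.
.bht_posterior <- function(design, data) {
  posterior_hyp_probs(data, design$hyps, design$prior_probs,
                      merge = list("H2*" = c("H2", "H3")),
                      nodes = design$nodes)
}

#' H2-versus-H3 split after an H2* conclusion
#'
#' @param design A [bht_design()] (or futility-variant) object.
#' @param data A [dose_data()] object.
#' @return `"H2"` if `p(x|H2)/p(x|H3)` strictly exceeds the design's ratio
#'   threshold (`Pb`, or the futility variant's split ratio), else `"H3"`.
#' @export
bht_split <- function(design, data) {
  m2 <- marginal_likelihood(data, design$hyps$H2, nodes = design$nodes)$value
  m3 <- marginal_likelihood(data, design$hyps$H3, nodes = design$nodes)$value
  thr <- if (!is.null(design$split_ratio)) design$split_ratio else design$Pb
  if (m3 == 0) return("H2")
  if (m2 / m3 > thr) "H2" else "H3"
}

#' @rdname interim
#' @export
interim.bht_design <- function(design, data, ...) {
  n_tot <- sum(data$n)
  if (n_tot < design$n_min) return(.decision("continue"))
  post <- .bht_posterior(design, data)
  hit <- which(post > design$Pa)
  if (length(hit) > 0L) {
    concl <- names(post)[hit[1L]]
    if (concl == "H2*") concl <- bht_split(design, data)
    return(.decision("stop", concl, post))
  }
  if (n_tot >= design$n_max) return(.decision("stop", "inconclusive", post))
  .decision("continue", posterior = post)
}

#' Futility-only BHT design (Simon-comparable variant)
#'
#' Monitoring allows early stopping only for futility: once past burn-in the
#' trial terminates (concluding H0) when `p(H0|x) > p_stop`, and the lower
#' dose arm is closed when `p(H1|x) > p_stop` (subsequent patients go to the
#' higher dose; posterior probabilities keep being updated with the frozen
#' lower-arm data).  At the end of the trial (each arm capped at `arm_max`)
#' the hypothesis whose posterior probability exceeds `p_final` is claimed,
#' an H2* claim being split by `p(x|H2)/p(x|H3) > split_ratio`; otherwise
#' the trial is inconclusive.
#'
#' @inheritParams bht_design
#' @param p_stop Futility threshold for stopping/arm closure.
#' @param p_final End-of-trial claim threshold.
#' @param split_ratio H2/H3 marginal-ratio cutoff at the final analysis.
#' @param arm_max Maximum sample size per dose arm.
#' @return An object of class
#'   `c("bht_futility_design", "bht_design", "med_design")`.
#' @export
bht_futility_design <- function(theta0 = 0.1, theta_star = 0.3, tau1 = 0.06,
                                tau2 = 0.015, prior_probs = rep(1 / 4, 4),
                                p_stop = 0.848, p_final = 0.5,
                                split_ratio = 1.37, n_min = 24, arm_max = 45,
                                cadence = 1, tox = NULL, nodes = 128) {
  d <- structure(list(
    name = "bht-futility",
    theta0 = theta0, theta_star = theta_star, tau1 = tau1, tau2 = tau2,
    prior_probs = prior_probs, p_stop = p_stop, p_final = p_final,
    split_ratio = split_ratio, n_min = n_min, arm_max = arm_max,
    n_max = 2L * arm_max, cadence = cadence, tox = tox, nodes = nodes,
    hyps = bht_hypotheses(2, theta0, tau1, tau2)),
    class = c("bht_futility_design", "bht_design", "med_design"))
  d
}

#' @export
print.bht_futility_design <- function(x, ...) {
  cat("Futility-only joint BHT design\n")
  cat(sprintf("  theta0 = %.3g, tau1 = %.4g, tau2 = %.4g\n",
              x$theta0, x$tau1, x$tau2))
  cat(sprintf("  stop/close when posterior > %.3g; final claim > %.3g; H2 iff ratio > %.3g\n",
              x$p_stop, x$p_final, x$split_ratio))
  cat(sprintf("  burn-in %d total, cap %d per arm\n", x$n_min, x$arm_max))
  invisible(x)
}

#' @rdname interim
#' @export
interim.bht_futility_design <- function(design, data, lower_closed = FALSE,
                                        final = FALSE, ...) {
  n_tot <- sum(data$n)
  if (n_tot < design$n_min && !final) return(.decision("continue"))
  post <- .bht_posterior(design, data)
  if (post[["H0"]] > design$p_stop)
    return(.decision("stop", "H0", post))
  if (!final) {
    if (!lower_closed && post[["H1"]] > design$p_stop)
      return(.decision("close_lower", posterior = post))
    return(.decision("continue", posterior = post))
  }
  over <- which(post > design$p_final)
  if (length(over) == 0L) return(.decision("stop", "inconclusive", post))
  concl <- names(post)[over[1L]]
  if (concl == "H2*") concl <- bht_split(design, data)
  .decision("stop", concl, post)
}
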