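# Dose data container and the symbolic hypothesis / model specifications.

#' Per-dose trial data
#'
#' Sufficient statistics of an ongoing or completed trial: per-dose response
#' counts, patient counts and (optionally) toxicity counts, doses indexed
#' from the lowest to the highest.
#'
#' @param x Integer vector of response counts per dose.
#' @param n Integer vector of patient counts per dose.
#' @param tox Optional integer vector of toxicity counts per dose (defaults
#'   to zeros).
#' @return An object of class `"dose_data"`.
#' @examples
#' dose_data(x = c(1, 6), n = c(12, 12))
#' @export
dose_data <- function(x, n, tox = NULL) {
  x <- as.integer(x); n <- as.integer(n)
  if (length(x) != length(n) || length(x) < 1L || length(x) > 3L)
    stop("`x` and `n` must have equal length 1, 2 or 3")
  if (is.null(tox)) tox <- integer(length(n)) else tox <- as.integer(tox)
  if (length(tox) != length(n)) stop("`tox` must match the number of doses")
  if (any(x < 0L) || any(x > n) || any(tox < 0L) || any(tox > n) || any(n < 0L))
    stop("counts must satisfy 0 <= x_i <= n_i and 0 <= tox_i <= n_i")
  structure(list(x = x, n = n, tox = tox), class = "dose_data")
}

#' @export
print.dose_data <- function(x, ...) {
  cat("dose data (low -> high):\n")
  print(data.frame(dose = seq_along(x$x), responses = x$x, patients = x$n,
                   toxicities = x$tox), row.names = FALSE)
  invisible(x)
}

#' Joint binomial likelihood
#'
#' Product over doses of binomial probability mass functions, including the
#' binomial coefficients (they cancel in posterior hypothesis probabilities
#' but keep marginal likelihood values comparable across parameterizations).
#'
#' @param data A [dose_data()] object.
#' @param theta Vector of per-dose response rates (recycled if scalar).
#' @return The likelihood value.
#' @export
binom_lik <- function(data, theta) {
  stopifnot(inherits(data, "dose_data"))
  theta <- rep_len(theta, length(data$n))
  if (any(theta < 0 | theta > 1)) stop("`theta` must lie in [0, 1]")
  prod(stats::dbinom(data$x, data$n, theta))
}

# ---------------------------------------------------------------------------
# Hypothesis / model specifications.
#
# A hypothesis is a contiguous partition of the dose indices into blocks, in
# dose order; the doses in one block share a response rate.  Each block
# carries a prior for that common rate:
#   - point:  the rate equals theta0 exactly;
#   - rim:    restricted inverse-moment prior anchored either at theta0
#             (anchor = 0) or at the realized rate of an earlier block
#             (anchor = block index);
#   - unif:   Uniform(0, 1) (used by the model-averaging families).
# Dedicated engines mark closed forms: "beta" for the all-uniform equal-rates
# model (beta-function marginal) and "kernel2d" for the two-dose strictly
# ordered model whose joint prior is the globally normalized kernel
# ((theta2-theta1)^2)^(-3/2) exp(-((theta2-theta1)^2/tau)^(-1)) on the
# triangle 0 < theta1 < theta2 < 1.
# ---------------------------------------------------------------------------

.block <- function(doses, type, anchor = 0L, tau = NA_real_) {
  list(doses = as.integer(doses), type = type, anchor = as.integer(anchor),
       tau = tau)
}

.new_hypothesis <- function(label, theta0, blocks, engine = "blocks",
                            tau = NA_real_) {
  doses <- sort(unlist(lapply(blocks, `[[`, "doses")))
  key <- paste(label, theta0, engine,
               paste(vapply(blocks, function(b) {
                 paste(b$type, b$anchor, b$tau, paste(b$doses, collapse = ","),
                       sep = ":")
               }, character(1)), collapse = ";"),
               sep = "#")
  structure(list(label = label, theta0 = theta0, blocks = blocks,
                 engine = engine, tau = tau, n_doses = max(doses), key = key),
            class = "med_hypothesis")
}

#' @export
print.med_hypothesis <- function(x, ...) {
  cat(sprintf("Hypothesis %s (theta0 = %.3g, %d dose(s)):\n", x$label,
              x$theta0, x$n_doses))
  for (b in x$blocks) {
    anchor <- if (b$anchor == 0L) "theta0" else sprintf("block %d", b$anchor)
    desc <- switch(b$type,
                   point = "= theta0",
                   rim = sprintf("~ rIM(anchor %s, tau = %.4g)", anchor, b$tau),
                   unif = "~ Uniform(0, 1)")
    cat(sprintf("  doses {%s} %s\n", paste(b$doses, collapse = ","), desc))
  }
  invisible(x)
}

#' Hypothesis families for the Bayesian hypothesis-testing design
#'
#' Builds the exact hypothesis list of the joint BHT design: `H0`-`H3` for
#' two doses, `H0`-`H7` for three doses.  `H0` puts every rate at the null
#' value `theta0`; the alternatives assign restricted inverse-moment priors
#' to promising rates, anchored at `theta0` for the first promising block and
#' at the previous block's realized rate for strict increments.
#'
#' @param n_doses 2 or 3.
#' @param theta0 Null response rate.
#' @param tau1 Scale of the promising-rate prior (mode at
#'   `theta0 + sqrt(2*tau1/3)`, the target rate).
#' @param tau2 Scale of the between-dose increment prior in the strictly
#'   ordered two-dose hypothesis `H3` and its three-dose analogue (mode at a
#'   difference of `sqrt(2*tau2/3)`).
#' @return A named list of hypothesis objects.
#' @export
bht_hypotheses <- function(n_doses = 2, theta0 = 0.1, tau1 = 0.06,
                           tau2 = 0.015) {
  if (n_doses == 2) {
    list(
      H0 = .new_hypothesis("H0", theta0, list(.block(1:2, "point"))),
      H1 = .new_hypothesis("H1", theta0, list(
        .block(1L, "point"),
        .block(2L, "rim", 0L, tau1))),
      H2 = .new_hypothesis("H2", theta0, list(
        .block(1:2, "rim", 0L, tau1))),
      H3 = .new_hypothesis("H3", theta0, list(
        .block(1L, "rim", 0L, tau1),
        .block(2L, "rim", 1L, tau2)))
    )
  } else if (n_doses == 3) {
    list(
      H0 = .new_hypothesis("H0", theta0, list(.block(1:3, "point"))),
      H1 = .new_hypothesis("H1", theta0, list(
        .block(1:2, "point"), .block(3L, "rim", 0L, tau1))),
      H2 = .new_hypothesis("H2", theta0, list(
        .block(1L, "point"), .block(2:3, "rim", 0L, tau1))),
      H3 = .new_hypothesis("H3", theta0, list(
        .block(1L, "point"), .block(2L, "rim", 0L, tau1),
        .block(3L, "rim", 2L, tau2))),
      H4 = .new_hypothesis("H4", theta0, list(
        .block(1:3, "rim", 0L, tau1))),
      H5 = .new_hypothesis("H5", theta0, list(
        .block(1L, "rim", 0L, tau1), .block(2:3, "rim", 1L, tau1))),
      H6 = .new_hypothesis("H6", theta0, list(
        .block(1:2, "rim", 0L, tau1), .block(3L, "rim", 1L, tau1))),
      H7 = .new_hypothesis("H7", theta0, list(
        .block(1L, "rim", 0L, tau1), .block(2L, "rim", 1L, tau1),
        .block(3L, "rim", 2L, tau1)))
    )
  } else stop("`n_doses` must be 2 or 3")
}

#' Model families for the Bayesian model-averaging design
#'
#' `M1`/`M2` for two doses (equal rates with a Uniform(0,1) prior versus
#' strictly ordered rates with a nonlocal prior on the increment) or
#' `M1`-`M4` for three doses.  The two-dose ordered model `M2` uses the
#' globally normalized joint kernel on the ordered triangle; the three-dose
#' models use hierarchical uniform x restricted inverse-moment priors.
#'
#' @param n_doses 2 or 3.
#' @param tau2 Scale of the increment prior.
#' @param theta0 Null rate carried along for bookkeeping (the models
#'   themselves do not use it).
#' @return A named list of model objects.
#' @export
bma_models <- function(n_doses = 2, tau2 = 0.015, theta0 = 0) {
  if (n_doses == 2) {
    list(
      M1 = .new_hypothesis("M1", theta0, list(.block(1:2, "unif")),
                           engine = "beta"),
      M2 = .new_hypothesis("M2", theta0, list(
        .block(1L, "unif"), .block(2L, "rim", 1L, tau2)),
        engine = "kernel2d", tau = tau2)
    )
  } else if (n_doses == 3) {
    list(
      M1 = .new_hypothesis("M1", theta0, list(.block(1:3, "unif")),
                           engine = "beta"),
      M2 = .new_hypothesis("M2", theta0, list(
        .block(1:2, "unif"), .block(3L, "rim", 1L, tau2))),
      M3 = .new_hypothesis("M3", theta0, list(
        .block(1L, "unif"), .block(2:3, "rim", 1L, tau2))),
      M4 = .new_hypothesis("M4", theta0, list(
        .block(1L, "unif"), .block(2L, "rim", 1L, tau2),
        .block(3L, "rim", 2L, tau2)))
    )
  } else stop("`n_doses` must be 2 or 3")
}
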