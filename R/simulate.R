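# Discrete-event simulation of trials under any design and scenario, and
# aggregation into operating-characteristic tables.
#
# RNG discipline: one master seed yields per-replicate substream seeds; each
# replicate pre-draws independent uniforms for assignment, response and
# toxicity per patient, so different designs can be compared on common
# random numbers.  Monte-Carlo posterior evaluations inside a trial (BIT
# tail probabilities, toxicity exceedance) run in their own substreams
# derived from the master seed and the sufficient statistic, which makes
# them cacheable across replicates and deterministic given the master seed.

#' Simulation scenario
#'
#' True per-dose response and toxicity probabilities.
#'
#' @param resp Vector of true response rates, low to high dose.
#' @param tox Vector of true toxicity rates (default 0.15 per dose, the low
#'   toxicity assumed in the motivating trial's simulations).
#' @param label Optional label (defaults to e.g. `"0.1 & 0.3"`).
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(resp, tox = rep(0.15, length(resp)), label = NULL) {
  if (any(resp < 0 | resp > 1) || any(tox < 0 | tox > 1))
    stop("rates must lie in [0, 1]")
  if (length(tox) != length(resp)) stop("`tox` must match `resp` in length")
  if (is.null(label)) label <- paste(format(resp, trim = TRUE), collapse = " & ")
  structure(list(resp = resp, tox = tox, label = label), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario %s: response %s, toxicity %s\n", x$label,
              paste(x$resp, collapse = "/"), paste(x$tox, collapse = "/")))
  invisible(x)
}

#' The twelve benchmark scenarios
#'
#' True response-rate pairs used throughout the operating-characteristic
#' comparisons, with toxicity 0.15 at both doses.
#'
#' @param tox Per-dose toxicity rate.
#' @return List of [scenario()] objects.
#' @export
table1_scenarios <- function(tox = 0.15) {
  pairs <- list(c(0.1, 0.1), c(0.2, 0.2), c(0.1, 0.2), c(0.3, 0.3),
                c(0.4, 0.4), c(0.5, 0.5), c(0.1, 0.3), c(0.1, 0.4),
                c(0.3, 0.4), c(0.3, 0.5), c(0.4, 0.5), c(0.4, 0.6))
  lapply(pairs, function(p) scenario(p, tox = rep(tox, 2)))
}

# Conclusion categories of a completed trial.  "low_promising" records the
# rare path where the high dose is closed for toxicity and the low dose is
# then found promising on its own.
.concl_levels <- c("H0", "H1", "H2", "H3", "inconclusive", "toxicity",
                   "low_promising")

.trial_result <- function(conclusion, n, looks, seed,
                          stop_reason = "efficacy") {
  structure(list(conclusion = conclusion, n = n, n_total = sum(n),
                 looks = looks, seed = seed, stop_reason = stop_reason),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("trial: %s after %d patients (%s), %d interim look(s)\n",
              x$conclusion, x$n_total, paste(x$n, collapse = "+"), x$looks))
  invisible(x)
}

.tox_exceed_cached <- function(monitor, tx, n, mc_seed_base) {
  key <- .key_num("tox", mc_seed_base, monitor$limit, monitor$Pc,
                  monitor$ndraws, paste(unlist(monitor$prior), collapse = ","),
                  .key_num(tx), .key_num(n))
  .cache_get(.cache_env("tox"), key, function() {
    tox_exceedance(tx, n, monitor,
                   seed = .derive_seed(mc_seed_base, c(7L, tx, n)))
  })
}

# Single-arm continuation after the high dose is closed for toxicity:
# evaluate the low dose on its own with the design's machinery.
.single_arm_check <- function(design, x1, n1, at_max) {
  if (inherits(design, "bht_design")) {
    hyps <- list(
      S0 = .new_hypothesis("S0", design$theta0, list(.block(1L, "point"))),
      S1 = .new_hypothesis("S1", design$theta0,
                           list(.block(1L, "rim", 0L, design$tau1))))
    d1 <- dose_data(x1, n1)
    m0 <- marginal_likelihood(d1, hyps$S0, nodes = design$nodes)$value
    m1 <- marginal_likelihood(d1, hyps$S1, nodes = design$nodes)$value
    p1 <- m1 / (m0 + m1)
    thr <- design$Pa
    if (p1 > thr) return("low_promising")
    if (1 - p1 > thr) return("H0")
  } else {
    # BMA / BIT: beta posterior under a Uniform(0, 1) prior
    lo <- design$theta0 + design$delta
    hi <- design$theta_star - design$delta
    a <- x1 + 1; b <- n1 - x1 + 1
    up <- if (inherits(design, "bma_design")) design$Pe else design$Ph
    dn <- if (inherits(design, "bma_design")) design$Pf else design$Pi
    if (stats::pbeta(hi, a, b, lower.tail = FALSE) > up) return("low_promising")
    if (stats::pbeta(lo, a, b) > dn) return("H0")
  }
  if (at_max) "inconclusive" else NA_character_
}

# --- joint two-arm designs: BHT-A/B, BMA, BIT ------------------------------

.sim_joint <- function(design, scen, seed, mc_seed_base) {
  n_max <- design$n_max
  u <- .with_seed(seed, list(assign = stats::runif(n_max),
                             resp = stats::runif(n_max),
                             tox = stats::runif(n_max)))
  x <- c(0L, 0L); n <- c(0L, 0L); tx <- c(0L, 0L)
  high_closed <- FALSE
  looks <- 0L
  for (i in seq_len(n_max)) {
    arm <- if (high_closed) 1L else if (u$assign[i] < 0.5) 1L else 2L
    n[arm] <- n[arm] + 1L
    x[arm] <- x[arm] + (u$resp[i] < scen$resp[arm])
    tx[arm] <- tx[arm] + (u$tox[i] < scen$tox[arm])
    if (!is.null(design$tox)) {
      act <- if (high_closed) {
        tox_action(.tox_exceed_cached(design$tox, tx[1], n[1], mc_seed_base),
                   design$tox)
      } else {
        tox_action(.tox_exceed_cached(design$tox, tx, n, mc_seed_base),
                   design$tox)
      }
      if (act == "terminate")
        return(.trial_result("toxicity", n, looks, seed, "toxicity"))
      if (act == "close_high" && !high_closed) high_closed <- TRUE
    }
    ntot <- sum(n)
    if (ntot >= design$n_min &&
        ((ntot - design$n_min) %% design$cadence == 0L || ntot == n_max)) {
      looks <- looks + 1L
      if (high_closed) {
        concl <- .single_arm_check(design, x[1], n[1], ntot == n_max)
        if (!is.na(concl))
          return(.trial_result(concl, n, looks, seed, "efficacy"))
      } else {
        dat <- dose_data(x, n, tx)
        dec <- if (inherits(design, "bit_design")) {
          interim(design, dat,
                  seed = .derive_seed(mc_seed_base, c(11L, x, n)))
        } else {
          interim(design, dat)
        }
        if (dec$action == "stop")
          return(.trial_result(dec$conclusion, n, looks, seed, "efficacy"))
      }
    }
  }
  # unreachable for standard configurations: the look at n_max stops
  .trial_result("inconclusive", n, looks, seed, "max_n")
}

# --- futility-only BHT (Simon-comparable) ----------------------------------

.sim_futility <- function(design, scen, seed, mc_seed_base) {
  cap <- design$arm_max
  n_max <- 2L * cap
  u <- .with_seed(seed, list(assign = stats::runif(n_max),
                             resp = stats::runif(n_max)))
  x <- c(0L, 0L); n <- c(0L, 0L)
  lower_closed <- FALSE
  looks <- 0L
  for (i in seq_len(n_max)) {
    open <- which(n < cap & !(c(lower_closed, FALSE)))
    if (length(open) == 0L) break
    arm <- if (length(open) == 2L) {
      if (u$assign[i] < 0.5) 1L else 2L
    } else open
    n[arm] <- n[arm] + 1L
    x[arm] <- x[arm] + (u$resp[i] < scen$resp[arm])
    if (sum(n) >= design$n_min &&
        (sum(n) - design$n_min) %% design$cadence == 0L) {
      looks <- looks + 1L
      dec <- interim(design, dose_data(x, n), lower_closed = lower_closed)
      if (dec$action == "stop")
        return(.trial_result(dec$conclusion, n, looks, seed, "futility"))
      if (dec$action == "close_lower") lower_closed <- TRUE
    }
  }
  dec <- interim(design, dose_data(x, n), lower_closed = lower_closed,
                 final = TRUE)
  .trial_result(dec$conclusion, n, looks + 1L, seed, "final_analysis")
}

# --- independent per-arm BHT ----------------------------------------------

.sim_indep <- function(design, scen, seed, mc_seed_base) {
  cap <- design$arm_max
  n_max <- 2L * cap
  u <- .with_seed(seed, list(assign = stats::runif(n_max),
                             resp = stats::runif(n_max),
                             tox = stats::runif(n_max)))
  x <- c(0L, 0L); n <- c(0L, 0L); tx <- c(0L, 0L)
  status <- c("open", "open")
  tox_closed <- c(FALSE, FALSE)
  looks <- 0L
  for (i in seq_len(n_max)) {
    open <- which(status == "open" & !tox_closed & n < cap)
    if (length(open) == 0L) break
    arm <- if (length(open) == 2L) {
      if (u$assign[i] < 0.5) 1L else 2L
    } else open
    n[arm] <- n[arm] + 1L
    x[arm] <- x[arm] + (u$resp[i] < scen$resp[arm])
    tx[arm] <- tx[arm] + (u$tox[i] < scen$tox[arm])
    if (!is.null(design$tox)) {
      # independent monitoring: exact beta tails, no order constraint
      exc <- vapply(1:2, function(j) {
        pr <- design$tox$prior[[j]]
        stats::pbeta(design$tox$limit, pr[1] + tx[j], pr[2] + n[j] - tx[j],
                     lower.tail = FALSE)
      }, numeric(1))
      toxic <- exc > design$tox$Pc
      if (all(toxic))
        return(.trial_result("toxicity", n, looks, seed, "toxicity"))
      tox_closed <- tox_closed | toxic
      if (all(tox_closed))
        return(.trial_result("toxicity", n, looks, seed, "toxicity"))
    }
    if (any(n[status == "open"] >= design$arm_min)) {
      looks <- looks + 1L
      dec <- interim(design, dose_data(x, n, tx), status = status)
      status <- dec$status
      if (dec$action == "stop") {
        concl <- if (any(tox_closed)) "inconclusive" else dec$conclusion
        reason <- if (any(tox_closed)) "toxicity_closure" else "efficacy"
        return(.trial_result(concl, n, looks, seed, reason))
      }
      if (any(tox_closed) && all(status != "open" | tox_closed)) {
        # remaining open arms are all toxicity-closed: nothing left to learn
        return(.trial_result("inconclusive", n, looks, seed,
                             "toxicity_closure"))
      }
    }
  }
  .trial_result("inconclusive", n, looks, seed, "max_n")
}

# --- independent Simon two-stage, two doses --------------------------------

.sim_simon2 <- function(design, scen, seed, mc_seed_base) {
  sd1 <- design$simon
  res <- .with_seed(seed, {
    lapply(1:2, function(arm) {
      x1 <- stats::rbinom(1L, sd1$n1, scen$resp[arm])
      if (x1 <= sd1$r1)
        return(list(rejected = TRUE, x = x1, n = sd1$n1))
      x2 <- stats::rbinom(1L, sd1$n - sd1$n1, scen$resp[arm])
      list(rejected = (x1 + x2) <= sd1$r, x = x1 + x2, n = sd1$n)
    })
  })
  rejected <- vapply(res, `[[`, logical(1), "rejected")
  rr <- vapply(res, function(a) a$x / a$n, numeric(1))
  n <- vapply(res, `[[`, integer(1), "n")
  concl <- simon_two_dose_conclusion(rejected, rr, design$delta)
  .trial_result(concl, n, 2L, seed, "two_stage")
}

#' Simulate one trial
#'
#' Runs a single trial under a design and scenario: patients are randomized
#' (equal probability per open arm), their binary response and toxicity
#' outcomes drawn from the scenario's true rates and observed immediately,
#' toxicity is monitored from the first patient (where the design monitors
#' toxicity) and efficacy after the design's burn-in, honoring arm closures
#' and stopping rules.
#'
#' @param design A design object.
#' @param scen A [scenario()] object.
#' @param seed Replicate seed (required: trials are reproducible by
#'   construction).
#' @param mc_seed_base Master seed from which within-trial Monte-Carlo
#'   substreams are derived (defaults to `seed`; [operating_characteristics()]
#'   passes its own master seed so the per-state caches are shared across
#'   replicates).
#' @return An object of class `"trial_result"`.
#' @export
simulate_trial <- function(design, scen, seed, mc_seed_base = seed) {
  stopifnot(inherits(design, "med_design"), inherits(scen, "scenario"))
  if (length(scen$resp) != 2L)
    stop("the trial simulator supports two-dose designs")
  if (inherits(design, "bht_futility_design"))
    .sim_futility(design, scen, seed, mc_seed_base)
  else if (inherits(design, "indep_bht_design"))
    .sim_indep(design, scen, seed, mc_seed_base)
  else if (inherits(design, "simon2_design"))
    .sim_simon2(design, scen, seed, mc_seed_base)
  else
    .sim_joint(design, scen, seed, mc_seed_base)
}

#' Operating characteristics by simulation
#'
#' Simulates `nsim` independent trials (per-replicate substreams of one
#' master seed) and aggregates conclusion frequencies and sample sizes.
#'
#' @param design A design object.
#' @param scen A [scenario()] object.
#' @param nsim Number of replicate trials.
#' @param seed Master seed.
#' @return An object of class `"oc_table"`: conclusion probabilities
#'   (including `P(H2*) = P(H2) + P(H3)`), average total and per-arm sample
#'   sizes, the fraction of inconclusive trials, replicate count and seed.
#' @export
operating_characteristics <- function(design, scen, nsim = 1000, seed = 1) {
  stopifnot(nsim >= 1)
  rep_seeds <- .with_seed(seed, sample.int(2147483646L, nsim))
  ns <- matrix(0L, nsim, 2L)
  concl <- character(nsim)
  looks <- integer(nsim)
  for (r in seq_len(nsim)) {
    tr <- simulate_trial(design, scen, seed = rep_seeds[r],
                         mc_seed_base = seed)
    ns[r, ] <- tr$n
    concl[r] <- tr$conclusion
    looks[r] <- tr$looks
  }
  p <- vapply(.concl_levels, function(l) mean(concl == l), numeric(1))
  structure(list(
    design = design$name, scenario = scen$label, n_reps = as.integer(nsim),
    seed = as.integer(seed),
    p = p, p_h2star = unname(p["H2"] + p["H3"]),
    avg_ss = mean(rowSums(ns)), avg_ss_arm = colMeans(ns),
    avg_looks = mean(looks)),
    class = "oc_table")
}

#' @export
print.oc_table <- function(x, ...) {
  cat(sprintf("design %s, scenario %s (%d trials, seed %d)\n",
              x$design, x$scenario, x$n_reps, x$seed))
  show <- c(x$p[c("H0", "H1", "H2", "H3")], "H2*" = x$p_h2star)
  cat("  P(conclude): ", paste(sprintf("%s %.3f", names(show), show),
                               collapse = ", "), "\n", sep = "")
  cat(sprintf("  avg sample size %.1f (%s per arm)\n", x$avg_ss,
              paste(sprintf("%.1f", x$avg_ss_arm), collapse = " / ")))
  cat(sprintf("  inconclusive %.3f, toxicity stop %.3f\n",
              x$p["inconclusive"], x$p["toxicity"]))
  if (x$p["low_promising"] > 0)
    cat(sprintf("  low dose alone promising %.3f\n", x$p["low_promising"]))
  invisible(x)
}

#' @export
summary.oc_table <- function(object, ...) as.data.frame(object)

#' @export
as.data.frame.oc_table <- function(x, ...) {
  data.frame(design = x$design, scenario = x$scenario,
             P_H0 = x$p[["H0"]], P_H1 = x$p[["H1"]], P_H2 = x$p[["H2"]],
             P_H3 = x$p[["H3"]], P_H2star = x$p_h2star,
             avg_ss = x$avg_ss, avg_ss1 = x$avg_ss_arm[1],
             avg_ss2 = x$avg_ss_arm[2],
             pct_inconclusive = x$p[["inconclusive"]],
             P_toxicity = x$p[["toxicity"]],
             P_low_promising = x$p[["low_promising"]],
             n_reps = x$n_reps, seed = x$seed)
}

#' @export
plot.oc_table <- function(x, ...) {
  show <- c(x$p[c("H0", "H1", "H2", "H3", "inconclusive")],
            "H2*" = x$p_h2star)
  graphics::barplot(show, ylab = "probability",
                    main = sprintf("%s, scenario %s", x$design, x$scenario),
                    ...)
  invisible(x)
}

#' Simulate trials from a design object
#'
#' `simulate()` method for design objects: returns one row per simulated
#' trial.
#'
#' @param object A design object.
#' @param nsim Number of trials.
#' @param seed Master seed (required for reproducibility).
#' @param scen A [scenario()] object.
#' @param ... Unused.
#' @return A data frame with columns `conclusion`, `n1`, `n2`, `n_total`.
#' @export
simulate.med_design <- function(object, nsim = 1, seed = 1, scen, ...) {
  rep_seeds <- .with_seed(seed, sample.int(2147483646L, nsim))
  rows <- lapply(seq_len(nsim), function(r) {
    tr <- simulate_trial(object, scen, seed = rep_seeds[r], mc_seed_base = seed)
    data.frame(conclusion = tr$conclusion, n1 = tr$n[1], n2 = tr$n[2],
               n_total = tr$n_total)
  })
  do.call(rbind, rows)
}

#' @export
print.med_design <- function(x, ...) {
  cat(sprintf("design: %s\n", x$name))
  utils::str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}
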