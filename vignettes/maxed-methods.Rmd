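---
title: "Methods: Bayesian dose-selection designs for the maximum effective dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian dose-selection designs for the maximum effective dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

For molecularly targeted agents the probability of response often increases
with dose and then plateaus.  The *maximum effective dose* (MaxED) is the
lowest dose that achieves a pre-specified target response rate and beyond
which further improvement is unlikely.  Phase II resources rarely allow more
than two or three doses to be compared, so the scientific questions reduce
to a small set of composite hypotheses about the ordered response rates
$\theta_1 \le \theta_2 (\le \theta_3)$: is any dose active at all, is only
the highest dose active, or are several doses active and essentially
equivalent — in which case the lower dose is the MaxED and should move
forward.

A frequentist test cannot *conclude* that two doses are equally effective;
it can only fail to reject equality.  The designs in this package are built
on Bayesian hypothesis tests with *nonlocal* alternative priors, which put
zero density on parameter values consistent with the null and therefore
accumulate evidence exponentially fast in favour of a true null as well as
a true alternative.  That is exactly the property needed to stop a trial
early *because the doses are equivalent*.

## The nonlocal prior

The inverse-moment prior with null value $\theta'$ is

$$\pi_I(\theta;\theta',k,\nu,\tau) \;=\;
  \frac{k\,\tau^{\nu/2}}{\Gamma(\nu/2k)}\,
  \big((\theta-\theta')^2\big)^{-(\nu+1)/2}
  \exp\!\left[-\left(\frac{(\theta-\theta')^2}{\tau}\right)^{-k}\right],$$

restricted to $(\theta', 1)$ and renormalized
($\pi_{rI} = \pi_I \cdot I(\theta' < \theta < 1)/P(\theta' < \theta < 1)$).
With the defaults $k = 1$, $\nu = 2$ the restriction mass is
$\tfrac12\exp[-\tau(1-\theta')^{-2}]$ and the mode sits at
$\theta' + \sqrt{2\tau/3}$.  The mode is how $\tau$ is chosen in practice:

* $\tau_1 = 0.06$ with $\theta_0 = 0.1$ puts the mode at the target rate
  $\theta_\star = 0.3$ (`imom_mode(im_prior(0.1, 0.06))`);
* $\tau_2 = 0.015$ puts the mode of the *between-dose difference* prior at
  0.1, the minimal clinically meaningful difference between doses.

The substitution $u = ((\theta-\theta')^2/\tau)^{-k}$ turns every tail
integral of $\pi_I$ into an incomplete gamma function with shape
$\nu/(2k)$, so the package's CDF (`primom`), quantile function (`qrimom`)
and sampler (`rrimom`) are closed-form for *any* $(k,\nu)$, not only the
defaults.  Sampling is exact inversion — no rejection step, hence exactly
reproducible under a seed.

## Hypotheses and marginal likelihoods

For two doses the joint Bayesian hypothesis test (BHT) entertains

* $H_0$: $\theta_1 = \theta_2 = \theta_0$ (nothing works),
* $H_1$: $\theta_1 = \theta_0$, $\theta_2 \sim \pi_{rI}(\cdot;\theta_0,\tau_1)$,
* $H_2$: $\theta_1 = \theta_2 \sim \pi_{rI}(\cdot;\theta_0,\tau_1)$,
* $H_3$: $\theta_1 \sim \pi_{rI}(\cdot;\theta_0,\tau_1)$,
  $\theta_2 \mid \theta_1 \sim \pi_{rI}(\cdot;\theta_1,\tau_2)$,

monitored through the merged alternative $H_2^\ast = H_2 \cup H_3$ ("both
doses promising").  The eight-hypothesis three-dose family and the
model-averaging families ($M_1$/$M_2$, $M_1$–$M_4$) are built by the same
block machinery (`bht_hypotheses()`, `bma_models()`): a hypothesis is a
contiguous partition of the doses into blocks sharing a rate, each block
carrying a point mass at $\theta_0$, a restricted inverse-moment prior
anchored at $\theta_0$ or at the previous block's realized rate, or a
Uniform(0,1) prior.

`marginal_likelihood()` integrates the joint binomial likelihood (including
the binomial coefficients, so values are comparable with the closed
beta-function form of the equal-rates uniform model) against these priors.

## Numerical choices

**Deterministic quadrature by default.**  Interim decisions compare
posterior probabilities against thresholds; a Monte-Carlo integrator would
make the *decision* random.  The default integrator is nested
Gauss–Legendre quadrature with 128 nodes per dimension, the node set split
at the prior mode $\theta' + \sqrt{2\tau/3}$ — the integrand's only sharp
feature (for small $\tau$ the density is nearly singular there).  Monte
Carlo (`method = "mc"`) is retained as an independent verification route
and the test suite requires the two to agree within three Monte-Carlo
standard errors across a grid of data states.  Because
$\exp[-\tau/(\theta-\theta')^2]$ is smooth but non-analytic at $\theta'$,
quadrature accuracy is ~$10^{-5}$ relative rather than machine precision;
that is irrelevant at the decision thresholds (0.65–0.85) but explains the
tolerance used when the no-data posterior is compared with the prior.

**Log-space restricted densities.**  In the strictly ordered hypotheses the
inner prior is anchored at the outer integration variable.  When that
anchor approaches 1 the restriction mass underflows like
$\exp[-\tau(1-\theta_1)^{-2}]$; the restricted density is therefore
evaluated entirely in log space (`pgamma(..., log.p = TRUE)`), and the
inversion sampler clamps at the upper support limit where denormal
arithmetic would otherwise push a draw microscopically above 1.

**The ordered model's prior.**  For the two-dose model-averaging design the
strictly ordered model $M_2$ is stated two ways that are not equivalent:
hierarchically ($\theta_1 \sim U(0,1)$,
$\theta_2\mid\theta_1 \sim \pi_{rI}(\cdot;\theta_1,\tau_2)$, whose
conditional normalizer depends on $\theta_1$) and as a joint kernel
$\propto ((\theta_2-\theta_1)^2)^{-3/2}
\exp[-((\theta_2-\theta_1)^2/\tau_2)^{-1}]$ on the triangle
$0<\theta_1<\theta_2<1$, which drops that normalizer.  The package follows
the joint kernel, normalized globally over the triangle, and integrates it
on a fixed 2000×2000 trapezoid grid — deterministic, cached per sufficient
statistic, with the three tail probabilities obtained from masked partial
sums of the same grid.  The hierarchical convention (with each conditional
properly normalized) is used for the three-dose model family, which exists
structurally but has no published operating characteristics to validate
against.

**Caching and RNG discipline.**  Continuous monitoring over 1000 simulated
trials revisits a lattice of sufficient statistics; marginal likelihoods
and toxicity exceedance probabilities are memoised by state.  One master
seed drives per-replicate substreams (assignment, response, toxicity
pre-drawn per patient, enabling common-random-number comparisons across
designs), while Monte-Carlo posterior evaluations inside a trial use
substreams derived from the master seed *and the data state*, making them
deterministic given the master seed and shareable across replicates.
Measured over a fresh 1000-replicate null-scenario run, well over half of
marginal-likelihood looks and about 83% of toxicity looks are cache hits;
Bernoulli randomization keeps the hit rate below what block randomization
would give because the per-arm sample-size split itself varies.

**Ties.**  All stop comparisons are strict (`>`), as stated; at
$P_a = 0.65 > 0.5$ at most one posterior probability can exceed the
threshold, so no tie-break rule is needed.

## The designs

* `bht_design()` (variants A and B): equal randomization; after a total
  burn-in of $n_0 = 24$ the posterior probabilities of
  $H_0, H_1, H_2^\ast$ are updated after every patient; stop when one
  exceeds $P_a = 0.65$ or at $N = 54$; an $H_2^\ast$ stop is refined to
  $H_2$ iff $p(x|H_2)/p(x|H_3) > P_b = 1.2$.  Variant A puts prior mass
  1/4 on each of $H_0$–$H_3$; variant B puts 1/3 on each of
  $H_0, H_1, H_2^\ast$.  A cohort-size option (`cadence`) supports
  semi-continuous monitoring but the published characteristics use
  per-patient monitoring.  At $N$ the same threshold is applied once more
  and the trial is inconclusive if nothing exceeds it — the only reading
  consistent with non-zero inconclusive rates.
* `bma_design()`: model-averaged tail probabilities
  $p_1$ (both promising), $p_2$ (only the higher), $p_3$ (neither), with
  stopping when $p_1 > P_e = 0.7$ or $p_2 + p_3 > P_f = 0.65$ and
  conclusions via the model odds ($P_g = 1.3$) and $p_2 - p_3$
  ($P_k = 0.02$).  If both stop conditions held simultaneously the $p_1$
  branch is taken (order of statement); with the standard thresholds both
  cannot exceed their cutoffs at once for long since
  $p_1 + p_2 + p_3 \le 1$.
* `bht_futility_design()`: the Simon-comparable variant — early stopping
  only for futility (terminate on $p(H_0|x) > 0.848$, close the lower arm
  on $p(H_1|x) > 0.848$), per-arm cap 45, final claims at posterior
  probability 0.5 with the $H_2/H_3$ ratio cutoff 1.37.  After the lower
  arm closes its data are frozen but all posteriors keep being updated with
  the full data, so a later futility stop remains possible.
* `indep_bht_design()`, `bit_design()`, `simon_two_dose_design()`: the
  benchmarks — independent per-arm nonlocal hypothesis tests, the Bayesian
  isotonic transformation design (uniform priors, precision-weighted
  isotonic projection of posterior draws, tail probabilities from the
  projected draws, equality mass = fraction of draws pooled by the
  projection), and the Simon optimal two-stage design applied independently
  per dose with the overall errors split as
  $1 - (1-\alpha)^{1/2}$, $1 - (1-\beta)^{1/2}$.

One caveat worth stating plainly: the independent design's printed
$H_2/H_3$ rule (conclude $H_2$ iff
$P(\theta_2-\theta_1 > 0.1\,|\,x) \le P_d = 0.11$) almost always returns
$H_3$ in practice, because even for identical per-arm data that posterior
probability is about 0.2–0.25 at the sample sizes where both arms stop.
The published split frequencies for this comparator cannot be reproduced
from the stated rule; the package implements the rule as stated and offers
a flat-posterior variant (`split_prior = "flat"`), and its other columns
(overall "both promising", null and single-dose conclusions) are unaffected.

## Toxicity monitoring

Toxicity probabilities $p_1^t \le p_2^t$ are monitored from the first
patient.  Independent beta posteriors are drawn jointly and each draw is
projected onto the ordered cone by weighted least-squares isotonic
regression (`pava()`; weights = unconstrained posterior precisions, i.e.
reciprocal beta-posterior variances, taken analytically rather than
estimated).  Dose $i$ is toxic when
$P(p_i^{t\ast} > \bar p \mid \text{data}) > P_c$ with $\bar p = 0.3$ and
$P_c = 0.8$; both doses toxic terminates the trial, only the higher toxic
closes that arm.  Exceedance uses 10,000 posterior draws per evaluation
(standard error below 0.005 near the threshold), in a state-keyed
substream.  Under the order constraint the per-draw projected vector is
monotone, so the exceedance probabilities are monotone by construction and
"only the lower dose toxic" cannot occur.

The informative priors Beta(0.5, 16.5) and Beta(0.5, 8.5) are reproduced by
`phase1_tox_priors()` from a Beta(0.5, 0.5) base and a phase I escalation
with four dose levels, three toxicity-free patients each, the phase II
doses equal to the two middle levels: every three toxicity-free patients at
a higher level count as five at the next lower level, compounded per level
gap and rounded to whole patients (3 + 5 + round(25/3) = 16 effective
patients at the lower dose, 3 + 5 = 8 at the higher).  The rounding step is
an interpretation — it is the only reading that reproduces both printed
priors exactly.

After a toxicity closure of the high arm the efficacy question degenerates
to a single-arm test on the low dose.  How conclusions should then be
labelled is not specified anywhere; the package continues with a single-arm
evaluation using the design's own machinery and reports the distinct
conclusion `low_promising` (or $H_0$/inconclusive).  With the informative
priors and 15% true toxicity this path occurs in well under 2% of
replicates, so it does not move any benchmark cell.

## The simulator as a stated world

`simulate_trial()`/`operating_characteristics()` emulate: equal (i.i.d.
Bernoulli-0.5) randomization, immediately observable binary response and
toxicity outcomes drawn from the scenario's true rates, toxicity checks
before efficacy checks at each patient, burn-in, arm closures and caps, and
the design's stopping rule.  They deliberately do **not** model accrual
time, delayed outcome assessment, dropout, outcome-adaptive randomization,
or correlation between response and toxicity.  A green simulation test
therefore establishes that the *decision rules* have the published
operating characteristics under the published data-generating assumptions —
not that a real trial with lagged outcomes would behave identically.

The twelve benchmark scenarios (`table1_scenarios()`) place true response
rates on a grid from (0.1, 0.1) to (0.4, 0.6) with toxicity fixed at 0.15;
these defaults are the stated world of the published comparison, not tuning
knobs.  Reproduction accuracy is bounded by binomial noise at 1000
replicates (±0.02–0.045 at three standard errors) and, for the joint BHT
design, by one systematic difference: the original implementation
integrated marginals by Monte Carlo of unstated size, whereas this package
integrates deterministically.  Under the null scenario the deterministic
posterior hovers near the stopping threshold, so integration noise in the
original tended to trigger slightly more early null stops; the package's
null-scenario null-conclusion rate centers ~0.02 below the published cell
(with matching direction in average sample size) while remaining within
three standard errors, and every other pinned cell reproduces centrally.

## Limitations

* Two-dose designs are fully simulated; the three-dose hypothesis and
  model families are implemented and tested at the marginal-likelihood
  level but no published three-dose operating characteristics exist to
  validate a three-dose simulation against.
* The BIT design's equality mass and the independent design's split rule
  are approximations whose published descriptions are incomplete (see
  above); both are implemented as stated with the interpretation recorded.
* Monitoring after every patient is computationally realistic here only
  because of sufficient-statistic caching; real-trial use would more
  likely use the `cadence` option.
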