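Package: maxed
Title: Bayesian Phase II Dose-Selection Designs for the Maximum Effective Dose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation of Bayesian phase II oncology trials that
    select the maximum effective dose (MaxED) among two or three doses under a
    monotone dose-response assumption.  Implements Bayesian hypothesis testing
    with nonlocal (inverse-moment) alternative priors, Bayesian model
    averaging with order-restricted priors, continuous toxicity monitoring via
    the Bayesian isotonic regression transformation (weighted
    pool-adjacent-violators), and comparator designs (independent per-arm
    Bayesian hypothesis tests, a Bayesian isotonic transformation efficacy
    design, and the Simon optimal two-stage design extended to two doses).  A
    seedable discrete-event trial simulator aggregates operating
    characteristics across scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
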