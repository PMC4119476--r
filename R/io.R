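# Configuration parsing, batch operating-characteristic runs, result
# serialization and the interim-report helper behind the command-line
# entry point (inst/cli/maxed).

#' Build a design from its command-line name
#'
#' Recognized names: `"bht-a"`, `"bht-b"`, `"bht-futility"`, `"bma"`,
#' `"bit"`, `"indep-bht"`, `"simon-i"` (delta 0.05), `"simon-ii"` (0.03),
#' `"simon-iii"` (0.07).  `overrides` is a named list of constructor
#' arguments replacing the defaults; every override is validated by the
#' design constructor before any simulation starts.
#'
#' @param name Design name.
#' @param overrides Named list of constructor arguments.
#' @return A design object.
#' @export
design_from_name <- function(name, overrides = list()) {
  ctor <- switch(name,
    "bht-a" = function(...) bht_design(variant = "A", ...),
    "bht-b" = function(...) bht_design(variant = "B", ...),
    "bht-futility" = bht_futility_design,
    "bma" = bma_design,
    "bit" = bit_design,
    "indep-bht" = indep_bht_design,
    "simon-i" = function(...) simon_two_dose_design(delta = 0.05, ...),
    "simon-ii" = function(...) simon_two_dose_design(delta = 0.03, ...),
    "simon-iii" = function(...) simon_two_dose_design(delta = 0.07, ...),
    stop(sprintf("unknown design name '%s'", name)))
  if (length(overrides) > 0 && is.null(names(overrides)))
    stop("`overrides` must be a named list")
  do.call(ctor, overrides)
}

#' Read a simulation run configuration
#'
#' JSON with fields `designs` (vector of design names), `scenarios` (array
#' of objects with `resp`, optional `tox` and `label`), `n_reps`, and
#' optional per-design `overrides`.
#'
#' @param path Path to the JSON configuration.
#' @return Validated list with `designs`, `scenarios` ([scenario()]
#'   objects), `n_reps` and `overrides`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cfg$designs) || length(cfg$designs) == 0)
    stop("configuration lists no designs")
  if (is.null(cfg$scenarios) || length(cfg$scenarios) == 0)
    stop("configuration lists no scenarios")
  scens <- lapply(cfg$scenarios, function(s) {
    if (is.null(s$resp)) stop("each scenario needs a `resp` vector")
    args <- list(resp = unlist(s$resp))
    if (!is.null(s$tox)) args$tox <- unlist(s$tox)
    if (!is.null(s$label)) args$label <- s$label
    do.call(scenario, args)
  })
  overrides <- if (is.null(cfg$overrides)) list() else cfg$overrides
  # validate every design (including overrides) up front
  for (nm in cfg$designs) {
    ov <- if (is.null(overrides[[nm]])) list() else overrides[[nm]]
    design_from_name(nm, ov)
  }
  list(designs = cfg$designs, scenarios = scens,
       n_reps = if (is.null(cfg$n_reps)) 1000L else as.integer(cfg$n_reps),
       overrides = overrides)
}

#' Run an operating-characteristic batch
#'
#' Simulates every (design, scenario) combination of a configuration and
#' writes one CSV of operating characteristics plus a JSON manifest
#' (seed, package version, configuration hash) to `out_dir`.
#'
#' @param config Path to a JSON run configuration (see [read_run_config()]).
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param n_reps Optional override of the configured replicate count.
#' @param quiet Suppress per-table console output?
#' @return Invisibly, the data frame of operating characteristics.
#' @export
run_oc_command <- function(config, seed, out_dir, n_reps = NULL,
                           quiet = FALSE) {
  cfg <- read_run_config(config)
  if (!is.null(n_reps)) cfg$n_reps <- as.integer(n_reps)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  rows <- list()
  for (nm in cfg$designs) {
    ov <- if (is.null(cfg$overrides[[nm]])) list() else cfg$overrides[[nm]]
    design <- design_from_name(nm, ov)
    for (scen in cfg$scenarios) {
      oc <- operating_characteristics(design, scen, nsim = cfg$n_reps,
                                      seed = seed)
      if (!quiet) print(oc)
      rows[[length(rows) + 1L]] <- as.data.frame(oc)
    }
  }
  tab <- do.call(rbind, rows)
  csv <- file.path(out_dir, "operating_characteristics.csv")
  write_oc_csv(tab, csv)
  manifest <- list(seed = seed, n_reps = cfg$n_reps,
                   package_version = as.character(utils::packageVersion("maxed")),
                   r_version = R.version.string,
                   config = normalizePath(config),
                   config_md5 = unname(tools::md5sum(config)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tab)
}

#' Write / read operating-characteristic tables as CSV
#'
#' Values round-trip exactly: numbers are written with full precision.
#'
#' @param tab Data frame of operating characteristics (rows from
#'   `as.data.frame()` applied to `oc_table` objects).
#' @param path File path.
#' @return `read_oc_csv()`: the data frame.
#' @export
write_oc_csv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(col) sprintf("%.17g", col))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_oc_csv
#' @export
read_oc_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  intcols <- intersect(names(tab), c("n_reps", "seed"))
  tab[intcols] <- lapply(tab[intcols], as.integer)
  tab
}

#' Interim decision report for observed trial data
#'
#' Real-trial use of the monitoring rules: given current per-dose counts,
#' prints the design's posterior summary, the toxicity exceedance
#' probabilities (where the design monitors toxicity) and the resulting
#' action.
#'
#' @param design A design object.
#' @param x,n,tox Per-dose response, patient and toxicity counts.
#' @param seed Seed for Monte-Carlo posterior evaluations.
#' @return Invisibly, a list with the efficacy decision and toxicity
#'   exceedance probabilities.
#' @export
interim_report <- function(design, x, n, tox = NULL, seed = 1) {
  dat <- dose_data(x, n, tox)
  exc <- NULL
  if (!is.null(design$tox)) {
    exc <- tox_exceedance(dat$tox, dat$n, design$tox, seed = seed)
    act <- tox_action(exc, design$tox)
    cat(sprintf("toxicity exceedance P(p_i > %.2g | data): %s -> %s\n",
                design$tox$limit,
                paste(sprintf("%.3f", exc), collapse = ", "), act))
    if (act == "terminate") {
      cat("action: terminate the trial for toxicity\n")
      return(invisible(list(decision = "terminate_toxicity",
                            tox_exceedance = exc)))
    }
    if (act == "close_high") cat("note: close the highest dose arm\n")
  }
  dec <- if (inherits(design, "bit_design")) {
    interim(design, dat, seed = seed)
  } else {
    interim(design, dat)
  }
  if (sum(dat$n) < design$n_min %||% 0) {
    cat(sprintf("action: continue (burn-in: %d of %d patients)\n",
                sum(dat$n), design$n_min))
  } else {
    print(dec)
  }
  invisible(list(decision = dec, tox_exceedance = exc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
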