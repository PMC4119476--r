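# Internal numerical utilities: Gauss-Legendre rules, seed plumbing, caches.

.maxed_env <- new.env(parent = emptyenv())

#' @keywords internal
.cache_env <- function(name) {
  if (is.null(.maxed_env[[name]])) {
    e <- new.env(parent = emptyenv())
    e$hits <- 0L
    e$misses <- 0L
    e$store <- new.env(parent = emptyenv())
    .maxed_env[[name]] <- e
  }
  .maxed_env[[name]]
}

.cache_get <- function(cache, key, compute) {
  v <- cache$store[[key]]
  if (!is.null(v)) {
    cache$hits <- cache$hits + 1L
    return(v)
  }
  cache$misses <- cache$misses + 1L
  v <- compute()
  cache$store[[key]] <- v
  v
}

#' Report or reset the internal computation caches
#'
#' Marginal likelihoods, toxicity exceedance probabilities and the BMA prior
#' grid are memoised by sufficient statistic so that continuous monitoring of
#' thousands of simulated trials revisits, rather than recomputes, the small
#' lattice of data states.  `cache_info()` returns hit/miss counters per
#' cache; `cache_clear()` empties all caches (and zeroes the counters).
#'
#' @return `cache_info()`: a data frame with one row per cache.
#' @export
cache_info <- function() {
  nm <- ls(.maxed_env)
  if (length(nm) == 0L) {
    return(data.frame(cache = character(), hits = integer(),
                      misses = integer(), size = integer()))
  }
  data.frame(
    cache = nm,
    hits = vapply(nm, function(x) .maxed_env[[x]]$hits, integer(1)),
    misses = vapply(nm, function(x) .maxed_env[[x]]$misses, integer(1)),
    size = vapply(nm, function(x) length(ls(.maxed_env[[x]]$store)), integer(1)),
    row.names = NULL
  )
}

#' @rdname cache_info
#' @export
cache_clear <- function() {
  rm(list = ls(.maxed_env), envir = .maxed_env)
  invisible(NULL)
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached by n.
.gauss_legendre <- function(n) {
  cache <- .cache_env("gl")
  .cache_get(cache, as.character(n), function() {
    if (n == 1L) return(list(x = 0, w = 2))
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    list(x = e$values[ord], w = 2 * e$vectors[1L, ord]^2)
  })
}

# Nodes/weights for integration over (a, b).
.gl_interval <- function(a, b, n) {
  g <- .gauss_legendre(n)
  list(x = (a + b) / 2 + (b - a) / 2 * g$x, w = g$w * (b - a) / 2)
}

# Split rule: half the nodes on each side of an interior peak, so sharply
# peaked inverse-moment integrands are resolved.
.gl_split <- function(a, b, split, n) {
  if (is.finite(split) && split > a && split < b) {
    n1 <- ceiling(n / 2)
    g1 <- .gl_interval(a, split, n1)
    g2 <- .gl_interval(split, b, n1)
    list(x = c(g1$x, g2$x), w = c(g1$w, g2$w))
  } else {
    .gl_interval(a, b, n)
  }
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic substream seed from a master seed and integer state key,
# kept below 2^31 - 1.
.derive_seed <- function(master, key) {
  h <- as.double(master) %% 2147483647
  for (k in as.double(key)) {
    h <- (h * 48271 + k + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

.key_num <- function(...) paste(..., sep = "|", collapse = "|")
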