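#' @importFrom stats rnorm sd var cor qr.coef qr.fitted qr.resid setNames
#' @importFrom utils read.delim write.table combn
NULL

## Classed conditions so callers (and tests) can distinguish failure modes.
.mmiStop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "mmiError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    .mmiStop("invalidArgumentError", "`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

.checkFraction <- function(x, name, upper.closed = TRUE) {
  hi.ok <- if (upper.closed) x <= 1 else x < 1
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || !hi.ok)
    .mmiStop("invalidArgumentError", "`%s` must lie in [0,1%s", name,
             if (upper.closed) "]" else ")")
  as.numeric(x)
}

.checkSeed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed != round(seed) || abs(seed) >= 2^31)
    .mmiStop("invalidArgumentError", "`seed` must be a single 32-bit integer")
  as.integer(seed)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards. All stochastic operations in
#' the package route through this helper so that analyses are reproducible
#' without clobbering the user's random stream.
#'
#' @param seed single integer seed (or `NULL` to leave the RNG alone).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- .checkSeed(seed)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Spawn reproducible child seeds from a master seed
#'
#' A collection generated from one master seed must be reproducible yet its
#' member datasets mutually independent. The spawning rule is: seed the RNG
#' with the master seed and draw `n` distinct integers uniformly from
#' 1..(2^31 - 2). Sampling without replacement guarantees that no two children
#' share a seed.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @return Integer vector of length `n` with distinct entries.
#' @export
spawnSeeds <- function(seed, n) {
  n <- .checkCount(n, "n", min = 1L)
  withSeed(seed, sample.int(2147483646L, n))
}

## z-score columns of a matrix; constant columns are reported by name.
.zscore <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  const <- colnames(X)[s == 0 | is.na(s)]
  s[s == 0 | is.na(s)] <- 1
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, s, "/")
  attr(Z, "constant") <- const
  Z
}

## Safe label -> column-name key ("E+M" -> "E_M")
.labelKey <- function(label) gsub("+", "_", label, fixed = TRUE)
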