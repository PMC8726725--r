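# Internal helpers: seed plumbing and small numeric utilities.

#' Derive a child seed from a master seed and a stream index
#'
#' All stochastic operations in the package draw their seeds from one integer
#' master seed through this counter-based scheme, so that independent stages
#' (sources, noise, counts, ...) use decoupled streams while the whole
#' pipeline stays reproducible from a single integer.
#'
#' @param seed master integer seed.
#' @param stream non-negative integer stream counter.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(as.double(seed)) %% m)
  for (k in seq_len(max(1L, length(stream)))) {
    s <- (s * 48271 + as.double(stream[k]) * 1000003 + 12345) %% m
  }
  as.integer(s)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded draws do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Rows of `m` scaled to unit Euclidean norm; all-zero rows left untouched.
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n < 1e-300] <- 1
  m / n
}

unit_cols <- function(m) {
  n <- sqrt(colSums(m^2))
  n[n < 1e-300] <- 1
  sweep(m, 2, n, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
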