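# Internal helpers: seeded evaluation, seed derivation, small numerics.

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`,
#' and restores the previous state on exit, so library functions never
#' clobber a user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a stream to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps values in [1, 2^31 - 2] so they
# remain valid 32-bit integer seeds.
derive_seed <- function(master, index) {
  a <- ((as.double(master) %% 2147483647) * 48271) %% 2147483647
  as.integer((a + as.double(index) * 8191) %% 2147483645) + 1L
}

# Linear interpolation of every row of a matrix onto new x positions.
# Vectorized over rows: one index/weight computation serves all rows.
# Values outside [min(x), max(x)] become NA.
interp_rows <- function(m, x, xout) {
  stopifnot(is.matrix(m), ncol(m) == length(x))
  idx <- findInterval(xout, x)
  n <- length(x)
  out <- matrix(NA_real_, nrow(m), length(xout))
  ok <- idx >= 1L & xout <= x[n]
  i0 <- pmin(pmax(idx[ok], 1L), n - 1L)
  w <- (xout[ok] - x[i0]) / (x[i0 + 1L] - x[i0])
  hit <- idx[ok] == n # exactly the last knot
  w[hit] <- 1
  i0[hit] <- n - 1L
  out[, ok] <- m[, i0, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, i0 + 1L, drop = FALSE] * rep(w, each = nrow(m))
  out
}

# Truncated normal draws via inverse-CDF; bounds are hard guarantees.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
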