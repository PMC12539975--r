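# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval of sorted draws containing the requested
#' posterior mass. Used for all interval reporting in the package; the 0.90
#' default matches the package-wide summary convention.
#'
#' @param x Numeric vector of posterior draws.
#' @param mass Probability mass the interval must contain, in (0, 1).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, mass = 0.90) {
  stopifnot(is.numeric(x), length(x) >= 2, mass > 0, mass < 1)
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(xs[1L], xs[n]))
  widths <- xs[(k + 1L):n] - xs[1L:(n - k)]
  i <- which.min(widths)
  c(xs[i], xs[i + k])
}

# Column-major linear indices of off-diagonal cells of an N x N matrix.
offdiag_indices <- function(n) {
  idx <- seq_len(n * n)
  idx[((idx - 1L) %% n) + 1L != ((idx - 1L) %/% n) + 1L]
}

# Ordered-pair bookkeeping for unordered dyads {i < j}: linear indices of the
# (i, j) and (j, i) cells for each pair, in a fixed pair order.
dyad_index <- function(n) {
  stopifnot(n >= 2)
  i <- sequence(seq_len(n - 1L))
  j <- rep(2L:n, times = 1L:(n - 1L))
  list(
    i = i, j = j, n_pairs = length(i),
    upper = i + (j - 1L) * n,  # cell [i, j], sender i
    lower = j + (i - 1L) * n   # cell [j, i], sender j
  )
}

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

stop_srm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic sub-seed derivation; keeps results < 2^31 for R's RNG.
derive_seed <- function(seed, stream) {
  (as.integer(seed) + 7919L * as.integer(stream)) %% 2147483587L
}
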