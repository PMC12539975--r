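# Constrained correlation objects shared by the simulator and the model.
#
# The dyadic random effects of a multiplex SRM couple the two directions of
# every unordered pair across all M layers, so their correlation matrix is
# 2M x 2M.  Because node labels within a dyad are arbitrary, that matrix must
# have the exchangeable block form
#     rho = [ C  B ]
#           [ B  C ]
# with C an M x M correlation matrix and B symmetric with entries in (-1, 1).
# During inference the constraint is imposed softly, by Normal(0, epsilon)
# penalties on the entrywise deviations from this structure.

#' Multiply a Cholesky factor into a correlation matrix
#'
#' @param factor Lower-triangular matrix with positive diagonal whose rows
#'   have unit norm (a Cholesky factor of a correlation matrix).
#' @return The implied correlation matrix `factor %*% t(factor)`.
#' @export
corr_from_cholesky <- function(factor) {
  stopifnot(is_square_matrix(factor))
  if (any(abs(factor[upper.tri(factor)]) > 1e-10)) {
    stop_srm("Cholesky factor must be lower triangular")
  }
  if (any(diag(factor) <= 0)) stop_srm("Cholesky factor needs a positive diagonal")
  tcrossprod(factor)
}

#' Tie dyadic scale parameters across pair directions
#'
#' The SD of effects on the i-to-j direction must equal the SD on the j-to-i
#' direction in every layer (node labels within a dyad are arbitrary), so only
#' M of the 2M dyadic scales are free.
#'
#' @param free Length-M vector of positive SDs, one per layer.
#' @return Length-2M vector `c(free, free)`, so entry m equals entry m + M.
#' @export
tie_dyadic_sigmas <- function(free) {
  if (!is.numeric(free) || length(free) < 1) stop_srm("free must be a numeric vector")
  if (any(!is.finite(free)) || any(free <= 0)) {
    stop_srm("dyadic scale parameters must be positive")
  }
  c(free, free)
}

#' Soft penalty enforcing the block structure of the dyadic correlation matrix
#'
#' Sums Normal(0, epsilon) log-densities over the deviations
#' `rho[m+M, n+M] - rho[m, n]` (equality of the two within-direction blocks)
#' and `rho[m, n+M] - rho[n, m+M]` (symmetry of the cross-direction block) for
#' all layer pairs m < n.  The penalty is maximal exactly when `rho` has the
#' required block form; for a single layer there are no cross-layer
#' constraints and the penalty is 0.
#'
#' @param rho Symmetric 2M x 2M matrix with unit diagonal.
#' @param epsilon Positive penalty scale (the SD of the constraint prior);
#'   default 0.01.
#' @return Scalar log-density increment.
#' @export
block_structure_penalty <- function(rho, epsilon = 0.01) {
  stopifnot(is_square_matrix(rho))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop_srm("epsilon must be a positive scalar")
  }
  K <- nrow(rho)
  if (K %% 2 != 0) stop_srm("rho must be 2M x 2M")
  M <- K %/% 2
  if (M < 2) return(0)
  lp <- 0
  for (m in seq_len(M - 1)) {
    for (n in (m + 1):M) {
      d_c <- rho[m + M, n + M] - rho[m, n]
      d_b <- rho[m, n + M] - rho[n, m + M]
      lp <- lp + stats::dnorm(d_c, 0, epsilon, log = TRUE) +
        stats::dnorm(d_b, 0, epsilon, log = TRUE)
    }
  }
  lp
}

# Gradient of block_structure_penalty with respect to the Cholesky factor Gam
# of rho = Gam %*% t(Gam).  Returns a K x K matrix (lower triangle relevant).
block_structure_penalty_grad_chol <- function(Gam, epsilon) {
  K <- nrow(Gam)
  M <- K %/% 2
  if (M < 2) return(matrix(0, K, K))
  rho <- tcrossprod(Gam)
  G <- matrix(0, K, K)  # d penalty / d rho[a, b], each scalar placed once
  for (m in seq_len(M - 1)) {
    for (n in (m + 1):M) {
      d_c <- rho[m + M, n + M] - rho[m, n]
      G[m + M, n + M] <- G[m + M, n + M] - d_c / epsilon^2
      G[m, n] <- G[m, n] + d_c / epsilon^2
      d_b <- rho[m, n + M] - rho[n, m + M]
      G[m, n + M] <- G[m, n + M] - d_b / epsilon^2
      G[n, m + M] <- G[n, m + M] + d_b / epsilon^2
    }
  }
  (G + t(G)) %*% Gam
}

#' Assemble a block-structured dyadic correlation matrix
#'
#' Builds the full 2M x 2M dyadic correlation matrix from its within-direction
#' block `C` and cross-direction block `B`.  Not every (C, B) pair yields a
#' positive-definite matrix; the assembly is validated and rejected if not.
#'
#' @param C M x M correlation matrix (within-direction, across layers).
#' @param B M x M symmetric matrix with entries in (-1, 1); its diagonal holds
#'   the within-layer dyadic reciprocity correlations.
#' @param tolerance Nonnegative tolerance used when checking the block
#'   identities of an assembled matrix.
#' @return An object of class `correlation_structure` with fields `m_layers`,
#'   `full`, `C_block`, `B_block`, `tolerance`.
#' @export
make_structured_correlation <- function(C, B, tolerance = 1e-8) {
  stopifnot(is_square_matrix(C), is_square_matrix(B))
  M <- nrow(C)
  if (nrow(B) != M) stop_srm("C and B must have the same dimension")
  if (max(abs(C - t(C))) > 1e-10) stop_srm("C must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-10) stop_srm("C must have a unit diagonal")
  if (max(abs(B - t(B))) > 1e-10) stop_srm("B must be symmetric")
  if (any(abs(B) >= 1)) stop_srm("entries of B must lie in (-1, 1)")
  full <- rbind(cbind(C, B), cbind(B, C))
  ev <- eigen(full, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop_srm("assembled 2M x 2M matrix is not positive definite (min eigenvalue %.3g)",
             min(ev))
  }
  structure(
    list(m_layers = M, full = full, C_block = C, B_block = B,
         tolerance = tolerance),
    class = "correlation_structure"
  )
}

# Check the block identities of a 2M x 2M matrix within tolerance.
is_block_structured <- function(rho, tolerance = 1e-8) {
  K <- nrow(rho)
  M <- K %/% 2
  if (K %% 2 != 0) return(FALSE)
  idx1 <- seq_len(M)
  idx2 <- M + idx1
  C1 <- rho[idx1, idx1, drop = FALSE]
  C2 <- rho[idx2, idx2, drop = FALSE]
  B12 <- rho[idx1, idx2, drop = FALSE]
  max(abs(C1 - C2)) <= tolerance && max(abs(B12 - t(B12))) <= tolerance
}

# ---------------------------------------------------------------------------
# Unconstrained parameterization of a correlation Cholesky factor.
#
# Free parameters z (one per strictly-lower-triangular entry, filled by row)
# map to canonical partial correlations w = tanh(z), from which the factor is
# built row by row so that each row has unit norm.  chol_corr_forward returns
# the factor plus the log Jacobian of the transform; chol_corr_reverse
# backpropagates a gradient with respect to the factor (and, optionally, the
# Jacobian and any terms accumulated on it) to a gradient with respect to z.

chol_corr_tri_index <- function(K) {
  Tidx <- matrix(0L, K, K)
  t <- 0L
  if (K >= 2) {
    for (i in 2:K) for (j in 1:(i - 1)) {
      t <- t + 1L
      Tidx[i, j] <- t
    }
  }
  Tidx
}

chol_corr_forward <- function(z, K) {
  stopifnot(length(z) == K * (K - 1) / 2)
  L <- diag(1, K)
  W <- matrix(0, K, K)
  Fm <- matrix(0, K, K)
  Fm[1, 1] <- 1
  logjac <- 0
  t <- 0L
  if (K >= 2) {
    for (i in 2:K) {
      ssq <- 0
      for (j in 1:(i - 1)) {
        t <- t + 1L
        w <- tanh(z[t])
        f <- sqrt(max(1 - ssq, 1e-300))
        W[i, j] <- w
        Fm[i, j] <- f
        L[i, j] <- w * f
        logjac <- logjac + log1p(-w * w)
        if (j >= 2) logjac <- logjac + log(f)
        ssq <- ssq + L[i, j]^2
      }
      L[i, i] <- sqrt(max(1 - ssq, 1e-300))
      Fm[i, i] <- L[i, i]
    }
  }
  list(L = L, W = W, Fm = Fm, logjac = logjac, K = K)
}

chol_corr_reverse <- function(fwd, gL, include_jacobian = TRUE) {
  K <- fwd$K
  dz <- numeric(K * (K - 1) / 2)
  if (K < 2) return(dz)
  L <- fwd$L; W <- fwd$W; Fm <- fwd$Fm
  t_end <- length(dz)
  # walk rows from the bottom so the flat index can be decremented in step
  t <- t_end
  for (i in K:2) {
    # gradient w.r.t. the running sum of squares ssq_{j} of row i
    dssq <- gL[i, i] * (-0.5 / Fm[i, i])
    for (j in (i - 1):1) {
      w <- W[i, j]; f <- Fm[i, j]
      dL <- gL[i, j] + dssq * 2 * L[i, j]
      dz[t] <- dL * f * (1 - w * w)
      if (include_jacobian) dz[t] <- dz[t] - 2 * w
      if (j >= 2) {
        dssq <- dssq + dL * w * (-0.5 / f)
        if (include_jacobian) dssq <- dssq - 0.5 / (f * f)
      }
      t <- t - 1L
    }
  }
  dz
}

# LKJ density of a correlation Cholesky factor (up to an additive constant):
# sum_k (K - k + 2 eta - 2) log L[k, k].
lkj_chol_log_density <- function(L, eta) {
  K <- nrow(L)
  if (K < 2) return(0)
  k <- 2:K
  sum((K - k + 2 * eta - 2) * log(diag(L)[k]))
}

lkj_chol_grad_diag <- function(L, eta) {
  K <- nrow(L)
  g <- numeric(K)
  if (K >= 2) {
    k <- 2:K
    g[k] <- (K - k + 2 * eta - 2) / diag(L)[k]
  }
  g
}

#' Sample a correlation matrix from the LKJ distribution
#'
#' Onion-method sampler; draws are deterministic given the RNG state, so
#' callers seed before use.  Used for prior baselines in the validation
#' module.
#'
#' @param K Matrix dimension.
#' @param eta Positive LKJ shape; 1 is uniform over correlation matrices,
#'   larger values concentrate toward the identity.
#' @return A K x K correlation matrix.
#' @export
sample_lkj_corr <- function(K, eta = 2.5) {
  stopifnot(K >= 1, eta > 0)
  if (K == 1) return(matrix(1, 1, 1))
  alpha <- eta + (K - 2) / 2
  r12 <- 2 * stats::rbeta(1, alpha, alpha) - 1
  R <- matrix(0, K, K)  # upper-triangular factor, columns have unit norm
  R[1, 1] <- 1
  R[1, 2] <- r12
  R[2, 2] <- sqrt(1 - r12^2)
  if (K > 2) {
    for (m in 2:(K - 1)) {
      alpha <- alpha - 0.5
      y <- stats::rbeta(1, m / 2, alpha)
      zvec <- stats::rnorm(m)
      zvec <- zvec / sqrt(sum(zvec^2))
      R[1:m, m + 1] <- sqrt(y) * zvec
      R[m + 1, m + 1] <- sqrt(1 - y)
    }
  }
  crossprod(R)
}
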