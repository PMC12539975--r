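# Parameter-recovery validation: Frobenius-norm comparison of true,
# posterior, and prior correlation matrices, plus a sweep harness.

#' Frobenius divergence between two matrices
#'
#' `Tr((A - B)' (A - B))`, i.e. the sum of squared entrywise differences
#' (the squared Frobenius norm).  Zero iff the matrices are equal; used to
#' score recovery of correlation matrices.
#'
#' @param true_matrix,estimate Matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
frobenius_divergence <- function(true_matrix, estimate) {
  if (!all(dim(true_matrix) == dim(estimate))) stop_srm("shape mismatch")
  sum((true_matrix - estimate)^2)
}

# Prior-only density over the unconstrained dyadic correlation parameters:
# LKJ + block-structure penalty + transform Jacobian.  Used to draw from the
# penalized prior by short MCMC (there is no closed-form sampler for the
# constrained prior).
structured_prior_density <- function(K, prior) {
  Tz <- (K * (K - 1L)) %/% 2L
  lower_mask <- lower.tri(matrix(0, K, K), diag = TRUE)
  list(
    n_par = Tz,
    lp_grad = function(z) {
      fwd <- chol_corr_forward(z, K)
      Gm <- fwd$L
      lp <- lkj_chol_log_density(Gm, prior$lkj_eta) + fwd$logjac +
        block_structure_penalty(tcrossprod(Gm), prior$epsilon)
      gGm <- block_structure_penalty_grad_chol(Gm, prior$epsilon)
      gGm[!lower_mask] <- 0
      diag(gGm) <- diag(gGm) + lkj_chol_grad_diag(Gm, prior$lkj_eta)
      list(lp = lp, grad = chol_corr_reverse(fwd, gGm, include_jacobian = TRUE))
    })
}

#' Prior baseline distribution of Frobenius divergences
#'
#' Draws correlation matrices from the prior and returns their Frobenius
#' divergence from a fixed true matrix, giving the distribution of the
#' divergence expected with no information from data.  For an unstructured
#' matrix the draws come from the LKJ prior directly; for a
#' `correlation_structure` truth the draws come from the penalized
#' (block-constrained) prior via short MCMC.
#'
#' @param true_matrix True correlation matrix (plain matrix for the
#'   generalized case, or a `correlation_structure` for the dyadic case).
#' @param n_draws Number of prior draws (default 500).
#' @param prior An `srm_priors` object (supplies the LKJ shape and penalty
#'   scale).
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` divergences.
#' @export
prior_norm_baseline <- function(true_matrix, n_draws = 500,
                                prior = prior_settings(), seed = 1L) {
  stopifnot(n_draws >= 1)
  structured <- inherits(true_matrix, "correlation_structure")
  truth <- if (structured) true_matrix$full else true_matrix
  K <- nrow(truth)
  set.seed(as.integer(seed))
  if (!structured) {
    vapply(seq_len(n_draws),
           function(i) frobenius_divergence(truth, sample_lkj_corr(K, prior$lkj_eta)),
           0)
  } else {
    dens <- structured_prior_density(K, prior)
    ch <- nuts_chain(dens$lp_grad, stats::rnorm(dens$n_par, 0, 0.1),
                     n_warmup = 300L, n_sample = n_draws,
                     target_accept = 0.9, max_treedepth = 10L)
    vapply(seq_len(n_draws), function(s) {
      rho <- tcrossprod(chol_corr_forward(ch$draws[s, ], K)$L)
      frobenius_divergence(truth, rho)
    }, 0)
  }
}

# Default truth family for recovery studies: moderate within-layer
# reciprocities, weaker cross-layer ones, unit-scale-ish SDs.
default_truth_family <- function(M) {
  K <- 2 * M
  sr_rho <- diag(K)
  for (m in seq_len(M)) {
    sr_rho[m, M + m] <- sr_rho[M + m, m] <- 0.4   # within-layer generalized
  }
  if (M >= 2) {
    for (m in 1:(M - 1)) for (n in (m + 1):M) {
      sr_rho[m, n] <- sr_rho[n, m] <- 0.15        # sender-sender across layers
      sr_rho[M + m, M + n] <- sr_rho[M + n, M + m] <- 0.15
    }
  }
  C <- diag(M); C[C == 0] <- 0.3
  B <- matrix(0.2, M, M); diag(B) <- 0.6
  srm_parameters(M, eta = rep(-1, M),
                 sr_sigma = rep(0.7, K), sr_rho = sr_rho,
                 dr_sigma = rep(0.8, M),
                 dr_rho = make_structured_correlation(C, B))
}

# HPDI coverage of the generative scalar parameters of a fit.
truth_coverage <- function(fit, truth, mass = 0.90) {
  inside <- function(x, value) {
    h <- hpdi(x, mass)
    value >= h[1] && value <= h[2]
  }
  d <- fit$draws
  M <- fit$map$M
  hits <- logical(0)
  for (m in seq_len(M)) hits <- c(hits, inside(d$eta[, m], truth$eta[m]))
  for (k in seq_len(2 * M)) hits <- c(hits, inside(d$sigma[, k], truth$sr_sigma[k]))
  for (m in seq_len(M)) hits <- c(hits, inside(d$dsigma[, m], truth$dr_sigma[m]))
  if (fit$map$Pf > 0) for (p in seq_len(fit$map$Pf)) for (m in seq_len(M)) {
    hits <- c(hits, inside(d$focal[, m, p], truth$focal_slopes[m, p]))
  }
  if (fit$map$Pt > 0) for (p in seq_len(fit$map$Pt)) for (m in seq_len(M)) {
    hits <- c(hits, inside(d$target[, m, p], truth$target_slopes[m, p]))
  }
  if (fit$map$Pd > 0) for (p in seq_len(fit$map$Pd)) for (m in seq_len(M)) {
    hits <- c(hits, inside(d$dyad[, m, p], truth$dyad_slopes[m, p]))
  }
  hits
}

#' Simulation-based parameter-recovery sweep
#'
#' For each grid cell (layer count M, node count N, outcome mode), simulates
#' a network from a known truth, fits the model, and scores recovery: the
#' posterior distribution of the Frobenius divergence between true and
#' estimated generalized/dyadic correlation matrices, matching prior
#' baselines, and HPDI coverage of the generative scalars.  Failed cells are
#' recorded and the sweep continues.
#'
#' @param grid Data frame with columns `M`, `N`, `mode` (outcome mode).
#' @param truth Function mapping a layer count to an `srm_parameters` object;
#'   defaults to the package's moderate-reciprocity truth family.
#' @param config An `srm_config` for the fits.
#' @param seed Integer seed; each cell derives its own sub-seed.
#' @param exposure Binomial exposure used when `mode == "binomial"`.
#' @param n_prior_draws Prior-baseline draws per cell (default 500).
#' @return Data frame of class `srm_recovery` with one row per cell.
#' @export
recovery_sweep <- function(grid, truth = default_truth_family,
                           config = sampler_config(), seed = 1L,
                           exposure = 10, n_prior_draws = 500) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("M", "N", "mode") %in% names(grid)))
  rows <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    M <- grid$M[cell]; N <- grid$N[cell]; mode <- as.character(grid$mode[cell])
    cell_seed <- derive_seed(seed, cell)
    res <- tryCatch({
      pars <- truth(M)
      sim <- simulate_multiplex_network(
        N, M, pars, outcome_mode = mode,
        exposure = if (mode == "binomial") exposure else NULL,
        seed = cell_seed)
      cfg <- config
      cfg$seed <- derive_seed(cell_seed, 1L)
      fit <- fit_multiplex_model(sim$data, config = cfg)
      S <- nrow(fit$draws$eta)
      frob_rho <- vapply(seq_len(S), function(s)
        frobenius_divergence(pars$sr_rho, fit$draws$rho[s, , ]), 0)
      frob_drho <- vapply(seq_len(S), function(s)
        frobenius_divergence(pars$dr_rho$full, fit$draws$drho[s, , ]), 0)
      base_rho <- prior_norm_baseline(pars$sr_rho, n_prior_draws,
                                      fit$priors, derive_seed(cell_seed, 2L))
      base_drho <- prior_norm_baseline(pars$dr_rho, n_prior_draws,
                                       fit$priors, derive_seed(cell_seed, 3L))
      cov <- truth_coverage(fit, pars)
      data.frame(
        M = M, N = N, mode = mode, seed = cell_seed, ok = TRUE,
        frob_rho_median = stats::median(frob_rho),
        frob_rho_q90 = stats::quantile(frob_rho, 0.9, names = FALSE),
        prior_rho_q10 = stats::quantile(base_rho, 0.1, names = FALSE),
        prior_rho_median = stats::median(base_rho),
        frob_drho_median = stats::median(frob_drho),
        frob_drho_q90 = stats::quantile(frob_drho, 0.9, names = FALSE),
        prior_drho_q10 = stats::quantile(base_drho, 0.1, names = FALSE),
        prior_drho_median = stats::median(base_drho),
        coverage = mean(cov), n_coverage_params = length(cov),
        max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
        n_divergent = sum(fit$sampler$divergences),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("recovery cell (M=%d, N=%d, %s) failed: %s",
                      M, N, mode, conditionMessage(e)), call. = FALSE)
      data.frame(M = M, N = N, mode = mode, seed = cell_seed, ok = FALSE,
                 frob_rho_median = NA, frob_rho_q90 = NA, prior_rho_q10 = NA,
                 prior_rho_median = NA, frob_drho_median = NA,
                 frob_drho_q90 = NA, prior_drho_q10 = NA,
                 prior_drho_median = NA, coverage = NA,
                 n_coverage_params = NA, max_rhat = NA, n_divergent = NA,
                 stringsAsFactors = FALSE)
    })
    rows[[cell]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("srm_recovery", class(out))
  out
}
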