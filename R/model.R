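# Joint log density of the multiplex SRM over unconstrained parameters.
#
# The density is the sum of: the outcome-family log likelihood at the
# assembled linear predictor; unit-normal priors on the raw (non-centred)
# sender/receiver and dyadic effects; exponential priors on all scale
# parameters; normal priors on intercepts, slopes and block offsets; LKJ
# priors on both correlation Cholesky factors; the Normal(0, epsilon) block
# structure penalty on the dyadic correlation matrix; and the log Jacobians
# of the log and Cholesky-correlation transforms.  The gradient is computed
# analytically alongside the value, which is what makes the built-in NUTS
# engine practical.

#' Prior settings for the multiplex SRM
#'
#' Defaults follow the model's weakly regularizing conventions:
#' Exponential(2.5) on sender/receiver and dyadic SDs, LKJ Cholesky(2.5) on
#' both correlation factors, unit-normal priors on intercepts, slopes and
#' block offsets, Exponential(1.0) on the Gaussian residual SD, and a
#' Normal(0, 0.01) penalty scale for the dyadic block-structure constraint.
#'
#' @param sd_rate Rate of the exponential prior on sigma and the dyadic SDs.
#' @param lkj_eta Shape of the LKJ prior on both Cholesky factors.
#' @param slope_sd SD of the normal priors on intercepts/slopes/block offsets.
#' @param psi_rate Rate of the exponential prior on the Gaussian residual SD.
#' @param epsilon Penalty scale (SD) for the dyadic block-structure constraint.
#' @return Object of class `srm_priors`.
#' @export
prior_settings <- function(sd_rate = 2.5, lkj_eta = 2.5, slope_sd = 1,
                           psi_rate = 1.0, epsilon = 0.01) {
  vals <- c(sd_rate, lkj_eta, slope_sd, psi_rate, epsilon)
  if (any(!is.finite(vals)) || any(vals <= 0)) stop_srm("all prior settings must be positive")
  structure(list(sd_rate = sd_rate, lkj_eta = lkj_eta, slope_sd = slope_sd,
                 psi_rate = psi_rate, epsilon = epsilon),
            class = "srm_priors")
}

# Layout of the unconstrained parameter vector.
param_map <- function(n_nodes, n_layers, designs = NULL,
                      outcome_mode = "bernoulli") {
  N <- as.integer(n_nodes); M <- as.integer(n_layers)
  K <- 2L * M
  Np <- (N * (N - 1L)) %/% 2L
  Pf <- if (is.null(designs)) 0L else ncol(designs$focal)
  Pt <- if (is.null(designs)) 0L else ncol(designs$target)
  Pd <- if (is.null(designs)) 0L else dim(designs$dyad)[3]
  block_levels <- if (is.null(designs)) integer() else
    vapply(designs$block, function(b) b$n_levels, 1L)
  Tz <- (K * (K - 1L)) %/% 2L
  sizes <- c(
    eta = M, focal = M * Pf, target = M * Pt, dyad = M * Pd,
    block = sum(M * block_levels^2),
    a_raw = N * K, d_raw = Np * K,
    log_sigma = K, log_dsigma = M,
    z_rho = Tz, z_drho = Tz,
    log_psi = if (outcome_mode == "gaussian") 1L else 0L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  idx <- Map(function(s, e) if (e >= s) s:e else integer(), starts, ends)
  names(idx) <- names(sizes)
  list(N = N, M = M, K = K, Np = Np, Pf = Pf, Pt = Pt, Pd = Pd,
       block_levels = block_levels, Tz = Tz, idx = idx,
       n_par = unname(ends[length(ends)]), outcome_mode = outcome_mode)
}

unpack_params <- function(u, map) {
  ix <- map$idx
  M <- map$M; K <- map$K
  blocks <- NULL
  if (length(map$block_levels)) {
    blocks <- vector("list", length(map$block_levels))
    off <- 0L
    bu <- u[ix$block]
    for (v in seq_along(map$block_levels)) {
      Lv <- map$block_levels[v]
      len <- M * Lv * Lv
      blocks[[v]] <- array(bu[off + seq_len(len)], dim = c(Lv, Lv, M))
      off <- off + len
    }
  }
  list(
    eta = u[ix$eta],
    focal = matrix(u[ix$focal], M, map$Pf),
    target = matrix(u[ix$target], M, map$Pt),
    dyad = matrix(u[ix$dyad], M, map$Pd),
    block = blocks,
    a_raw = matrix(u[ix$a_raw], map$N, K),
    d_raw = matrix(u[ix$d_raw], map$Np, K),
    log_sigma = u[ix$log_sigma],
    log_dsigma = u[ix$log_dsigma],
    z_rho = u[ix$z_rho],
    z_drho = u[ix$z_drho],
    log_psi = if (length(ix$log_psi)) u[ix$log_psi] else NULL)
}

#' Count the unconstrained scalar parameters of a multiplex SRM
#'
#' The dyadic raw effects alone contribute M * N * (N - 1) parameters, so
#' model size scales with the square of the number of nodes.
#'
#' @param n_nodes,n_layers Network size N and layer count M.
#' @param designs Optional `srm_designs`; `NULL` means intercept-only.
#' @param outcome_mode Outcome family (gaussian adds the residual-SD
#'   parameter).
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(n_nodes, n_layers, designs = NULL,
                                  outcome_mode = "bernoulli") {
  param_map(n_nodes, n_layers, designs, outcome_mode)$n_par
}

#' Multiplex SRM log likelihood at a given linear predictor
#'
#' Sums the outcome family's log probability mass/density over all layers and
#' off-diagonal cells; diagonal cells are excluded.
#'
#' @param data A `multiplex_data` object.
#' @param theta N x N x M array of linear-predictor values.
#' @param psi Residual SD (used only for gaussian outcomes).
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(data, theta, psi = 1) {
  stopifnot(inherits(data, "multiplex_data"))
  N <- data$n_nodes; M <- data$n_layers
  if (!is.array(theta) || !all(dim(theta) == c(N, N, M))) {
    stop_srm("theta must be an N x N x M array")
  }
  od <- offdiag_indices(N)
  ll <- 0
  for (m in seq_len(M)) {
    th <- theta[, , m][od]
    g <- data$outcomes[, , m][od]
    ll <- ll + switch(data$outcome_mode,
      bernoulli = sum(stats::dbinom(g, 1L, link_mean(th, data$link_mode), log = TRUE)),
      binomial = {
        e <- data$exposure[, , m][od]
        sum(stats::dbinom(g, e, link_mean(th, data$link_mode), log = TRUE))
      },
      poisson = sum(stats::dpois(g, exp(th), log = TRUE)),
      gaussian = sum(stats::dnorm(g, th, psi, log = TRUE)))
  }
  ll
}

# Family-specific log likelihood (including constants) and score dll/dtheta
# at off-diagonal cells; stable forms used inside the density closure.
family_ll_score <- function(th, g, size, mode, link, psi = NULL) {
  if (mode %in% c("bernoulli", "binomial")) {
    if (link == "logit") {
      # g*log p + (size-g)*log(1-p) collapses to g*th - size*log(1+e^th)
      pos <- th > 0
      e <- exp(-abs(th))
      lse <- log1p(e)                     # log(1 + e^th), overflow-safe
      lse[pos] <- lse[pos] + th[pos]
      denom <- 1 + e
      p <- e / denom
      p[pos] <- 1 / denom[pos]
      list(ll = sum(g * th - size * lse), s = g - size * p)
    } else {  # probit
      logp <- pmax(stats::pnorm(th, log.p = TRUE), -7e2)
      log1mp <- pmax(stats::pnorm(-th, log.p = TRUE), -7e2)
      dln <- stats::dnorm(th, log = TRUE)
      list(ll = sum(g * logp + (size - g) * log1mp),
           s = g * exp(dln - logp) - (size - g) * exp(dln - log1mp))
    }
  } else if (mode == "poisson") {
    eth <- exp(pmin(th, 3e2))
    list(ll = sum(g * th - eth), s = g - eth)
  } else {  # gaussian
    r <- g - th
    n <- length(th)
    list(ll = -n * log(psi) - 0.5 * n * log(2 * pi) - 0.5 * sum(r * r) / psi^2,
         s = r / psi^2,
         dlogpsi = sum(r * r) / psi^2 - n)
  }
}

#' Build the differentiable joint log density of a multiplex SRM
#'
#' Returns a closure evaluating the joint log density and its analytic
#' gradient over the unconstrained parameter vector.  This is the object the
#' NUTS engine samples from; it is exported so the density can be inspected,
#' optimized, or checked against finite differences directly.
#'
#' @param data A `multiplex_data` object.
#' @param designs An `srm_designs` object for the same data.
#' @param priors An `srm_priors` object.
#' @param include_likelihood If `FALSE`, the likelihood term is dropped and
#'   the closure evaluates the (penalized) prior only.
#' @return List with elements `n_par`, `map`, `lp_grad(u)` (returns
#'   `list(lp, grad)`), `lp(u)`, and `unpack(u)`.
#' @export
srm_density <- function(data, designs, priors = prior_settings(),
                        include_likelihood = TRUE) {
  stopifnot(inherits(data, "multiplex_data"), inherits(designs, "srm_designs"),
            inherits(priors, "srm_priors"))
  N <- data$n_nodes; M <- data$n_layers; K <- 2L * M
  map <- param_map(N, M, designs, data$outcome_mode)
  od <- offdiag_indices(N)
  dy <- dyad_index(N)
  i_od <- ((od - 1L) %% N) + 1L
  j_od <- ((od - 1L) %/% N) + 1L
  Xf <- designs$focal; Xt <- designs$target
  Pf <- map$Pf; Pt <- map$Pt; Pd <- map$Pd
  Xd_od <- if (Pd > 0) {
    vapply(seq_len(Pd), function(p) designs$dyad[, , p][od], numeric(length(od)))
  } else matrix(0, length(od), 0)
  n_block <- length(designs$block)
  Iv <- lapply(designs$block, function(b) {
    m <- matrix(0, N, b$n_levels)
    m[cbind(seq_len(N), b$index)] <- 1
    m
  })
  bidx <- lapply(designs$block, function(b) b$index)
  mode <- data$outcome_mode; link <- data$link_mode
  g_od <- lapply(seq_len(M), function(m) data$outcomes[, , m][od])
  e_od <- if (mode == "binomial") {
    lapply(seq_len(M), function(m) data$exposure[, , m][od])
  } else if (mode == "bernoulli") {
    lapply(seq_len(M), function(m) rep(1, length(od)))
  } else NULL
  # constants dropped from the per-eval family terms
  const_ll <- 0
  if (mode == "binomial") {
    const_ll <- sum(vapply(seq_len(M), function(m) sum(lchoose(e_od[[m]], g_od[[m]])), 0))
  } else if (mode == "poisson") {
    const_ll <- -sum(vapply(seq_len(M), function(m) sum(lgamma(g_od[[m]] + 1)), 0))
  }
  lower_mask <- lower.tri(matrix(0, K, K), diag = TRUE)
  ix <- map$idx

  lp_grad <- function(u) {
    p <- unpack_params(u, map)
    sigma <- exp(p$log_sigma)
    dsig <- exp(p$log_dsigma)
    vs <- c(dsig, dsig)
    fr <- chol_corr_forward(p$z_rho, K)
    fd <- chol_corr_forward(p$z_drho, K)
    L <- fr$L; Gm <- fd$L
    # fold the scale vectors into the (small) factors: one N x K product
    A <- p$a_raw %*% t(L * sigma)    # row k of L scaled by sigma[k]
    D <- p$d_raw %*% t(Gm * vs)
    psi <- if (!is.null(p$log_psi)) exp(p$log_psi) else NULL

    lp <- 0
    grad <- numeric(map$n_par)
    dA <- matrix(0, N, K)
    dD <- matrix(0, map$Np, K)
    g_eta <- numeric(M)
    g_focal <- matrix(0, M, Pf); g_target <- matrix(0, M, Pt)
    g_dyad <- matrix(0, M, Pd)
    g_block <- if (n_block) lapply(map$block_levels, function(Lv) array(0, c(Lv, Lv, M))) else NULL
    dlogpsi_acc <- 0

    if (include_likelihood) {
      lp <- lp + const_ll
      for (m in seq_len(M)) {
        af <- p$eta[m] + A[, m]
        if (Pf > 0) af <- af + drop(Xf %*% p$focal[m, ])
        bt <- A[, M + m]
        if (Pt > 0) bt <- bt + drop(Xt %*% p$target[m, ])
        th <- rep(bt, each = N)
        dim(th) <- c(N, N)
        th <- th + af                 # af recycles down columns

        th[dy$upper] <- th[dy$upper] + D[, m]
        th[dy$lower] <- th[dy$lower] + D[, M + m]
        if (Pd > 0) th[od] <- th[od] + drop(Xd_od %*% p$dyad[m, ])
        if (n_block) for (v in seq_len(n_block)) {
          th <- th + p$block[[v]][, , m][bidx[[v]], bidx[[v]]]
        }
        fam <- family_ll_score(th[od], g_od[[m]],
                               if (!is.null(e_od)) e_od[[m]] else NULL,
                               mode, link, psi)
        if (!is.finite(fam$ll)) {
          return(list(lp = -Inf, grad = grad))
        }
        lp <- lp + fam$ll
        if (!is.null(fam$dlogpsi)) dlogpsi_acc <- dlogpsi_acc + fam$dlogpsi
        S <- matrix(0, N, N); S[od] <- fam$s
        rs <- rowSums(S); cs <- colSums(S)
        g_eta[m] <- sum(fam$s)
        dA[, m] <- dA[, m] + rs
        dA[, M + m] <- dA[, M + m] + cs
        if (Pf > 0) g_focal[m, ] <- crossprod(Xf, rs)
        if (Pt > 0) g_target[m, ] <- crossprod(Xt, cs)
        if (Pd > 0) g_dyad[m, ] <- crossprod(Xd_od, fam$s)
        if (n_block) for (v in seq_len(n_block)) {
          g_block[[v]][, , m] <- crossprod(Iv[[v]], S) %*% Iv[[v]]
        }
        dD[, m] <- S[dy$upper]
        dD[, M + m] <- S[dy$lower]
      }
    }

    # backpropagate through the non-centred random-effect assembly
    dsigma_vec <- colSums(dA * A) / sigma
    gA_raw <- dA %*% (L * sigma) - p$a_raw
    gL <- crossprod(dA, p$a_raw) * sigma
    dvs <- colSums(dD * D) / vs
    gD_raw <- dD %*% (Gm * vs) - p$d_raw
    gGm <- crossprod(dD, p$d_raw) * vs

    # unit-normal priors on raw effects
    lp <- lp - 0.5 * sum(p$a_raw^2) - 0.5 * length(p$a_raw) * log(2 * pi)
    lp <- lp - 0.5 * sum(p$d_raw^2) - 0.5 * length(p$d_raw) * log(2 * pi)

    # normal priors on intercepts, slopes, block offsets
    sl2 <- priors$slope_sd^2
    npr <- function(x) sum(stats::dnorm(x, 0, priors$slope_sd, log = TRUE))
    lp <- lp + npr(p$eta) + npr(p$focal) + npr(p$target) + npr(p$dyad)
    g_eta <- g_eta - p$eta / sl2
    if (Pf > 0) g_focal <- g_focal - p$focal / sl2
    if (Pt > 0) g_target <- g_target - p$target / sl2
    if (Pd > 0) g_dyad <- g_dyad - p$dyad / sl2
    if (n_block) for (v in seq_len(n_block)) {
      lp <- lp + npr(p$block[[v]])
      g_block[[v]] <- g_block[[v]] - p$block[[v]] / sl2
    }

    # exponential priors on scales (with log-transform Jacobians)
    lrate <- log(priors$sd_rate)
    lp <- lp + K * lrate - priors$sd_rate * sum(sigma) + sum(p$log_sigma)
    g_lsig <- dsigma_vec * sigma - priors$sd_rate * sigma + 1
    lp <- lp + M * lrate - priors$sd_rate * sum(dsig) + sum(p$log_dsigma)
    g_ldsig <- (dvs[1:M] + dvs[M + 1:M]) * dsig - priors$sd_rate * dsig + 1
    if (!is.null(psi)) {
      lp <- lp + log(priors$psi_rate) - priors$psi_rate * psi + p$log_psi
      g_lpsi <- dlogpsi_acc - priors$psi_rate * psi + 1
    }

    # LKJ priors + transform Jacobians on both correlation factors
    lp <- lp + lkj_chol_log_density(L, priors$lkj_eta) + fr$logjac
    gL[!lower_mask] <- 0
    diag(gL) <- diag(gL) + lkj_chol_grad_diag(L, priors$lkj_eta)
    gz_rho <- chol_corr_reverse(fr, gL, include_jacobian = TRUE)

    rho_d <- tcrossprod(Gm)
    lp <- lp + lkj_chol_log_density(Gm, priors$lkj_eta) + fd$logjac +
      block_structure_penalty(rho_d, priors$epsilon)
    gGm <- gGm + block_structure_penalty_grad_chol(Gm, priors$epsilon)
    gGm[!lower_mask] <- 0
    diag(gGm) <- diag(gGm) + lkj_chol_grad_diag(Gm, priors$lkj_eta)
    gz_drho <- chol_corr_reverse(fd, gGm, include_jacobian = TRUE)

    grad[ix$eta] <- g_eta
    if (Pf > 0) grad[ix$focal] <- as.numeric(g_focal)
    if (Pt > 0) grad[ix$target] <- as.numeric(g_target)
    if (Pd > 0) grad[ix$dyad] <- as.numeric(g_dyad)
    if (n_block) grad[ix$block] <- unlist(lapply(g_block, as.numeric))
    grad[ix$a_raw] <- as.numeric(gA_raw)
    grad[ix$d_raw] <- as.numeric(gD_raw)
    grad[ix$log_sigma] <- g_lsig
    grad[ix$log_dsigma] <- g_ldsig
    grad[ix$z_rho] <- gz_rho
    grad[ix$z_drho] <- gz_drho
    if (length(ix$log_psi)) grad[ix$log_psi] <- g_lpsi
    list(lp = lp, grad = grad)
  }

  list(n_par = map$n_par, map = map,
       lp_grad = lp_grad,
       lp = function(u) lp_grad(u)$lp,
       unpack = function(u) unpack_params(u, map))
}

#' Joint log density of the multiplex SRM at an unconstrained point
#'
#' Convenience wrapper around [srm_density()] for a single evaluation.
#'
#' @inheritParams srm_density
#' @param u Unconstrained parameter vector (length
#'   `count_free_parameters(...)` for the same data/designs).
#' @return Scalar log density.
#' @export
joint_log_density <- function(data, designs, u, priors = prior_settings()) {
  srm_density(data, designs, priors)$lp(u)
}
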