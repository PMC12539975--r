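# Model fitting: run the NUTS engine on the SRM density and package draws
# on constrained scales together with convergence diagnostics.

#' Sampler configuration
#'
#' @param chains Number of MCMC chains (run sequentially).
#' @param warmup_draws,sampling_draws Iterations per chain for adaptation and
#'   retained sampling.
#' @param seed Integer seed; chain c uses a sub-seed derived from it, so the
#'   full fit is reproducible bit-for-bit.
#' @param target_acceptance Dual-averaging target acceptance statistic.
#' @param max_tree_depth Maximum NUTS doubling depth.
#' @param link_mode Optional link override applied to the data before
#'   fitting.
#' @param thin_random_effects Keep every k-th draw of the per-node and
#'   per-dyad random effects (scalar parameters are never thinned); bounds
#'   memory for large N.
#' @return Object of class `srm_config`.
#' @export
sampler_config <- function(chains = 2L, warmup_draws = 1000L, sampling_draws = 1000L,
                           seed = 1L, target_acceptance = 0.9,
                           max_tree_depth = 10L, link_mode = NULL,
                           thin_random_effects = 1L) {
  stopifnot(chains >= 1, warmup_draws > 0, sampling_draws > 0,
            target_acceptance > 0, target_acceptance < 1, max_tree_depth >= 1,
            thin_random_effects >= 1)
  structure(list(chains = as.integer(chains),
                 warmup_draws = as.integer(warmup_draws),
                 sampling_draws = as.integer(sampling_draws),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance,
                 max_tree_depth = as.integer(max_tree_depth),
                 link_mode = link_mode,
                 thin_random_effects = as.integer(thin_random_effects)),
            class = "srm_config")
}

# Labels for the 2M rows/cols of the generalized and dyadic correlation
# matrices, matching the reporting convention for multiplex reciprocity.
generalized_labels <- function(layer_names) {
  c(paste0(layer_names, " (out)"), paste0(layer_names, " (in)"))
}
dyadic_labels <- function(layer_names) {
  c(paste0(layer_names, " (i to j)"), paste0(layer_names, " (j to i)"))
}

#' Fit the Bayesian multiplex social relations model
#'
#' Runs the built-in NUTS engine on the joint log density defined by the
#' data, designs, and priors, then transforms draws to constrained scales.
#' Identical data, configuration, and seed give identical draws.
#'
#' @param data A `multiplex_data` object.
#' @param designs An `srm_designs` object; `NULL` fits the intercept-only
#'   model.
#' @param priors An `srm_priors` object.
#' @param config An `srm_config` object.
#' @param prior_only If `TRUE`, sample from the (penalized) prior with the
#'   likelihood switched off.
#' @return Object of class `srm_fit` containing per-draw constrained
#'   parameters, per-draw random effects, diagnostics, and provenance.
#' @export
fit_multiplex_model <- function(data, designs = NULL, priors = prior_settings(),
                                config = sampler_config(), prior_only = FALSE) {
  stopifnot(inherits(data, "multiplex_data"), inherits(config, "srm_config"))
  if (data$n_nodes < 4) stop_srm("at least 4 nodes are required")
  if (!is.null(config$link_mode) && config$link_mode != data$link_mode) {
    if (!config$link_mode %in% MODE_LINKS[[data$outcome_mode]]) {
      stop_srm("link override '%s' incompatible with outcome mode", config$link_mode)
    }
    data$link_mode <- config$link_mode
  }
  if (is.null(designs)) designs <- build_designs(data)
  od <- offdiag_indices(data$n_nodes)
  for (m in seq_len(data$n_layers)) {
    if (stats::var(data$outcomes[, , m][od]) == 0 && !prior_only) {
      stop_srm(paste0("outcome layer '%s' has zero variance off the diagonal; ",
                      "the SRM cannot separate its components. Check the data ",
                      "or drop the layer."), data$layer_names[m])
    }
  }

  dens <- srm_density(data, designs, priors, include_likelihood = !prior_only)
  map <- dens$map
  N <- map$N; M <- map$M; K <- map$K

  chains <- vector("list", config$chains)
  for (c in seq_len(config$chains)) {
    set.seed(derive_seed(config$seed, c))
    init <- stats::runif(dens$n_par, -0.1, 0.1)
    chains[[c]] <- nuts_chain(dens$lp_grad, init,
                              n_warmup = config$warmup_draws,
                              n_sample = config$sampling_draws,
                              target_accept = config$target_acceptance,
                              max_treedepth = config$max_tree_depth)
  }

  U <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(config$chains), each = config$sampling_draws)
  S <- nrow(U)
  ix <- map$idx

  # constrained scalar draws
  sigma <- exp(U[, ix$log_sigma, drop = FALSE])
  dsigma <- exp(U[, ix$log_dsigma, drop = FALSE])
  psi <- if (length(ix$log_psi)) exp(U[, ix$log_psi]) else NULL
  rho <- array(NA_real_, c(S, K, K))
  drho <- array(NA_real_, c(S, K, K))
  L_list <- vector("list", S)
  G_list <- vector("list", S)
  for (s in seq_len(S)) {
    L_list[[s]] <- chol_corr_forward(U[s, ix$z_rho], K)$L
    G_list[[s]] <- chol_corr_forward(U[s, ix$z_drho], K)$L
    rho[s, , ] <- tcrossprod(L_list[[s]])
    drho[s, , ] <- tcrossprod(G_list[[s]])
  }
  gl <- generalized_labels(data$layer_names)
  dl <- dyadic_labels(data$layer_names)
  dimnames(rho) <- list(NULL, gl, gl)
  dimnames(drho) <- list(NULL, dl, dl)

  block <- NULL
  if (length(map$block_levels)) {
    block <- vector("list", length(map$block_levels))
    names(block) <- names(designs$block)
    off <- 0L
    bu <- U[, ix$block, drop = FALSE]
    for (v in seq_along(map$block_levels)) {
      Lv <- map$block_levels[v]
      len <- M * Lv * Lv
      block[[v]] <- array(bu[, off + seq_len(len), drop = FALSE],
                          dim = c(S, Lv, Lv, M),
                          dimnames = list(NULL, designs$block[[v]]$levels,
                                          designs$block[[v]]$levels,
                                          data$layer_names))
      off <- off + len
    }
  }

  # random-effect draws on constrained scales (optionally thinned)
  re_idx <- seq(1L, S, by = config$thin_random_effects)
  sr_eff <- array(NA_real_, c(length(re_idx), N, K))
  dy_eff <- array(NA_real_, c(length(re_idx), map$Np, K))
  for (t in seq_along(re_idx)) {
    s <- re_idx[t]
    a_raw <- matrix(U[s, ix$a_raw], N, K)
    d_raw <- matrix(U[s, ix$d_raw], map$Np, K)
    sr_eff[t, , ] <- sweep(a_raw %*% t(L_list[[s]]), 2, sigma[s, ], `*`)
    dy_eff[t, , ] <- sweep(d_raw %*% t(G_list[[s]]), 2,
                           c(dsigma[s, ], dsigma[s, ]), `*`)
  }

  lp <- unlist(lapply(chains, `[[`, "lp"))
  draws <- list(
    eta = matrix(U[, ix$eta, drop = FALSE], S, M,
                 dimnames = list(NULL, data$layer_names)),
    focal = array(U[, ix$focal, drop = FALSE], c(S, M, map$Pf),
                  dimnames = list(NULL, data$layer_names, designs$focal_names)),
    target = array(U[, ix$target, drop = FALSE], c(S, M, map$Pt),
                   dimnames = list(NULL, data$layer_names, designs$target_names)),
    dyad = array(U[, ix$dyad, drop = FALSE], c(S, M, map$Pd),
                 dimnames = list(NULL, data$layer_names, designs$dyad_names)),
    block = block,
    sigma = sigma, dsigma = dsigma,
    varsigma = cbind(dsigma, dsigma),   # tied dyadic scales, length 2M
    rho = rho, drho = drho, psi = psi,
    sr_effects = sr_eff, dyad_effects = dy_eff, lp = lp)

  scalar <- build_scalar_matrix(draws, data, designs, map)
  diag_tab <- diagnostics_table(scalar, chain_id, config$chains)

  structure(
    list(draws = draws, scalar = scalar, chain_id = chain_id,
         re_draw_idx = re_idx,
         diagnostics = diag_tab,
         sampler = list(
           stepsize = vapply(chains, `[[`, 0, "stepsize"),
           divergences = vapply(chains, function(x) sum(x$divergent), 0L),
           treedepth = vapply(chains, function(x) mean(x$treedepth), 0)),
         data = data, designs = designs, priors = priors, config = config,
         prior_only = prior_only, map = map,
         provenance = list(
           n_nodes = N, n_layers = M,
           outcome_mode = data$outcome_mode, link_mode = data$link_mode,
           data_checksum = sum(data$outcomes, na.rm = TRUE),
           package_version = tryCatch(
             as.character(utils::packageVersion("srmnet")),
             error = function(e) "unknown"))),
    class = "srm_fit"
  )
}

# Flatten the reported (non-random-effect) parameters to a named draw matrix
# for diagnostics.
build_scalar_matrix <- function(draws, data, designs, map) {
  S <- nrow(draws$eta)
  M <- map$M; K <- map$K
  cols <- list()
  nm <- character()
  add <- function(x, label) { cols[[length(cols) + 1L]] <<- x; nm <<- c(nm, label) }
  for (m in seq_len(M)) add(draws$eta[, m], paste0("eta[", data$layer_names[m], "]"))
  for (p in seq_len(map$Pf)) for (m in seq_len(M)) {
    add(draws$focal[, m, p], paste0("focal[", data$layer_names[m], ",", designs$focal_names[p], "]"))
  }
  for (p in seq_len(map$Pt)) for (m in seq_len(M)) {
    add(draws$target[, m, p], paste0("target[", data$layer_names[m], ",", designs$target_names[p], "]"))
  }
  for (p in seq_len(map$Pd)) for (m in seq_len(M)) {
    add(draws$dyad[, m, p], paste0("dyad[", data$layer_names[m], ",", designs$dyad_names[p], "]"))
  }
  if (!is.null(draws$block)) {
    for (v in names(draws$block)) {
      b <- draws$block[[v]]
      lev <- dimnames(b)[[2]]
      for (m in seq_len(M)) for (uu in seq_along(lev)) for (ww in seq_along(lev)) {
        add(b[, uu, ww, m], paste0("block[", data$layer_names[m], ",", v, ",",
                                   lev[uu], "->", lev[ww], "]"))
      }
    }
  }
  for (k in seq_len(K)) add(draws$sigma[, k], paste0("sigma[", generalized_labels(data$layer_names)[k], "]"))
  for (m in seq_len(M)) add(draws$dsigma[, m], paste0("dsigma[", data$layer_names[m], "]"))
  gl <- generalized_labels(data$layer_names)
  dl <- dyadic_labels(data$layer_names)
  for (a in 1:(K - 1)) for (b in (a + 1):K) {
    add(draws$rho[, a, b], paste0("rho[", gl[a], " x ", gl[b], "]"))
  }
  for (a in 1:(K - 1)) for (b in (a + 1):K) {
    add(draws$drho[, a, b], paste0("drho[", dl[a], " x ", dl[b], "]"))
  }
  if (!is.null(draws$psi)) add(draws$psi, "psi")
  add(draws$lp, "lp__")
  out <- do.call(cbind, cols)
  colnames(out) <- nm
  out
}

#' Split-chain potential scale reduction factor
#'
#' @param mat Iterations x chains matrix of draws for one parameter.
#' @return Split-R-hat (NA for constant draws).
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  S <- nrow(mat)
  half <- S %/% 2L
  if (half < 2) return(NA_real_)
  sp <- cbind(mat[1:half, , drop = FALSE],
              mat[(S - half + 1):S, , drop = FALSE])
  C <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(if (B == 0) NA_real_ else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size (split chains, initial-positive-sequence estimator)
#'
#' @param mat Iterations x chains matrix of draws for one parameter.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(mat) {
  mat <- as.matrix(mat)
  S <- nrow(mat)
  half <- S %/% 2L
  if (half < 4) return(NA_real_)
  sp <- cbind(mat[1:half, , drop = FALSE],
              mat[(S - half + 1):S, , drop = FALSE])
  C <- ncol(sp)
  vars <- apply(sp, 2, stats::var)
  if (all(vars == 0)) return(NA_real_)
  means <- colMeans(sp)
  W <- mean(vars)
  var_plus <- W * (half - 1) / half + stats::var(means)
  lag_max <- half - 1L
  acov <- sapply(seq_len(C), function(c) {
    a <- stats::acf(sp[, c], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer initial monotone positive sequence over lag pairs
  tau <- 1
  t <- 1L
  prev_pair <- Inf
  while (t + 2L <= length(rho)) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(C * half / tau, 1e-3)
}

diagnostics_table <- function(scalar, chain_id, n_chains) {
  S_per <- sum(chain_id == 1L)
  res <- data.frame(parameter = colnames(scalar),
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(ncol(scalar))) {
    mat <- matrix(scalar[, p], S_per, n_chains)
    res$rhat[p] <- if (n_chains >= 2 || S_per >= 4) split_rhat(mat) else NA_real_
    res$ess[p] <- ess_basic(mat)
  }
  res
}

#' Check convergence diagnostics of a fit
#'
#' Flags parameters whose split-R-hat exceeds `rhat_max` or whose effective
#' sample size falls below `ess_min`.
#'
#' @param fit An `srm_fit` object (or a list with elements `scalar`,
#'   `chain_id`, and chain count, for injected draws).
#' @param rhat_max Split-R-hat threshold (default 1.05).
#' @param ess_min Effective-sample-size threshold (default 100).
#' @return List with `pass` (logical), `table` (per-parameter diagnostics
#'   with flags), and `n_divergent` where available.
#' @export
check_diagnostics <- function(fit, rhat_max = 1.05, ess_min = 100) {
  if (inherits(fit, "srm_fit")) {
    n_chains <- fit$config$chains
    if (n_chains < 2) stop_srm("R-hat requires at least 2 chains")
    tab <- fit$diagnostics
    n_div <- sum(fit$sampler$divergences)
  } else {
    n_chains <- length(unique(fit$chain_id))
    if (n_chains < 2) stop_srm("R-hat requires at least 2 chains")
    tab <- diagnostics_table(fit$scalar, fit$chain_id, n_chains)
    n_div <- fit$n_divergent %||% NA_integer_
  }
  tab$rhat_flag <- !is.na(tab$rhat) & tab$rhat > rhat_max
  tab$ess_flag <- !is.na(tab$ess) & tab$ess < ess_min
  list(pass = !any(tab$rhat_flag | tab$ess_flag, na.rm = TRUE),
       table = tab, n_divergent = n_div,
       rhat_max = rhat_max, ess_min = ess_min)
}

#' @export
print.srm_fit <- function(x, ...) {
  cat(sprintf("srm_fit: %d nodes, %d layer(s), %s/%s%s\n",
              x$map$N, x$map$M, x$data$outcome_mode, x$data$link_mode,
              if (x$prior_only) " [prior only]" else ""))
  cat(sprintf("  %d chain(s) x %d draws (warmup %d), %d divergent transition(s)\n",
              x$config$chains, x$config$sampling_draws, x$config$warmup_draws,
              sum(x$sampler$divergences)))
  rh <- x$diagnostics$rhat
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f over %d reported parameters\n",
              max(rh, na.rm = TRUE), min(x$diagnostics$ess, na.rm = TRUE),
              nrow(x$diagnostics)))
  invisible(x)
}
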