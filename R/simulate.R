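# Generative engine for multiplex SRM networks.
#
# Every downstream stage (model, inference, post-processing, validation) is
# exercised against data produced here, so the simulator carries the full
# generative parameter set and returns the latent effects alongside the
# observable network.

#' Generative parameter set for a multiplex SRM
#'
#' @param n_layers Number of network layers M.
#' @param eta Length-M vector of layer intercepts (link scale).
#' @param focal_slopes,target_slopes M x P matrices of per-layer slopes on
#'   node covariates (out-degree and in-degree sides respectively); `NULL`
#'   means no covariate effects.
#' @param dyad_slopes M x P_d matrix of per-layer slopes on dyadic covariates.
#' @param block_params Named list, one entry per block variable, each an
#'   L_v x L_v x M array of tie intercept offsets indexed by (sender block,
#'   receiver block, layer).
#' @param sr_mu Length-2M mean vector for sender/receiver effects (zeros in
#'   almost all applications).
#' @param sr_sigma Length-2M vector of nonnegative SDs: first M entries are
#'   sender-effect SDs per layer, last M receiver-effect SDs.
#' @param sr_rho 2M x 2M generalized-reciprocity correlation matrix (no block
#'   constraint).
#' @param dr_mu Length-M mean vector for dyadic effects (normally zeros).
#' @param dr_sigma Length-M vector of nonnegative dyadic SDs (one per layer;
#'   the two directions of a pair share a scale).
#' @param dr_rho Dyadic-reciprocity correlation: a `correlation_structure`
#'   from [make_structured_correlation()], or a 2M x 2M matrix already in
#'   block form.
#' @param psi Positive Gaussian residual SD (used only in gaussian mode).
#' @return Object of class `srm_parameters`.
#' @export
srm_parameters <- function(n_layers, eta = rep(0, n_layers),
                           focal_slopes = NULL, target_slopes = NULL,
                           dyad_slopes = NULL, block_params = NULL,
                           sr_mu = rep(0, 2 * n_layers),
                           sr_sigma = rep(1, 2 * n_layers),
                           sr_rho = diag(2 * n_layers),
                           dr_mu = rep(0, n_layers),
                           dr_sigma = rep(1, n_layers),
                           dr_rho = NULL, psi = 1) {
  M <- as.integer(n_layers)
  stopifnot(M >= 1)
  K <- 2L * M
  if (length(eta) != M) stop_srm("eta must have length M = %d", M)
  chk_slopes <- function(s, what) {
    if (is.null(s)) return(matrix(0, M, 0))
    s <- as.matrix(s)
    if (nrow(s) != M) stop_srm("%s must have one row per layer", what)
    s
  }
  focal_slopes <- chk_slopes(focal_slopes, "focal_slopes")
  target_slopes <- chk_slopes(target_slopes, "target_slopes")
  dyad_slopes <- chk_slopes(dyad_slopes, "dyad_slopes")
  if (!is.null(block_params)) {
    if (!is.list(block_params) || is.null(names(block_params))) {
      stop_srm("block_params must be a named list, one entry per block variable")
    }
    block_params <- lapply(block_params, function(b) {
      b <- if (is.list(b)) array(unlist(b), dim = c(nrow(b[[1]]), ncol(b[[1]]), length(b))) else b
      if (!is.array(b) || length(dim(b)) != 3 || dim(b)[1] != dim(b)[2] || dim(b)[3] != M) {
        stop_srm("each block_params entry must be an L x L x M array")
      }
      b
    })
  }
  if (length(sr_mu) != K || length(sr_sigma) != K) stop_srm("sr_mu and sr_sigma must have length 2M")
  if (any(sr_sigma < 0)) stop_srm("sr_sigma must be nonnegative")
  stopifnot(is_square_matrix(sr_rho), nrow(sr_rho) == K)
  if (max(abs(sr_rho - t(sr_rho))) > 1e-10 || max(abs(diag(sr_rho) - 1)) > 1e-10) {
    stop_srm("sr_rho must be a correlation matrix")
  }
  if (min(eigen(sr_rho, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop_srm("sr_rho must be positive definite")
  }
  if (length(dr_mu) != M || length(dr_sigma) != M) stop_srm("dr_mu and dr_sigma must have length M")
  if (any(dr_sigma < 0)) stop_srm("dr_sigma must be nonnegative")
  if (is.null(dr_rho)) {
    dr_rho <- make_structured_correlation(diag(M), matrix(0, M, M))
  } else if (!inherits(dr_rho, "correlation_structure")) {
    stopifnot(is_square_matrix(dr_rho), nrow(dr_rho) == K)
    if (!is_block_structured(dr_rho, 1e-8)) {
      stop_srm("dr_rho must have the exchangeable block structure [C B; B C]")
    }
    dr_rho <- make_structured_correlation(dr_rho[1:M, 1:M, drop = FALSE],
                                          dr_rho[1:M, M + 1:M, drop = FALSE])
  }
  if (dr_rho$m_layers != M) stop_srm("dr_rho has the wrong number of layers")
  if (!is.numeric(psi) || psi <= 0) stop_srm("psi must be positive")
  structure(
    list(n_layers = M, eta = as.numeric(eta),
         focal_slopes = focal_slopes, target_slopes = target_slopes,
         dyad_slopes = dyad_slopes, block_params = block_params,
         sr_mu = as.numeric(sr_mu), sr_sigma = as.numeric(sr_sigma),
         sr_rho = sr_rho, dr_mu = as.numeric(dr_mu),
         dr_sigma = as.numeric(dr_sigma), dr_rho = dr_rho,
         psi = as.numeric(psi)),
    class = "srm_parameters"
  )
}

#' Draw correlated sender/receiver random effects
#'
#' Each node's length-2M effect vector (sender effects for all layers, then
#' receiver effects) is `sr_mu + sr_sigma * (L g)` with `g` iid standard
#' normal and `L` the Cholesky factor of `sr_rho`; rows are independent
#' across nodes.
#'
#' @param params An `srm_parameters` object.
#' @param n_nodes Number of nodes N.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return N x 2M matrix; columns 1..M are sender effects, M+1..2M receiver.
#' @export
sample_sr_effects <- function(params, n_nodes, seed = NULL) {
  stopifnot(inherits(params, "srm_parameters"))
  if (!is.null(seed)) set.seed(seed)
  K <- 2L * params$n_layers
  L <- t(chol(params$sr_rho))
  G <- matrix(stats::rnorm(n_nodes * K), n_nodes, K)
  A <- tcrossprod(G, L)           # rows = L %*% g
  A <- sweep(A, 2, params$sr_sigma, `*`)
  sweep(A, 2, params$sr_mu, `+`)
}

#' Draw correlated dyad-level random effects
#'
#' For each unordered pair {i < j} one 2M-vector is drawn with per-direction
#' scales `c(dr_sigma, dr_sigma)` and correlation `dr_rho`; the first M
#' entries become the i-to-j effects across layers and the last M the j-to-i
#' effects.  The block structure of `dr_rho` and the tied scales make the
#' joint law exchangeable in the pair labels.
#'
#' @inheritParams sample_sr_effects
#' @return N x N x M array of dyadic effects with zero diagonal; the per-pair
#'   draw matrix is attached as attribute `"pair_matrix"`.
#' @export
sample_dyadic_effects <- function(params, n_nodes, seed = NULL) {
  stopifnot(inherits(params, "srm_parameters"))
  if (!is.null(seed)) set.seed(seed)
  M <- params$n_layers
  K <- 2L * M
  dy <- dyad_index(n_nodes)
  Gam <- t(chol(params$dr_rho$full))
  vs <- c(params$dr_sigma, params$dr_sigma)  # tied across pair directions
  W <- matrix(stats::rnorm(dy$n_pairs * K), dy$n_pairs, K)
  D <- tcrossprod(W, Gam)
  D <- sweep(D, 2, vs, `*`)
  D <- sweep(D, 2, c(params$dr_mu, params$dr_mu), `+`)
  delta <- array(0, dim = c(n_nodes, n_nodes, M))
  for (m in seq_len(M)) {
    dm <- matrix(0, n_nodes, n_nodes)
    dm[dy$upper] <- D[, m]
    dm[dy$lower] <- D[, M + m]
    delta[, , m] <- dm
  }
  attr(delta, "pair_matrix") <- D
  attr(delta, "pair_index") <- dy
  delta
}

#' Block intercept offset for a dyad
#'
#' Sums, over block variables v, the offset indexed by the sender's and
#' receiver's block memberships: `sum_v B_v[b(i,v), b(j,v), m]`.  With no
#' block variables the offset is 0.
#'
#' @param block_params Named list of L_v x L_v x M offset arrays (as in
#'   [srm_parameters()]); `NULL` for none.
#' @param block_design Block part of an `srm_designs` object (list with an
#'   integer membership `index` per variable).
#' @param i,j Sender and receiver node indices (vectorized, recycled).
#' @param m Layer index.
#' @return Numeric vector of offsets.
#' @export
block_offset <- function(block_params, block_design, i, j, m) {
  n <- max(length(i), length(j))
  out <- numeric(n)
  if (is.null(block_params) || length(block_design) == 0) return(out)
  if (length(block_params) != length(block_design)) {
    stop_srm("block_params and block_design disagree on the number of variables")
  }
  i <- rep_len(i, n); j <- rep_len(j, n)
  for (v in seq_along(block_design)) {
    b <- block_design[[v]]$index
    Bv <- block_params[[v]]
    if (max(b) > dim(Bv)[1]) stop_srm("block index exceeds declared level range")
    out <- out + Bv[, , m][cbind(b[i], b[j])]
  }
  out
}

#' Linear predictor of the multiplex SRM
#'
#' Assembles the link-scale predictor for sender i, receiver j, layer m:
#' intercept + sender effect + receiver effect + dyadic effect + block offset
#' + focal, target and dyadic covariate terms.
#'
#' @param params An `srm_parameters` object.
#' @param sr_effects N x 2M matrix from [sample_sr_effects()].
#' @param dyadic_effects N x N x M array from [sample_dyadic_effects()].
#' @param designs An `srm_designs` object (covariate stores may be empty).
#' @param i,j Node index vectors (recycled; `i == j` is an error).
#' @param m Layer index.
#' @return Numeric vector of predictor values theta[i, j, m].
#' @export
linear_predictor <- function(params, sr_effects, dyadic_effects, designs, i, j, m) {
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  if (any(i == j)) stop_srm("the linear predictor is undefined on the diagonal (i == j)")
  M <- params$n_layers
  th <- params$eta[m] + sr_effects[i, m] + sr_effects[j, M + m] +
    dyadic_effects[cbind(i, j, m)] +
    block_offset(params$block_params, designs$block, i, j, m)
  if (ncol(designs$focal) > 0) {
    th <- th + drop(designs$focal[i, , drop = FALSE] %*% params$focal_slopes[m, ])
  }
  if (ncol(designs$target) > 0) {
    th <- th + drop(designs$target[j, , drop = FALSE] %*% params$target_slopes[m, ])
  }
  if (dim(designs$dyad)[3] > 0) {
    for (p in seq_len(dim(designs$dyad)[3])) {
      th <- th + designs$dyad[, , p][cbind(i, j)] * params$dyad_slopes[m, p]
    }
  }
  th
}

# Designs straight from covariate stores (no multiplex_data needed): the
# simulator applies slopes to covariates exactly as provided.
designs_from_covariates <- function(n_nodes, node_covariates = NULL,
                                    dyad_covariates = NULL, block_factors = NULL) {
  node_form <- if (is.null(node_covariates) || ncol(node_covariates) == 0) ~1 else
    stats::reformulate(names(node_covariates))
  dyad_form <- if (is.null(dyad_covariates) || length(dyad_covariates) == 0) ~1 else
    stats::reformulate(names(dyad_covariates))
  block_form <- if (is.null(block_factors) || ncol(block_factors) == 0) ~1 else
    stats::reformulate(names(block_factors))
  # reuse the validated builder through a shell data object
  shell <- multiplex_data(
    outcomes = stats::setNames(list(matrix(0, n_nodes, n_nodes)), "shell"),
    node_covariates = node_covariates, dyad_covariates = dyad_covariates,
    block_factors = block_factors, outcome_mode = "gaussian",
    link_mode = "identity")
  build_designs(shell, block_regression = block_form,
                focal_regression = node_form, target_regression = node_form,
                dyad_regression = dyad_form, standardize = FALSE)
}

link_mean <- function(theta, link_mode) {
  switch(link_mode,
    logit = stats::plogis(theta),
    probit = stats::pnorm(theta),
    log = exp(theta),
    identity = theta,
    stop_srm("unknown link_mode '%s'", link_mode))
}

#' Simulate a multiplex network from known parameters
#'
#' Draws sender/receiver and dyadic random effects, assembles the linear
#' predictor for every ordered pair, and samples outcomes under the requested
#' family and link.  Covariates may be supplied (data frame / list of
#' matrices / factors) or requested by count, in which case numeric
#' covariates are iid standard normal, dyadic covariates iid standard normal
#' matrices, and block memberships uniform over levels.
#'
#' @param n_nodes,n_layers Network size N and layer count M.
#' @param params An `srm_parameters` object with matching dimensions.
#' @param node_covariates Data frame of node covariates, or an integer number
#'   of standard-normal covariates to generate, or `NULL`.
#' @param dyad_covariates Named list of N x N matrices, or an integer count
#'   to generate, or `NULL`.
#' @param block_factors Data frame of factors, or an integer vector of level
#'   counts to generate (one entry per block variable), or `NULL`.
#' @param outcome_mode One of "bernoulli", "binomial", "poisson", "gaussian".
#' @param link_mode Link (defaults to the family's standard link).
#' @param exposure Binomial trial counts: a single nonnegative integer, an
#'   N x N matrix, or a list of per-layer matrices.  Required for binomial.
#' @param layer_names Optional layer labels.
#' @param seed Integer seed; one seed controls all draws.
#' @return Object of class `sim_multiplex`: `data` (a `multiplex_data`),
#'   `truth` (the parameters), `latent` (sr effects, dyadic effects, theta
#'   array), `designs`, and `seed`.
#' @export
simulate_multiplex_network <- function(n_nodes, n_layers, params,
                                       node_covariates = NULL,
                                       dyad_covariates = NULL,
                                       block_factors = NULL,
                                       outcome_mode = c("bernoulli", "binomial", "poisson", "gaussian"),
                                       link_mode = NULL, exposure = NULL,
                                       layer_names = NULL, seed = 1L) {
  outcome_mode <- match.arg(outcome_mode)
  link_mode <- link_mode %||% MODE_LINKS[[outcome_mode]][1]
  if (!link_mode %in% MODE_LINKS[[outcome_mode]]) {
    stop_srm("link_mode '%s' is incompatible with outcome_mode '%s'", link_mode, outcome_mode)
  }
  stopifnot(inherits(params, "srm_parameters"))
  M <- params$n_layers
  if (M != n_layers) stop_srm("params are for %d layers, not %d", M, n_layers)
  N <- as.integer(n_nodes)
  layer_names <- layer_names %||% paste0("layer_", seq_len(M))
  if (outcome_mode == "binomial" && is.null(exposure)) {
    stop_srm("exposure required for binomial simulation")
  }

  set.seed(as.integer(seed))

  if (is.numeric(node_covariates) && length(node_covariates) == 1) {
    node_covariates <- as.data.frame(
      stats::setNames(replicate(node_covariates, stats::rnorm(N), simplify = FALSE),
                      paste0("X", seq_len(node_covariates))))
  }
  if (is.numeric(dyad_covariates) && length(dyad_covariates) == 1) {
    k <- dyad_covariates
    dyad_covariates <- stats::setNames(
      replicate(k, matrix(stats::rnorm(N * N), N, N), simplify = FALSE),
      paste0("D", seq_len(k)))
    dyad_covariates <- lapply(dyad_covariates, function(d) { diag(d) <- 0; d })
  }
  if (is.numeric(block_factors)) {
    lv <- as.integer(block_factors)
    block_factors <- as.data.frame(
      stats::setNames(lapply(seq_along(lv), function(v) {
        factor(sample(LETTERS[seq_len(lv[v])], N, replace = TRUE),
               levels = LETTERS[seq_len(lv[v])])
      }), paste0("B", seq_along(lv))))
  }

  designs <- designs_from_covariates(N, node_covariates, dyad_covariates, block_factors)
  if (ncol(designs$focal) != ncol(params$focal_slopes)) {
    stop_srm("focal_slopes have %d columns but the focal design has %d",
             ncol(params$focal_slopes), ncol(designs$focal))
  }
  if (ncol(designs$target) != ncol(params$target_slopes)) {
    stop_srm("target_slopes do not match the target design")
  }
  if (dim(designs$dyad)[3] != ncol(params$dyad_slopes)) {
    stop_srm("dyad_slopes do not match the dyadic design")
  }
  if (!is.null(params$block_params) && length(params$block_params) != length(designs$block)) {
    stop_srm("block_params do not match the block design")
  }

  sr <- sample_sr_effects(params, N)
  delta <- sample_dyadic_effects(params, N)

  E_layers <- NULL
  if (outcome_mode == "binomial") {
    one_layer <- function(e) {
      if (length(e) == 1) matrix(as.integer(e), N, N) else {
        stopifnot(is_square_matrix(e), nrow(e) == N)
        matrix(as.integer(e), N, N)
      }
    }
    E_layers <- if (is.list(exposure)) lapply(exposure, one_layer)
                else replicate(M, one_layer(exposure), simplify = FALSE)
    if (length(E_layers) != M) stop_srm("exposure list must have one entry per layer")
    names(E_layers) <- layer_names
  }

  od <- offdiag_indices(N)
  idx_i <- rep(seq_len(N), times = N)[od]
  idx_j <- rep(seq_len(N), each = N)[od]
  theta <- array(0, dim = c(N, N, M))
  G_layers <- vector("list", M)
  for (m in seq_len(M)) {
    th <- matrix(0, N, N)
    th[od] <- linear_predictor(params, sr, delta, designs, idx_i, idx_j, m)
    theta[, , m] <- th
    mu <- link_mean(th[od], link_mode)
    g <- matrix(0, N, N)
    g[od] <- switch(outcome_mode,
      bernoulli = stats::rbinom(length(od), 1L, mu),
      binomial  = stats::rbinom(length(od), E_layers[[m]][od], mu),
      poisson   = stats::rpois(length(od), mu),
      gaussian  = stats::rnorm(length(od), th[od], params$psi))
    G_layers[[m]] <- g
  }
  names(G_layers) <- layer_names

  data <- multiplex_data(G_layers, exposure = E_layers,
                         node_covariates = node_covariates,
                         dyad_covariates = dyad_covariates,
                         block_factors = block_factors,
                         outcome_mode = outcome_mode, link_mode = link_mode)

  structure(
    list(data = data, truth = params,
         latent = list(sr_effects = sr, dyadic_effects = delta, theta = theta),
         designs = designs, seed = as.integer(seed)),
    class = "sim_multiplex"
  )
}

#' Write a parameter manifest for exact re-simulation
#'
#' Serializes an `srm_parameters` object plus the simulation seed as JSON.
#'
#' @param params An `srm_parameters` object.
#' @param seed Integer seed used (or to be used) for simulation.
#' @param path Output file path.
#' @export
write_parameter_manifest <- function(params, seed, path) {
  stopifnot(inherits(params, "srm_parameters"))
  out <- list(
    n_layers = params$n_layers, eta = params$eta,
    focal_slopes = params$focal_slopes, target_slopes = params$target_slopes,
    dyad_slopes = params$dyad_slopes,
    block_params = lapply(params$block_params, function(b) {
      list(dim = dim(b), values = as.numeric(b))
    }),
    sr_mu = params$sr_mu, sr_sigma = params$sr_sigma, sr_rho = params$sr_rho,
    dr_mu = params$dr_mu, dr_sigma = params$dr_sigma,
    dr_rho_C = params$dr_rho$C_block, dr_rho_B = params$dr_rho$B_block,
    psi = params$psi, seed = as.integer(seed))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' Read a parameter manifest written by [write_parameter_manifest()]
#'
#' @param path Manifest file path.
#' @return List with `params` (an `srm_parameters` object) and `seed`.
#' @export
read_parameter_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- j$n_layers
  mk_mat <- function(x, nr) if (is.null(x) || length(x) == 0) NULL else matrix(unlist(x), nrow = nr)
  block <- NULL
  if (!is.null(j$block_params) && length(j$block_params)) {
    block <- lapply(j$block_params, function(b) array(b$values, dim = b$dim))
  }
  params <- srm_parameters(
    n_layers = M, eta = j$eta,
    focal_slopes = mk_mat(j$focal_slopes, M), target_slopes = mk_mat(j$target_slopes, M),
    dyad_slopes = mk_mat(j$dyad_slopes, M), block_params = block,
    sr_mu = j$sr_mu, sr_sigma = j$sr_sigma, sr_rho = matrix(unlist(j$sr_rho), 2 * M),
    dr_mu = j$dr_mu, dr_sigma = j$dr_sigma,
    dr_rho = make_structured_correlation(matrix(unlist(j$dr_rho_C), M),
                                         matrix(unlist(j$dr_rho_B), M)),
    psi = j$psi)
  list(params = params, seed = j$seed)
}
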