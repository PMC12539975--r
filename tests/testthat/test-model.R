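# Joint density: likelihood oracles, gradient correctness, parameter
# counting, non-centred equivalence, exchangeability.

test_that("parameter counts match direct enumeration", {
  # analytic oracle assembled term by term
  count_oracle <- function(N, M, Pf = 0, Pt = 0, Pd = 0, levels = integer(),
                           gaussian = FALSE) {
    K <- 2 * M
    M + M * (Pf + Pt + Pd) + sum(M * levels^2) + N * K + M * N * (N - 1) +
      K + M + 2 * (K * (K - 1) / 2) + as.integer(gaussian)
  }
  expect_equal(count_free_parameters(250, 4), count_oracle(250, 4))
  expect_equal(count_free_parameters(10, 1), count_oracle(10, 1))
  expect_equal(count_free_parameters(10, 1, outcome_mode = "gaussian"),
               count_oracle(10, 1, gaussian = TRUE))
  # the dyadic raw effects alone: M * N * (N-1)
  expect_equal(4 * 250 * 249, 249000)
  # one focal covariate adds exactly M parameters
  sim <- quick_sim(N = 10, seed = 2)
  set.seed(2)
  dat <- multiplex_data(
    setNames(lapply(1:2, function(m) sim$data$outcomes[, , m]),
             sim$data$layer_names),
    node_covariates = data.frame(X1 = rnorm(10)),
    outcome_mode = "bernoulli")
  d0 <- build_designs(dat)
  d1 <- build_designs(dat, focal_regression = ~X1)
  expect_equal(count_free_parameters(10, 2, d1) - count_free_parameters(10, 2, d0),
               2)
})

test_that("log likelihood matches closed forms and the per-cell oracle", {
  # fair-coin mass: 1 layer, N = 3, theta = 0 -> 6 * log(0.5)
  g <- matrix(c(0, 1, 0, 1, 0, 0, 1, 1, 0), 3, 3); diag(g) <- 0
  d <- multiplex_data(list(l = g), outcome_mode = "bernoulli")
  expect_equal(log_likelihood(d, array(0, c(3, 3, 1))), 6 * log(0.5))
  # zero-exposure cells contribute nothing, whatever theta is
  e0 <- matrix(0L, 4, 4)
  d0 <- multiplex_data(list(l = matrix(0, 4, 4)), exposure = list(l = e0),
                       outcome_mode = "binomial")
  th_a <- array(0, c(4, 4, 1)); th_b <- array(3, c(4, 4, 1))
  expect_equal(log_likelihood(d0, th_a), log_likelihood(d0, th_b))
  expect_equal(log_likelihood(d0, th_b), 0)
  # random instances vs brute-force double loop, all four families
  for (mode in c("bernoulli", "binomial", "poisson", "gaussian")) {
    sim <- quick_sim(N = 6, mode = mode, seed = 31)
    th <- sim$latent$theta + 0.1
    expect_equal(log_likelihood(sim$data, th, psi = 1),
                 oracle_loglik(sim$data, th, psi = 1), tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences, all families", {
  set.seed(51)
  truth <- srm_parameters(2, eta = c(-0.5, 0.2),
                          focal_slopes = matrix(c(0.4, -0.2), 2, 1),
                          target_slopes = matrix(c(0.1, 0.3), 2, 1),
                          dyad_slopes = matrix(c(0.2, -0.1), 2, 1),
                          block_params = list(B1 = array(rnorm(8, 0, 0.4), c(2, 2, 2))),
                          sr_sigma = rep(0.8, 4), dr_sigma = c(0.7, 0.9),
                          psi = 0.8)
  cases <- list(c("bernoulli", "logit"), c("binomial", "probit"),
                c("poisson", "log"), c("gaussian", "identity"))
  for (cs in cases) {
    sim <- simulate_multiplex_network(
      6, 2, truth, node_covariates = 1, dyad_covariates = 1, block_factors = 2L,
      outcome_mode = cs[1], link_mode = cs[2],
      exposure = if (cs[1] == "binomial") 5 else NULL, seed = 52)
    des <- build_designs(sim$data, ~B1, ~X1, ~X1, ~D1)
    dens <- srm_density(sim$data, des)
    u <- rnorm(dens$n_par, 0, 0.3)
    r <- dens$lp_grad(u)
    h <- 1e-5
    fd <- vapply(seq_len(dens$n_par), function(t) {
      up <- u; um <- u
      up[t] <- up[t] + h; um[t] <- um[t] - h
      (dens$lp(up) - dens$lp(um)) / (2 * h)
    }, 0)
    expect_lt(max(abs(r$grad - fd) / (abs(fd) + 1e-4)), 1e-5)
  }
})

test_that("with scales near zero, raw dyadic effects decouple from the likelihood", {
  sim <- quick_sim(N = 6, seed = 61)
  dens <- srm_density(sim$data, build_designs(sim$data))
  map <- dens$map
  u <- numeric(dens$n_par)
  u[map$idx$log_sigma] <- -20
  u[map$idx$log_dsigma] <- -20
  u2 <- u
  k <- map$idx$d_raw[1]
  u2[k] <- 1.3
  # the lp difference is exactly the unit-normal prior difference
  expect_equal(dens$lp(u2) - dens$lp(u), dnorm(1.3, log = TRUE) - dnorm(0, log = TRUE),
               tolerance = 1e-8)
})

test_that("a single-layer model has no cross-layer coupling", {
  sim <- quick_sim(N = 7, M = 1, seed = 71)
  dens <- srm_density(sim$data, build_designs(sim$data))
  u <- rnorm(dens$n_par, 0, 0.2)
  expect_true(is.finite(dens$lp(u)))
  # the block-structure penalty is vacuous for M = 1 ...
  fd <- srmnet:::chol_corr_forward(u[dens$map$idx$z_drho], 2)
  expect_equal(block_structure_penalty(tcrossprod(fd$L), 0.01), 0)
  # ... so the density decomposes into likelihood + standard SRM priors:
  # check against a hand-assembled single-layer density at the same point
  p <- dens$unpack(u)
  sigma <- exp(p$log_sigma); dsig <- exp(p$log_dsigma)
  L <- srmnet:::chol_corr_forward(p$z_rho, 2)
  A <- sweep(p$a_raw %*% t(L$L), 2, sigma, `*`)
  Gm <- srmnet:::chol_corr_forward(p$z_drho, 2)
  D <- sweep(p$d_raw %*% t(Gm$L), 2, c(dsig, dsig), `*`)
  N <- 7
  dy <- srmnet:::dyad_index(N)
  th <- array(0, c(N, N, 1))
  for (i in 1:N) for (j in 1:N) if (i != j) th[i, j, 1] <- p$eta + A[i, 1] + A[j, 2]
  th[, , 1][dy$upper] <- th[, , 1][dy$upper] + D[, 1]
  th[, , 1][dy$lower] <- th[, , 1][dy$lower] + D[, 2]
  manual <- log_likelihood(sim$data, th) +
    sum(dnorm(p$a_raw, log = TRUE)) + sum(dnorm(p$d_raw, log = TRUE)) +
    dnorm(p$eta, log = TRUE) +
    sum(dexp(sigma, 2.5, log = TRUE)) + sum(p$log_sigma) +
    dexp(dsig, 2.5, log = TRUE) + p$log_dsigma +
    srmnet:::lkj_chol_log_density(L$L, 2.5) + L$logjac +
    srmnet:::lkj_chol_log_density(Gm$L, 2.5) + Gm$logjac
  expect_equal(dens$lp(u), manual, tolerance = 1e-8)
})

test_that("non-centred assembly reproduces the multivariate normal law", {
  # pushforward of iid normals through scale * (L z) has covariance
  # diag(sigma) rho diag(sigma); Monte Carlo vs the analytic target
  set.seed(81)
  M <- 2
  rho <- sample_lkj_corr(4, 2)
  sigma <- c(0.6, 1.2, 0.9, 0.5)
  pars <- srm_parameters(M, sr_sigma = sigma, sr_rho = rho)
  draws <- sample_sr_effects(pars, 1e5, seed = 82)
  target <- diag(sigma) %*% rho %*% diag(sigma)
  emp <- cov(draws)
  n <- nrow(draws)
  for (a in 1:4) for (b in 1:4) {
    se <- sqrt((target[a, a] * target[b, b] + target[a, b]^2) / n)
    expect_lt(abs(emp[a, b] - target[a, b]), 3 * se)
  }
})

test_that("the joint density respects node-relabeling exchangeability", {
  # Relabeling nodes permutes sender/receiver rows and maps each dyad's raw
  # 2M-vector through Gamma^-1 P Gamma (P swaps halves when the pair order
  # flips), which reproduces the permuted dyadic effects exactly.  The
  # likelihood, scale, and correlation terms are then all invariant, so the
  # density can shift only by the unit-normal prior on the transformed raw
  # vectors; when the dyadic correlation is exactly block-structured that
  # map is orthogonal and even this shift vanishes.
  set.seed(91)
  sim <- quick_sim(N = 6, seed = 91)
  dens <- srm_density(sim$data, build_designs(sim$data))
  u <- rnorm(dens$n_par, 0, 0.3)
  N <- 6; M <- 2; K <- 4
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  G2 <- sim$data$outcomes[perm, perm, , drop = FALSE]
  d2 <- multiplex_data(setNames(lapply(1:M, function(m) G2[, , m]),
                                sim$data$layer_names),
                       outcome_mode = "bernoulli")
  dens2 <- srm_density(d2, build_designs(d2))
  map <- dens$map
  u2 <- u
  a_raw <- matrix(u[map$idx$a_raw], N, K)
  u2[map$idx$a_raw] <- as.numeric(a_raw[perm, ])
  Gm <- srmnet:::chol_corr_forward(u[map$idx$z_drho], K)$L
  P_swap <- diag(K)[c((M + 1):K, 1:M), ]
  Q_swap <- solve(Gm) %*% P_swap %*% Gm
  dy <- srmnet:::dyad_index(N)
  d_raw <- matrix(u[map$idx$d_raw], map$Np, K)
  d_raw2 <- d_raw
  for (p in seq_len(map$Np)) {
    i0 <- perm[dy$i[p]]; j0 <- perm[dy$j[p]]  # original labels of new pair p
    pr <- which(dy$i == min(i0, j0) & dy$j == max(i0, j0))
    d_raw2[p, ] <- if (i0 > j0) drop(Q_swap %*% d_raw[pr, ]) else d_raw[pr, ]
  }
  u2[map$idx$d_raw] <- as.numeric(d_raw2)
  prior_shift <- -0.5 * (sum(d_raw2^2) - sum(d_raw^2))
  expect_equal(dens2$lp(u2) - dens$lp(u), prior_shift, tolerance = 1e-8)

  # with an exactly block-structured correlation the half-swap is orthogonal
  # and the density is fully invariant
  cs <- make_structured_correlation(matrix(c(1, 0.3, 0.3, 1), 2),
                                    matrix(c(0.6, 0.2, 0.2, 0.5), 2))
  Gs <- t(chol(cs$full))
  Qs <- solve(Gs) %*% P_swap %*% Gs
  expect_equal(crossprod(Qs), diag(K), tolerance = 1e-12)
})

test_that("logit and probit links agree on the latent tie ordering", {
  sim <- simulate_multiplex_network(40, 2, test_truth(2),
                                    outcome_mode = "binomial", exposure = 10,
                                    seed = 77)
  # posterior-mode linear predictors under each link (deterministic)
  theta_hat <- function(link) {
    d <- sim$data
    d$link_mode <- link
    dens <- srm_density(d, build_designs(d))
    set.seed(1)
    u0 <- runif(dens$n_par, -0.05, 0.05)
    opt <- optim(u0, fn = function(u) -dens$lp_grad(u)$lp,
                 gr = function(u) -dens$lp_grad(u)$grad,
                 method = "L-BFGS-B", control = list(maxit = 1000))
    p <- dens$unpack(opt$par)
    K <- 4; M <- 2; N <- 40
    sigma <- exp(p$log_sigma); dsig <- exp(p$log_dsigma)
    L <- srmnet:::chol_corr_forward(p$z_rho, K)$L
    Gm <- srmnet:::chol_corr_forward(p$z_drho, K)$L
    A <- sweep(p$a_raw %*% t(L), 2, sigma, `*`)
    D <- sweep(p$d_raw %*% t(Gm), 2, c(dsig, dsig), `*`)
    dy <- srmnet:::dyad_index(N)
    th <- c()
    for (m in 1:M) {
      t1 <- matrix(p$eta[m] + A[, m], N, N) + matrix(A[, M + m], N, N, byrow = TRUE)
      t1[dy$upper] <- t1[dy$upper] + D[, m]
      t1[dy$lower] <- t1[dy$lower] + D[, M + m]
      th <- c(th, t1[srmnet:::offdiag_indices(N)])
    }
    th
  }
  expect_gt(cor(theta_hat("logit"), theta_hat("probit"), method = "spearman"),
            0.99)
})
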