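# Simulation engine: sender/receiver and dyadic effect sampling, linear
# predictor assembly, outcome families, determinism.

test_that("zero scales collapse random effects to their means", {
  p0 <- srm_parameters(2, sr_mu = c(1, 2, 3, 4), sr_sigma = rep(0, 4),
                       dr_mu = c(0.5, -0.5), dr_sigma = rep(0, 2))
  sr <- sample_sr_effects(p0, 10, seed = 1)
  expect_equal(unname(sr), matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4))
  dd <- sample_dyadic_effects(p0, 6, seed = 1)
  expect_equal(unname(dd[1, 2, ]), c(0.5, -0.5))
  expect_equal(unname(dd[2, 1, ]), c(0.5, -0.5))
})

test_that("sender/receiver effects reproduce their generative moments", {
  p <- srm_parameters(2, sr_sigma = rep(1, 4))
  sr <- sample_sr_effects(p, 1e5, seed = 2)
  expect_equal(unname(apply(sr, 2, sd)), rep(1, 4), tolerance = 0.02)
  # M = 1 with generalized reciprocity 0.8
  rho <- matrix(c(1, 0.8, 0.8, 1), 2)
  p1 <- srm_parameters(1, sr_sigma = c(1, 1), sr_rho = rho)
  sr1 <- sample_sr_effects(p1, 1e5, seed = 3)
  expect_equal(cor(sr1[, 1], sr1[, 2]), 0.8, tolerance = 0.01)
})

test_that("dyadic effects carry the requested reciprocity correlation", {
  p1 <- srm_parameters(1, dr_sigma = 1,
                       dr_rho = make_structured_correlation(matrix(1), matrix(0.6)))
  dd <- sample_dyadic_effects(p1, 64, seed = 4)  # 2016 pairs
  D <- attr(dd, "pair_matrix")
  expect_gt(nrow(D), 2000)
  expect_equal(cor(D[, 1], D[, 2]), 0.6, tolerance = 0.05)
  # the two directions land in transposed cells
  dy <- attr(dd, "pair_index")
  expect_equal(dd[cbind(dy$i, dy$j, 1)], D[, 1])
  expect_equal(dd[cbind(dy$j, dy$i, 1)], D[, 2])
})

test_that("the linear predictor assembles all terms and matches an oracle", {
  # degenerate cases with closed forms
  p0 <- srm_parameters(2, eta = c(-1.5, 0), sr_sigma = rep(0, 4), dr_sigma = rep(0, 2))
  sim0 <- simulate_multiplex_network(5, 2, p0, outcome_mode = "bernoulli", seed = 1)
  expect_equal(linear_predictor(p0, sim0$latent$sr_effects,
                                sim0$latent$dyadic_effects, sim0$designs, 1, 2, 1),
               -1.5)
  p1 <- srm_parameters(2, eta = c(0, 0), focal_slopes = matrix(c(2, 0), 2, 1),
                       target_slopes = matrix(0, 2, 1), dyad_slopes = matrix(0, 2, 1),
                       sr_sigma = rep(0, 4), dr_sigma = rep(0, 2))
  nc <- data.frame(X1 = c(0.5, 0, 0, 0, 0))
  dc <- list(D1 = matrix(0, 5, 5))
  sim1 <- simulate_multiplex_network(5, 2, p1, node_covariates = nc,
                                     dyad_covariates = dc,
                                     outcome_mode = "bernoulli", seed = 1)
  expect_equal(linear_predictor(p1, sim1$latent$sr_effects,
                                sim1$latent$dyadic_effects, sim1$designs, 1, 2, 1),
               1.0)
  expect_error(linear_predictor(p1, sim1$latent$sr_effects,
                                sim1$latent$dyadic_effects, sim1$designs, 2, 2, 1),
               "diagonal")

  # random configuration vs an independently coded term-by-term sum
  set.seed(33)
  M <- 2; N <- 6
  pars <- srm_parameters(M, eta = rnorm(2),
                         focal_slopes = matrix(rnorm(4), 2, 2),
                         target_slopes = matrix(rnorm(4), 2, 2),
                         dyad_slopes = matrix(rnorm(2), 2, 1),
                         block_params = list(G = array(rnorm(18), c(3, 3, 2))),
                         sr_sigma = rep(0.9, 4), dr_sigma = rep(0.6, 2))
  sim <- simulate_multiplex_network(N, M, pars, node_covariates = 2,
                                    dyad_covariates = 1, block_factors = 3L,
                                    outcome_mode = "poisson", seed = 44)
  sr <- sim$latent$sr_effects; dd <- sim$latent$dyadic_effects
  des <- sim$designs
  for (m in 1:M) for (i in 1:N) for (j in 1:N) {
    if (i == j) next
    manual <- pars$eta[m] + sr[i, m] + sr[j, M + m] + dd[i, j, m] +
      pars$block_params$G[des$block$B1$index[i], des$block$B1$index[j], m] +
      sum(des$focal[i, ] * pars$focal_slopes[m, ]) +
      sum(des$target[j, ] * pars$target_slopes[m, ]) +
      des$dyad[i, j, 1] * pars$dyad_slopes[m, 1]
    expect_equal(linear_predictor(pars, sr, dd, des, i, j, m), unname(manual),
                 tolerance = 1e-12)
    expect_equal(sim$latent$theta[i, j, m], unname(manual), tolerance = 1e-12)
  }
})

test_that("block offsets sum lookups over block variables", {
  des <- list(block = list(
    v1 = list(index = c(1L, 2L, 1L, 2L), n_levels = 2L),
    v2 = list(index = c(1L, 1L, 2L, 2L), n_levels = 2L)))
  bp1 <- array(c(1, 3, 2, 4), c(2, 2, 1))    # column-major: [u, w]
  bp2 <- array(c(10, 30, 20, 40), c(2, 2, 1))
  expect_equal(block_offset(NULL, list(), 1, 2, 1), 0)
  expect_equal(block_offset(list(v1 = bp1), des$block["v1"], 1, 2, 1),
               bp1[1, 2, 1])
  # V = 2: exhaustive enumeration oracle on the 4-node toy
  for (i in 1:4) for (j in 1:4) {
    manual <- bp1[des$block$v1$index[i], des$block$v1$index[j], 1] +
      bp2[des$block$v2$index[i], des$block$v2$index[j], 1]
    expect_equal(block_offset(list(v1 = bp1, v2 = bp2), des$block, i, j, 1),
                 manual)
  }
})

test_that("simulated outcomes match their analytic means under each link", {
  flat <- function(M) srm_parameters(M, sr_sigma = rep(0, 2 * M), dr_sigma = rep(0, M))
  # logistic(0) = 0.5 at N = 2000
  sim_b <- simulate_multiplex_network(2000, 1, flat(1), outcome_mode = "bernoulli",
                                      seed = 6)
  od <- sim_b$data$outcomes[, , 1][upper.tri(diag(2000)) | lower.tri(diag(2000))]
  expect_equal(mean(od), 0.5, tolerance = 0.02)
  # exp(0) = 1
  sim_p <- simulate_multiplex_network(2000, 1, flat(1), outcome_mode = "poisson",
                                      seed = 7)
  odp <- sim_p$data$outcomes[, , 1][upper.tri(diag(2000)) | lower.tri(diag(2000))]
  expect_equal(mean(odp), 1, tolerance = 3 * sd(odp) / sqrt(length(odp)))
  # binomial with eta = -1: mean = E * logistic(-1)
  pb <- srm_parameters(1, eta = -1, sr_sigma = c(0, 0), dr_sigma = 0)
  sim_bin <- simulate_multiplex_network(600, 1, pb, outcome_mode = "binomial",
                                        exposure = 8, seed = 8)
  odb <- sim_bin$data$outcomes[, , 1][srmnet:::offdiag_indices(600)]
  mu <- 8 * plogis(-1)
  expect_equal(mean(odb), mu, tolerance = 3 * sd(odb) / sqrt(length(odb)))
  # gaussian identity: mean theta = eta
  pg <- srm_parameters(1, eta = 0.7, sr_sigma = c(0, 0), dr_sigma = 0, psi = 0.5)
  sim_g <- simulate_multiplex_network(600, 1, pg, outcome_mode = "gaussian", seed = 9)
  odg <- sim_g$data$outcomes[, , 1][srmnet:::offdiag_indices(600)]
  expect_equal(mean(odg), 0.7, tolerance = 3 * sd(odg) / sqrt(length(odg)))
})

test_that("simulated reciprocities converge to their generative matrices", {
  pars <- test_truth(2)
  sim <- simulate_multiplex_network(2000, 2, pars, outcome_mode = "bernoulli",
                                    seed = 10)
  sr <- sim$latent$sr_effects
  # generalized: corr(alpha_m, beta_m) ~ sr_rho[m, M+m] = 0.4
  expect_equal(cor(sr[, 1], sr[, 3]), 0.4, tolerance = 0.06)
  expect_equal(cor(sr[, 2], sr[, 4]), 0.4, tolerance = 0.06)
  D <- attr(sim$latent$dyadic_effects, "pair_matrix")
  # dyadic: within-layer reciprocity 0.6, cross-layer same-direction 0.3
  expect_equal(cor(D[, 1], D[, 3]), 0.6, tolerance = 0.05)
  expect_equal(cor(D[, 1], D[, 2]), 0.3, tolerance = 0.05)
})

test_that("simulation is deterministic given a seed and respects exposure 0", {
  pars <- test_truth(2)
  s1 <- simulate_multiplex_network(15, 2, pars, outcome_mode = "binomial",
                                   exposure = 6, seed = 99)
  s2 <- simulate_multiplex_network(15, 2, pars, outcome_mode = "binomial",
                                   exposure = 6, seed = 99)
  expect_identical(s1$data$outcomes, s2$data$outcomes)
  expect_identical(s1$latent, s2$latent)
  s3 <- simulate_multiplex_network(15, 2, pars, outcome_mode = "binomial",
                                   exposure = 0, seed = 99)
  expect_true(all(s3$data$outcomes == 0))
})

test_that("parameter manifests round-trip exactly", {
  pars <- srm_parameters(2, eta = c(-1, 0.5),
                         focal_slopes = matrix(c(0.4, -0.3), 2, 1),
                         target_slopes = matrix(c(0.1, 0.2), 2, 1),
                         block_params = list(g = array(rnorm(8), c(2, 2, 2))),
                         sr_sigma = rep(0.7, 4),
                         dr_sigma = c(0.8, 0.6),
                         dr_rho = make_structured_correlation(
                           matrix(c(1, 0.3, 0.3, 1), 2),
                           matrix(c(0.6, 0.2, 0.2, 0.5), 2)))
  p <- withr::local_tempfile(fileext = ".json")
  write_parameter_manifest(pars, 42, p)
  back <- read_parameter_manifest(p)
  expect_equal(back$seed, 42)
  expect_equal(back$params$eta, pars$eta)
  expect_equal(back$params$dr_rho$full, pars$dr_rho$full)
  expect_equal(back$params$block_params$g, pars$block_params$g)
  # identical re-simulation from the manifest (covariates regenerate from
  # the same seed)
  a <- simulate_multiplex_network(10, 2, pars, node_covariates = 1,
                                  block_factors = 2L,
                                  outcome_mode = "bernoulli", seed = back$seed)
  b <- simulate_multiplex_network(10, 2, back$params, node_covariates = 1,
                                  block_factors = 2L,
                                  outcome_mode = "bernoulli", seed = back$seed)
  expect_identical(a$data$outcomes, b$data$outcomes)
})
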