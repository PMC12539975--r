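# Posterior post-processing: HPD intervals, summary tables, variance
# partitions, adjusted correlations, contrasts, network metrics.

# One small fit with block structure shared across the tests in this file.
make_pp_fit <- function() {
  pars <- srm_parameters(
    2, eta = c(-0.8, -0.8),
    block_params = list(B1 = array(c(0.8, -0.4, -0.4, 0.6,
                                     0.2, 0.1, 0.1, -0.3), c(2, 2, 2))),
    sr_sigma = rep(0.7, 4), dr_sigma = c(0.8, 0.8),
    dr_rho = make_structured_correlation(matrix(c(1, 0.3, 0.3, 1), 2),
                                         matrix(c(0.6, 0.2, 0.2, 0.6), 2)))
  sim <- simulate_multiplex_network(10, 2, pars, block_factors = 2L,
                                    outcome_mode = "binomial", exposure = 8,
                                    layer_names = c("give", "take"), seed = 301)
  fit_multiplex_model(sim$data, build_designs(sim$data, block_regression = ~B1),
                      config = sampler_config(chains = 2, warmup_draws = 100,
                                              sampling_draws = 100, seed = 12,
                                              max_tree_depth = 8))
}
pp_fit <- make_pp_fit()

test_that("hpdi finds the narrowest interval of the requested mass", {
  expect_equal(hpdi(1:5, 0.9), c(1, 5))
  # skewed unimodal draws: HPDI is narrower than the equal-tailed interval,
  # verified against a brute-force scan over all contiguous windows
  set.seed(41)
  x <- rexp(2000)
  h <- hpdi(x, 0.8)
  xs <- sort(x)
  k <- ceiling(0.8 * length(xs))
  widths <- xs[(k + 1):length(xs)] - xs[1:(length(xs) - k)]
  expect_equal(h[2] - h[1], min(widths))
  et <- unname(quantile(x, c(0.1, 0.9)))
  expect_lt(h[2] - h[1], et[2] - et[1])
  # symmetric draws give a roughly symmetric interval
  set.seed(42)
  z <- rnorm(5000)
  hz <- hpdi(z, 0.9)
  expect_lt(abs(hz[1] + hz[2]), 0.15)
})

test_that("summary tables are ordered and complete", {
  s <- summarize_fit(pp_fit)
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  expect_setequal(unique(s$category),
                  c("block", "sigma", "generalized", "dyadic corr"))
  # per layer: 3 sigma rows; 2M x 2M upper triangles for the correlations
  expect_equal(sum(s$category == "sigma"), 6)
  expect_equal(sum(s$category == "generalized"), 6)
  expect_equal(sum(s$category == "dyadic corr"), 6)
  # monotone relabeling equivariance: summary is pure bookkeeping
  s50 <- summarize_fit(pp_fit, hpdi_mass = 0.5)
  expect_true(all(s50$upper - s50$lower <= s$upper - s$lower + 1e-12))
})

test_that("variance partitions are normalized and nest correctly", {
  v4 <- variance_partition(pp_fit, 4)
  sums <- apply(v4$draws, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(v4$draws >= 0 & v4$draws <= 1))
  v3 <- variance_partition(pp_fit, 3)
  expect_equal(v3$draws[, , "dyadic+residual"],
               v4$draws[, , "dyadic"] + v4$draws[, , "residual"])
  expect_equal(v3$draws[, , "focal"], v4$draws[, , "focal"])
  expect_error(variance_partition(pp_fit, 5), "3 or 4")
  # the adjusted-mode companion correlations shrink toward zero
  c_cor <- variance_partition(pp_fit, 4, mode = "cor")$correlations
  c_adj <- variance_partition(pp_fit, 4, mode = "adj")$correlations
  expect_true(all(abs(c_adj$median) <= abs(c_cor$median) + 1e-12))
})

test_that("four equal variance components each get one quarter", {
  # synthetic draws: sigma chosen so every component equals the logit
  # residual pi^2/3
  s <- sqrt(pi^2 / 3)
  fake <- structure(list(
    draws = list(eta = matrix(0, 5, 1), sigma = matrix(s, 5, 2),
                 dsigma = matrix(s, 5, 1), psi = NULL,
                 drho = array(0.5, c(5, 2, 2))),
    map = list(M = 1), data = list(link_mode = "logit", layer_names = "l")),
    class = "srm_fit")
  v <- variance_partition(fake, 4)
  expect_equal(unname(v$draws[1, 1, ]), rep(0.25, 4), tolerance = 1e-12)
  # gaussian mode: residual share is psi^2 / total, analytically
  fake$data$link_mode <- "identity"
  fake$draws$psi <- rep(2, 5)
  vg <- variance_partition(fake, 4)
  tot <- s^2 * 3 + 4
  expect_equal(unname(vg$draws[1, 1, "residual"]), 4 / tot, tolerance = 1e-12)
})

test_that("the variance adjustment factor follows sigma^2/(sigma^2+1)", {
  expect_equal(adjusted_dyadic_correlation(0.8, 1), 0.4)
  expect_equal(adjusted_dyadic_correlation(0.5, 2), 0.4)
  expect_equal(adjusted_dyadic_correlation(0.9, 1e-6), 0, tolerance = 1e-9)
  expect_equal(adjusted_dyadic_correlation(0.7, 1e6), 0.7, tolerance = 1e-9)
  # monotone increasing in sigma and bounded by rho
  sig <- seq(0.1, 5, length.out = 50)
  vals <- adjusted_dyadic_correlation(0.6, sig)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 0.6))
  expect_error(adjusted_dyadic_correlation(0.5, 0), "positive")
})

test_that("reciprocity matrices carry the layer labelling convention", {
  gen <- reciprocity_matrices(pp_fit, "generalized")
  expect_equal(gen$labels, c("give (out)", "take (out)", "give (in)", "take (in)"))
  dyd <- reciprocity_matrices(pp_fit, "dyadic")
  expect_equal(dyd$labels,
               c("give (i to j)", "take (i to j)", "give (j to i)", "take (j to i)"))
  # correlation summaries are symmetric in their labels
  expect_equal(dyd$median, t(dyd$median))
  expect_equal(gen$median, t(gen$median))
  expect_true(all(diag(gen$median) == 1))
  expect_true(all(dyd$lower <= dyd$upper))
})

test_that("block contrasts are exact draw-wise differences", {
  same <- block_contrast(pp_fit, "B1", "give", c("A", "A"), c("A", "A"))
  expect_identical(same$draws, rep(0, length(same$draws)))
  expect_equal(same$lower, 0)
  expect_equal(same$upper, 0)
  ab <- block_contrast(pp_fit, "B1", "give", c("A", "A"), c("A", "B"))
  ba <- block_contrast(pp_fit, "B1", "give", c("A", "B"), c("A", "A"))
  expect_equal(ab$draws, -ba$draws)
  # additivity: (a-b) + (b-c) = (a-c) draw by draw
  bc <- block_contrast(pp_fit, "B1", "give", c("A", "B"), c("B", "B"))
  ac <- block_contrast(pp_fit, "B1", "give", c("A", "A"), c("B", "B"))
  expect_equal(ab$draws + bc$draws, ac$draws, tolerance = 1e-12)
  expect_error(block_contrast(pp_fit, "B1", "give", c("A", "Z"), c("A", "A")),
               "unknown block cell")
})

test_that("posterior network metrics propagate draw-level uncertainty", {
  const <- posterior_network_metric(pp_fit, function(x) 1, 1)
  expect_true(all(const == 1))
  dens_draws <- posterior_network_metric(
    pp_fit, function(x) mean(x, na.rm = TRUE), "give")
  expect_length(dens_draws, length(pp_fit$re_draw_idx))
  od <- srmnet:::offdiag_indices(10)
  obs <- mean(pp_fit$data$outcomes[, , 1][od] / 8)
  # posterior mean tie probability tracks the observed density
  expect_equal(mean(dens_draws), obs, tolerance = 0.05)
  expect_error(posterior_network_metric(pp_fit, function(x) stop("boom"), 1),
               "draw 1")
})
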