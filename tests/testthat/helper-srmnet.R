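# Shared fixtures and independent oracles, built in code at test time.

# Moderate-reciprocity truth used across tests (kept small and explicit so
# oracles can refer to the exact numbers).
test_truth <- function(M = 2) {
  K <- 2 * M
  sr_rho <- diag(K)
  for (m in seq_len(M)) sr_rho[m, M + m] <- sr_rho[M + m, m] <- 0.4
  C <- diag(M); C[C == 0] <- 0.3
  B <- matrix(0.2, M, M); diag(B) <- 0.6
  srm_parameters(M, eta = rep(-1, M), sr_sigma = rep(0.7, K), sr_rho = sr_rho,
                 dr_sigma = rep(0.8, M),
                 dr_rho = make_structured_correlation(C, B))
}

# Brute-force per-cell log likelihood in a double loop.
oracle_loglik <- function(data, theta, psi = 1) {
  N <- data$n_nodes
  ll <- 0
  for (m in seq_len(data$n_layers)) for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    th <- theta[i, j, m]
    g <- data$outcomes[i, j, m]
    ll <- ll + switch(data$outcome_mode,
      bernoulli = dbinom(g, 1, srmnet:::link_mean(th, data$link_mode), log = TRUE),
      binomial = dbinom(g, data$exposure[i, j, m],
                        srmnet:::link_mean(th, data$link_mode), log = TRUE),
      poisson = dpois(g, exp(th), log = TRUE),
      gaussian = dnorm(g, th, psi, log = TRUE))
  }
  unname(ll)
}

is_correlation_matrix <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) &&
    max(abs(x - t(x))) < tol && max(abs(diag(x) - 1)) < tol &&
    min(eigen(x, symmetric = TRUE, only.values = TRUE)$values) > -tol
}

# Small simulated instance used by several files.
quick_sim <- function(N = 8, M = 2, mode = "bernoulli", seed = 101, ...) {
  simulate_multiplex_network(N, M, test_truth(M), outcome_mode = mode,
                             exposure = if (mode == "binomial") 5 else NULL,
                             seed = seed, ...)
}
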