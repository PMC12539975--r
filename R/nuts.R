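# Built-in No-U-Turn Hamiltonian Monte Carlo engine.
#
# Multinomial NUTS with dual-averaging step-size adaptation and windowed
# diagonal mass-matrix estimation.  The engine is generic: it samples any
# target supplied as a log-density-with-gradient closure, which is how the
# multiplex SRM density (and the prior-only density used for baselines) are
# plugged in.  All randomness flows through R's RNG, so chains are exactly
# reproducible from a seed.

kinetic_energy <- function(r, inv_mass) 0.5 * sum(r * r * inv_mass)

leapfrog <- function(q, r, grad, v_eps, lp_grad, inv_mass) {
  r1 <- r + 0.5 * v_eps * grad
  q1 <- q + v_eps * (inv_mass * r1)
  fg <- lp_grad(q1)
  ok <- is.finite(fg$lp) && all(is.finite(fg$grad))
  if (ok) r1 <- r1 + 0.5 * v_eps * fg$grad
  list(q = q1, r = r1, lp = fg$lp, grad = fg$grad, ok = ok)
}

uturn <- function(q_plus, q_minus, r_plus, r_minus, inv_mass) {
  dq <- q_plus - q_minus
  (sum(dq * (inv_mass * r_minus)) < 0) || (sum(dq * (inv_mass * r_plus)) < 0)
}

build_tree <- function(q, r, grad, lp, v, depth, eps, H0, lp_grad, inv_mass) {
  if (depth == 0L) {
    st <- leapfrog(q, r, grad, v * eps, lp_grad, inv_mass)
    if (!st$ok) {
      return(list(divergent = TRUE, turning = FALSE, n_leapfrog = 1L,
                  log_w = -Inf, sum_alpha = 0, n_alpha = 1L))
    }
    H1 <- -st$lp + kinetic_energy(st$r, inv_mass)
    divergent <- !is.finite(H1) || (H1 - H0) > 1000
    alpha <- if (is.finite(H1)) min(1, exp(H0 - H1)) else 0
    list(q_minus = st$q, r_minus = st$r, g_minus = st$grad,
         q_plus = st$q, r_plus = st$r, g_plus = st$grad,
         q_prop = st$q, lp_prop = st$lp, g_prop = st$grad,
         log_w = if (divergent) -Inf else -H1,
         sum_alpha = alpha, n_alpha = 1L,
         divergent = divergent, turning = FALSE, n_leapfrog = 1L)
  } else {
    t1 <- build_tree(q, r, grad, lp, v, depth - 1L, eps, H0, lp_grad, inv_mass)
    if (t1$divergent || t1$turning) return(t1)
    if (v == 1) {
      t2 <- build_tree(t1$q_plus, t1$r_plus, t1$g_plus, NA, v, depth - 1L,
                       eps, H0, lp_grad, inv_mass)
    } else {
      t2 <- build_tree(t1$q_minus, t1$r_minus, t1$g_minus, NA, v, depth - 1L,
                       eps, H0, lp_grad, inv_mass)
    }
    out <- t1
    out$n_leapfrog <- t1$n_leapfrog + t2$n_leapfrog
    out$sum_alpha <- t1$sum_alpha + t2$sum_alpha
    out$n_alpha <- t1$n_alpha + t2$n_alpha
    if (t2$divergent || t2$turning) {
      out$divergent <- t2$divergent
      out$turning <- t2$turning
      return(out)
    }
    if (v == 1) {
      out$q_plus <- t2$q_plus; out$r_plus <- t2$r_plus; out$g_plus <- t2$g_plus
    } else {
      out$q_minus <- t2$q_minus; out$r_minus <- t2$r_minus; out$g_minus <- t2$g_minus
    }
    lse <- log_sum_exp(t1$log_w, t2$log_w)
    if (is.finite(t2$log_w) && stats::runif(1) < exp(t2$log_w - lse)) {
      out$q_prop <- t2$q_prop; out$lp_prop <- t2$lp_prop; out$g_prop <- t2$g_prop
    }
    out$log_w <- lse
    out$turning <- uturn(out$q_plus, out$q_minus, out$r_plus, out$r_minus, inv_mass)
    out
  }
}

find_reasonable_stepsize <- function(q, lp, grad, lp_grad, inv_mass) {
  eps <- 1
  r <- stats::rnorm(length(q)) / sqrt(inv_mass)
  H0 <- -lp + kinetic_energy(r, inv_mass)
  ratio_at <- function(eps) {
    st <- leapfrog(q, r, grad, eps, lp_grad, inv_mass)
    if (!st$ok) return(-Inf)
    H0 - (-st$lp + kinetic_energy(st$r, inv_mass))
  }
  ratio <- ratio_at(eps)
  a <- if (is.finite(ratio) && ratio > log(0.5)) 1 else -1
  for (k in 1:50) {
    eps <- eps * 2^a
    ratio <- ratio_at(eps)
    if (!is.finite(ratio)) { if (a == 1) { eps <- eps / 2; break } else next }
    if (a * ratio <= a * log(0.5)) break
  }
  max(eps, 1e-8)
}

# Warmup schedule for mass-matrix windows (Stan-style expanding windows).
adapt_windows <- function(n_warmup) {
  if (n_warmup < 60) {
    return(list(init = max(5L, floor(0.15 * n_warmup)),
                ends = floor(0.9 * n_warmup)))
  }
  init <- min(75L, floor(0.15 * n_warmup))
  term <- min(50L, floor(0.1 * n_warmup))
  last <- n_warmup - term
  ends <- integer()
  w <- 25L
  pos <- init
  while (pos + w < last) {
    if (pos + 3L * w >= last) w <- last - pos  # absorb the tail
    pos <- pos + w
    ends <- c(ends, pos)
    w <- 2L * w
  }
  if (length(ends) == 0 || ends[length(ends)] != last) ends <- c(ends, last)
  list(init = init, ends = ends)
}

# One NUTS chain; the caller seeds the RNG.
nuts_chain <- function(lp_grad, init, n_warmup, n_sample,
                       target_accept = 0.9, max_treedepth = 10L,
                       adapt_mass = TRUE) {
  dim <- length(init)
  q <- init
  fg <- lp_grad(q)
  if (!is.finite(fg$lp)) stop_srm("non-finite log density at the initial point")
  lp <- fg$lp; grad <- fg$grad
  inv_mass <- rep(1, dim)

  eps <- find_reasonable_stepsize(q, lp, grad, lp_grad, inv_mass)
  mu <- log(10 * eps)
  log_eps_bar <- 0; h_bar <- 0
  da_count <- 0L
  gamma <- 0.05; t0 <- 10; kap <- 0.75

  win <- adapt_windows(n_warmup)
  win_ends <- win$ends
  # Welford accumulators for the current window
  wf_n <- 0L; wf_mean <- numeric(dim); wf_m2 <- numeric(dim)

  n_total <- n_warmup + n_sample
  draws <- matrix(NA_real_, n_sample, dim)
  lp_out <- numeric(n_sample)
  div_out <- logical(n_sample)
  depth_out <- integer(n_sample)
  accept_out <- numeric(n_sample)
  n_div_warmup <- 0L

  for (it in seq_len(n_total)) {
    r0 <- stats::rnorm(dim) / sqrt(inv_mass)
    H0 <- -lp + kinetic_energy(r0, inv_mass)
    q_minus <- q; q_plus <- q; r_minus <- r0; r_plus <- r0
    g_minus <- grad; g_plus <- grad
    q_prop <- q; lp_prop <- lp; g_prop <- grad
    log_w <- -H0
    sum_alpha <- 0; n_alpha <- 0L
    divergent <- FALSE
    depth <- 0L
    while (depth < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == 1) {
        tr <- build_tree(q_plus, r_plus, g_plus, NA, v, depth, eps, H0, lp_grad, inv_mass)
      } else {
        tr <- build_tree(q_minus, r_minus, g_minus, NA, v, depth, eps, H0, lp_grad, inv_mass)
      }
      sum_alpha <- sum_alpha + tr$sum_alpha
      n_alpha <- n_alpha + tr$n_alpha
      if (tr$divergent) { divergent <- TRUE; break }
      if (!tr$turning) {
        # biased progressive sampling toward the new subtree
        if (is.finite(tr$log_w) && stats::runif(1) < exp(tr$log_w - log_w)) {
          q_prop <- tr$q_prop; lp_prop <- tr$lp_prop; g_prop <- tr$g_prop
        }
        log_w <- log_sum_exp(log_w, tr$log_w)
      }
      if (v == 1) {
        q_plus <- tr$q_plus; r_plus <- tr$r_plus; g_plus <- tr$g_plus
      } else {
        q_minus <- tr$q_minus; r_minus <- tr$r_minus; g_minus <- tr$g_minus
      }
      depth <- depth + 1L
      if (tr$turning || uturn(q_plus, q_minus, r_plus, r_minus, inv_mass)) break
    }
    q <- q_prop; lp <- lp_prop; grad <- g_prop
    accept_stat <- if (n_alpha > 0) sum_alpha / n_alpha else 0

    if (it <= n_warmup) {
      if (divergent) n_div_warmup <- n_div_warmup + 1L
      # dual averaging on the log step size
      da_count <- da_count + 1L
      h_bar <- (1 - 1 / (da_count + t0)) * h_bar +
        (target_accept - accept_stat) / (da_count + t0)
      log_eps <- mu - sqrt(da_count) / gamma * h_bar
      w_da <- da_count^(-kap)
      log_eps_bar <- w_da * log_eps + (1 - w_da) * log_eps_bar
      eps <- exp(log_eps)
      if (adapt_mass && it > win$init) {
        wf_n <- wf_n + 1L
        dlt <- q - wf_mean
        wf_mean <- wf_mean + dlt / wf_n
        wf_m2 <- wf_m2 + dlt * (q - wf_mean)
        if (it %in% win_ends && wf_n > 1L) {
          v_est <- wf_m2 / (wf_n - 1L)
          inv_mass <- (wf_n / (wf_n + 5)) * v_est + 1e-3 * (5 / (wf_n + 5))
          wf_n <- 0L; wf_mean[] <- 0; wf_m2[] <- 0
          eps <- find_reasonable_stepsize(q, lp, grad, lp_grad, inv_mass)
          mu <- log(10 * eps)
          da_count <- 0L; h_bar <- 0; log_eps_bar <- 0
        }
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      s <- it - n_warmup
      draws[s, ] <- q
      lp_out[s] <- lp
      div_out[s] <- divergent
      depth_out[s] <- depth
      accept_out[s] <- accept_stat
    }
  }

  list(draws = draws, lp = lp_out, divergent = div_out, treedepth = depth_out,
       accept_stat = accept_out, stepsize = eps, inv_mass = inv_mass,
       n_divergent_warmup = n_div_warmup)
}
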