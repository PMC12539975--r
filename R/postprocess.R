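# Posterior post-processing: summary tables, variance partitions, adjusted
# correlations, reciprocity matrices, block contrasts, and posterior network
# metrics.

#' Summarize a multiplex SRM fit
#'
#' One row per reported parameter with the posterior median and highest
#' posterior density interval.  Layer intercepts are reported in the block
#' category; block offsets are re-centred within each variable and layer for
#' display (contrasts should always be computed with [block_contrast()],
#' which uses the raw offsets).
#'
#' @param fit An `srm_fit` object.
#' @param hpdi_mass Probability mass of the reported HPD interval (default
#'   0.90).
#' @return Data frame with columns `category`, `outcome`, `effect`,
#'   `median`, `lower`, `upper`.
#' @export
summarize_fit <- function(fit, hpdi_mass = 0.90) {
  stopifnot(inherits(fit, "srm_fit"), hpdi_mass > 0, hpdi_mass < 1)
  if (nrow(fit$draws$eta) == 0) stop_srm("fit contains no draws")
  d <- fit$draws
  layers <- fit$data$layer_names
  M <- fit$map$M; K <- fit$map$K
  rows <- list()
  add <- function(category, outcome, effect, x) {
    h <- hpdi(x, hpdi_mass)
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, outcome = outcome, effect = effect,
      median = stats::median(x), lower = h[1], upper = h[2],
      stringsAsFactors = FALSE)
  }
  for (m in seq_len(M)) add("block", layers[m], "intercept", d$eta[, m])
  if (!is.null(d$block)) {
    for (v in names(d$block)) {
      b <- d$block[[v]]
      lev <- dimnames(b)[[2]]
      for (m in seq_len(M)) {
        centred <- b[, , , m, drop = FALSE]
        dim(centred) <- c(dim(b)[1], length(lev), length(lev))
        centred <- centred - rowMeans(matrix(centred, nrow = dim(b)[1]))
        for (uu in seq_along(lev)) for (ww in seq_along(lev)) {
          add("block", layers[m], paste0(v, ": ", lev[uu], " to ", lev[ww]),
              centred[, uu, ww])
        }
      }
    }
  }
  for (p in seq_len(fit$map$Pf)) for (m in seq_len(M)) {
    add("focal", layers[m], fit$designs$focal_names[p], d$focal[, m, p])
  }
  for (p in seq_len(fit$map$Pt)) for (m in seq_len(M)) {
    add("target", layers[m], fit$designs$target_names[p], d$target[, m, p])
  }
  for (p in seq_len(fit$map$Pd)) for (m in seq_len(M)) {
    add("dyadic", layers[m], fit$designs$dyad_names[p], d$dyad[, m, p])
  }
  for (m in seq_len(M)) {
    add("sigma", layers[m], "focal", d$sigma[, m])
    add("sigma", layers[m], "target", d$sigma[, M + m])
    add("sigma", layers[m], "dyadic", d$dsigma[, m])
  }
  if (!is.null(d$psi)) add("sigma", "all layers", "residual", d$psi)
  gl <- generalized_labels(layers)
  for (a in 1:(K - 1)) for (b in (a + 1):K) {
    add("generalized", gl[a], gl[b], d$rho[, a, b])
  }
  dl <- dyadic_labels(layers)
  for (a in 1:(K - 1)) for (b in (a + 1):K) {
    add("dyadic corr", dl[a], dl[b], d$drho[, a, b])
  }
  out <- do.call(rbind, rows)
  attr(out, "hpdi_mass") <- hpdi_mass
  out
}

#' @export
summary.srm_fit <- function(object, hpdi_mass = 0.90, ...) {
  summarize_fit(object, hpdi_mass)
}

# Residual variance on the latent (link) scale per outcome family.
latent_residual_variance <- function(fit) {
  switch(fit$data$link_mode,
    logit = rep(pi^2 / 3, nrow(fit$draws$eta)),
    probit = rep(1, nrow(fit$draws$eta)),
    identity = fit$draws$psi^2,
    log = rep(0, nrow(fit$draws$eta)))  # latent log scale; see vignette caveat
}

#' Variance partition coefficients per layer
#'
#' Partitions the latent-scale variance of each layer into focal (sender),
#' target (receiver), dyadic, and residual components per posterior draw.
#' The residual term is pi^2/3 for logit, 1 for probit, psi^2 for gaussian,
#' and 0 for poisson (whose partitions are reported on the latent log scale).
#' A three-way partition merges the dyadic and residual components, which is
#' better identified when dyadic reciprocity is weak.  The companion
#' within-layer dyadic correlation table is unadjusted for `mode = "cor"` and
#' variance-adjusted (multiplied by dyadic_var / (dyadic_var + 1)) for
#' `mode = "adj"`.
#'
#' @param fit An `srm_fit` object.
#' @param n_partitions 3 or 4.
#' @param mode `"cor"` (raw latent correlations) or `"adj"`
#'   (variance-adjusted, comparable to observed-scale estimates).
#' @param hpdi_mass Interval mass for the summary table.
#' @return Object of class `srm_vpc` with `draws` (S x M x components array),
#'   `summary` (data frame), and `correlations` (within-layer dyadic
#'   correlation summary under the requested mode).
#' @export
variance_partition <- function(fit, n_partitions = 4, mode = c("cor", "adj"),
                               hpdi_mass = 0.90) {
  stopifnot(inherits(fit, "srm_fit"))
  mode <- match.arg(mode)
  if (!n_partitions %in% c(3, 4)) stop_srm("n_partitions must be 3 or 4")
  d <- fit$draws
  S <- nrow(d$eta); M <- fit$map$M
  layers <- fit$data$layer_names
  r <- latent_residual_variance(fit)
  comp4 <- c("focal", "target", "dyadic", "residual")
  draws4 <- array(NA_real_, c(S, M, 4), dimnames = list(NULL, layers, comp4))
  for (m in seq_len(M)) {
    vf <- d$sigma[, m]^2
    vt <- d$sigma[, M + m]^2
    vd <- d$dsigma[, m]^2
    tot <- vf + vt + vd + r
    draws4[, m, ] <- cbind(vf, vt, vd, r) / tot
  }
  if (n_partitions == 3) {
    comp <- c("focal", "target", "dyadic+residual")
    draws <- array(NA_real_, c(S, M, 3), dimnames = list(NULL, layers, comp))
    draws[, , 1:2] <- draws4[, , 1:2]
    draws[, , 3] <- draws4[, , 3] + draws4[, , 4]
  } else {
    draws <- draws4
  }
  sm <- do.call(rbind, lapply(seq_len(M), function(m) {
    do.call(rbind, lapply(seq_len(dim(draws)[3]), function(k) {
      h <- hpdi(draws[, m, k], hpdi_mass)
      data.frame(layer = layers[m], component = dimnames(draws)[[3]][k],
                 median = stats::median(draws[, m, k]), lower = h[1], upper = h[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  cors <- do.call(rbind, lapply(seq_len(M), function(m) {
    rho_m <- d$drho[, m, M + m]
    if (mode == "adj") rho_m <- adjusted_dyadic_correlation(rho_m, d$dsigma[, m])
    h <- hpdi(rho_m, hpdi_mass)
    data.frame(layer = layers[m], mode = mode,
               median = stats::median(rho_m), lower = h[1], upper = h[2],
               stringsAsFactors = FALSE)
  }))
  structure(list(draws = draws, summary = sm, correlations = cors,
                 n_partitions = n_partitions, mode = mode),
            class = "srm_vpc")
}

#' @export
print.srm_vpc <- function(x, ...) {
  cat(sprintf("%d-way variance partition (mode = %s)\n", x$n_partitions, x$mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Variance-adjusted dyadic correlation
#'
#' Rescales a latent dyadic reciprocity correlation by
#' `sigma^2 / (sigma^2 + 1)`, the factor by which an observation-level
#' (unit-noise) analysis understates the latent correlation.  With
#' `sigma = 1` the factor is exactly 1/2; as `sigma` grows the adjusted value
#' approaches the latent correlation.
#'
#' @param rho_draw Latent dyadic correlation draw(s).
#' @param sigma_draw Positive dyadic SD draw(s).
#' @return Adjusted correlation(s) `rho * sigma^2 / (sigma^2 + 1)`.
#' @export
adjusted_dyadic_correlation <- function(rho_draw, sigma_draw) {
  if (any(sigma_draw <= 0)) stop_srm("sigma_draw must be positive")
  rho_draw * sigma_draw^2 / (sigma_draw^2 + 1)
}

#' Posterior reciprocity matrices
#'
#' Entrywise posterior medians and HPD intervals of the generalized
#' (sender/receiver) or dyadic correlation matrix, with a flag for entries
#' whose interval excludes zero ("reliably non-zero" at the stated mass).
#'
#' @param fit An `srm_fit` object.
#' @param type `"dyadic"` or `"generalized"`.
#' @param hpdi_mass Interval mass used for flagging (default 0.90).
#' @return Object of class `srm_reciprocity` with `median`, `lower`, `upper`,
#'   `flagged` matrices and `labels`.
#' @export
reciprocity_matrices <- function(fit, type = c("dyadic", "generalized"),
                                 hpdi_mass = 0.90) {
  stopifnot(inherits(fit, "srm_fit"))
  type <- match.arg(type)
  arr <- if (type == "dyadic") fit$draws$drho else fit$draws$rho
  K <- dim(arr)[2]
  labels <- dimnames(arr)[[2]]
  med <- lo <- hi <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    x <- arr[, a, b]
    med[a, b] <- stats::median(x)
    if (a == b) { lo[a, b] <- hi[a, b] <- 1; next }
    h <- hpdi(x, hpdi_mass)
    lo[a, b] <- h[1]; hi[a, b] <- h[2]
  }
  flagged <- (lo > 0 | hi < 0) & row(med) != col(med)
  structure(list(type = type, median = med, lower = lo, upper = hi,
                 flagged = flagged, labels = labels, hpdi_mass = hpdi_mass),
            class = "srm_reciprocity")
}

#' @export
print.srm_reciprocity <- function(x, digits = 2, ...) {
  cat(sprintf("%s reciprocity (posterior median; * = %d%% HPDI excludes 0)\n",
              x$type, round(100 * x$hpdi_mass)))
  out <- matrix(sprintf(paste0("%.", digits, "f%s"), x$median,
                        ifelse(x$flagged, "*", " ")),
                nrow(x$median), dimnames = dimnames(x$median))
  print(out, quote = FALSE)
  invisible(x)
}

#' Posterior contrast between two block-offset cells
#'
#' Block offsets cannot be interpreted marginally (a constant can shift the
#' intercept and all offsets without changing the likelihood), so differences
#' between cells are the meaningful quantity.  The contrast is computed
#' draw-by-draw on the raw (non-recentred) offsets, where the shared shift
#' cancels.
#'
#' @param fit An `srm_fit` object with block parameters.
#' @param variable Block variable name.
#' @param layer Layer name.
#' @param focal_cell,base_cell Length-2 character vectors
#'   `c(sender_level, receiver_level)` naming the two cells; the result is
#'   focal minus base.
#' @param hpdi_mass Interval mass for the summary.
#' @return List with `draws`, `median`, `lower`, `upper`, and the cell
#'   labels.
#' @export
block_contrast <- function(fit, variable, layer, focal_cell, base_cell,
                           hpdi_mass = 0.90) {
  stopifnot(inherits(fit, "srm_fit"))
  if (is.null(fit$draws$block) || !variable %in% names(fit$draws$block)) {
    stop_srm("no block parameters for variable '%s'", variable)
  }
  b <- fit$draws$block[[variable]]
  lev <- dimnames(b)[[2]]
  m <- match(layer, fit$data$layer_names)
  if (is.na(m)) stop_srm("unknown layer '%s'", layer)
  cell_idx <- function(cell) {
    idx <- match(cell, lev)
    if (anyNA(idx) || length(idx) != 2) {
      stop_srm("unknown block cell (%s); levels are: %s",
               paste(cell, collapse = " to "), paste(lev, collapse = ", "))
    }
    idx
  }
  fc <- cell_idx(focal_cell); bc <- cell_idx(base_cell)
  dr <- b[, fc[1], fc[2], m] - b[, bc[1], bc[2], m]
  h <- hpdi(dr, hpdi_mass)
  list(draws = dr, median = stats::median(dr), lower = h[1], upper = h[2],
       focal_cell = paste(focal_cell, collapse = " to "),
       base_cell = paste(base_cell, collapse = " to "),
       variable = variable, layer = layer, hpdi_mass = hpdi_mass)
}

# Rebuild the linear-predictor matrix of one layer for one retained draw.
theta_matrix_draw <- function(fit, t, m) {
  s <- fit$re_draw_idx[t]
  d <- fit$draws
  N <- fit$map$N; M <- fit$map$M
  dy <- dyad_index(N)
  af <- d$eta[s, m] + d$sr_effects[t, , m]
  bt <- d$sr_effects[t, , M + m]
  if (fit$map$Pf > 0) af <- af + drop(fit$designs$focal %*% d$focal[s, m, ])
  if (fit$map$Pt > 0) bt <- bt + drop(fit$designs$target %*% d$target[s, m, ])
  th <- matrix(af, N, N) + matrix(bt, N, N, byrow = TRUE)
  th[dy$upper] <- th[dy$upper] + d$dyad_effects[t, , m]
  th[dy$lower] <- th[dy$lower] + d$dyad_effects[t, , M + m]
  if (fit$map$Pd > 0) for (p in seq_len(fit$map$Pd)) {
    th <- th + fit$designs$dyad[, , p] * d$dyad[s, m, p]
  }
  if (!is.null(d$block)) for (v in names(d$block)) {
    bidx <- fit$designs$block[[v]]$index
    th <- th + d$block[[v]][s, , , m][bidx, bidx]
  }
  diag(th) <- NA
  th
}

#' Posterior distribution of a network metric on the latent network
#'
#' For each retained posterior draw, reconstructs the latent tie-probability
#' (or rate/mean) matrix of one layer from that draw's parameters and random
#' effects, and applies a user metric, yielding the metric's posterior
#' distribution with full uncertainty propagation.
#'
#' @param fit An `srm_fit` object.
#' @param metric Function taking an N x N numeric matrix (diagonal `NA`) and
#'   returning a scalar or vector.
#' @param layer Layer name or index.
#' @param scale `"expectation"` applies the inverse link (tie probability /
#'   rate / mean); `"linear"` leaves the matrix on the link scale.
#' @return Vector (or matrix) of metric values, one per retained draw.
#' @export
posterior_network_metric <- function(fit, metric, layer = 1,
                                     scale = c("expectation", "linear")) {
  stopifnot(inherits(fit, "srm_fit"), is.function(metric))
  scale <- match.arg(scale)
  m <- if (is.character(layer)) match(layer, fit$data$layer_names) else as.integer(layer)
  if (is.na(m) || m < 1 || m > fit$map$M) stop_srm("unknown layer")
  n_re <- length(fit$re_draw_idx)
  vals <- vector("list", n_re)
  for (t in seq_len(n_re)) {
    th <- theta_matrix_draw(fit, t, m)
    if (scale == "expectation") th <- link_mean(th, fit$data$link_mode)
    vals[[t]] <- tryCatch(metric(th), error = function(e) {
      stop_srm("metric failed at draw %d: %s", t, conditionMessage(e))
    })
  }
  if (all(lengths(vals) == 1L)) unlist(vals) else do.call(rbind, vals)
}
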