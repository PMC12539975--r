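# Observed-data container and design assembly.
#
# A multiplex network is stored as an N x N x M outcome array G over one
# common node set, with G[i, j, m] the (directed) tie strength from sender i
# to receiver j in layer m.  Diagonal cells are stored but masked: self-ties
# are undefined in the social relations model and never enter any likelihood
# or summary.  All layers must share one outcome family, and Binomial layers
# require a matching exposure array of trial counts.

MODE_LINKS <- list(
  bernoulli = c("logit", "probit"),
  binomial  = c("logit", "probit"),
  poisson   = "log",
  gaussian  = "identity"
)

as_layer_array <- function(layers, what) {
  if (is.array(layers) && length(dim(layers)) == 3) {
    nm <- dimnames(layers)[[3]] %||% paste0("layer_", seq_len(dim(layers)[3]))
    layers <- lapply(seq_len(dim(layers)[3]), function(m) layers[, , m])
    names(layers) <- nm
  }
  if (!is.list(layers) || length(layers) == 0) {
    stop_srm("%s must be a non-empty named list of N x N matrices", what)
  }
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop_srm("%s layers must have unique non-empty names", what)
  }
  for (l in layers) {
    if (!is.matrix(l) || !is.numeric(l)) stop_srm("%s layers must be numeric matrices", what)
    if (nrow(l) != ncol(l)) stop_srm("%s layers must be square", what)
  }
  ns <- vapply(layers, nrow, 1L)
  if (length(unique(ns)) != 1) stop_srm("%s layers disagree on N", what)
  layers
}

collect_labels <- function(x) {
  if (is.matrix(x)) {
    rn <- rownames(x); cn <- colnames(x)
    if (!is.null(rn) && !is.null(cn) && !identical(rn, cn)) {
      stop_srm("row and column labels of a layer disagree")
    }
    rn %||% cn
  } else if (is.data.frame(x)) {
    rn <- rownames(x)
    if (identical(rn, as.character(seq_len(nrow(x))))) NULL else rn
  } else {
    NULL
  }
}

#' Assemble and validate a multiplex network data object
#'
#' Organizes outcome layers, optional exposure layers, node- and dyad-level
#' covariates, and block-structuring factors into one validated container.
#' Nodes are matched by position across all inputs; when labels are supplied
#' anywhere they must agree everywhere (no silent reordering).  Any missing
#' value off the diagonal is an error.
#'
#' @param outcomes Named list of M square N x N numeric matrices (or an
#'   N x N x M array); entry (i, j) is the tie from sender i to receiver j.
#' @param exposure Optional named list matching `outcomes` in names and order;
#'   required when `outcome_mode = "binomial"` (nonnegative integer trial
#'   counts bounding the outcomes).
#' @param node_covariates Optional data frame with one row per node (numeric
#'   or factor columns), used by focal/target regressions.
#' @param dyad_covariates Optional named list of N x N numeric matrices, used
#'   by the dyadic regression.
#' @param block_factors Optional data frame of factor columns (>= 2 levels
#'   each) defining block/assortativity structure.
#' @param outcome_mode One of "bernoulli", "binomial", "poisson", "gaussian".
#' @param link_mode One of "logit", "probit" (Bernoulli/Binomial), "log"
#'   (Poisson), "identity" (Gaussian).
#' @return An object of class `multiplex_data`.
#' @export
multiplex_data <- function(outcomes, exposure = NULL, node_covariates = NULL,
                           dyad_covariates = NULL, block_factors = NULL,
                           outcome_mode = c("bernoulli", "binomial", "poisson", "gaussian"),
                           link_mode = NULL) {
  outcome_mode <- match.arg(outcome_mode)
  link_mode <- link_mode %||% MODE_LINKS[[outcome_mode]][1]
  if (!link_mode %in% MODE_LINKS[[outcome_mode]]) {
    stop_srm("link_mode '%s' is incompatible with outcome_mode '%s' (allowed: %s)",
             link_mode, outcome_mode, paste(MODE_LINKS[[outcome_mode]], collapse = ", "))
  }

  outcomes <- as_layer_array(outcomes, "outcome")
  M <- length(outcomes)
  N <- nrow(outcomes[[1]])
  layer_names <- names(outcomes)

  labels <- NULL
  check_labels <- function(lab, where) {
    if (is.null(lab)) return(invisible())
    if (length(lab) != N) stop_srm("labels in %s have wrong length", where)
    if (is.null(labels)) labels <<- lab
    else if (!identical(as.character(labels), as.character(lab))) {
      stop_srm("node labels in %s disagree with labels supplied elsewhere", where)
    }
    invisible()
  }
  for (m in seq_len(M)) check_labels(collect_labels(outcomes[[m]]), sprintf("outcome layer '%s'", layer_names[m]))

  od <- offdiag_indices(N)
  for (m in seq_len(M)) {
    g <- outcomes[[m]][od]
    if (anyNA(g) || any(!is.finite(g))) {
      stop_srm("outcome layer '%s' has missing/non-finite off-diagonal values", layer_names[m])
    }
    bad <- switch(outcome_mode,
      bernoulli = any(!g %in% c(0, 1)),
      binomial  = any(g < 0 | g != round(g)),
      poisson   = any(g < 0 | g != round(g)),
      gaussian  = FALSE)
    if (bad) stop_srm("outcome layer '%s' violates the %s support", layer_names[m], outcome_mode)
  }

  if (outcome_mode == "binomial") {
    if (is.null(exposure)) stop_srm("exposure required for binomial outcomes")
    exposure <- as_layer_array(exposure, "exposure")
    if (nrow(exposure[[1]]) != N) stop_srm("exposure layers disagree with outcomes on N")
    if (!identical(names(exposure), layer_names)) {
      stop_srm("exposure layer names must match outcome layer names in the same order (got: %s vs %s)",
               paste(names(exposure), collapse = ","), paste(layer_names, collapse = ","))
    }
    for (m in seq_len(M)) {
      e <- exposure[[m]][od]
      if (anyNA(e) || any(e < 0 | e != round(e))) {
        stop_srm("exposure layer '%s' must contain nonnegative integers", layer_names[m])
      }
      if (any(outcomes[[m]][od] > e)) {
        stop_srm("outcomes exceed exposure in layer '%s'", layer_names[m])
      }
      check_labels(collect_labels(exposure[[m]]), sprintf("exposure layer '%s'", layer_names[m]))
    }
  } else if (!is.null(exposure)) {
    stop_srm("exposure is only meaningful for binomial outcomes")
  }

  if (!is.null(node_covariates)) {
    if (!is.data.frame(node_covariates) || nrow(node_covariates) != N) {
      stop_srm("node_covariates must be a data frame with N = %d rows", N)
    }
    if (anyNA(node_covariates)) stop_srm("node_covariates contain missing values")
    check_labels(collect_labels(node_covariates), "node_covariates")
    node_covariates <- as.data.frame(lapply(node_covariates, function(col) {
      if (is.character(col)) factor(col) else col
    }), stringsAsFactors = FALSE)
  }

  if (!is.null(dyad_covariates)) {
    if (!is.list(dyad_covariates) || is.null(names(dyad_covariates)) ||
        any(names(dyad_covariates) == "")) {
      stop_srm("dyad_covariates must be a named list of N x N numeric matrices")
    }
    for (nm in names(dyad_covariates)) {
      d <- dyad_covariates[[nm]]
      if (!is.matrix(d) || !is.numeric(d) || nrow(d) != N || ncol(d) != N) {
        stop_srm("dyad covariate '%s' must be a numeric N x N matrix", nm)
      }
      if (anyNA(d[od]) || any(!is.finite(d[od]))) {
        stop_srm("dyad covariate '%s' has missing off-diagonal values", nm)
      }
      check_labels(collect_labels(d), sprintf("dyad covariate '%s'", nm))
    }
  }

  if (!is.null(block_factors)) {
    if (!is.data.frame(block_factors) || nrow(block_factors) != N) {
      stop_srm("block_factors must be a data frame with N = %d rows", N)
    }
    if (anyNA(block_factors)) stop_srm("block_factors contain missing values")
    check_labels(collect_labels(block_factors), "block_factors")
    block_factors <- as.data.frame(lapply(block_factors, function(col) {
      if (is.character(col)) col <- factor(col)
      if (!is.factor(col)) stop_srm("block variables must be factors (categorical)")
      col <- droplevels(col)
      if (nlevels(col) < 2) stop_srm("block variables need at least 2 observed levels")
      col
    }), stringsAsFactors = FALSE)
  }

  G <- array(unlist(outcomes, use.names = FALSE), dim = c(N, N, M),
             dimnames = list(labels, labels, layer_names))
  E <- if (outcome_mode == "binomial") {
    array(unlist(exposure, use.names = FALSE), dim = c(N, N, M),
          dimnames = list(labels, labels, layer_names))
  } else NULL

  structure(
    list(n_nodes = N, n_layers = M, layer_names = layer_names,
         node_names = labels, outcomes = G, exposure = E,
         outcome_mode = outcome_mode, link_mode = link_mode,
         node_covariates = node_covariates, dyad_covariates = dyad_covariates,
         block_factors = block_factors),
    class = "multiplex_data"
  )
}

#' @export
print.multiplex_data <- function(x, ...) {
  cat(sprintf("multiplex_data: %d nodes, %d layer(s) [%s], %s/%s\n",
              x$n_nodes, x$n_layers, paste(x$layer_names, collapse = ", "),
              x$outcome_mode, x$link_mode))
  if (!is.null(x$node_covariates)) {
    cat("  node covariates:", paste(names(x$node_covariates), collapse = ", "), "\n")
  }
  if (!is.null(x$dyad_covariates)) {
    cat("  dyad covariates:", paste(names(x$dyad_covariates), collapse = ", "), "\n")
  }
  if (!is.null(x$block_factors)) {
    cat("  block factors:", paste(names(x$block_factors), collapse = ", "), "\n")
  }
  invisible(x)
}

formula_vars <- function(f, what) {
  if (is.null(f)) return(character())
  if (!inherits(f, "formula")) stop_srm("%s must be a one-sided formula", what)
  tl <- attr(stats::terms(f), "term.labels")
  if (any(grepl("[:*]", tl))) {
    stop_srm("%s: only additive main effects are supported (no interactions)", what)
  }
  tl
}

# Reference-coded indicator expansion of node covariates; reference level is
# the first level in sorted order.  Numeric columns optionally standardized.
expand_node_design <- function(covs, vars, standardize, what) {
  if (length(vars) == 0) {
    return(list(X = matrix(0, 0, 0), names = character(), reference = character()))
  }
  N <- nrow(covs %||% data.frame(x = numeric(0)))
  if (is.null(covs)) stop_srm("%s references covariates but none were supplied", what)
  missing_vars <- setdiff(vars, names(covs))
  if (length(missing_vars)) {
    stop_srm("%s: unknown variable(s): %s", what, paste(missing_vars, collapse = ", "))
  }
  cols <- list(); cnames <- character(); refs <- character()
  for (v in vars) {
    col <- covs[[v]]
    if (is.factor(col)) {
      lev <- sort(levels(droplevels(col)))
      col <- factor(col, levels = lev)
      refs <- c(refs, stats::setNames(lev[1], v))
      for (l in lev[-1]) {
        cols[[length(cols) + 1L]] <- as.numeric(col == l)
        cnames <- c(cnames, paste0(v, "=", l))
      }
    } else {
      x <- as.numeric(col)
      if (standardize) {
        s <- stats::sd(x)
        x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
      }
      cols[[length(cols) + 1L]] <- x
      cnames <- c(cnames, v)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- cnames
  list(X = X, names = cnames, reference = refs)
}

#' Assemble design matrices from the four regression formulas
#'
#' Builds the focal (sender), target (receiver), dyadic, and block design
#' structures used by both the simulator and the model.  Intercept-only
#' formulas (`~ 1`) yield zero-column designs; layer intercepts are always
#' separate parameters.  Categorical covariates are expanded to
#' reference-coded indicators (reference = first level in sorted order).
#'
#' @param data A `multiplex_data` object.
#' @param block_regression Formula over `block_factors` columns (categorical
#'   only); each variable contributes a full sender-block x receiver-block
#'   matrix of intercept offsets per layer.
#' @param focal_regression,target_regression Formulas over `node_covariates`.
#' @param dyad_regression Formula over the names of `dyad_covariates`.
#' @param standardize If `TRUE` (recommended), numeric covariate columns are
#'   centred and scaled to mean 0, SD 1 so slope priors act on a common scale.
#' @return An object of class `srm_designs`.
#' @export
build_designs <- function(data, block_regression = ~1, focal_regression = ~1,
                          target_regression = ~1, dyad_regression = ~1,
                          standardize = TRUE) {
  stopifnot(inherits(data, "multiplex_data"))
  N <- data$n_nodes
  fv <- formula_vars(focal_regression, "focal_regression")
  tv <- formula_vars(target_regression, "target_regression")
  dv <- formula_vars(dyad_regression, "dyad_regression")
  bv <- formula_vars(block_regression, "block_regression")

  overlap <- intersect(bv, union(fv, tv))
  if (length(overlap)) {
    stop_srm("variable(s) %s used in both block and focal/target regressions; choose one role",
             paste(overlap, collapse = ", "))
  }

  focal <- expand_node_design(data$node_covariates, fv, standardize, "focal_regression")
  target <- expand_node_design(data$node_covariates, tv, standardize, "target_regression")
  if (length(fv) == 0) focal$X <- matrix(0, N, 0)
  if (length(tv) == 0) target$X <- matrix(0, N, 0)

  dyad <- array(0, dim = c(N, N, length(dv)),
                dimnames = list(NULL, NULL, dv))
  if (length(dv)) {
    if (is.null(data$dyad_covariates)) stop_srm("dyad_regression references covariates but none were supplied")
    missing_vars <- setdiff(dv, names(data$dyad_covariates))
    if (length(missing_vars)) {
      stop_srm("dyad_regression: unknown variable(s): %s", paste(missing_vars, collapse = ", "))
    }
    od <- offdiag_indices(N)
    for (k in seq_along(dv)) {
      d <- data$dyad_covariates[[dv[k]]]
      if (standardize) {
        mu <- mean(d[od]); s <- stats::sd(d[od])
        d <- if (s > 0) (d - mu) / s else d - mu
      }
      diag(d) <- 0
      dyad[, , k] <- d
    }
  }

  block <- list()
  if (length(bv)) {
    if (is.null(data$block_factors)) stop_srm("block_regression references variables but no block_factors were supplied")
    missing_vars <- setdiff(bv, names(data$block_factors))
    if (length(missing_vars)) {
      stop_srm("block_regression: unknown variable(s): %s", paste(missing_vars, collapse = ", "))
    }
    for (v in bv) {
      col <- data$block_factors[[v]]
      if (!is.factor(col)) stop_srm("block variable '%s' must be categorical", v)
      lev <- sort(levels(droplevels(col)))
      col <- factor(col, levels = lev)
      block[[v]] <- list(name = v, index = as.integer(col), levels = lev,
                         n_levels = length(lev))
    }
  }

  structure(
    list(focal = focal$X, target = target$X, dyad = dyad, block = block,
         focal_names = focal$names, target_names = target$names,
         dyad_names = dv,
         reference_levels = c(focal$reference, target$reference),
         standardize = standardize,
         n_nodes = N),
    class = "srm_designs"
  )
}

# ---------------------------------------------------------------------------
# Delimited-text interfaces: square matrix CSV (with optional node labels)
# and long edge-list CSV.

#' Write a square layer matrix to CSV
#'
#' @param mat Square numeric matrix; row/column names, if present, are
#'   written as labels.
#' @param path Output file path.
#' @export
write_layer_matrix <- function(mat, path) {
  stopifnot(is_square_matrix(mat))
  if (is.null(rownames(mat))) {
    utils::write.table(mat, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.csv(mat, path, row.names = TRUE)
  }
  invisible(path)
}

#' Read a square layer matrix from CSV
#'
#' Accepts either a bare numeric matrix or one with a header row and a
#' leading column of node labels (the format `write_layer_matrix` produces).
#'
#' @param path CSV file path.
#' @param labels Optional node labels to assign (and check against any labels
#'   present in the file).
#' @return Square numeric matrix, with labels when available.
#' @export
read_layer_matrix <- function(path, labels = NULL) {
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_labels <- any(is.na(suppressWarnings(as.numeric(gsub("\"", "", cells)))))
  if (has_labels) {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    mat <- as.matrix(df)
    colnames(mat) <- colnames(df)
  } else {
    mat <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(mat) <- NULL
  }
  if (nrow(mat) != ncol(mat)) stop_srm("matrix in '%s' is not square", path)
  if (!is.numeric(mat)) stop_srm("matrix in '%s' has non-numeric cells", path)
  if (!is.null(labels)) {
    if (!is.null(rownames(mat)) && !identical(rownames(mat), as.character(labels))) {
      stop_srm("labels in '%s' disagree with supplied labels", path)
    }
    dimnames(mat) <- list(labels, labels)
  }
  mat
}

#' Write a multiplex data object as a long edge list CSV
#'
#' One row per off-diagonal cell per layer with columns
#' `sender, receiver, layer, value` (plus `exposure` for binomial data).
#'
#' @param data A `multiplex_data` object.
#' @param path Output file path.
#' @export
write_edge_list <- function(data, path) {
  stopifnot(inherits(data, "multiplex_data"))
  N <- data$n_nodes
  ids <- data$node_names %||% as.character(seq_len(N))
  od <- offdiag_indices(N)
  sender <- rep(ids, times = N)[od]
  receiver <- rep(ids, each = N)[od]
  rows <- lapply(seq_len(data$n_layers), function(m) {
    df <- data.frame(sender = sender, receiver = receiver,
                     layer = data$layer_names[m],
                     value = data$outcomes[, , m][od],
                     stringsAsFactors = FALSE)
    if (!is.null(data$exposure)) df$exposure <- data$exposure[, , m][od]
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long edge list CSV back into layer matrices
#'
#' @param path CSV with columns `sender, receiver, layer, value` and
#'   optionally `exposure`.
#' @return List with `outcomes` (named list of matrices), `exposure` (or
#'   `NULL`), and `node_names`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sender", "receiver", "layer", "value")
  if (!all(need %in% names(df))) {
    stop_srm("edge list must have columns %s", paste(need, collapse = ", "))
  }
  ids <- sort(unique(c(as.character(df$sender), as.character(df$receiver))))
  N <- length(ids)
  layers <- unique(df$layer)
  mk <- function(values, sub) {
    m <- matrix(0, N, N, dimnames = list(ids, ids))
    m[cbind(match(as.character(sub$sender), ids),
            match(as.character(sub$receiver), ids))] <- values
    m
  }
  outcomes <- list(); exposure <- if ("exposure" %in% names(df)) list() else NULL
  for (l in layers) {
    sub <- df[df$layer == l, ]
    outcomes[[l]] <- mk(sub$value, sub)
    if (!is.null(exposure)) exposure[[l]] <- mk(sub$exposure, sub)
  }
  list(outcomes = outcomes, exposure = exposure, node_names = ids)
}
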