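#' Declare a network layer
#'
#' A layer is one slice of the adjacency tensor, typed by the distribution
#' family that generated its entries. Gaussian layers carry a fixed
#' observation variance `sigma2`; the model estimates only the mean.
#'
#' @param index 1-based layer index, unique within a schema.
#' @param family one of `"bernoulli"`, `"poisson"`, `"gaussian"`.
#' @param directed logical; undirected layers are stored symmetrically and
#'   their likelihood sums run over unordered pairs (`i < j`) only.
#' @param sigma2 positive likelihood variance, Gaussian layers only.
#' @return a `layer_spec` object.
#' @export
layer_spec <- function(index, family = c("bernoulli", "poisson", "gaussian"),
                       directed = TRUE, sigma2 = NULL) {
  family <- match.arg(family)
  if (family == "gaussian") {
    if (is.null(sigma2)) sigma2 <- 1.0
    stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  } else if (!is.null(sigma2)) {
    stop("sigma2 is only meaningful for gaussian layers")
  }
  structure(list(index = as.integer(index), family = family,
                 directed = isTRUE(directed), sigma2 = sigma2),
            class = "layer_spec")
}

#' Declare a node attribute
#'
#' @param index 1-based attribute index.
#' @param family one of `"categorical"`, `"poisson"`, `"gaussian"`.
#' @param Z number of categories (categorical only, `Z >= 2`).
#' @param sigma2 positive likelihood variance, Gaussian attributes only.
#' @return an `attribute_spec` object.
#' @export
attribute_spec <- function(index, family = c("categorical", "poisson", "gaussian"),
                           Z = NULL, sigma2 = NULL) {
  family <- match.arg(family)
  if (family == "categorical") {
    if (is.null(Z)) stop("categorical attributes require Z")
    Z <- as.integer(Z)
    if (Z < 2L) stop("Z must be >= 2")
  } else if (!is.null(Z)) {
    stop("Z is only meaningful for categorical attributes")
  }
  if (family == "gaussian") {
    if (is.null(sigma2)) sigma2 <- 1.0
    stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  } else if (!is.null(sigma2)) {
    stop("sigma2 is only meaningful for gaussian attributes")
  }
  structure(list(index = as.integer(index), family = family, Z = Z,
                 sigma2 = sigma2),
            class = "attribute_spec")
}

#' Construct a typed multilayer network
#'
#' Holds the adjacency tensor as a list of `N x N` matrices (one per layer)
#' together with per-entry observation masks. Self-loop (diagonal) entries
#' are always unobserved: the model has no self-interaction term. For
#' undirected layers only the upper triangle (`i < j`) is observed, so each
#' unordered pair contributes once to the likelihood.
#'
#' @param A list of `N x N` numeric matrices, one per layer.
#' @param layers list of [layer_spec()] objects, parallel to `A`.
#' @param mask optional list of `N x N` logical matrices; defaults to all
#'   observed (minus the diagonal, and the lower triangle of undirected
#'   layers). The diagonal is forced unobserved regardless.
#' @param node_ids optional character vector of node names.
#' @return a `typed_network` object.
#' @export
typed_network <- function(A, layers, mask = NULL, node_ids = NULL) {
  stopifnot(is.list(A), is.list(layers), length(A) == length(layers))
  L <- length(A)
  N <- if (L > 0L) nrow(A[[1L]]) else length(node_ids)
  if (is.null(N)) stop("cannot determine N: provide layers or node_ids")
  for (l in seq_len(L)) {
    if (!is.matrix(A[[l]]) || !all(dim(A[[l]]) == c(N, N)))
      stop("layer ", l, ": A must be an N x N matrix")
  }
  if (is.null(mask)) {
    mask <- lapply(seq_len(L), function(l) {
      m <- matrix(TRUE, N, N)
      if (!layers[[l]]$directed) m[lower.tri(m, diag = TRUE)] <- FALSE
      m
    })
  }
  for (l in seq_len(L)) {
    diag(mask[[l]]) <- FALSE
    if (!layers[[l]]$directed) mask[[l]][lower.tri(mask[[l]])] <- FALSE
    A[[l]][!mask[[l]] & is.na(A[[l]])] <- 0  # unobserved cells need no value
  }
  if (is.null(node_ids)) node_ids <- as.character(seq_len(N))
  structure(list(N = N, L = L, layers = layers, A = A, mask = mask,
                 node_ids = node_ids,
                 directed = any(vapply(layers, function(s) s$directed, TRUE))),
            class = "typed_network")
}

#' Construct a node-attribute table
#'
#' @param X `N x P` numeric matrix; categorical attributes stored as integer
#'   labels in `1..Z`; `NA` marks missing entries (masked automatically).
#' @param attrs list of [attribute_spec()] objects, one per column.
#' @param mask optional `N x P` logical matrix of observed entries.
#' @param node_ids optional character vector of node names.
#' @return an `attribute_table` object.
#' @export
attribute_table <- function(X, attrs, mask = NULL, node_ids = NULL) {
  stopifnot(is.matrix(X), is.list(attrs), ncol(X) == length(attrs))
  if (is.null(mask)) mask <- !is.na(X)
  mask <- mask & !is.na(X)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(X)))
  structure(list(N = nrow(X), P = ncol(X), attrs = attrs, X = X, mask = mask,
                 node_ids = node_ids),
            class = "attribute_table")
}

#' Construct a latent state
#'
#' When `directed = FALSE` the in-coming memberships are aliased to the
#' out-going ones (`U = V`): only `U` is stored and [state_V()] returns it,
#' so any mutation of `U` is seen through `V`.
#'
#' @param U `N x K` matrix of out-going membership scores (real-valued).
#' @param V `N x K` matrix of in-coming membership scores, or `NULL` for
#'   undirected networks.
#' @param W list of `K x K` affinity matrices, one per layer.
#' @param H `K x Pstar` community-covariate matrix (`Pstar` expands each
#'   categorical attribute into its `Z` columns).
#' @param directed logical.
#' @return a `latent_state` object.
#' @export
latent_state <- function(U, W, H, V = NULL, directed = !is.null(V)) {
  stopifnot(is.matrix(U), is.list(W))
  if (directed && is.null(V)) stop("directed states require V")
  if (!directed) V <- NULL
  stopifnot(all(is.finite(U)), all(vapply(W, function(w) all(is.finite(w)), TRUE)))
  if (length(H)) stopifnot(all(is.finite(H)))
  structure(list(U = U, V = V, W = W, H = H, directed = directed,
                 K = ncol(U), N = nrow(U)),
            class = "latent_state")
}

#' In-coming membership scores of a latent state
#'
#' Returns `V` for directed states and the aliased `U` otherwise.
#' @param state a `latent_state`.
#' @return an `N x K` matrix.
#' @export
state_V <- function(state) if (state$directed) state$V else state$U

#' Gaussian prior specification
#'
#' Independent Gaussian priors per latent block; scalar means/variances are
#' broadcast over the block.
#'
#' @param mean_U,mean_V,mean_W,mean_H prior means (scalars).
#' @param var_U,var_V,var_W,var_H prior variances (positive scalars).
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(mean_U = 0, var_U = 1, mean_V = 0, var_V = 1,
                       mean_W = 0, var_W = 1, mean_H = 0, var_H = 1) {
  vars <- c(var_U, var_V, var_W, var_H)
  if (any(vars <= 0)) stop("prior variances must be positive")
  structure(list(mean_U = mean_U, var_U = var_U, mean_V = mean_V, var_V = var_V,
                 mean_W = mean_W, var_W = var_W, mean_H = mean_H, var_H = var_H),
            class = "prior_spec")
}

#' Fitting configuration
#'
#' @param K number of communities (`K >= 2` whenever Laplace matching to the
#'   simplex will be applied downstream).
#' @param step_size Adam step size.
#' @param max_iter maximum optimizer iterations.
#' @param tol relative objective-change convergence tolerance, assessed over
#'   a trailing window of `tol_window` iterations.
#' @param tol_window window length for the convergence check.
#' @param seed integer seed driving initialization.
#' @param covariance_mode `"none"` (MAP only) or `"blockwise"` (Laplace).
#' @param n_restarts independent restarts; the best objective wins.
#' @return a `fit_config` object.
#' @export
fit_config <- function(K, step_size = 0.01, max_iter = 2000L, tol = 1e-6,
                       tol_window = 50L, seed = 1L,
                       covariance_mode = c("none", "blockwise"),
                       n_restarts = 3L) {
  covariance_mode <- match.arg(covariance_mode)
  stopifnot(K >= 1, step_size > 0, max_iter >= 1, tol > 0, tol_window >= 1,
            n_restarts >= 1)
  structure(list(K = as.integer(K), step_size = step_size,
                 max_iter = as.integer(max_iter), tol = tol,
                 tol_window = as.integer(tol_window), seed = as.integer(seed),
                 covariance_mode = covariance_mode,
                 n_restarts = as.integer(n_restarts)),
            class = "fit_config")
}

#' Total H columns implied by a list of attribute specs
#' @param attrs list of `attribute_spec`s.
#' @return integer `Pstar`.
#' @export
n_h_columns <- function(attrs) {
  if (!length(attrs)) return(0L)
  sum(vapply(attrs, function(a) if (a$family == "categorical") a$Z else 1L, 1L))
}

#' Column offsets of each attribute inside H
#' @param attrs list of `attribute_spec`s.
#' @return integer vector of first-column indices (1-based).
#' @export
h_offsets <- function(attrs) {
  widths <- vapply(attrs, function(a) if (a$family == "categorical") a$Z else 1L, 1L)
  if (!length(widths)) return(integer())
  cumsum(c(1L, widths[-length(widths)]))
}

#' Validate a typed network and attribute table against their schemas
#'
#' Reports (rather than raises) domain violations: Bernoulli entries outside
#' \{0, 1\}, negative or non-integer Poisson values, categorical labels outside
#' `1..Z`, asymmetric observed entries in undirected layers.
#'
#' @param network a `typed_network` or `NULL`.
#' @param table an `attribute_table` or `NULL`.
#' @return a character vector of violations; empty when everything is valid.
#' @export
validate_data <- function(network = NULL, table = NULL) {
  out <- character()
  if (!is.null(network)) {
    for (l in seq_len(network$L)) {
      spec <- network$layers[[l]]
      a <- network$A[[l]]; m <- network$mask[[l]]
      idx <- which(m, arr.ind = TRUE)
      v <- a[m]
      bad <- switch(spec$family,
        bernoulli = !(v %in% c(0, 1)),
        poisson = !(is.finite(v) & v >= 0 & v == round(v)),
        gaussian = !is.finite(v))
      if (any(bad)) {
        for (r in utils::head(which(bad), 20L)) {
          out <- c(out, sprintf(
            "layer %d (%s): entry (%d, %d) = %g outside domain",
            l, spec$family, idx[r, 1L], idx[r, 2L], v[r]))
        }
      }
      if (any(diag(m))) out <- c(out, sprintf("layer %d: diagonal entries marked observed", l))
    }
  }
  if (!is.null(table)) {
    for (p in seq_len(table$P)) {
      spec <- table$attrs[[p]]
      v <- table$X[table$mask[, p], p]
      rows <- which(table$mask[, p])
      bad <- switch(spec$family,
        categorical = !(v %in% seq_len(spec$Z)),
        poisson = !(is.finite(v) & v >= 0 & v == round(v)),
        gaussian = !is.finite(v))
      if (any(bad)) {
        for (r in utils::head(which(bad), 20L)) {
          out <- c(out, sprintf(
            "attribute %d (%s): entry (node %d) = %g outside domain",
            p, spec$family, rows[r], v[r]))
        }
      }
    }
  }
  out
}

#' @export
print.typed_network <- function(x, ...) {
  cat(sprintf("typed_network: N = %d nodes, L = %d layers (%s)\n", x$N, x$L,
              paste(vapply(x$layers, function(s) s$family, ""), collapse = ", ")))
  invisible(x)
}

#' @export
print.attribute_table <- function(x, ...) {
  cat(sprintf("attribute_table: N = %d nodes, P = %d attributes (%s)\n",
              x$N, x$P,
              paste(vapply(x$attrs, function(s) s$family, ""), collapse = ", ")))
  invisible(x)
}

#' @export
print.latent_state <- function(x, ...) {
  cat(sprintf("latent_state: N = %d, K = %d, %d layer(s), %s\n", x$N, x$K,
              length(x$W), if (x$directed) "directed" else "undirected (U = V)"))
  invisible(x)
}
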