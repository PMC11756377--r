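# Packing of the latent state into a single parameter vector (U, then V for
# directed networks, then the L affinity matrices, then H), the matching
# expansion of priors, and the log-posterior itself. The plain-R
# log-posterior here is the reference definition; the compiled objective
# used by the optimizer must agree with it (and is tested to).

pack_state <- function(state) {
  c(as.vector(state$U),
    if (state$directed) as.vector(state$V),
    unlist(lapply(state$W, as.vector), use.names = FALSE),
    as.vector(state$H))
}

unpack_state <- function(theta, N, K, L, attrs, directed) {
  Pstar <- n_h_columns(attrs)
  off <- 0L
  take <- function(n) {
    v <- theta[(off + 1L):(off + n)]
    off <<- off + n
    v
  }
  U <- matrix(take(N * K), N, K)
  V <- if (directed) matrix(take(N * K), N, K) else NULL
  W <- lapply(seq_len(L), function(l) matrix(take(K * K), K, K))
  H <- if (Pstar > 0L) matrix(take(K * Pstar), K, Pstar) else matrix(0, K, 0L)
  latent_state(U = U, V = V, W = W, H = H, directed = directed)
}

# per-coordinate prior mean and variance vectors aligned with pack_state()
prior_vectors <- function(priors, N, K, L, attrs, directed) {
  Pstar <- n_h_columns(attrs)
  mean <- c(rep(priors$mean_U, N * K),
            if (directed) rep(priors$mean_V, N * K),
            rep(priors$mean_W, L * K * K),
            rep(priors$mean_H, K * Pstar))
  var <- c(rep(priors$var_U, N * K),
           if (directed) rep(priors$var_V, N * K),
           rep(priors$var_W, L * K * K),
           rep(priors$var_H, K * Pstar))
  list(mean = mean, var = var)
}

#' Gaussian log-prior of a latent state
#'
#' Sum of independent Gaussian log-densities over every entry of `U`, `V`,
#' `W` and `H`; for undirected states `V` is aliased to `U` and contributes
#' no separate terms.
#'
#' @param state a `latent_state`.
#' @param priors a [prior_spec()].
#' @param attrs list of attribute specs (fixes the width of `H`).
#' @return scalar log-density.
#' @export
log_prior <- function(state, priors, attrs = list()) {
  pv <- prior_vectors(priors, state$N, state$K, length(state$W), attrs,
                      state$directed)
  theta <- pack_state(state)
  sum(dnorm(theta, pv$mean, sqrt(pv$var), log = TRUE))
}

#' Log-posterior of a latent state (up to the evidence constant)
#'
#' `network_loglik + attribute_loglik + log_prior`, each term summing only
#' over observed entries.
#'
#' @param state a `latent_state`.
#' @param network a `typed_network` (or `NULL`).
#' @param table an `attribute_table` (or `NULL`).
#' @param priors a [prior_spec()].
#' @return scalar log-posterior.
#' @export
log_posterior <- function(state, network = NULL, table = NULL,
                          priors = prior_spec()) {
  attrs <- if (is.null(table)) list() else table$attrs
  total <- log_prior(state, priors, attrs)
  if (!is.null(network) && network$L > 0L)
    total <- total + network_loglik(network, expected_edges(state, network$layers))
  if (!is.null(table) && table$P > 0L)
    total <- total + attribute_loglik(table, expected_attributes(state, table$attrs))
  total
}

# ---- bridge to the compiled objective/gradient ----

# Precompute the dense arrays the compiled objective consumes.
model_data <- function(network, table, priors, K, directed) {
  N <- if (!is.null(network)) network$N else table$N
  L <- if (!is.null(network)) network$L else 0L
  A <- array(0, dim = c(N, N, max(L, 0L)))
  M <- array(0L, dim = c(N, N, max(L, 0L)))
  layer_fam <- integer(L)
  layer_s2 <- numeric(L)
  for (l in seq_len(L)) {
    a <- network$A[[l]]
    a[!network$mask[[l]]] <- 0
    a[is.na(a)] <- 0
    A[, , l] <- a
    M[, , l] <- network$mask[[l]] * 1L
    layer_fam[l] <- .fam_code_layer(network$layers[[l]]$family)
    layer_s2[l] <- if (is.null(network$layers[[l]]$sigma2)) 1.0 else network$layers[[l]]$sigma2
  }
  P <- if (!is.null(table)) table$P else 0L
  X <- matrix(0, N, P)
  XM <- matrix(0L, N, P)
  attr_fam <- integer(P)
  attr_Z <- integer(P)
  attr_s2 <- numeric(P)
  for (p in seq_len(P)) {
    x <- table$X[, p]
    x[!table$mask[, p]] <- 0
    x[is.na(x)] <- 0
    if (table$attrs[[p]]$family == "categorical") x <- x - 1  # 0-based for C++
    X[, p] <- x
    XM[, p] <- table$mask[, p] * 1L
    attr_fam[p] <- .fam_code_attr(table$attrs[[p]]$family)
    attr_Z[p] <- if (is.null(table$attrs[[p]]$Z)) 1L else table$attrs[[p]]$Z
    attr_s2[p] <- if (is.null(table$attrs[[p]]$sigma2)) 1.0 else table$attrs[[p]]$sigma2
  }
  attrs <- if (!is.null(table)) table$attrs else list()
  pv <- prior_vectors(priors, N, K, L, attrs, directed)
  storage.mode(M) <- "integer"
  list(N = N, K = as.integer(K), L = L, directed = directed, A = A, M = M,
       layer_fam = layer_fam, layer_s2 = layer_s2, X = X, XM = XM,
       attr_fam = attr_fam, attr_Z = attr_Z, attr_s2 = attr_s2,
       attrs = attrs, prior_mean = pv$mean, prior_var = pv$var)
}

# value and analytic gradient of the log-posterior at a packed theta
obj_grad <- function(theta, md, want_grad = TRUE) {
  .obj_grad_cpp(theta, md$N, md$K, md$directed, md$A, md$M, md$layer_fam,
                md$layer_s2, md$X, md$XM, md$attr_fam, md$attr_Z, md$attr_s2,
                md$prior_mean, md$prior_var, want_grad)
}
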