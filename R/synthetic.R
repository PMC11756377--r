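# Synthetic heterogeneous attributed multilayer networks drawn from the
# model itself: latents from Gaussian hyperpriors, then edges and
# attributes from the per-family likelihoods at the implied expected
# values. Used as ground truth for recovery tests and benchmarks.

#' Default benchmark schemas: three heterogeneous layers, three attributes
#'
#' One Bernoulli, one Poisson and one Gaussian layer; one categorical
#' attribute with `Z` categories, one Poisson and one Gaussian attribute.
#'
#' @param Z categories of the categorical attribute.
#' @param directed layer directedness.
#' @param sigma2 Gaussian likelihood variance for the real-valued layer and
#'   attribute.
#' @return list with elements `layers` and `attrs`.
#' @export
benchmark_schema <- function(Z = 4L, directed = TRUE, sigma2 = 1.0) {
  list(
    layers = list(
      layer_spec(1L, "bernoulli", directed = directed),
      layer_spec(2L, "poisson", directed = directed),
      layer_spec(3L, "gaussian", directed = directed, sigma2 = sigma2)),
    attrs = list(
      attribute_spec(1L, "categorical", Z = Z),
      attribute_spec(2L, "poisson"),
      attribute_spec(3L, "gaussian", sigma2 = sigma2)))
}

#' Draw a latent state from Gaussian hyperpriors
#'
#' `U`, `V` and `H` entries are i.i.d. Gaussian; affinity matrices get an
#' additive boost on their diagonal (on the unconstrained scale, before the
#' link) so layers are assortative by default.
#'
#' @param N,K nodes and communities.
#' @param layers,attrs schema lists (see [benchmark_schema()]).
#' @param seed integer seed.
#' @param mean,sd hyperprior mean and standard deviation of the membership
#'   blocks `U` and `V`. The default `sd = 3` plants overlapping but
#'   identifiable communities (median top membership weight around 0.85);
#'   `sd = 1` yields nodes so uniformly mixed that expected edge and
#'   attribute values barely vary between nodes.
#' @param w_sd hyperprior standard deviation of affinity entries.
#' @param w_diag_boost additive shift on diagonal entries of each affinity
#'   matrix; `0` removes the assortative structure.
#' @param h_sd hyperprior standard deviation of the community-covariate
#'   matrix. The default (2) makes per-community attribute profiles
#'   distinct enough that attributes carry real signal about memberships;
#'   at `h_sd = 1` the between-node variation of expected attribute values
#'   is smaller than the observation noise and constant predictors are
#'   near-optimal.
#' @param h_diag_boost additive shift on the "diagonal" entries (community
#'   `k`, category `k mod Z`) of each categorical block of `H`, making
#'   communities prefer distinct categories, in the same spirit as the
#'   assortative `w_diag_boost`; `0` leaves the profiles unstructured.
#' @param directed draw separate `U` and `V`?
#' @return a `latent_state`.
#' @export
sample_latent <- function(N, K, layers, attrs, seed = 1L, mean = 0, sd = 3,
                          w_sd = 1, w_diag_boost = 2, h_sd = 2,
                          h_diag_boost = 2, directed = TRUE) {
  Pstar <- n_h_columns(attrs)
  withr::with_seed(seed, {
    U <- matrix(rnorm(N * K, mean, sd), N, K)
    V <- if (directed) matrix(rnorm(N * K, mean, sd), N, K) else NULL
    W <- lapply(seq_along(layers), function(l) {
      w <- matrix(rnorm(K * K, mean, w_sd), K, K)
      diag(w) <- diag(w) + w_diag_boost
      w
    })
    H <- matrix(rnorm(K * Pstar, mean, h_sd), K, Pstar)
    off <- h_offsets(attrs)
    for (p in seq_along(attrs)) {
      if (attrs[[p]]$family == "categorical") {
        for (k in seq_len(K)) {
          z <- ((k - 1L) %% attrs[[p]]$Z) + 1L
          H[k, off[p] + z - 1L] <- H[k, off[p] + z - 1L] + h_diag_boost
        }
      }
    }
    latent_state(U = U, V = V, W = W, H = H, directed = directed)
  })
}

#' Sample a network from a latent state
#'
#' Per-entry draws at the expected values: Bernoulli(`lambda`),
#' Poisson(`lambda`) or Normal(`lambda`, `sigma2`). Diagonals are masked
#' out; undirected layers are sampled on the upper triangle and mirrored.
#'
#' @param state a `latent_state`.
#' @param layers list of [layer_spec()]s.
#' @param seed integer seed.
#' @return a `typed_network`.
#' @export
sample_network <- function(state, layers, seed = 1L) {
  Lambda <- expected_edges(state, layers)
  N <- state$N
  withr::with_seed(seed, {
    A <- lapply(seq_along(layers), function(l) {
      lam <- Lambda[[l]]
      a <- switch(layers[[l]]$family,
        bernoulli = matrix(rbinom(N * N, 1L, lam), N, N),
        poisson = matrix(rpois(N * N, lam), N, N),
        gaussian = matrix(rnorm(N * N, lam, sqrt(layers[[l]]$sigma2)), N, N))
      if (!layers[[l]]$directed) a[lower.tri(a)] <- t(a)[lower.tri(a)]
      diag(a) <- 0
      a
    })
    typed_network(A, layers)
  })
}

#' Sample node attributes from a latent state
#'
#' @param state a `latent_state`.
#' @param attrs list of [attribute_spec()]s.
#' @param seed integer seed.
#' @return an `attribute_table`.
#' @export
sample_attributes <- function(state, attrs, seed = 1L) {
  Pi <- expected_attributes(state, attrs)
  N <- state$N
  withr::with_seed(seed, {
    X <- vapply(seq_along(attrs), function(p) {
      a <- attrs[[p]]
      switch(a$family,
        categorical = apply(Pi[[p]], 1L, function(pr) sample.int(a$Z, 1L, prob = pr)),
        poisson = as.numeric(rpois(N, Pi[[p]])),
        gaussian = rnorm(N, Pi[[p]], sqrt(a$sigma2)))
    }, numeric(N))
    attribute_table(X, attrs)
  })
}

#' Sample a complete synthetic dataset
#'
#' @param N,K nodes and communities.
#' @param seed integer seed (latents, edges and attributes use fixed
#'   offsets of it).
#' @param schema schema list, defaults to [benchmark_schema()].
#' @param ... passed to [sample_latent()].
#' @return list with `network`, `table`, `state` (ground-truth latents) and
#'   `membership` (softmax of the true `U`, rows summing to one).
#' @export
sample_dataset <- function(N, K, seed = 1L, schema = benchmark_schema(), ...) {
  state <- sample_latent(N, K, schema$layers, schema$attrs, seed = seed, ...)
  network <- sample_network(state, schema$layers, seed = seed + 1L)
  table <- sample_attributes(state, schema$attrs, seed = seed + 2L)
  list(network = network, table = table, state = state,
       membership = softmax_rows(state$U), seed = seed, N = N, K = K)
}

#' Generate a benchmark suite over a grid of sizes and community counts
#'
#' Emits one dataset per `(N, K, replicate)` cell with three heterogeneous
#' layers and three attributes, each with ground-truth latents and
#' softmax-normalized memberships.
#'
#' @param N_grid,K_grid integer vectors.
#' @param n_replicates replicates per cell, each with a distinct seed.
#' @param seed base seed.
#' @param schema schema list.
#' @param ... passed to [sample_latent()].
#' @return list of datasets as returned by [sample_dataset()].
#' @export
make_benchmark <- function(N_grid = c(100L, 200L), K_grid = c(3L),
                           n_replicates = 1L, seed = 1L,
                           schema = benchmark_schema(), ...) {
  out <- list()
  i <- 0L
  for (N in N_grid) for (K in K_grid) for (r in seq_len(n_replicates)) {
    i <- i + 1L
    out[[i]] <- sample_dataset(N, K, seed = seed + 101L * (i - 1L),
                               schema = schema, ...)
  }
  out
}
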