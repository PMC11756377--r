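#' Row-wise softmax
#'
#' Maps each row of a real matrix onto the probability simplex, computed
#' stably by subtracting the row maximum before exponentiating.
#'
#' @param M numeric matrix (or vector, treated as one row).
#' @return a row-stochastic matrix of the same shape.
#' @export
softmax_rows <- function(M) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  if (!all(is.finite(M))) {
    bad <- which(!apply(M, 1L, function(r) all(is.finite(r))))
    stop("non-finite values in row(s): ", paste(bad, collapse = ", "))
  }
  E <- exp(M - apply(M, 1L, max))
  E / rowSums(E)
}

#' Link transformation for a distribution family
#'
#' Maps unconstrained real scores into the parameter space of a family:
#' logistic for Bernoulli, exponential for Poisson, identity for Gaussian,
#' and row-wise softmax across categories for categorical blocks.
#'
#' @param value numeric scalar/vector/matrix of unconstrained scores; for
#'   `"categorical"`, a matrix whose rows are softmaxed across columns.
#' @param family one of `"bernoulli"`, `"poisson"`, `"gaussian"`,
#'   `"categorical"`.
#' @return transformed value(s) in the family's parameter space.
#' @export
link_transform <- function(value, family) {
  switch(family,
    bernoulli = stats::plogis(value),
    poisson = exp(value),
    gaussian = value,
    categorical = softmax_rows(value),
    stop("unknown family: ", family))
}

# derivative of the scalar link, used by the plain-R gradient checks
link_deriv <- function(value, family) {
  switch(family,
    bernoulli = { p <- stats::plogis(value); p * (1 - p) },
    poisson = exp(value),
    gaussian = value * 0 + 1,
    stop("no scalar derivative for family: ", family))
}

#' Expected edge values
#'
#' Computes the expected-value tensor `lambda[[l]][i, j] =
#' f(U_i)' g_l(W_l) f(V_j)` with `f` the row softmax and `g_l` the layer's
#' link applied entrywise to the affinity matrix. Because `f(U_i)` and
#' `f(V_j)` are probability vectors, each `lambda` is a convex combination
#' of transformed affinities and lies in the layer's parameter space with no
#' clipping.
#'
#' @param state a `latent_state`.
#' @param layers list of [layer_spec()]s.
#' @return list of `N x N` matrices, one per layer.
#' @export
expected_edges <- function(state, layers) {
  if (length(state$W) != length(layers))
    stop("state has ", length(state$W), " affinity matrices for ",
         length(layers), " layers")
  mU <- softmax_rows(state$U)
  mV <- softmax_rows(state_V(state))
  lapply(seq_along(layers), function(l) {
    G <- link_transform(state$W[[l]], layers[[l]]$family)
    mU %*% G %*% t(mV)
  })
}

#' Expected attribute values
#'
#' Computes `pi[i, x] = mbar_i' g_x(H-block)` with
#' `mbar = (f(U) + f(V)) / 2` the average membership; categorical blocks are
#' row-softmaxed across categories so each node's expected category
#' distribution is a mixture of per-community category distributions and
#' sums to one.
#'
#' @param state a `latent_state`.
#' @param attrs list of [attribute_spec()]s.
#' @return list with one element per attribute: a length-`N` vector
#'   (Poisson/Gaussian) or `N x Z` matrix (categorical).
#' @export
expected_attributes <- function(state, attrs) {
  if (ncol(state$H) != n_h_columns(attrs))
    stop("H has ", ncol(state$H), " columns; schema implies ", n_h_columns(attrs))
  mU <- softmax_rows(state$U)
  mbar <- if (state$directed) (mU + softmax_rows(state$V)) / 2 else mU
  off <- h_offsets(attrs)
  lapply(seq_along(attrs), function(p) {
    a <- attrs[[p]]
    if (a$family == "categorical") {
      B <- state$H[, off[p]:(off[p] + a$Z - 1L), drop = FALSE]
      mbar %*% softmax_rows(B)
    } else {
      drop(mbar %*% link_transform(state$H[, off[p]], a$family))
    }
  })
}

#' Network log-likelihood
#'
#' Sum of per-entry log-densities over observed (masked-in) entries only:
#' Bernoulli, Poisson (including the `-log(A!)` constant), or Gaussian with
#' the layer's fixed `sigma2`.
#'
#' @param network a `typed_network`.
#' @param Lambda expected values from [expected_edges()].
#' @return a finite scalar.
#' @export
network_loglik <- function(network, Lambda) {
  total <- 0
  for (l in seq_len(network$L)) {
    spec <- network$layers[[l]]
    m <- network$mask[[l]]
    a <- network$A[[l]][m]
    lam <- Lambda[[l]][m]
    total <- total + switch(spec$family,
      bernoulli = {
        if (any(lam <= 0 | lam >= 1)) stop("bernoulli lambda outside (0,1) in layer ", l)
        sum(a * log(lam) + (1 - a) * log1p(-lam))
      },
      poisson = {
        if (any(lam <= 0)) stop("poisson lambda non-positive in layer ", l)
        sum(a * log(lam) - lam - lgamma(a + 1))
      },
      gaussian = sum(dnorm(a, lam, sqrt(spec$sigma2), log = TRUE)))
  }
  total
}

#' Attribute log-likelihood
#'
#' As [network_loglik()], with categorical / Poisson / Gaussian node
#' attributes over observed table entries.
#'
#' @param table an `attribute_table`.
#' @param Pi expected values from [expected_attributes()].
#' @return a finite scalar.
#' @export
attribute_loglik <- function(table, Pi) {
  total <- 0
  for (p in seq_len(table$P)) {
    spec <- table$attrs[[p]]
    obs <- table$mask[, p]
    x <- table$X[obs, p]
    total <- total + switch(spec$family,
      categorical = {
        pim <- Pi[[p]][obs, , drop = FALSE]
        if (any(pim <= 0)) stop("categorical pi non-positive in attribute ", p)
        sum(log(pim[cbind(seq_along(x), x)]))
      },
      poisson = {
        pi <- Pi[[p]][obs]
        if (any(pi <= 0)) stop("poisson pi non-positive in attribute ", p)
        sum(x * log(pi) - pi - lgamma(x + 1))
      },
      gaussian = sum(dnorm(x, Pi[[p]][obs], sqrt(spec$sigma2), log = TRUE)))
  }
  total
}
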