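#' Blockwise Laplace approximation of the posterior
#'
#' Approximates each latent block's posterior with a Gaussian centred at
#' the MAP: the covariance of block `b` is the inverse of the negative
#' block Hessian of the log-posterior at the MAP. The posterior is treated
#' as factorized across blocks (rows of `U`, rows of `V`, each layer's
#' affinity matrix, each attribute's column block of `H`), so only
#' within-block curvature is inverted. Hessians are obtained by central
#' finite differences of the exact analytic gradient, then symmetrized and
#' jittered (`1e-8` on the diagonal) before inversion; a block whose
#' smallest eigenvalue is still non-positive raises an error naming the
#' block.
#'
#' @param state MAP `latent_state` (from [fit_map()]).
#' @param network,table,priors the data and priors the MAP was fitted to.
#' @param blocks optional character subset of `c("U", "V", "W", "H")`.
#' @return a `gaussian_posterior`: list of blocks (`mean`, `cov`, `label`)
#'   plus convenience matrices `U_mean` / `U_var` (and `V_mean` / `V_var`)
#'   holding per-row posterior means and diagonal variances.
#' @export
laplace_covariance <- function(state, network = NULL, table = NULL,
                               priors = prior_spec(),
                               blocks = c("U", "V", "W", "H")) {
  md <- model_data(network, table, priors, state$K, state$directed)
  theta <- pack_state(state)
  N <- state$N; K <- state$K; L <- md$L
  Pstar <- n_h_columns(md$attrs)

  idx_U <- function(i) i + N * (seq_len(K) - 1L)
  v_base <- N * K
  w_base <- (if (state$directed) 2L else 1L) * N * K
  h_base <- w_base + L * K * K

  out <- list(blocks = list())
  add_block <- function(label, idx) {
    Sig <- block_covariance(theta, md, idx, label)
    out$blocks[[label]] <<- list(label = label, mean = theta[idx], cov = Sig)
  }

  if ("U" %in% blocks)
    for (i in seq_len(N)) add_block(sprintf("U.%d", i), idx_U(i))
  if (state$directed && "V" %in% blocks)
    for (i in seq_len(N)) add_block(sprintf("V.%d", i), v_base + idx_U(i))
  if ("W" %in% blocks && L > 0L)
    for (l in seq_len(L))
      add_block(sprintf("W.%d", l), w_base + (l - 1L) * K * K + seq_len(K * K))
  if ("H" %in% blocks && Pstar > 0L) {
    off <- h_offsets(md$attrs)
    for (p in seq_along(md$attrs)) {
      width <- if (md$attrs[[p]]$family == "categorical") md$attrs[[p]]$Z else 1L
      idx <- h_base + (off[p] - 1L) * K + seq_len(width * K)
      add_block(sprintf("H.%d", p), idx)
    }
  }

  if ("U" %in% blocks) {
    out$U_mean <- state$U
    out$U_var <- t(vapply(seq_len(N), function(i)
      diag(out$blocks[[sprintf("U.%d", i)]]$cov), numeric(K)))
  }
  if (state$directed && "V" %in% blocks) {
    out$V_mean <- state$V
    out$V_var <- t(vapply(seq_len(N), function(i)
      diag(out$blocks[[sprintf("V.%d", i)]]$cov), numeric(K)))
  }
  out$K <- K
  structure(out, class = "gaussian_posterior")
}

# negative block Hessian of the log-posterior, by central differences of
# the exact analytic gradient restricted to the block; symmetrized
neg_block_hessian <- function(theta, md, idx, h = 1e-5) {
  d <- length(idx)
  Hm <- matrix(0, d, d)
  for (c in seq_len(d)) {
    hc <- h * max(1, abs(theta[idx[c]]))
    tp <- theta; tp[idx[c]] <- tp[idx[c]] + hc
    tm <- theta; tm[idx[c]] <- tm[idx[c]] - hc
    gp <- obj_grad(tp, md)$grad[idx]
    gm <- obj_grad(tm, md)$grad[idx]
    Hm[, c] <- (gp - gm) / (2 * hc)
  }
  -(Hm + t(Hm)) / 2
}

# conditioned and inverted negative block Hessian
block_covariance <- function(theta, md, idx, label, h = 1e-5, jitter = 1e-8) {
  d <- length(idx)
  A <- neg_block_hessian(theta, md, idx, h) + diag(jitter, d)
  ev <- eigen(A, symmetric = TRUE)
  if (min(ev$values) <= 0)
    stop("singular block Hessian for block ", label,
         " (min eigenvalue ", signif(min(ev$values), 3),
         "); the state may not be at a maximum - consider more iterations ",
         "or larger jitter")
  Sig <- ev$vectors %*% (t(ev$vectors) / ev$values)
  (Sig + t(Sig)) / 2
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat(sprintf("gaussian_posterior: %d block(s), K = %d\n",
              length(x$blocks), x$K))
  invisible(x)
}
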