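# Small fixtures built in code, shared across test files.

tiny_schema <- function(Z = 4L, directed = TRUE) {
  benchmark_schema(Z = Z, directed = directed)
}

tiny_dataset <- function(N = 12L, K = 3L, seed = 42L, ...) {
  sample_dataset(N, K, seed = seed, ...)
}

# central finite-difference gradient of the plain-R log-posterior
fd_gradient <- function(theta, md, h = 1e-5) {
  vapply(seq_along(theta), function(c) {
    tp <- theta; tp[c] <- tp[c] + h
    tm <- theta; tm[c] <- tm[c] - h
    (hamnet:::obj_grad(tp, md, want_grad = FALSE)$value -
       hamnet:::obj_grad(tm, md, want_grad = FALSE)$value) / (2 * h)
  }, 0.0)
}

# central second differences of the objective itself (independent of the
# analytic-gradient path used by the implementation's Hessian)
fd_hessian_block <- function(theta, md, idx, h = 2e-3) {
  d <- length(idx)
  H <- matrix(0, d, d)
  f <- function(t) hamnet:::obj_grad(t, md, want_grad = FALSE)$value
  f0 <- f(theta)
  for (a in seq_len(d)) {
    for (b in a:d) {
      if (a == b) {
        tp <- theta; tp[idx[a]] <- tp[idx[a]] + h
        tm <- theta; tm[idx[a]] <- tm[idx[a]] - h
        H[a, a] <- (f(tp) - 2 * f0 + f(tm)) / h^2
      } else {
        tpp <- theta; tpp[idx[a]] <- tpp[idx[a]] + h; tpp[idx[b]] <- tpp[idx[b]] + h
        tpm <- theta; tpm[idx[a]] <- tpm[idx[a]] + h; tpm[idx[b]] <- tpm[idx[b]] - h
        tmp <- theta; tmp[idx[a]] <- tmp[idx[a]] - h; tmp[idx[b]] <- tmp[idx[b]] + h
        tmm <- theta; tmm[idx[a]] <- tmm[idx[a]] - h; tmm[idx[b]] <- tmm[idx[b]] - h
        H[a, b] <- H[b, a] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h^2)
      }
    }
  }
  H
}

random_state <- function(N, K, L, attrs, directed = TRUE, seed = 1L) {
  Pstar <- n_h_columns(attrs)
  withr::with_seed(seed, latent_state(
    U = matrix(rnorm(N * K), N, K),
    V = if (directed) matrix(rnorm(N * K), N, K) else NULL,
    W = lapply(seq_len(L), function(l) matrix(rnorm(K * K), K, K)),
    H = matrix(rnorm(K * Pstar), K, Pstar),
    directed = directed))
}

# all K! permutations of 1..K (K small)
all_perms <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(first) {
    rest <- setdiff(seq_len(K), first)
    cbind(first, matrix(rest[sub], nrow(sub), K - 1L))
  }))
}
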