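test_that("softmax_rows is stable, normalized and shift-invariant", {
  expect_equal(drop(softmax_rows(c(0, 0, 0))), rep(1 / 3, 3))
  expect_equal(drop(softmax_rows(c(log(2), 0))), c(2 / 3, 1 / 3))
  for (c in c(-1000, 0, 7, 1000)) {
    expect_equal(drop(softmax_rows(c(c, c + 1, c + 2))),
                 drop(softmax_rows(c(0, 1, 2))))
  }
  M <- matrix(rnorm(20), 4, 5)
  expect_equal(rowSums(softmax_rows(M)), rep(1, 4), tolerance = 1e-12)
  M[2, 3] <- Inf
  expect_error(softmax_rows(M), "row\\(s\\): 2")
})

test_that("link_transform maps into each family's parameter space", {
  expect_equal(link_transform(0, "bernoulli"), 0.5)
  expect_equal(link_transform(0, "poisson"), 1.0)
  expect_equal(link_transform(3.7, "gaussian"), 3.7)
  expect_equal(rowSums(link_transform(matrix(rnorm(6), 2, 3), "categorical")),
               rep(1, 2))
  expect_error(link_transform(0, "cauchy"), "unknown family")
})

test_that("expected edge values follow the bilinear membership form", {
  layers <- list(layer_spec(1, "bernoulli"))
  # K = 1: memberships are degenerate [1], lambda = g(W)
  st <- latent_state(U = matrix(0, 4, 1), V = matrix(0, 4, 1),
                     W = list(matrix(0, 1, 1)), H = matrix(0, 1, 0))
  expect_equal(unique(as.vector(expected_edges(st, layers)[[1]])), 0.5)
  expect_equal(unique(as.vector(
    expected_edges(st, list(layer_spec(1, "poisson")))[[1]])), 1.0)

  # K = 2 one-hot memberships pick out a single affinity entry
  big <- 50
  Wl <- matrix(c(0.3, 0.9, 0.7, 0.2), 2, 2)  # [[a, b], [c, d]] with b = 0.7
  st2 <- latent_state(
    U = matrix(c(big, 0), 2, 2, byrow = TRUE),   # f(U_i) -> (1, 0)
    V = matrix(c(0, big), 2, 2, byrow = TRUE),   # f(V_j) -> (0, 1)
    W = list(Wl), H = matrix(0, 2, 0))
  lam <- expected_edges(st2, list(layer_spec(1, "gaussian")))[[1]]
  expect_equal(lam[1, 2], Wl[1, 2], tolerance = 1e-12)
})

test_that("expected edge values lie in the parameter space for arbitrary latents", {
  for (seed in 1:5) {
    st <- random_state(6, 3, 3, list(), seed = seed)
    st$U <- st$U * 10; st$W <- lapply(st$W, function(w) w * 10)
    lam <- expected_edges(st, tiny_schema()$layers)
    expect_true(all(lam[[1]] > 0 & lam[[1]] < 1))
    expect_true(all(lam[[2]] > 0))
    expect_true(all(is.finite(lam[[3]])))
  }
})

test_that("expected attribute values mix community profiles correctly", {
  attrs <- list(attribute_spec(1, "gaussian"))
  h <- 2.4
  st <- latent_state(U = matrix(rnorm(5), 5, 1), V = matrix(rnorm(5), 5, 1),
                     W = list(), H = matrix(h, 1, 1))
  expect_equal(expected_attributes(st, attrs)[[1]], rep(h, 5))

  attrs_cat <- list(attribute_spec(1, "categorical", Z = 4))
  st2 <- random_state(5, 3, 0, attrs_cat, seed = 2)
  st2$H[] <- 0
  Pi <- expected_attributes(st2, attrs_cat)[[1]]
  expect_equal(as.vector(Pi), rep(1 / 4, 20))

  # undirected aliasing: the U/V average equals f(U)
  st3 <- random_state(5, 3, 0, attrs_cat, directed = FALSE, seed = 3)
  Pi3 <- expected_attributes(st3, attrs_cat)[[1]]
  expect_equal(Pi3, softmax_rows(st3$U) %*% softmax_rows(st3$H))
  expect_equal(rowSums(Pi3), rep(1, 5), tolerance = 1e-12)
})

test_that("log-likelihoods match single-entry closed forms and a loop oracle", {
  # single Bernoulli entry A = 1 with lambda = 0.5
  A <- list(matrix(0, 2, 2)); A[[1]][1, 2] <- 1
  m <- list(matrix(FALSE, 2, 2)); m[[1]][1, 2] <- TRUE
  net <- typed_network(A, list(layer_spec(1, "bernoulli")), mask = m)
  expect_equal(network_loglik(net, list(matrix(0.5, 2, 2))), log(0.5))

  # single Poisson entry A = 0, lambda = 1
  net$layers[[1]] <- layer_spec(1, "poisson")
  net$A[[1]][1, 2] <- 0
  expect_equal(network_loglik(net, list(matrix(1, 2, 2))), -1)

  # one categorical entry with uniform probabilities, one exact Gaussian
  tab <- attribute_table(matrix(c(2, 1.3), 1, 2),
                         list(attribute_spec(1, "categorical", Z = 4),
                              attribute_spec(2, "gaussian", sigma2 = 1)))
  Pi <- list(matrix(1 / 4, 1, 4), 1.3)
  expect_equal(attribute_loglik(tab, Pi), log(1 / 4) - 0.5 * log(2 * pi))

  # random instance against a brute-force loop over entries
  ds <- tiny_dataset(N = 8, seed = 9)
  st <- random_state(8, 3, 3, ds$table$attrs, seed = 4)
  Lam <- expected_edges(st, ds$network$layers)
  ref <- 0
  for (l in 1:3) {
    spec <- ds$network$layers[[l]]
    for (i in 1:8) for (j in 1:8) {
      if (!ds$network$mask[[l]][i, j]) next
      a <- ds$network$A[[l]][i, j]; lam <- Lam[[l]][i, j]
      ref <- ref + switch(spec$family,
        bernoulli = dbinom(a, 1, lam, log = TRUE),
        poisson = dpois(a, lam, log = TRUE),
        gaussian = dnorm(a, lam, sqrt(spec$sigma2), log = TRUE))
    }
  }
  expect_equal(network_loglik(ds$network, Lam), ref, tolerance = 1e-10)

  Pi <- expected_attributes(st, ds$table$attrs)
  refx <- 0
  for (p in 1:3) {
    spec <- ds$table$attrs[[p]]
    for (i in 1:8) {
      if (!ds$table$mask[i, p]) next
      x <- ds$table$X[i, p]
      refx <- refx + switch(spec$family,
        categorical = log(Pi[[p]][i, x]),
        poisson = dpois(x, Pi[[p]][i], log = TRUE),
        gaussian = dnorm(x, Pi[[p]][i], sqrt(spec$sigma2), log = TRUE))
    }
  }
  expect_equal(attribute_loglik(ds$table, Pi), refx, tolerance = 1e-10)
})

test_that("log-likelihood is equivariant under consistent node relabeling", {
  ds <- tiny_dataset(N = 10, seed = 3)
  st <- random_state(10, 3, 3, ds$table$attrs, seed = 5)
  base <- network_loglik(ds$network, expected_edges(st, ds$network$layers)) +
    attribute_loglik(ds$table, expected_attributes(st, ds$table$attrs))
  perm <- withr::with_seed(1, sample(10))
  net2 <- ds$network
  for (l in 1:3) {
    net2$A[[l]] <- ds$network$A[[l]][perm, perm]
    net2$mask[[l]] <- ds$network$mask[[l]][perm, perm]
  }
  tab2 <- ds$table
  tab2$X <- ds$table$X[perm, , drop = FALSE]
  tab2$mask <- ds$table$mask[perm, , drop = FALSE]
  st2 <- st
  st2$U <- st$U[perm, ]; st2$V <- st$V[perm, ]
  relabeled <- network_loglik(net2, expected_edges(st2, net2$layers)) +
    attribute_loglik(tab2, expected_attributes(st2, tab2$attrs))
  expect_equal(relabeled, base, tolerance = 1e-10)
})

test_that("log-likelihood depends only on the set of observed entries", {
  ds <- tiny_dataset(N = 8, seed = 6)
  st <- random_state(8, 3, 3, ds$table$attrs, seed = 7)
  Lam <- expected_edges(st, ds$network$layers)
  base <- network_loglik(ds$network, Lam)
  # corrupt values outside the mask: no effect
  net2 <- ds$network
  net2$A[[1]][!net2$mask[[1]]] <- 77
  expect_equal(network_loglik(net2, Lam), base)
})
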