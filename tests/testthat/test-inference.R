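test_that("log_prior matches closed forms and a loop oracle", {
  attrs <- tiny_schema()$attrs
  st <- random_state(4, 2, 3, attrs, seed = 1)
  st$U[] <- 0; st$V[] <- 0; st$H[] <- 0
  for (l in 1:3) st$W[[l]][] <- 0
  D <- 2 * 4 * 2 + 3 * 4 + 2 * 6
  expect_equal(log_prior(st, prior_spec(), attrs), -D / 2 * log(2 * pi))

  st2 <- random_state(4, 2, 3, attrs, seed = 2)
  pv <- hamnet:::prior_vectors(prior_spec(mean_U = 0.5, var_W = 2), 4, 2, 3,
                               attrs, TRUE)
  theta <- hamnet:::pack_state(st2)
  ref <- sum(vapply(seq_along(theta), function(i)
    dnorm(theta[i], pv$mean[i], sqrt(pv$var[i]), log = TRUE), 0.0))
  expect_equal(log_prior(st2, prior_spec(mean_U = 0.5, var_W = 2), attrs), ref)
})

test_that("log_posterior reduces to the prior when nothing is observed", {
  ds <- tiny_dataset(N = 6, seed = 8)
  for (l in 1:3) ds$network$mask[[l]][] <- FALSE
  ds$table$mask[] <- FALSE
  st <- random_state(6, 3, 3, ds$table$attrs, seed = 3)
  expect_equal(log_posterior(st, ds$network, ds$table),
               log_prior(st, prior_spec(), ds$table$attrs))
})

test_that("adding one observed entry adds exactly its log-density", {
  ds <- tiny_dataset(N = 6, seed = 8)
  st <- random_state(6, 3, 3, ds$table$attrs, seed = 3)
  net0 <- ds$network
  net0$mask[[1]][1, 2] <- FALSE
  base <- log_posterior(st, net0, ds$table)
  with_entry <- log_posterior(st, ds$network, ds$table)
  lam <- expected_edges(st, ds$network$layers)[[1]][1, 2]
  expect_equal(with_entry - base,
               dbinom(ds$network$A[[1]][1, 2], 1, lam, log = TRUE),
               tolerance = 1e-9)
})

test_that("compiled objective equals the plain-R log-posterior", {
  for (seed in 1:3) {
    ds <- tiny_dataset(N = 9, seed = seed)
    md <- hamnet:::model_data(ds$network, ds$table, prior_spec(), 3, TRUE)
    st <- random_state(9, 3, 3, ds$table$attrs, seed = seed + 10)
    theta <- hamnet:::pack_state(st)
    expect_equal(hamnet:::obj_grad(theta, md, want_grad = FALSE)$value,
                 log_posterior(st, ds$network, ds$table), tolerance = 1e-10)
  }
})

test_that("analytic gradient matches central finite differences", {
  ds <- tiny_dataset(N = 10, seed = 2)
  md <- hamnet:::model_data(ds$network, ds$table, prior_spec(), 3, TRUE)
  theta <- withr::with_seed(4, rnorm(length(md$prior_mean)))
  g <- hamnet:::obj_grad(theta, md)$grad
  fd <- fd_gradient(theta, md)
  expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-5)
})

test_that("fit_map with no observations recovers the prior mean", {
  net <- typed_network(list(matrix(0, 5, 5)), list(layer_spec(1, "bernoulli")),
                       mask = list(matrix(FALSE, 5, 5)))
  cfg <- fit_config(K = 2, seed = 1, max_iter = 5000, step_size = 0.05,
                    tol = 1e-10, n_restarts = 1)
  pri <- prior_spec(mean_U = 0.7, mean_V = -0.3, mean_W = 1.2)
  fit <- suppressWarnings(fit_map(net, priors = pri, config = cfg))
  expect_lt(max(abs(fit$state$U - 0.7)), 1e-3)
  expect_lt(max(abs(fit$state$V + 0.3)), 1e-3)
  expect_lt(max(abs(fit$state$W[[1]] - 1.2)), 1e-3)
})

test_that("scalar Gaussian toy recovers the conjugate posterior exactly", {
  x <- 1.7
  tab <- attribute_table(matrix(x, 1, 1),
                         list(attribute_spec(1, "gaussian", sigma2 = 1)))
  cfg <- fit_config(K = 1, seed = 2, max_iter = 3000, n_restarts = 1)
  fit <- fit_map(table = tab, config = cfg)
  expect_equal(drop(fit$state$H), x / 2, tolerance = 1e-4)
  post <- laplace_covariance(fit$state, table = tab)
  expect_equal(drop(post$blocks$H.1$cov), 0.5, tolerance = 1e-6)
})

test_that("the optimizer reaches at least the generating state's objective", {
  ds <- tiny_dataset(N = 30, seed = 19)
  cfg <- fit_config(K = 3, seed = 1, step_size = 0.05, max_iter = 800,
                    n_restarts = 1)
  fit <- suppressWarnings(fit_map(ds$network, ds$table, config = cfg))
  truth_obj <- log_posterior(ds$state, ds$network, ds$table, prior_spec())
  expect_gte(fit$objective, truth_obj - 0.01 * abs(truth_obj))
})

test_that("fits are bitwise deterministic given seed and config", {
  ds <- tiny_dataset(N = 8, seed = 4)
  cfg <- fit_config(K = 2, seed = 9, max_iter = 120, n_restarts = 2)
  f1 <- suppressWarnings(fit_map(ds$network, ds$table, config = cfg))
  f2 <- suppressWarnings(fit_map(ds$network, ds$table, config = cfg))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$state$U, f2$state$U)
})

test_that("objective trace is non-decreasing after burn-in within tolerance", {
  # network-only fit so no label-realignment phases interleave the trace
  ds <- tiny_dataset(N = 10, seed = 5)
  cfg <- fit_config(K = 3, seed = 1, max_iter = 600, n_restarts = 1)
  fit <- suppressWarnings(fit_map(ds$network, config = cfg))
  tr <- fit$trace
  burn <- ceiling(length(tr) * 0.05)
  drops <- diff(tr[burn:length(tr)])
  expect_gt(min(drops), -1e-2 * max(abs(diff(range(tr))), 1))
})

test_that("prior-only Laplace covariance equals the prior covariance", {
  net <- typed_network(list(matrix(0, 4, 4)), list(layer_spec(1, "poisson")),
                       mask = list(matrix(FALSE, 4, 4)))
  pri <- prior_spec(var_U = 2, var_V = 0.5, var_W = 3)
  cfg <- fit_config(K = 2, seed = 1, max_iter = 1500, n_restarts = 1)
  fit <- suppressWarnings(fit_map(net, priors = pri, config = cfg))
  post <- laplace_covariance(fit$state, net, priors = pri)
  expect_equal(post$blocks$U.1$cov, diag(2, 2), tolerance = 1e-4)
  expect_equal(post$blocks$V.3$cov, diag(0.5, 2), tolerance = 1e-4)
  expect_equal(post$blocks$W.1$cov, diag(3, 4), tolerance = 1e-4)
})

test_that("block Hessians match second differences of the objective", {
  ds <- tiny_dataset(N = 6, seed = 12)
  md <- hamnet:::model_data(ds$network, ds$table, prior_spec(), 2, TRUE)
  cfg <- fit_config(K = 2, seed = 3, max_iter = 2500, n_restarts = 1)
  fit <- suppressWarnings(fit_map(ds$network, ds$table, config = cfg))
  theta <- hamnet:::pack_state(fit$state)
  post <- laplace_covariance(fit$state, ds$network, ds$table)
  # U row block and the categorical H block, against the objective-value FD
  idx_U3 <- 3 + 6 * (0:1)
  ref <- -fd_hessian_block(theta, md, idx_U3)
  expect_equal(solve(post$blocks$U.3$cov), ref, tolerance = 1e-3)
  h_base <- 2 * 6 * 2 + 3 * 4
  idx_H1 <- h_base + 1:8
  refH <- -fd_hessian_block(theta, md, idx_H1)
  expect_equal(solve(post$blocks$H.1$cov), refH, tolerance = 1e-3)
})
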