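test_that("folds partition observed cells evenly and deterministically", {
  ds <- tiny_dataset(N = 11, seed = 21)
  plan <- make_folds(ds$network, ds$table, 5, seed = 3)
  for (l in 1:3) {
    cells <- plan$network[[l]]$cells
    expect_setequal(cells, which(ds$network$mask[[l]]))
    sizes <- tabulate(plan$network[[l]]$fold, 5)
    expect_lte(diff(range(sizes)), 1)
  }
  # 100 cells over 5 folds -> exactly 20 each
  A <- list(matrix(0, 11, 11))
  m <- list(matrix(FALSE, 11, 11))
  offdiag <- which(row(m[[1]]) != col(m[[1]]))
  m[[1]][offdiag[1:100]] <- TRUE
  net1 <- typed_network(A, list(layer_spec(1, "bernoulli")), mask = m)
  p1 <- make_folds(net1, n_folds = 5, seed = 1)
  expect_equal(tabulate(p1$network[[1]]$fold, 5), rep(20, 5))

  plan2 <- make_folds(ds$network, ds$table, 5, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_folds(net1, n_folds = 200, seed = 1), "fewer observed")
})

test_that("held-out predictions live in each family's parameter space", {
  ds <- tiny_dataset(N = 10, seed = 22)
  plan <- make_folds(ds$network, ds$table, 4, seed = 2)
  st <- random_state(10, 3, 3, ds$table$attrs, seed = 1)
  pr <- predict_heldout(st, ds$network, ds$table, plan, 2)
  expect_true(all(pr$layer1$pred > 0 & pr$layer1$pred < 1))
  expect_true(all(pr$layer2$pred > 0))
  expect_equal(rowSums(pr$attr1$pred), rep(1, nrow(pr$attr1$pred)),
               tolerance = 1e-12)
  expect_true(all(pr$attr2$pred > 0))
})

test_that("leakage is detected when held-out cells were observed during fit", {
  ds <- tiny_dataset(N = 10, seed = 22)
  plan <- make_folds(ds$network, ds$table, 4, seed = 2)
  st <- random_state(10, 3, 3, ds$table$attrs, seed = 1)
  expect_error(
    predict_heldout(st, ds$network, ds$table, plan, 2,
                    train_network = ds$network),
    "leakage")
  tr <- hamnet:::mask_fold(ds$network, ds$table, plan, 2)
  expect_silent(predict_heldout(st, ds$network, ds$table, plan, 2,
                                train_network = tr$network,
                                train_table = tr$table))
})

test_that("fitting never reads held-out values", {
  ds <- tiny_dataset(N = 10, seed = 23)
  plan <- make_folds(ds$network, ds$table, 4, seed = 5)
  tr <- hamnet:::mask_fold(ds$network, ds$table, plan, 1)
  cfg <- fit_config(K = 2, seed = 7, max_iter = 150, n_restarts = 1)
  f1 <- suppressWarnings(fit_map(tr$network, tr$table, config = cfg))
  # corrupt the held-out cells wildly; the fitted state must be identical
  tr2 <- tr
  held <- plan$network[[1]]$cells[plan$network[[1]]$fold == 1]
  tr2$network$A[[1]][held] <- 1 - tr2$network$A[[1]][held]
  heldx <- plan$table[[3]]$cells[plan$table[[3]]$fold == 1]
  tr2$table$X[heldx, 3] <- 1e6
  f2 <- suppressWarnings(fit_map(tr2$network, tr2$table, config = cfg))
  expect_identical(f1$state$U, f2$state$U)
  expect_identical(f1$trace, f2$trace)
})

test_that("metrics match closed forms and an all-pairs AUC oracle", {
  expect_equal(unname(score_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                                        "bernoulli")), 1)
  expect_equal(unname(score_predictions(c(3, 1), c(3, 1), "poisson")), 0)
  expect_equal(unname(score_predictions(c(1, 2), c(1, 2), "gaussian")), 0)
  pm <- matrix(c(0.8, 0.1, 0.1, 0.1, 0.8, 0.1), 2, 3, byrow = TRUE)
  expect_equal(unname(score_predictions(pm, c(1, 2), "categorical")), 1)

  # hand-computable 4-point AUC with a tie, against pair counting
  scores <- c(0.2, 0.5, 0.5, 0.9); labels <- c(0, 1, 0, 1)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  brute <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                       ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(auc_score(scores, labels), brute)
  expect_true(is.na(auc_score(c(0.1, 0.9), c(1, 1))))

  expect_equal(unname(score_predictions(c(0, 4), c(1, 2), "poisson")), 1.5)
  expect_equal(unname(score_predictions(c(0, 4), c(1, 2), "poisson",
                                        mae_mode = "max")), 2)
})

test_that("baselines are the declared constant predictors", {
  expect_equal(baseline_predict(c(0, 0, 0, 1), "bernoulli", "average"), 0.25)
  expect_equal(baseline_predict(c(1, 1, 2, 4), "poisson", "max_frequency"), 1)
  expect_equal(baseline_predict(rep(c(1, 2, 2, 3), 5), "categorical",
                                "uniform", Z = 4), rep(0.25, 4))
  expect_equal(baseline_predict(c(1, 2, 2, 3), "categorical", "average", Z = 4),
               c(0.25, 0.5, 0.25, 0))
  expect_equal(baseline_predict(c(1, 2, 2, 3), "categorical",
                                "max_frequency", Z = 4), c(0, 1, 0, 0))
  expect_error(baseline_predict(c(1, 2), "gaussian", "uniform"), "categorical")
})

test_that("cross_validate reports the requested grid reproducibly", {
  ds <- tiny_dataset(N = 14, seed = 31)
  cfg <- fit_config(K = 2, seed = 4, max_iter = 120, n_restarts = 1,
                    step_size = 0.05)
  rep1 <- cross_validate(ds$network, ds$table, K_grid = 2, config = cfg,
                         n_folds = 3)
  expect_equal(unique(rep1$aggregated$K), 2)
  expect_setequal(unique(rep1$aggregated$target),
                  c("layer1", "layer2", "layer3", "attr1", "attr2", "attr3"))
  expect_true(all(rep1$aggregated$mean[rep1$aggregated$metric == "auc"] >= 0 &
                    rep1$aggregated$mean[rep1$aggregated$metric == "auc"] <= 1))
  rep2 <- cross_validate(ds$network, ds$table, K_grid = 2, config = cfg,
                         n_folds = 3)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_equal(nrow(rep1$selection), 6)
})

test_that("posterior-predictive distances are non-negative with the right pair counts", {
  ds <- tiny_dataset(N = 10, seed = 33)
  rep <- posterior_predictive_check(ds$state, ds$network, ds$table,
                                    n_samples = 2, seed = 4)
  for (tn in names(rep)) {
    expect_length(rep[[tn]]$sample_vs_sample, 1)  # choose(2, 2) = 1 pair
    expect_length(rep[[tn]]$sample_vs_input, 2)
    expect_true(all(rep[[tn]]$sample_vs_sample >= 0))
    expect_true(all(rep[[tn]]$sample_vs_input >= 0))
  }
  rep5 <- posterior_predictive_check(ds$state, ds$network, ds$table,
                                     n_samples = 5, seed = 4)
  expect_length(rep5$layer1$sample_vs_sample, choose(5, 2))
})

test_that("well-specified posterior-predictive distances overlap; corrupted ones do not", {
  ds <- tiny_dataset(N = 40, seed = 35)
  rep <- posterior_predictive_check(ds$state, ds$network, ds$table,
                                    n_samples = 8, seed = 6)
  for (tn in c("layer1", "layer3")) {
    ss <- rep[[tn]]$sample_vs_sample; si <- rep[[tn]]$sample_vs_input
    expect_lt(max(min(si), min(ss)), min(max(si), max(ss)) + 1e-12)
  }
  bad <- ds$state
  bad$W <- lapply(bad$W, function(w) w * 0)
  repb <- posterior_predictive_check(bad, ds$network, ds$table,
                                     n_samples = 8, seed = 6)
  expect_gt(min(repb$layer2$sample_vs_input), max(repb$layer2$sample_vs_sample))
})
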