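# Masked cross-validation, per-type prediction metrics, constant baselines,
# model selection over K, and posterior-predictive checks. Hold-outs are
# cellwise: individual (i, j, layer) and (i, attribute) entries are removed
# from the likelihood via the observation masks, matching the entrywise
# conditional independence of the model.

target_names <- function(network = NULL, table = NULL) {
  c(if (!is.null(network)) sprintf("layer%d", seq_len(network$L)),
    if (!is.null(table)) sprintf("attr%d", seq_len(table$P)))
}

#' Assign observed cells to cross-validation folds
#'
#' Every observed cell of every target (each layer, each attribute) is
#' assigned uniformly at random to exactly one of `n_folds` folds;
#' deterministic per seed. Fold sizes per target differ by at most one.
#'
#' @param network a `typed_network` (or `NULL`).
#' @param table an `attribute_table` (or `NULL`).
#' @param n_folds number of folds, `>= 2`.
#' @param seed integer seed.
#' @return a `fold_plan`: per-target integer fold labels aligned with the
#'   observed-cell indices.
#' @export
make_folds <- function(network = NULL, table = NULL, n_folds = 5L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  plan <- list(n_folds = as.integer(n_folds), seed = as.integer(seed),
               network = NULL, table = NULL)
  withr::with_seed(seed, {
    if (!is.null(network)) {
      plan$network <- lapply(seq_len(network$L), function(l) {
        cells <- which(network$mask[[l]])
        if (length(cells) < n_folds)
          stop("layer ", l, " has fewer observed cells (", length(cells),
               ") than folds (", n_folds, ")")
        list(cells = cells,
             fold = sample(rep(seq_len(n_folds), length.out = length(cells))))
      })
    }
    if (!is.null(table)) {
      plan$table <- lapply(seq_len(table$P), function(p) {
        cells <- which(table$mask[, p])
        if (length(cells) < n_folds)
          stop("attribute ", p, " has fewer observed cells (", length(cells),
               ") than folds (", n_folds, ")")
        list(cells = cells,
             fold = sample(rep(seq_len(n_folds), length.out = length(cells))))
      })
    }
  })
  structure(plan, class = "fold_plan")
}

# training copies with one fold's cells masked out
mask_fold <- function(network, table, plan, fold) {
  out <- list(network = network, table = table)
  if (!is.null(network)) {
    for (l in seq_len(network$L)) {
      held <- plan$network[[l]]$cells[plan$network[[l]]$fold == fold]
      out$network$mask[[l]][held] <- FALSE
    }
  }
  if (!is.null(table)) {
    for (p in seq_len(table$P)) {
      held <- plan$table[[p]]$cells[plan$table[[p]]$fold == fold]
      out$table$mask[held + (p - 1L) * table$N] <- FALSE
    }
  }
  out
}

#' Predict held-out cells from a fitted state
#'
#' Predictions are the fitted expected values at the held-out indices: a
#' probability for Bernoulli cells, a rate for Poisson, a mean for
#' Gaussian, and a category distribution for categorical attributes. When
#' the training objects used for the fit are supplied, any held-out cell
#' still observed in them raises a leakage error.
#'
#' @param state fitted `latent_state`.
#' @param network,table the full (unmasked) data.
#' @param plan a `fold_plan`.
#' @param fold fold index to score.
#' @param train_network,train_table optional training copies for the
#'   leakage audit.
#' @return list per target with `family`, `truth` and `pred`.
#' @export
predict_heldout <- function(state, network = NULL, table = NULL, plan, fold,
                            train_network = NULL, train_table = NULL) {
  out <- list()
  if (!is.null(network)) {
    Lambda <- expected_edges(state, network$layers)
    for (l in seq_len(network$L)) {
      held <- plan$network[[l]]$cells[plan$network[[l]]$fold == fold]
      if (!is.null(train_network) && any(train_network$mask[[l]][held]))
        stop("leakage: held-out cells of layer ", l, " were observed during fit")
      out[[sprintf("layer%d", l)]] <- list(
        family = network$layers[[l]]$family,
        truth = network$A[[l]][held],
        pred = Lambda[[l]][held])
    }
  }
  if (!is.null(table)) {
    Pi <- expected_attributes(state, table$attrs)
    for (p in seq_len(table$P)) {
      held <- plan$table[[p]]$cells[plan$table[[p]]$fold == fold]
      if (!is.null(train_table) && any(train_table$mask[held + (p - 1L) * table$N]))
        stop("leakage: held-out cells of attribute ", p, " were observed during fit")
      rows <- held
      pred <- if (table$attrs[[p]]$family == "categorical")
        Pi[[p]][rows, , drop = FALSE] else Pi[[p]][rows]
      out[[sprintf("attr%d", p)]] <- list(
        family = table$attrs[[p]]$family,
        truth = table$X[rows, p],
        pred = pred)
    }
  }
  out
}

#' Rank-based AUC with mid-rank ties
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 truth.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score held-out predictions with the per-family metric
#'
#' AUC for Bernoulli targets, absolute error for Poisson targets (mean by
#' default, maximum with `mae_mode = "max"`), RMSE for Gaussian targets,
#' and argmax-category accuracy for categorical targets. A Bernoulli
#' hold-out containing a single class yields `NA`, never a silent 0.5.
#'
#' @param pred predictions (vector, or matrix of category probabilities).
#' @param truth observed values (categorical: integer labels in `1..Z`).
#' @param family distribution family of the target.
#' @param mae_mode `"mean"` or `"max"` absolute error for Poisson targets.
#' @return named scalar metric value.
#' @export
score_predictions <- function(pred, truth, family, mae_mode = c("mean", "max")) {
  mae_mode <- match.arg(mae_mode)
  if (!length(truth)) stop("empty held-out set")
  switch(family,
    bernoulli = c(auc = auc_score(pred, truth)),
    poisson = c(mae = if (mae_mode == "mean") mean(abs(pred - truth))
                      else max(abs(pred - truth))),
    gaussian = c(rmse = sqrt(mean((pred - truth)^2))),
    categorical = {
      if (is.matrix(pred)) {
        guess <- max.col(pred, ties.method = "first")
      } else {
        guess <- pred
      }
      c(accuracy = mean(guess == truth))
    },
    stop("unknown family: ", family))
}

#' Constant baseline predictors from the training cells
#'
#' `"average"` predicts the training mean (for categorical targets, the
#' empirical category frequencies); `"max_frequency"` predicts the modal
#' training value (for categorical, probability one on the modal
#' category); `"uniform"` (categorical only) predicts `1/Z` per category.
#'
#' @param train_values observed training-cell values.
#' @param family target family.
#' @param mode baseline flavour.
#' @param Z category count (categorical only).
#' @return a constant prediction: scalar, or a length-`Z` probability
#'   vector for categorical targets.
#' @export
baseline_predict <- function(train_values, family,
                             mode = c("average", "max_frequency", "uniform"),
                             Z = NULL) {
  mode <- match.arg(mode)
  if (!length(train_values)) stop("empty training set")
  if (family == "categorical") {
    if (is.null(Z)) stop("categorical baseline requires Z")
    if (mode == "uniform") return(rep(1 / Z, Z))
    freq <- tabulate(train_values, nbins = Z) / length(train_values)
    if (mode == "average") return(freq)
    p <- rep(0, Z); p[which.max(freq)] <- 1
    return(p)
  }
  if (mode == "uniform") stop("uniform baseline is defined for categorical targets only")
  if (mode == "average") return(mean(train_values))
  tab <- table(train_values)
  as.numeric(names(tab)[which.max(tab)])
}

#' Masked k-fold cross-validation over a grid of community counts
#'
#' For each `K` and fold, refits the model with the fold's cells masked
#' out of the likelihood, predicts them from the fitted expected values,
#' and scores each target with its per-family metric alongside the
#' constant baselines. No single scalar winner is forced across targets:
#' the selection table reports the best `K` per metric.
#'
#' @param network a `typed_network` (or `NULL`).
#' @param table an `attribute_table` (or `NULL`).
#' @param K_grid integer vector of community counts to evaluate.
#' @param config a [fit_config()]; its `K` is overridden by the grid and
#'   its seed drives folds and fits.
#' @param priors a [prior_spec()].
#' @param n_folds folds (default 5).
#' @param mae_mode `"mean"` or `"max"` (see [score_predictions()]).
#' @return a `cv_report`: `per_fold` and `aggregated` data frames (mean and
#'   `mean +/- 1.96 SE` over folds) and a `selection` data frame with the
#'   best `K` per target.
#' @export
cross_validate <- function(network = NULL, table = NULL, K_grid = 2:4,
                           config = fit_config(K = 3), priors = prior_spec(),
                           n_folds = 5L, mae_mode = c("mean", "max")) {
  mae_mode <- match.arg(mae_mode)
  stopifnot(length(K_grid) >= 1L)
  plan <- make_folds(network, table, n_folds, seed = config$seed)
  rows <- list()
  for (K in K_grid) {
    for (fold in seq_len(n_folds)) {
      tr <- mask_fold(network, table, plan, fold)
      cfg <- config
      cfg$K <- as.integer(K)
      cfg$covariance_mode <- "none"
      fit <- suppressWarnings(
        fit_map(tr$network, tr$table, priors = priors, config = cfg))
      preds <- predict_heldout(fit$state, network, table, plan, fold,
                               train_network = tr$network, train_table = tr$table)
      for (tn in names(preds)) {
        pr <- preds[[tn]]
        metric <- score_predictions(pr$pred, pr$truth, pr$family, mae_mode)
        bl <- fold_baselines(tn, pr, tr, network, table, mae_mode)
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, fold = fold, target = tn, family = pr$family,
          metric = names(metric), value = unname(metric),
          baseline_average = bl["average"], baseline_max_frequency = bl["max_frequency"],
          baseline_uniform = bl["uniform"], row.names = NULL)
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  agg <- aggregate_cv(per_fold)
  structure(list(per_fold = per_fold, aggregated = agg,
                 selection = select_K(agg), plan = plan,
                 K_grid = K_grid, mae_mode = mae_mode),
            class = "cv_report")
}

# baseline metric values for one target in one fold
fold_baselines <- function(tn, pr, tr, network, table, mae_mode) {
  out <- c(average = NA_real_, max_frequency = NA_real_, uniform = NA_real_)
  if (startsWith(tn, "layer")) {
    l <- as.integer(sub("layer", "", tn))
    train_values <- network$A[[l]][tr$network$mask[[l]]]
    Z <- NULL
  } else {
    p <- as.integer(sub("attr", "", tn))
    train_values <- table$X[tr$table$mask[, p], p]
    Z <- table$attrs[[p]]$Z
  }
  n <- length(pr$truth)
  modes <- c("average", "max_frequency", if (pr$family == "categorical") "uniform")
  for (mode in modes) {
    b <- baseline_predict(train_values, pr$family, mode, Z = Z)
    bp <- if (pr$family == "categorical")
      matrix(b, n, length(b), byrow = TRUE) else rep(b, n)
    if (pr$family == "bernoulli") {
      # a constant score carries no ranking information: random-choice 0.5
      out[mode] <- 0.5
    } else {
      out[mode] <- unname(score_predictions(bp, pr$truth, pr$family, mae_mode))
    }
  }
  out
}

aggregate_cv <- function(per_fold) {
  keys <- unique(per_fold[, c("K", "target", "family", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- merge(keys[r, , drop = FALSE], per_fold)
    se <- sd(sub$value) / sqrt(nrow(sub))
    data.frame(keys[r, , drop = FALSE],
               mean = mean(sub$value), se = se,
               ci_lo = mean(sub$value) - 1.96 * se,
               ci_hi = mean(sub$value) + 1.96 * se,
               baseline_average = mean(sub$baseline_average),
               baseline_max_frequency = mean(sub$baseline_max_frequency),
               baseline_uniform = mean(sub$baseline_uniform),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

select_K <- function(agg) {
  higher_better <- c(auc = TRUE, accuracy = TRUE, mae = FALSE, rmse = FALSE)
  keys <- unique(agg[, c("target", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- agg[agg$target == keys$target[r] & agg$metric == keys$metric[r], ]
    best <- if (higher_better[[keys$metric[r]]]) which.max(sub$mean) else which.min(sub$mean)
    data.frame(target = keys$target[r], metric = keys$metric[r],
               best_K = sub$K[best], best_value = sub$mean[best],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cross-validation over K = {", paste(x$K_grid, collapse = ", "), "}\n")
  print(x$aggregated[, c("K", "target", "metric", "mean", "ci_lo", "ci_hi",
                         "baseline_average")], digits = 3)
  cat("\nbest K per target metric:\n")
  print(x$selection, digits = 3)
  invisible(x)
}

# per-target distance between two datasets over a fixed set of cells
dataset_distance <- function(v1, v2, family) {
  switch(family,
    bernoulli = mean(v1 != v2),          # Hamming rate
    poisson = mean(abs(v1 - v2)),
    gaussian = sqrt(mean((v1 - v2)^2)),  # RMSE
    categorical = mean(v1 != v2),        # disagreement rate
    stop("unknown family: ", family))
}

#' Posterior-predictive goodness-of-fit check
#'
#' Draws `n_samples` replicate datasets from the fitted state and compares
#' per-target distances among replicates (sample-vs-sample) with distances
#' between each replicate and the observed data (sample-vs-input). For a
#' well-fitting model the two distance distributions overlap; input data
#' systematically farther from the replicates than the replicates are from
#' each other indicates misfit. The comparison is reported descriptively
#' (both distance sets and their medians), not as a single p-value.
#'
#' @param state fitted `latent_state`.
#' @param network,table observed data.
#' @param n_samples number of replicates, `>= 2`.
#' @param seed integer seed.
#' @return a `ppc_report`: per target, vectors `sample_vs_sample` and
#'   `sample_vs_input` plus their medians.
#' @export
posterior_predictive_check <- function(state, network = NULL, table = NULL,
                                       n_samples = 10L, seed = 1L) {
  stopifnot(n_samples >= 2L)
  reps <- lapply(seq_len(n_samples), function(s) {
    list(network = if (!is.null(network))
           sample_network(state, network$layers, seed = seed + 17L * s),
         table = if (!is.null(table))
           sample_attributes(state, table$attrs, seed = seed + 17L * s + 1L))
  })
  values_of <- function(obj, tn) {
    if (startsWith(tn, "layer")) {
      l <- as.integer(sub("layer", "", tn))
      obj$network$A[[l]][network$mask[[l]]]
    } else {
      p <- as.integer(sub("attr", "", tn))
      obj$table$X[table$mask[, p], p]
    }
  }
  input <- list(network = network, table = table)
  fams <- c(if (!is.null(network)) vapply(network$layers, `[[`, "", "family"),
            if (!is.null(table)) vapply(table$attrs, `[[`, "", "family"))
  tns <- target_names(network, table)
  out <- list()
  for (t in seq_along(tns)) {
    tn <- tns[t]
    rv <- lapply(reps, values_of, tn = tn)
    iv <- values_of(input, tn)
    ss <- c()
    for (a in seq_len(n_samples - 1L)) for (b in (a + 1L):n_samples)
      ss <- c(ss, dataset_distance(rv[[a]], rv[[b]], fams[t]))
    si <- vapply(rv, function(v) dataset_distance(v, iv, fams[t]), 0.0)
    out[[tn]] <- list(family = fams[t], sample_vs_sample = ss,
                      sample_vs_input = si,
                      median_ss = stats::median(ss), median_si = stats::median(si))
  }
  structure(out, class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  for (tn in names(x)) {
    cat(sprintf("%s (%s): median sample-vs-sample %.4f, sample-vs-input %.4f\n",
                tn, x[[tn]]$family, x[[tn]]$median_ss, x[[tn]]$median_si))
  }
  invisible(x)
}
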