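# hamnet

Probabilistic inference for **h**eterogeneous **a**ttributed
**m**ultilayer **net**works.

Real interaction data rarely come as a single homogeneous graph: people
are linked by several relation types at once (binary friendships, call
counts, geographical distances) and carry attributes of mixed type
(caste or religion, years of education, income). `hamnet` is for
practitioners — computational social scientists, systems biologists,
network statisticians — who want one principled model over all of it
rather than one bespoke model per data type.

## The model

For $N$ nodes observed through $L$ layers $A_\ell$ (Bernoulli, Poisson or
Gaussian) and $P$ node attributes $X_{\cdot x}$ (categorical, Poisson or
Gaussian), a single mixed-membership structure with $K$ overlapping
communities generates everything:

$$\lambda_{ij\ell} = f(U_i)^\top\, g_\ell(W_\ell)\, f(V_j),\qquad
  \pi_{ix} = \tfrac12\,(f(U_i)+f(V_i))^\top\, g_x(H_{\cdot x}),$$

where $U, V$ are out-/in-going membership scores, $W_\ell$ a per-layer
$K\times K$ affinity matrix, $H$ a community–covariate matrix, $f$ the
row softmax, and $g$ the family's link (logistic, exponential, identity,
or softmax across categories). Entries of $A$ and $X$ are conditionally
independent given the latents; all latents carry Gaussian priors.

Inference is MAP by gradient ascent (Adam, exact analytic gradients in
compiled code) followed by a blockwise Laplace approximation: each row of
$U$/$V$, each $W_\ell$ and each attribute block of $H$ gets a Gaussian
posterior with covariance from the inverted negative block Hessian.
Gaussian posteriors are then mapped to interpretable domains — Dirichlet
distributions on the membership simplex via Laplace matching
($\alpha_k = \Sigma_{kk}^{-1}(1 - 2/K + e^{\mu_k} K^{-2}\sum_l e^{-\mu_l})$),
lognormal and logit-normal laws for positive and unit-interval views —
and summarized per node by the mean pairwise *overlap* of the $K$
posterior densities and the variance of their mixture (the
$L_2$-barycenter), which quantify how mixed each node's membership is.

The package also ships the full validation apparatus: a synthetic
benchmark generator (the model run forwards), masked cellwise $k$-fold
cross-validation with per-type metrics (AUC / MAE / RMSE / accuracy)
against mean, modal-value and uniform baselines, model selection over
$K$, and posterior-predictive goodness-of-fit checks.

## Worked example

```r
library(hamnet)

# a directed benchmark dataset: 3 heterogeneous layers, 3 attributes
ds <- sample_dataset(N = 100, K = 3, seed = 42)
validate_data(ds$network, ds$table)   # character(0): clean

cfg <- fit_config(K = 3, seed = 1, step_size = 0.05, max_iter = 2000,
                  n_restarts = 1, covariance_mode = "blockwise")
fit <- fit_map(ds$network, ds$table,
               priors = prior_spec(var_U = 9, var_V = 9, var_H = 4),
               config = cfg)
fit
#> hamnet_fit: K = 3, log-posterior = -41375.3126, 1824 iteration(s), converged

# Dirichlet memberships on the simplex (Laplace matching)
alpha <- match_dirichlet_all(fit$posterior)
head(t(apply(alpha, 1, dirichlet_mean)), 3)
#>           [,1]       [,2]      [,3]
#> [1,] 0.5565308 0.36219610 0.0812731
#> [2,] 0.1196110 0.72144100 0.1589480
#> [3,] 0.2108884 0.09925475 0.6898569

head(ds$membership, 3)   # softmax-normalized ground truth, same labels
#>             [,1]        [,2]         [,3]
#> [1,] 0.624785815 0.375188918 2.526705e-05
#> [2,] 0.007101462 0.887712906 1.051856e-01
#> [3,] 0.081207146 0.001347151 9.174457e-01

head(membership_summary(fit$posterior), 3)
#>   node   overlap   sigma2
#> 1    1 0.5729200 4.894790
#> 2    2 0.6320786 4.466676
#> 3    3 0.6117464 4.686653
```

The recovered simplex means track the planted memberships node by node
(node 1 split between communities 1 and 2, node 2 dominated by
community 2, node 3 by community 3). `overlap` is the mean pairwise
overlap of each node's three posterior densities and `sigma2` the
variance of their mixture; lower overlap / higher variance would flag
harder memberships.

Held-out prediction with baselines on the same dataset:

```r
rep <- cross_validate(ds$network, ds$table, K_grid = 3, config = cfg,
                      priors = prior_spec(var_U = 9, var_V = 9, var_H = 4),
                      n_folds = 5)
rep$aggregated[, c("target", "metric", "mean", "baseline_average")]
#>   target   metric   mean baseline_average
#> 1 layer1      auc 0.6667            0.500
#> 2 layer2      mae 1.7335            3.765
#> 3 layer3     rmse 1.0014            1.166
#> 4  attr1 accuracy 0.4600            0.460
#> 5  attr2      mae 0.9758            1.291
#> 6  attr3     rmse 0.9848            1.613
```

The model clearly beats the constant baselines on five of the six
targets of this single replicate; the categorical attribute sits at its
modal baseline here (a per-replicate coin flip at N = 100), while the
20-replicate aggregate in the acceptance suite exceeds it decisively.
For Bernoulli layers the meaningful reference is the random-choice AUC
of 0.5 — a constant predictor carries no ranking information.

A thin command-line wrapper (`inst/cli/hamnet`) exposes the same
pipeline as subcommands `generate`, `fit`, `cv`, `transform`,
`interpret`, `ppc` over the package's text formats (edge-list TSV +
JSON schema, attribute CSV + JSON schema).

## Package layout

* `R/` — model, inference, transforms, interpretation, synthetic
  generator, evaluation, I/O, CLI
* `src/` — compiled log-posterior objective and analytic gradient
* `vignettes/hamnet-methods.Rmd` — the methods vignette: model,
  assumptions, numerical choices, benchmark design, limitations
* `tests/testthat/` — unit, property and acceptance-style tests
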