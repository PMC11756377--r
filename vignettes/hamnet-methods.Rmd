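---
title: "Modelling heterogeneous attributed multilayer networks with hamnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heterogeneous attributed multilayer networks with hamnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hamnet` fits a generative model to multilayer networks in which the $L$
layers and the $P$ node attributes may each follow a different
distribution family. The data are an adjacency tensor $A$ of dimension
$L \times N \times N$ (Bernoulli, Poisson or Gaussian layers) and an
$N \times P$ design matrix $X$ (categorical, Poisson or Gaussian
attributes). Both are driven by one shared mixed-membership community
structure with $K$ communities:

* $U, V \in \mathbb{R}^{N \times K}$: out-going and in-coming membership
  scores per node (aliased, $U = V$, for undirected networks);
* $W_\ell \in \mathbb{R}^{K \times K}$: per-layer affinity matrix;
* $H \in \mathbb{R}^{K \times P^\*}$: community–covariate matrix, where a
  categorical attribute with $Z$ categories occupies a $K \times Z$ block
  (one column per category) and every other attribute one column.

Expected values are built from transformed latents,
$$\lambda_{ij\ell} = f(U_i)^\top g_\ell(W_\ell)\, f(V_j), \qquad
  \pi_{ix} = \tfrac12\big(f(U_i) + f(V_i)\big)^\top g_x(H_{\cdot x}),$$
with $f$ the row-wise softmax and $g$ the family link applied entrywise:
logistic (Bernoulli), exponential (Poisson), identity (Gaussian), and a
row-wise softmax across the $Z$ columns of a categorical block. Because
$f(U_i)$ and $f(V_j)$ are probability vectors, every $\lambda$ and $\pi$
is a convex combination of transformed scores and lies in its family's
parameter space by construction — no clipping anywhere. Gaussian
likelihood variances $\sigma^2$ are fixed hyperparameters (default 1),
never inferred; Poisson log-densities keep the $-\log A!$ constant so
objective values are comparable across configurations.

All latent entries have independent Gaussian priors. Self-loops are never
modelled: diagonal cells are permanently masked. A single mask mechanism
also carries missing data and cross-validation hold-outs; every
likelihood sum runs over observed cells only. For undirected layers only
the upper triangle is observed, so each dyad contributes once.

## Inference

The MAP estimate maximizes the log-posterior by Adam with exact analytic
gradients, implemented in compiled code (the gradients of the
softmax/link compositions are derived in closed form and verified against
central finite differences in the test suite). Defaults: step size 0.01,
at most 2000 iterations, convergence when the relative objective change
over a 50-iteration window falls below $10^{-6}$, three prior-drawn
restarts keeping the best objective. All randomness flows from one seed;
fits are bit-reproducible.

One structural subtlety required care. The network likelihood is exactly
invariant under *independent* column relabelings of $U$ and $V$ — any
relabeling of $V$ is absorbed by the columns of each $W_\ell$ — while the
attribute term couples the two labelings through the average membership.
In directed attributed fits, first-order ascent regularly converges with
$V$'s community labels permuted relative to $U$'s, wasting the attribute
signal. `fit_map()` therefore finishes with a greedy discrete
refinement: transpositions of $V$'s labels (applied jointly to $V$ and
the affinity columns, leaving the network term untouched) are re-polished
briefly with Adam and kept only when the full log-posterior improves. In
simulation this restores label agreement essentially always and lifts
attribute prediction to the level attained by the generating parameters.

Uncertainty comes from a blockwise Laplace approximation around the MAP:
the posterior is treated as factorized over blocks (each row of $U$ and
$V$, each $W_\ell$, each attribute's column block of $H$), and each
block's covariance is the inverse of its negative Hessian, computed by
central differences of the analytic gradient, symmetrized, jittered by
$10^{-8}$ on the diagonal, and checked for positive definiteness. Full
joint Hessians are deliberately avoided: downstream interpretation
consumes per-row means and diagonal variances only. A MAP-only mode
(`covariance_mode = "none"`) skips all Hessian work, which is what the
cross-validation loop uses.

## Interpretable posteriors

Gaussian posteriors live on the real line; three transformations map them
to interpretable domains:

* **Dirichlet via Laplace matching.** For a membership row with posterior
  mean $\mu$ and diagonal variances $\Sigma_{kk}$,
  $$\alpha_k = \frac{1}{\Sigma_{kk}}\Big(1 - \frac{2}{K} +
    \frac{e^{\mu_k}}{K^2}\sum_{l=1}^K e^{-\mu_l}\Big),$$
  the exact inverse of the softmax-basis Laplace approximation of a
  Dirichlet (the test suite pins the round trip to $10^{-12}$). Only
  diagonal covariance entries enter; off-diagonal information is
  discarded by design. The formula is most faithful for concentrated
  posteriors: for Gaussians actually in the image of the forward map with
  $\alpha \gtrsim 2$, the Dirichlet mean tracks the Monte-Carlo mean of
  softmaxed Gaussian draws to about 0.01, but for arbitrary
  mean/variance combinations (dispersed, strongly asymmetric) the
  discrepancy can reach 0.1 or more — a known limitation of the
  diagonal-only matching, not of the implementation.
* **Lognormal / logit-normal closed forms** for $\exp(\theta)$ and
  $\mathrm{logistic}(\theta)$, with closed-form lognormal moments and
  quadrature for logit-normal means.
* **MAP-only path:** softmax of the point estimates, exposed separately
  and labelled as carrying no uncertainty.

Two per-node summaries quantify membership hardness. The *overlap* is the
average area of intersection between all pairs of a node's $K$
per-community posterior densities (Gauss–Kronrod quadrature on the union
of $\pm 8\sigma$ supports, absolute tolerance $10^{-8}$); 1 means fully
mixed, values near 0 hard membership. The *barycenter variance* is the
variance of the equal-weight mixture of the $K$ densities,
$\frac1K\sum_k(\sigma_k^2 + \mu_k^2) - (\frac1K\sum_k \mu_k)^2$; it moves
opposite to the overlap as means separate. The mixture reading of the
"$L_2$ barycenter" was chosen because only its variance is consumed and
the equal-weight mixture reproduces the intended qualitative behaviour
with a closed form; alternative weightings would change numbers, not
trends.

## The synthetic benchmark

`sample_dataset()` draws latents from Gaussian hyperpriors and then data
from the model itself: three heterogeneous layers (Bernoulli, Poisson,
Gaussian) and three attributes (categorical with $Z = 4$, Poisson,
Gaussian), directed by default. Hyperprior defaults were chosen once and
frozen:

* $U, V \sim \mathcal N(0, 3^2)$. Memberships are overlapping but
  identifiable (median top weight about 0.85). With unit variance,
  softmaxed rows are so uniformly mixed that expected edge and attribute
  values barely vary across nodes; constant predictors are then
  near-optimal *even for the generating parameters*, and the benchmark
  cannot exercise prediction at all.
* $W \sim \mathcal N(0, 1)$ plus $+2$ on the diagonal: assortative layers
  (toggleable via `w_diag_boost`).
* $H \sim \mathcal N(0, 2^2)$, plus $+2$ on the $(k, k \bmod Z)$ entries
  of categorical blocks so communities prefer distinct categories — the
  attribute analogue of the assortative boost. Without it, independently
  drawn community profiles frequently share one modal category and
  categorical prediction collapses onto the marginal mode.

What the generator does *not* emulate about real data: sparsity (Bernoulli
layers come out dense, around 0.4–0.6), degree heterogeneity beyond what
mixed memberships induce, reciprocity, and any misspecification — data
are drawn from the model family itself. Passing benchmarks therefore
demonstrates correct inference under the model's own assumptions, not
robustness to violated ones.

## Evaluation protocol

Cross-validation masks individual cells (entries of $A$ and $X$), never
whole nodes, matching the entrywise conditional independence of the
likelihood; folds partition each target's observed cells uniformly at
random, deterministically per seed. Predictions for held-out cells are
the fitted expected values; a mask audit raises an error if a held-out
cell was observed during fitting, and a test corrupts held-out values to
prove the fitted state is bit-identical. Metrics are per-family: AUC
(rank-based, mid-rank ties; a one-class hold-out yields `NA`, never a
silent 0.5), absolute error for Poisson targets (mean by default,
maximum via `mae_mode = "max"` since both readings of "MAE" circulate),
RMSE for Gaussian targets, argmax accuracy for categorical ones.
Baselines are constant predictors from the training cells: mean, modal
value, and (categorical) uniform $1/Z$; for AUC a constant carries no
ranking information, so the random-choice 0.5 is reported. Aggregates are
means with $\pm 1.96\,\mathrm{SE}$ intervals. No scalar winner across
heterogeneous targets is forced; `cross_validate()` reports the best $K$
per metric.

The posterior-predictive check draws replicate datasets from a fitted
state and compares per-target distances among replicates with distances
between replicates and the input (Hamming rate, mean absolute
difference, RMSE, disagreement rate by family), reported descriptively as
the two distance sets and their medians rather than a single p-value.

## Problem sizes and settings used by the shipped checks

The acceptance-style checks run the benchmark at $N = 200$, $K^* = 3$
(20 seeds, 5-fold CV; Adam step 0.05, 500 iterations, single restart) and
community-count recovery at $N = 100$ over $K \in \{2,3,4,5\}$ (10 seeds,
3-fold CV, 400 iterations). These sizes were chosen as the smallest at
which the benchmark's signal comfortably exceeds fold noise; prediction
quality at these settings is indistinguishable from runs several times
longer, because the score-relevant structure converges well before the
objective's last slow decimals. Priors in these runs match the generating
hyperpriors (variances 9 for memberships, 4 for $H$), the standard
well-specified simulation design.

## Known limitations

* Dense $L \times N \times N$ storage; intended for $N$ up to a few
  thousand, not sparse massive graphs.
* $K$ is an input, selected by cross-validation, never inferred.
* The diagonal-only Laplace matching degrades for dispersed posteriors
  (see above); report MAP-softmax memberships alongside Dirichlet means
  when variances are large.
* Only the four built-in families are supported; adding one means
  extending the per-family link and log-density dispatch in one R and one
  compiled location — localized, but not a runtime plug-in registry.
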