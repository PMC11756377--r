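#' Laplace matching: Gaussian posterior to Dirichlet concentrations
#'
#' Maps the mean and diagonal covariance of a node's Gaussian membership
#' posterior into the concentration vector of a Dirichlet distribution over
#' the softmax-transformed memberships:
#' \deqn{\alpha_k = \frac{1}{\Sigma_{kk}}\Big(1 - \frac{2}{K} +
#'   \frac{e^{\mu_k}}{K^2}\sum_{l=1}^K e^{-\mu_l}\Big).}
#' Only diagonal covariance entries enter; off-diagonal information is
#' deliberately discarded. For `K >= 2` and positive variances every
#' `alpha_k` is strictly positive, since `1 - 2/K >= 0` and the second term
#' is positive.
#'
#' @param mu length-`K` posterior mean vector.
#' @param sigma_diag length-`K` vector of positive posterior variances.
#' @return length-`K` positive concentration vector.
#' @export
match_dirichlet <- function(mu, sigma_diag) {
  K <- length(mu)
  if (K < 2L) stop("simplex undefined for K = 1")
  if (length(sigma_diag) != K) stop("mu and sigma_diag lengths differ")
  if (any(sigma_diag <= 0)) stop("variances must be positive")
  (1 / sigma_diag) * (1 - 2 / K + exp(mu) / K^2 * sum(exp(-mu)))
}

#' Dirichlet posteriors for every node's membership
#'
#' Applies [match_dirichlet()] to each row of the `U` (and, for directed
#' fits, `V`) posterior means and diagonal variances.
#'
#' @param posterior a `gaussian_posterior` from [laplace_covariance()].
#' @param which `"U"` or `"V"`.
#' @return an `N x K` matrix of concentration parameters.
#' @export
match_dirichlet_all <- function(posterior, which = c("U", "V")) {
  which <- match.arg(which)
  mu <- posterior[[paste0(which, "_mean")]]
  va <- posterior[[paste0(which, "_var")]]
  if (is.null(mu)) stop("posterior has no ", which, " block")
  t(vapply(seq_len(nrow(mu)), function(i) match_dirichlet(mu[i, ], va[i, ]),
           numeric(ncol(mu))))
}

#' Mean of a Dirichlet distribution
#'
#' @param alpha positive concentration vector.
#' @return simplex point `alpha / sum(alpha)`.
#' @export
dirichlet_mean <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  alpha / sum(alpha)
}

#' Closed-form transformed posteriors (lognormal / logit-normal)
#'
#' A Gaussian posterior `N(mu, sigma2)` on an unconstrained latent induces a
#' lognormal law on `exp(theta)` and a logit-normal law on
#' `logistic(theta)`; both keep `(mu, sigma2)` as their parameters. The
#' returned object evaluates the density and the mean (closed form
#' `exp(mu + sigma2/2)` for the lognormal; numerical quadrature for the
#' logit-normal, which has no closed-form moments).
#'
#' @param mu Gaussian mean (scalar).
#' @param sigma2 Gaussian variance (non-negative scalar).
#' @param kind `"lognormal"` or `"logitnormal"`.
#' @return a `transformed_posterior` with elements `kind`, `mu`, `sigma2`,
#'   `density(x)` and `mean()`.
#' @export
transform_closed_form <- function(mu, sigma2, kind = c("lognormal", "logitnormal")) {
  kind <- match.arg(kind)
  stopifnot(sigma2 >= 0)
  dens <- if (kind == "lognormal") {
    function(x) stats::dlnorm(x, meanlog = mu, sdlog = sqrt(sigma2))
  } else {
    function(x) {
      ifelse(x > 0 & x < 1,
             dnorm(log(x / (1 - x)), mu, sqrt(sigma2)) / (x * (1 - x)),
             0)
    }
  }
  mean_fun <- if (kind == "lognormal") {
    function() exp(mu + sigma2 / 2)
  } else {
    function() {
      if (sigma2 == 0) return(stats::plogis(mu))
      integrate(function(z) stats::plogis(mu + sqrt(sigma2) * z) * dnorm(z),
                -Inf, Inf, abs.tol = 1e-10)$value
    }
  }
  structure(list(kind = kind, mu = mu, sigma2 = sigma2, density = dens,
                 mean = mean_fun),
            class = "transformed_posterior")
}

#' Point-estimate memberships from a MAP state
#'
#' The MAP-only interpretation path: softmax of the point estimates, with
#' no uncertainty attached. The uncertainty-aware alternative is
#' `dirichlet_mean(match_dirichlet(...))` on a Laplace posterior.
#'
#' @param state a `latent_state`.
#' @param which `"U"` or `"V"`.
#' @return `N x K` row-stochastic membership matrix.
#' @export
map_memberships <- function(state, which = c("U", "V")) {
  which <- match.arg(which)
  softmax_rows(if (which == "U") state$U else state_V(state))
}
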