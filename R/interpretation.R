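# Uncertainty-aware membership summaries: how much a node's K per-community
# posterior densities overlap (mixed membership) and how spread out their
# equal-weight mixture is (hard membership).

#' Area of overlap between two Gaussian densities
#'
#' Computes `integral of min(N(t; m1, v1), N(t; m2, v2)) dt` by adaptive
#' quadrature over the union of the two `mean +/- 8 sd` supports. Equals 1
#' for identical densities and tends to 0 as the means separate; for equal
#' variances it has the closed form `2 * pnorm(-|m1 - m2| / (2 * sd))`.
#'
#' @param m1,v1 mean and (positive) variance of the first Gaussian.
#' @param m2,v2 mean and variance of the second.
#' @return overlap area in `[0, 1]`.
#' @export
pairwise_overlap <- function(m1, v1, m2, v2) {
  if (v1 <= 0 || v2 <= 0) stop("variances must be positive")
  s1 <- sqrt(v1); s2 <- sqrt(v2)
  lo <- min(m1 - 8 * s1, m2 - 8 * s2)
  hi <- max(m1 + 8 * s1, m2 + 8 * s2)
  val <- integrate(function(t) pmin(dnorm(t, m1, s1), dnorm(t, m2, s2)),
                   lo, hi, abs.tol = 1e-8, subdivisions = 500L)$value
  min(max(val, 0), 1)
}

#' Mean pairwise overlap of a node's membership posteriors
#'
#' Average of [pairwise_overlap()] over all `K(K-1)/2` unordered pairs of
#' the node's per-community Gaussian posteriors. Ranges from 0 (no overlap:
#' hard membership) to 1 (identical distributions: fully mixed).
#'
#' @param means,vars length-`K` vectors of posterior means and variances.
#' @return scalar in `[0, 1]`.
#' @export
mean_overlap <- function(means, vars) {
  K <- length(means)
  if (K < 2L) stop("need K >= 2 distributions")
  pairs <- utils::combn(K, 2L)
  mean(apply(pairs, 2L, function(p)
    pairwise_overlap(means[p[1L]], vars[p[1L]], means[p[2L]], vars[p[2L]])))
}

#' Variance of the L2-barycenter (mixture) of membership posteriors
#'
#' The barycenter is the equal-weight average of the node's `K` component
#' densities; its variance has the closed form
#' `mean(vars + means^2) - mean(means)^2`. Higher values indicate harder
#' memberships (components far apart), lower values more mixed membership.
#'
#' @param means,vars length-`K` vectors of posterior means and variances.
#' @return non-negative scalar.
#' @export
barycenter_variance <- function(means, vars) {
  mean(vars + means^2) - mean(means)^2
}

#' Per-node membership summary table
#'
#' @param posterior a `gaussian_posterior` with a `U` block.
#' @param which `"U"` or `"V"`.
#' @return data frame with columns `node`, `overlap`, `sigma2`.
#' @export
membership_summary <- function(posterior, which = c("U", "V")) {
  which <- match.arg(which)
  mu <- posterior[[paste0(which, "_mean")]]
  va <- posterior[[paste0(which, "_var")]]
  if (is.null(mu)) stop("posterior has no ", which, " block")
  data.frame(
    node = seq_len(nrow(mu)),
    overlap = vapply(seq_len(nrow(mu)), function(i)
      mean_overlap(mu[i, ], va[i, ]), 0.0),
    sigma2 = vapply(seq_len(nrow(mu)), function(i)
      barycenter_variance(mu[i, ], va[i, ]), 0.0))
}
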