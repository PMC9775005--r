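# Multi-kernel maximum mean discrepancy (MK-MMD).
#
# The squared MK-MMD between distributions p and q is the RKHS distance
# between their mean embeddings, d_k^2(p, q) = || E_p[phi(x)] - E_q[phi(x)] ||^2,
# under a characteristic kernel k = sum_u beta_u k_u that is a convex
# combination (beta_u >= 0, sum beta_u = 1) of m positive semi-definite
# Gaussian kernels. d_k^2(p, q) = 0 iff p = q, which is what makes it usable
# as an alignment loss between source and target feature distributions.

#' Construct a convex Gaussian kernel family
#'
#' Bandwidths follow the median heuristic: the median pairwise Euclidean
#' distance of the pooled features, scaled geometrically by `spacing` around
#' the center (for `m = 5`, `spacing = 2`: median times 1/4, 1/2, 1, 2, 4).
#' Mixture weights start uniform and stay fixed during training; each kernel
#' is `k_u(x, y) = exp(-||x - y||^2 / (2 sigma_u^2))`.
#'
#' @param pooled_feats n x d matrix of features pooled across both domains.
#' @param m Number of kernels (default 5).
#' @param spacing Geometric bandwidth spacing (default 2).
#' @return An object of class `kernel_family` with fields `bandwidths` and
#'   `beta` (convex weights summing to 1).
#' @export
make_kernel_family <- function(pooled_feats, m = 5L, spacing = 2) {
  if (is.vector(pooled_feats)) pooled_feats <- matrix(pooled_feats, ncol = 1)
  if (!is.matrix(pooled_feats) || nrow(pooled_feats) < 1L) {
    stop_invalid("`pooled_feats` must be a nonempty matrix")
  }
  if (m < 1) stop_invalid("`m` must be >= 1")
  check_scalar(spacing, "spacing", positive = TRUE)
  m <- as.integer(m)
  med <- if (nrow(pooled_feats) >= 2L) {
    stats::median(stats::dist(pooled_feats))
  } else {
    0
  }
  if (!is.finite(med) || med <= 0) {
    warning("median pairwise distance is zero; falling back to bandwidth 1.0")
    med <- 1.0
  }
  exponents <- seq_len(m) - (m + 1) / 2
  structure(
    list(bandwidths = med * spacing^exponents, beta = rep(1 / m, m),
         kernel = "gaussian"),
    class = "kernel_family"
  )
}

#' Set the mixture weights of a kernel family
#'
#' @param family A `kernel_family`.
#' @param beta Nonnegative weights; renormalized to sum to 1.
#' @return The updated family.
#' @export
set_kernel_weights <- function(family, beta) {
  if (length(beta) != length(family$bandwidths) || any(beta < 0) ||
      sum(beta) <= 0) {
    stop_invalid("`beta` must be nonnegative, same length as the kernels, with positive sum")
  }
  family$beta <- beta / sum(beta)
  family
}

# Squared Euclidean cross-distance matrix between row sets.
.sqdist <- function(x, y) {
  xx <- rowSums(x^2)
  yy <- rowSums(y^2)
  d2 <- outer(xx, yy, `+`) - 2 * tcrossprod(x, y)
  pmax(d2, 0)
}

# Convex-combination Gram matrix sum_u beta_u exp(-D2 / (2 sigma_u^2)).
.multi_gram <- function(d2, family) {
  K <- matrix(0, nrow(d2), ncol(d2))
  for (u in seq_along(family$bandwidths)) {
    K <- K + family$beta[u] * exp(-d2 / (2 * family$bandwidths[u]^2))
  }
  K
}

#' Empirical squared MK-MMD between two feature samples
#'
#' The biased estimator is the full Gram double sum
#' `mean(K_ss) + mean(K_tt) - 2 mean(K_st)` and is always nonnegative. The
#' unbiased estimator excludes the diagonal self-similarity terms of the
#' within-domain sums and can be slightly negative; its expectation is 0
#' when the two distributions coincide.
#'
#' @param source_feats n x d matrix of source features.
#' @param target_feats n' x d matrix of target features.
#' @param family A [make_kernel_family()] object.
#' @param estimator `"biased"` (default) or `"unbiased"`.
#' @return Scalar estimate of the squared MK-MMD.
#' @export
mk_mmd2 <- function(source_feats, target_feats, family,
                    estimator = c("biased", "unbiased")) {
  estimator <- match.arg(estimator)
  if (is.vector(source_feats)) source_feats <- matrix(source_feats, ncol = 1)
  if (is.vector(target_feats)) target_feats <- matrix(target_feats, ncol = 1)
  n <- nrow(source_feats); np <- nrow(target_feats)
  if (n < 1L || np < 1L) stop_invalid("both feature sets must be nonempty")
  if (ncol(source_feats) != ncol(target_feats)) {
    stop_invalid("source and target feature dimensions differ")
  }
  if (estimator == "unbiased" && (n < 2L || np < 2L)) {
    stop_invalid("the unbiased estimator needs at least 2 samples per domain")
  }
  Kss <- .multi_gram(.sqdist(source_feats, source_feats), family)
  Ktt <- .multi_gram(.sqdist(target_feats, target_feats), family)
  Kst <- .multi_gram(.sqdist(source_feats, target_feats), family)
  if (estimator == "biased") {
    mean(Kss) + mean(Ktt) - 2 * mean(Kst)
  } else {
    (sum(Kss) - sum(diag(Kss))) / (n * (n - 1)) +
      (sum(Ktt) - sum(diag(Ktt))) / (np * (np - 1)) -
      2 * mean(Kst)
  }
}

# Gradient of the biased squared MK-MMD with respect to both feature sets
# (features as rows). Bandwidths are treated as constants. Returns the value
# together with d/dS and d/dT.
mk_mmd2_grad <- function(source_feats, target_feats, family) {
  n <- nrow(source_feats); np <- nrow(target_feats)
  d2ss <- .sqdist(source_feats, source_feats)
  d2tt <- .sqdist(target_feats, target_feats)
  d2st <- .sqdist(source_feats, target_feats)
  Kss <- .multi_gram(d2ss, family)
  Ktt <- .multi_gram(d2tt, family)
  Kst <- .multi_gram(d2st, family)
  value <- mean(Kss) + mean(Ktt) - 2 * mean(Kst)

  # W = sum_u beta_u K_u / sigma_u^2 carries the Gaussian derivative factor:
  # d k_u(x, y) / d x = k_u(x, y) (y - x) / sigma_u^2.
  wgram <- function(d2) {
    W <- matrix(0, nrow(d2), ncol(d2))
    for (u in seq_along(family$bandwidths)) {
      s2 <- family$bandwidths[u]^2
      W <- W + family$beta[u] * exp(-d2 / (2 * s2)) / s2
    }
    W
  }
  Wss <- wgram(d2ss); Wtt <- wgram(d2tt); Wst <- wgram(d2st)

  gS <- (2 / n^2) * (Wss %*% source_feats - rowSums(Wss) * source_feats) -
    (2 / (n * np)) * (Wst %*% target_feats - rowSums(Wst) * source_feats)
  gT <- (2 / np^2) * (Wtt %*% target_feats - rowSums(Wtt) * target_feats) -
    (2 / (n * np)) * (t(Wst) %*% source_feats - colSums(Wst) * target_feats)
  list(value = value, grad_source = gS, grad_target = gT)
}
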