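# Covariance-alignment (CORAL) loss and the gradient-reversal construction
# used by the adversarial adaptation variant.

#' CORAL loss: squared Frobenius distance between feature covariances
#'
#' `(1 / (4 d^2)) * || C_s - C_t ||_F^2` over the empirical (sample,
#' denominator n - 1) covariance matrices of the two feature sets. Zero iff
#' the empirical covariances coincide; symmetric in the two domains.
#'
#' @param source_feats n x d matrix (n >= 2).
#' @param target_feats n' x d matrix (n' >= 2).
#' @return Nonnegative scalar.
#' @export
coral_loss <- function(source_feats, target_feats) {
  if (is.vector(source_feats)) source_feats <- matrix(source_feats, ncol = 1)
  if (is.vector(target_feats)) target_feats <- matrix(target_feats, ncol = 1)
  if (nrow(source_feats) < 2L || nrow(target_feats) < 2L) {
    stop_invalid("coral_loss needs at least 2 samples per domain")
  }
  if (ncol(source_feats) != ncol(target_feats)) {
    stop_invalid("source and target feature dimensions differ")
  }
  d <- ncol(source_feats)
  Cs <- stats::cov(source_feats)
  Ct <- stats::cov(target_feats)
  sum((Cs - Ct)^2) / (4 * d^2)
}

# CORAL loss with gradients w.r.t. both feature sets (features as rows).
coral_loss_grad <- function(source_feats, target_feats) {
  d <- ncol(source_feats)
  n <- nrow(source_feats); np <- nrow(target_feats)
  Xs <- scale(source_feats, center = TRUE, scale = FALSE)
  Xt <- scale(target_feats, center = TRUE, scale = FALSE)
  Cs <- crossprod(Xs) / (n - 1)
  Ct <- crossprod(Xt) / (np - 1)
  D <- Cs - Ct
  value <- sum(D^2) / (4 * d^2)
  # dL/dC_s = D / (2 d^2); C_s = Xs' Xs / (n-1); centering is idempotent so
  # the centered gradient maps straight back onto the raw features.
  gS <- Xs %*% D / (d^2 * (n - 1))
  gS <- sweep(gS, 2, colMeans(gS))      # back through the centering
  gT <- -Xt %*% D / (d^2 * (np - 1))
  gT <- sweep(gT, 2, colMeans(gT))
  list(value = value, grad_source = gS, grad_target = gT)
}

#' Gradient-reversal pseudo-layer
#'
#' The forward pass is the identity; the backward pass multiplies incoming
#' gradients by `-lambda`. Placing a domain discriminator behind this node
#' trains the discriminator normally while pushing the feature extractor to
#' make the two domains indistinguishable.
#'
#' @param features Numeric matrix or vector.
#' @param lambda_ Finite reversal strength (0 blocks the gradient entirely).
#' @return An object of class `grad_reverse` with fields `value` (the
#'   unchanged features) and `backward(grad)` returning `-lambda_ * grad`.
#' @export
grad_reverse <- function(features, lambda_ = 1) {
  check_scalar(lambda_, "lambda_", nonneg = TRUE)
  structure(
    list(value = features,
         lambda = lambda_,
         backward = function(grad) -lambda_ * grad),
    class = "grad_reverse"
  )
}
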