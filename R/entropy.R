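# Entropy estimates and their gradients: the shape-space (correspondence)
# term and the per-shape Parzen (surface-sampling) term.

#' Gaussian shape-space entropy estimate
#'
#' Under the Gaussian generative model the differential entropy of the
#' shape-space variable is, up to additive constants,
#' \eqn{H \approx \frac12 \sum_i \log(\lambda_i + a)} where the
#' \eqn{\lambda_i} are the eigenvalues of the sample covariance of the rows
#' (mean-subtracted, divisor K-1) and `a` regularizes vanishing modes.
#' All dM eigenvalues are counted (zeros contribute \eqn{\log a}).
#'
#' @param z_samples K x dM matrix of vectorized particle systems (rows).
#' @param cov_regularization positive eigenvalue regularizer.
#' @return scalar entropy estimate (additive constants dropped).
#' @export
shape_space_entropy <- function(z_samples, cov_regularization) {
  z <- as.matrix(z_samples)
  K <- nrow(z); dM <- ncol(z)
  if (K < 2L) stop("insufficient-samples: need at least 2 shape-space samples")
  if (!is.finite(cov_regularization) || cov_regularization <= 0)
    stop("cov_regularization must be > 0")
  Y <- sweep(z, 2L, colMeans(z))
  residual_entropy(Y, cov_regularization)
}

# entropy of an already mean/model-subtracted residual matrix; eigenvalues
# come from the smaller of the Gram (K x K) and scatter (dM x dM) sides so
# that exactly dM covariance eigenvalues are counted
residual_entropy <- function(Y, cov_regularization) {
  K <- nrow(Y); dM <- ncol(Y)
  S <- if (K <= dM) tcrossprod(Y) else crossprod(Y)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0) / (K - 1)
  0.5 * (sum(log(ev + cov_regularization)) +
         max(dM - K, 0L) * log(cov_regularization))
}

#' Correspondence (shape-space entropy) gradient
#'
#' Exact gradient of [shape_space_entropy()] with respect to the sample
#' matrix, evaluated on the residuals \eqn{Y = Z - \hat{Z}(model)}:
#' \deqn{G = Y (Y^\top Y + (K-1)\,a\,I)^{-1}}
#' (the covariance normalization cancels in the derivative), computed
#' through the K x K dual (Gram) system
#' \eqn{G = (Y Y^\top + (K-1)\,a\,I)^{-1} Y}, never forming the dM x dM
#' covariance.  For the constant-mean model this is the gradient of
#' the cross-sectional entropy; for regression models Y holds the residuals
#' from the temporal model and the same expression applies with the residual
#' covariance in place of the sample covariance.
#'
#' @param z_samples K x dM matrix.
#' @param mean_model dM-vector (broadcast) or K x dM matrix of per-sample
#'   model predictions.
#' @param cov_regularization positive eigenvalue regularizer (same scale as
#'   in [shape_space_entropy()]).
#' @return K x dM gradient matrix.
#' @export
correspondence_gradient <- function(z_samples, mean_model, cov_regularization) {
  z <- as.matrix(z_samples)
  K <- nrow(z)
  if (K < 2L) stop("insufficient-samples: need at least 2 shape-space samples")
  if (!is.finite(cov_regularization) || cov_regularization <= 0)
    stop("cov_regularization must be > 0")
  if (is.null(dim(mean_model))) {
    Y <- sweep(z, 2L, as.numeric(mean_model))
  } else {
    Y <- z - as.matrix(mean_model)
  }
  corr_grad_from_Y(Y, cov_regularization)
}

#' Parzen-window entropy of one particle set
#'
#' Leave-one-out kernel-density entropy estimate of the configuration-space
#' distribution on a single shape:
#' \eqn{H(X) \approx -\frac1M \sum_i \log \hat p(x_i)} with isotropic
#' Gaussian kernels of width `kernel_width` (scalar, or per-particle vector).
#'
#' @param particles M x d matrix.
#' @param kernel_width positive scalar or length-M vector.
#' @return scalar entropy estimate (0 when M = 1).
#' @export
parzen_entropy <- function(particles, kernel_width) {
  X <- as.matrix(particles)
  M <- nrow(X); d <- ncol(X)
  if (M < 2L) return(0)
  sig <- rep_len(kernel_width, M)
  D2 <- pairwise_sq_dists(X)
  W <- exp(-D2 / (2 * sig^2))   # rows scaled by own sigma
  diag(W) <- 0
  s <- rowSums(W)
  dens <- s / ((M - 1) * (2 * pi * sig^2)^(d / 2))
  -mean(log(pmax(dens, 1e-300)))
}

pairwise_sq_dists <- function(X) {
  G <- tcrossprod(X)
  n <- rowSums(X^2)
  D2 <- outer(n, n, "+") - 2 * G
  D2[D2 < 0] <- 0
  D2
}

#' Surface-sampling (Parzen entropy) gradient
#'
#' Exact ascent gradient of [parzen_entropy()] with respect to particle
#' positions; acts as a Gaussian-weighted mutual repulsion that spreads
#' particles uniformly over their shape.  The caller is responsible for
#' projecting the result onto the surface tangent plane.
#'
#' @param particles M x d matrix of particles on one surface.
#' @param kernel_width positive scalar (or per-particle vector) kernel width.
#' @param surface unused here; accepted so callers can pass context through.
#' @return M x d matrix (zero when M = 1).
#' @export
sampling_gradient <- function(particles, kernel_width, surface = NULL) {
  X <- as.matrix(particles)
  M <- nrow(X)
  if (any(kernel_width <= 0)) stop("kernel_width must be > 0")
  if (M < 2L) return(matrix(0, M, ncol(X)))
  sig <- rep_len(kernel_width, M)
  D2 <- pairwise_sq_dists(X)
  W <- exp(-D2 / (2 * sig^2))
  diag(W) <- 0
  P <- W / pmax(rowSums(W), 1e-300)      # row-stochastic responsibilities
  B <- P / sig^2                          # own-term, rows weighted by 1/sig_i^2
  C <- B + t(B)                           # own + cross terms of d(-1/M sum log s_k)
  (rowSums(C) * X - C %*% X) / M
}
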