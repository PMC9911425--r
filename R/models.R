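# Temporal shape models: constant mean, per-coordinate linear regression,
# and polynomial regression in the principal-component subspace with
# elastic-net regularization.

#' Constant-mean shape model
#' @param z_samples K x dM matrix.
#' @return an object of class `st_constant_model`.
#' @export
fit_constant_model <- function(z_samples) {
  structure(list(mean = colMeans(as.matrix(z_samples))),
            class = "st_constant_model")
}

#' @export
predict.st_constant_model <- function(object, times, ...) {
  matrix(object$mean, length(times), length(object$mean), byrow = TRUE)
}

#' Per-coordinate linear regression of shape on time
#'
#' Ordinary least squares fit of \eqn{f(t) = a + b t} independently for each
#' of the dM particle coordinates.
#'
#' @param z_samples K x dM matrix.
#' @param times length-K time values.
#' @return object of class `st_linear_model` with dM-vectors `intercept` and
#'   `slope`.
#' @export
fit_linear_regression <- function(z_samples, times) {
  z <- as.matrix(z_samples)
  times <- as.numeric(times)
  if (nrow(z) < 2L || length(times) != nrow(z))
    stop("need K >= 2 samples with matching times")
  if (max(times) - min(times) <= 0)
    stop("degenerate-design: all time values identical")
  X <- cbind(1, times)
  coef <- solve(crossprod(X), crossprod(X, z))
  structure(list(intercept = coef[1L, ], slope = coef[2L, ]),
            class = "st_linear_model")
}

#' @export
predict.st_linear_model <- function(object, times, ...) {
  outer(rep(1, length(times)), object$intercept) +
    outer(as.numeric(times), object$slope)
}

#' Principal subspace of the shape-space sample
#'
#' Mean-centered thin SVD; eigenvalues are squared singular values divided
#' by K-1; min(K-1, dM) components are retained; each eigenvector's
#' largest-magnitude entry is made positive (deterministic sign).
#'
#' @param z_samples K x dM matrix.
#' @return object of class `principal_subspace` with fields `mean`,
#'   `eigenvectors` (dM x R), `eigenvalues` (length R, non-increasing).
#' @export
fit_pca_subspace <- function(z_samples) {
  z <- as.matrix(z_samples)
  K <- nrow(z); dM <- ncol(z)
  if (K < 2L) stop("insufficient-samples: need K >= 2")
  mu <- colMeans(z)
  Yc <- sweep(z, 2L, mu)
  R <- min(K - 1L, dM)
  sv <- svd(Yc, nu = 0L, nv = R)
  U <- sv$v
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(mean = mu, eigenvectors = U,
                 eigenvalues = (sv$d[seq_len(R)]^2) / (K - 1)),
            class = "principal_subspace")
}

#' Project shape-space samples onto a principal subspace
#' @param subspace a `principal_subspace`.
#' @param z_samples K x dM matrix (or dM-vector).
#' @return K x R matrix of PCA scores.
#' @export
project_scores <- function(subspace, z_samples) {
  z <- if (is.null(dim(z_samples))) matrix(z_samples, 1L) else as.matrix(z_samples)
  sweep(z, 2L, subspace$mean) %*% subspace$eigenvectors
}

# affine map of raw times onto [-1, 1] (guards the Vandermonde conditioning)
time_transform_fit <- function(times) {
  lo <- min(times); hi <- max(times)
  if (hi - lo <= 0) list(center = lo, scale = 1)
  else list(center = (lo + hi) / 2, scale = (hi - lo) / 2)
}

time_transform_apply <- function(tf, times) (as.numeric(times) - tf$center) / tf$scale

# orthogonal polynomial design (discrete orthonormal basis on the fitting
# times); the raw monomial basis t^p is numerically unusable at degree T-1
# (Gram condition ~1e8), while an orthogonal basis spans the same model
# class and makes the L1 penalty select polynomial orders directly.
# `coefs` carries the basis so folds and prediction share it.
poly_design <- function(tt, degree, coefs = NULL) {
  if (is.null(coefs)) {
    B <- stats::poly(tt, degree = degree)
    structure(unclass(B)[, , drop = FALSE], coefs = attr(B, "coefs"))
  } else {
    unclass(stats::poly(tt, degree = degree, coefs = coefs))[, , drop = FALSE]
  }
}

#' Elastic-net polynomial regression in the principal subspace
#'
#' Fits, independently per principal component r, the polynomial
#' \eqn{h_r(t) = \beta_{0r} + \sum_{p=1}^P \beta_{pr} t^p} minimizing
#' \deqn{\sum_k \|q_k - h(t_k)\|^2 + r_1 \sum_p \|\beta_p\|_1
#'       + r_2 \sum_p \|\beta_p\|_2^2}
#' with the intercept unpenalized, by cyclic coordinate descent.  Raw times
#' are affinely mapped to [-1, 1] before powers are taken; coefficients are
#' stored in transformed units together with the map.
#'
#' @param scores K x R matrix of PCA scores (or any per-sample responses).
#' @param times length-K time values.
#' @param degree polynomial degree P >= 1.
#' @param r1 L1 penalty weight (>= 0).
#' @param r2 L2 penalty weight (>= 0).
#' @param subspace optional `principal_subspace` used by [predict_shape()].
#' @param time_transform optional precomputed affine time map.
#' @param basis optional precomputed orthogonal-basis coefficients (from a
#'   previous fit on the same time design), so CV folds share one basis.
#' @param tol coordinate-descent convergence tolerance.
#' @param max_sweeps maximum coordinate-descent sweeps.
#' @return object of class `st_polynomial_model`; `coefficients` is a
#'   (P+1) x R matrix, rows beta_0 ... beta_P in the orthogonal basis.
#' @export
fit_polynomial_elastic_net <- function(scores, times, degree, r1 = 0, r2 = 0,
                                       subspace = NULL, time_transform = NULL,
                                       basis = NULL,
                                       tol = 1e-9, max_sweeps = 10000L) {
  Q <- if (is.null(dim(scores))) matrix(scores, ncol = 1L) else as.matrix(scores)
  K <- nrow(Q); R <- ncol(Q)
  times <- as.numeric(times)
  stopifnot(length(times) == K, degree >= 1L, r1 >= 0, r2 >= 0)
  if (is.null(basis) && length(unique(times)) < degree + 1L)
    stop("need at least degree+1 distinct times to build the polynomial basis")
  tf <- if (is.null(time_transform)) time_transform_fit(times) else time_transform
  tt <- time_transform_apply(tf, times)
  X <- poly_design(tt, degree, coefs = basis)
  if (is.null(basis)) basis <- attr(X, "coefs")
  xm <- colMeans(X); ym <- colMeans(Q)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Q, 2L, ym)
  G <- crossprod(Xc)                       # P x P
  Cy <- crossprod(Xc, Yc)                  # P x R
  beta <- matrix(0, degree, R)
  converged <- FALSE
  if (r1 == 0) {
    # pure ridge/OLS: exact solve (the polynomial Gram at high degree is too
    # ill-conditioned for naive coordinate descent to crawl through)
    beta <- tryCatch(solve(G + r2 * diag(degree), Cy), error = function(e) NULL)
    converged <- !is.null(beta)
  }
  if (!converged) {
    beta <- matrix(0, degree, R)
    obj_prev <- Inf; stall <- 0L
    for (sweep_i in seq_len(max_sweeps)) {
      delta <- 0
      for (p in seq_len(degree)) {
        rho <- Cy[p, ] - G[p, ] %*% beta + G[p, p] * beta[p, ]
        bnew <- soft_threshold(drop(rho), r1 / 2) / (G[p, p] + r2)
        delta <- max(delta, max(abs(bnew - beta[p, ])))
        beta[p, ] <- bnew
      }
      if (delta < tol * max(1, max(abs(beta)))) { converged <- TRUE; break }
      # penalized objective up to the constant sum(Yc^2): detects the flat
      # tail of ill-conditioned designs where coefficient moves stay large
      obj <- sum(beta * (G %*% beta)) - 2 * sum(beta * Cy) +
        r1 * sum(abs(beta)) + r2 * sum(beta^2)
      if (obj_prev - obj < 1e-13 * (1 + abs(obj))) {
        stall <- stall + 1L
        if (stall >= 3L) { converged <- TRUE; break }
      } else stall <- 0L
      obj_prev <- obj
    }
  }
  if (!converged) {
    obj <- en_objective_internal(Q, X, beta, xm, ym, r1, r2)
    stop(sprintf("numerical error: coordinate descent did not converge (last objective %.6e)",
                 obj))
  }
  b0 <- ym - drop(crossprod(beta, xm))
  structure(list(degree = degree, coefficients = rbind(b0, beta, deparse.level = 0),
                 r1 = r1, r2 = r2, time_transform = tf, basis = basis,
                 subspace = subspace),
            class = "st_polynomial_model")
}

soft_threshold <- function(x, g) sign(x) * pmax(abs(x) - g, 0)

en_objective_internal <- function(Q, X, beta, xm, ym, r1, r2) {
  b0 <- ym - drop(crossprod(beta, xm))
  pred <- sweep(X %*% beta, 2L, b0, `+`)
  sum((Q - pred)^2) + r1 * sum(abs(beta)) + r2 * sum(beta^2)
}

#' Elastic-net objective value of a fitted polynomial model
#'
#' Evaluates the penalized SSE the model minimizes (for diagnostics and
#' testing against independent solvers).
#' @param model an `st_polynomial_model`.
#' @param scores K x R score matrix.
#' @param times length-K times.
#' @return scalar objective value.
#' @export
elastic_net_objective <- function(model, scores, times) {
  Q <- if (is.null(dim(scores))) matrix(scores, ncol = 1L) else as.matrix(scores)
  H <- predict_scores(model, times)
  beta <- model$coefficients[-1L, , drop = FALSE]
  sum((Q - H)^2) + model$r1 * sum(abs(beta)) + model$r2 * sum(beta^2)
}

#' Predicted PCA scores of a polynomial model at given times
#' @param model an `st_polynomial_model`.
#' @param times numeric vector.
#' @return length(times) x R matrix.
#' @export
predict_scores <- function(model, times) {
  tt <- time_transform_apply(model$time_transform, times)
  X <- cbind(1, poly_design(tt, model$degree, coefs = model$basis))
  X %*% model$coefficients
}

#' @export
predict.st_polynomial_model <- function(object, times, ...) {
  if (is.null(object$subspace))
    stop("model has no principal subspace attached; cannot map to shape space")
  H <- predict_scores(object, times)
  sweep(H %*% t(object$subspace$eigenvectors), 2L, object$subspace$mean, `+`)
}

#' Predicted shape at a time point
#'
#' Maps the polynomial in the principal subspace back to shape space,
#' \eqn{g(t) = U h(t) + \mu}.  Extrapolation outside the observed time range
#' is permitted and is the caller's responsibility.
#'
#' @param model an `st_polynomial_model` (with subspace) or
#'   `st_linear_model`.
#' @param t scalar time.
#' @return dM-vector.
#' @export
predict_shape <- function(model, t) {
  drop(stats::predict(model, times = t))
}

#' Residuals of shape samples under a temporal model
#'
#' Returns \eqn{Y = Z - \hat Z(t)}; this matrix feeds
#' [correspondence_gradient()], replacing the sample covariance with the
#' residual covariance.
#'
#' @param z_samples K x dM matrix.
#' @param model a fitted `st_constant_model`, `st_linear_model` or
#'   `st_polynomial_model`.
#' @param times length-K time values.
#' @return K x dM residual matrix.
#' @export
residual_matrix <- function(z_samples, model, times) {
  z <- as.matrix(z_samples)
  z - stats::predict(model, times = times)
}

#' Select elastic-net weights by subject-stratified cross validation
#'
#' Splits whole subjects into 5 folds (preserving the repeated-measures
#' structure), fits the polynomial on each training split for every (r1,r2)
#' pair and returns the pair minimizing the mean held-out squared prediction
#' error.  Ties (within 1e-10 relative) break toward larger r1 + r2.  With
#' fewer than 5 subjects the split degrades to leave-one-subject-out with a
#' warning.
#'
#' @param scores K x R score matrix.
#' @param times length-K times.
#' @param degree polynomial degree.
#' @param grid data.frame/matrix with columns r1, r2 (or list of pairs).
#' @param rng_seed integer seed controlling the fold assignment.
#' @param subjects length-K subject labels.
#' @param n_folds number of folds (default 5).
#' @return list with elements r1, r2, cv_error (grid errors), folds.
#' @export
select_regularization_cv <- function(scores, times, degree, grid, rng_seed,
                                     subjects, n_folds = 5L) {
  Q <- if (is.null(dim(scores))) matrix(scores, ncol = 1L) else as.matrix(scores)
  K <- nrow(Q)
  if (K < 10L) stop("need K >= 10 samples for cross validation")
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("empty regularization grid")
  names(grid)[1:2] <- c("r1", "r2")
  subjects <- as.character(subjects)
  usub <- unique(subjects)
  if (length(usub) < n_folds) {
    warning("fewer than ", n_folds,
            " subjects: falling back to leave-one-subject-out CV")
    n_folds <- length(usub)
  }
  fold_of <- with_seed(rng_seed, {
    f <- integer(length(usub))
    f[sample(length(usub))] <- rep_len(seq_len(n_folds), length(usub))
    stats::setNames(f, usub)
  })
  fold_k <- fold_of[subjects]
  tf <- time_transform_fit(times)
  basis <- attr(poly_design(time_transform_apply(tf, times), degree), "coefs")
  err <- matrix(NA_real_, nrow(grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold_k != f; te <- !tr
    if (!any(te) || sum(tr) < 2L) next
    for (g in seq_len(nrow(grid))) {
      m <- fit_polynomial_elastic_net(Q[tr, , drop = FALSE], times[tr], degree,
                                      r1 = grid$r1[g], r2 = grid$r2[g],
                                      time_transform = tf, basis = basis)
      pr <- predict_scores(m, times[te])
      err[g, f] <- mean((Q[te, , drop = FALSE] - pr)^2)
    }
  }
  mean_err <- rowMeans(err, na.rm = TRUE)
  best <- min(mean_err)
  cand <- which(mean_err <= best * (1 + 1e-10) + 1e-300)
  pick <- cand[which.max(grid$r1[cand] + grid$r2[cand])]
  list(r1 = grid$r1[pick], r2 = grid$r2[pick],
       cv_error = data.frame(grid, error = mean_err), folds = fold_k)
}

#' Default elastic-net regularization grid
#' @return data.frame of (r1, r2) pairs (Cartesian over
#'   \{0, 1e-4, 1e-3, 1e-2, 1e-1, 1\}).
#' @export
default_regularization_grid <- function() {
  v <- c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1)
  expand.grid(r1 = v, r2 = v)
}
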