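test_that("linear regression: noiseless line, constant data, normal equations", {
  t <- 1:8
  Z <- outer(rep(1, 8), rep(2, 6)) + outer(t, rep(3, 6))
  m <- fit_linear_regression(Z, t)
  expect_equal(m$intercept, rep(2, 6), tolerance = 1e-10)
  expect_equal(m$slope, rep(3, 6), tolerance = 1e-10)
  Zc <- outer(rep(1, 8), c(1, -2, 0.5))
  mc <- fit_linear_regression(Zc, t)
  expect_equal(mc$slope, rep(0, 3), tolerance = 1e-12)
  expect_equal(mc$intercept, c(1, -2, 0.5), tolerance = 1e-12)
  set.seed(1)
  t10 <- runif(10); Z10 <- matrix(rnorm(60), 10, 6)
  m10 <- fit_linear_regression(Z10, t10)
  X <- cbind(1, t10)
  cf <- solve(crossprod(X), crossprod(X, Z10))
  expect_equal(rbind(m10$intercept, m10$slope), unname(cf), tolerance = 1e-10)
  expect_error(fit_linear_regression(Z10, rep(1, 10)), "degenerate-design")
})

test_that("principal subspace: reconstruction, rank, covariance oracle", {
  set.seed(2)
  Z <- matrix(rnorm(10 * 6), 10, 6)
  sub <- fit_pca_subspace(Z)
  q <- project_scores(sub, Z)
  rec <- sweep(q %*% t(sub$eigenvectors), 2, sub$mean, `+`)
  expect_lt(max(abs(rec - Z)), 1e-8)
  expect_lt(max(abs(crossprod(sub$eigenvectors) -
                    diag(ncol(sub$eigenvectors)))), 1e-10)
  expect_true(all(diff(sub$eigenvalues) <= 1e-12))
  ev_dense <- sort(eigen(stats::cov(Z), symmetric = TRUE)$values,
                   decreasing = TRUE)[seq_along(sub$eigenvalues)]
  expect_lt(max(abs(sub$eigenvalues - ev_dense)) / ev_dense[1], 1e-9)
  # 1-D data has exactly one non-negligible eigenvalue
  line <- outer(seq(0, 1, length.out = 7), c(1, 2, 3, 0, -1, 4))
  evl <- fit_pca_subspace(line)$eigenvalues
  expect_gt(evl[1], 0)
  expect_lt(evl[2] / evl[1], 1e-20)
})

test_that("elastic net: exact line, full shrinkage, proximal-gradient oracle", {
  t <- 1:8
  q <- cbind(0.5 + 2 * t, 1 - 0.3 * t)
  pm <- fit_polynomial_elastic_net(q, t, degree = 1L)
  expect_lt(max(abs(predict_scores(pm, t) - q)), 1e-9)
  lin <- fit_linear_regression(q, t)
  expect_lt(max(abs(predict_scores(pm, t) - predict(lin, t))), 1e-9)
  # huge L1 shrinks all non-intercept coefficients to exactly 0
  pm2 <- fit_polynomial_elastic_net(q, t, degree = 3L, r1 = 1e8)
  expect_equal(max(abs(pm2$coefficients[-1, ])), 0)
  expect_equal(pm2$coefficients[1, ], unname(colMeans(q)), tolerance = 1e-12)
  # objective matches an independent proximal-gradient solver to 1e-6
  set.seed(3)
  q3 <- matrix(rnorm(16), 8, 2)
  r1 <- 0.3; r2 <- 0.2; P <- 3L
  pm3 <- fit_polynomial_elastic_net(q3, t, degree = P, r1 = r1, r2 = r2)
  obj_cd <- elastic_net_objective(pm3, q3, t)
  # oracle: FISTA-free proximal gradient on the same design and objective
  X <- cbind(1, dynshape:::poly_design(
    dynshape:::time_transform_apply(pm3$time_transform, t), P,
    coefs = pm3$basis))
  Xc <- X[, -1, drop = FALSE]
  prox_obj <- function(y) {
    b <- rep(0, P); b0 <- mean(y)
    L <- 2 * (max(eigen(crossprod(Xc))$values) + r2)
    for (i in 1:50000) {
      r <- b0 + Xc %*% b - y
      g <- 2 * crossprod(Xc, r) + 2 * r2 * b
      b <- sign(b - g / L) * pmax(abs(b - g / L) - r1 / L, 0)
      b0 <- b0 - mean(r)
    }
    sum((y - b0 - Xc %*% b)^2) + r1 * sum(abs(b)) + r2 * sum(b^2)
  }
  obj_pg <- prox_obj(q3[, 1]) + prox_obj(q3[, 2])
  expect_lt(abs(obj_cd - obj_pg), 1e-6)
})

test_that("single-subject unregularized degree T-1 polynomial interpolates", {
  T <- 6L
  t <- 1:T
  set.seed(4)
  q <- matrix(rnorm(T * 3), T, 3)
  pm <- fit_polynomial_elastic_net(q, t, degree = T - 1L, r1 = 0, r2 = 0)
  expect_lt(max(abs(predict_scores(pm, t) - q)), 1e-7)
})

test_that("predict_shape maps scores back through the subspace", {
  set.seed(5)
  Z <- matrix(rnorm(8 * 9), 8, 9)
  sub <- fit_pca_subspace(Z)
  q <- project_scores(sub, Z)
  pm <- fit_polynomial_elastic_net(q, 1:8, degree = 7L, r1 = 0, r2 = 0,
                                   subspace = sub)
  # degree T-1 unregularized interpolates: g(t_k) recovers each sample
  for (k in c(1, 5, 8))
    expect_equal(predict_shape(pm, k), Z[k, ], tolerance = 1e-6)
  # all-zero coefficients return the mean for every t
  pm0 <- pm
  pm0$coefficients[] <- 0
  expect_equal(predict_shape(pm0, 3.7), sub$mean)
})

test_that("residual_matrix: perfect model, constant model, OLS orthogonality", {
  set.seed(6)
  t <- 1:10
  Z <- outer(rep(1, 10), rnorm(4)) + outer(t, rnorm(4)) +
    matrix(rnorm(40), 10, 4) * 0.2
  lm1 <- fit_linear_regression(Z, t)
  Y <- residual_matrix(Z, lm1, t)
  expect_lt(max(abs(colMeans(Y))), 1e-10)
  expect_lt(max(abs(crossprod(Y, t))), 1e-8)
  cm <- fit_constant_model(Z)
  expect_equal(residual_matrix(Z, cm, t), sweep(Z, 2, colMeans(Z)),
               tolerance = 1e-12)
  Zlin <- predict(lm1, t)
  expect_lt(max(abs(residual_matrix(Zlin, lm1, t))), 1e-10)
})

test_that("cross-validation selects sensibly and deterministically", {
  set.seed(7)
  K <- 40L
  subjects <- rep(sprintf("s%d", 1:10), each = 4)
  times <- rep(1:4, 10)
  # noiseless cubic scores
  q <- cbind(0.2 * times^3 - times, 0.5 * times^2)
  grid <- default_regularization_grid()
  sel <- select_regularization_cv(q, times, degree = 3L, grid, rng_seed = 1L,
                                  subjects = subjects)
  best_err <- min(sel$cv_error$error)
  expect_lte(sel$cv_error$error[sel$cv_error$r1 == sel$r1 &
                                sel$cv_error$r2 == sel$r2][1], best_err + 1e-12)
  sel2 <- select_regularization_cv(q, times, degree = 3L, grid, rng_seed = 1L,
                                   subjects = subjects)
  expect_identical(sel[c("r1", "r2")], sel2[c("r1", "r2")])
  expect_warning(
    select_regularization_cv(matrix(rnorm(24), 12, 2), rep(1:4, 3), 2L, grid,
                             rng_seed = 1L,
                             subjects = rep(c("a", "b", "c"), each = 4)),
    "leave-one-subject-out")
})

test_that("pure-noise scores select the largest-shrinkage pair (majority)", {
  grid <- data.frame(r1 = c(0, 1), r2 = c(0, 1))
  subjects <- rep(sprintf("s%d", 1:10), each = 4)
  times <- rep(1:4, 10)
  picks <- vapply(1:20, function(rep) {
    set.seed(100 + rep)
    q <- matrix(rnorm(80), 40, 2)
    sel <- select_regularization_cv(q, times, degree = 3L, grid,
                                    rng_seed = rep, subjects = subjects)
    sel$r1 + sel$r2
  }, numeric(1))
  expect_gt(mean(picks == 2), 0.5)
})

test_that("disentangled gradient matches finite differences on a toy system", {
  co <- tiny_cohort(n_subjects = 3L, n_timepoints = 3L)
  ps <- analytic_system(co, M = 2L)
  aw <- 0.7; a <- 0.05
  G <- disentangled_gradient(ps, aw, a)
  Z <- as_shape_matrix(ps)
  cells <- attr(Z, "cells")
  obj <- function(Zv) {
    Zm <- matrix(Zv, nrow(Z), ncol(Z))
    H <- 0
    for (tt in 1:3) H <- H + shape_space_entropy(Zm[cells$t == tt, ], a)
    for (nn in 1:3) H <- H + shape_space_entropy(Zm[cells$n == nn, ], a)
    aw * H
  }
  FD <- matrix(fd_gradient(obj, as.vector(Z)), nrow(Z), ncol(Z))
  for (k in seq_len(nrow(cells))) {
    expect_lt(max(abs(G[cells$n[k], cells$t[k], ] - FD[k, ])) /
                max(abs(FD)), 1e-5)
  }
  # identical shapes give a zero gradient
  surfaces <- matrix(vector("list", 9), 3, 3)
  for (i in seq_along(surfaces)) surfaces[[i]] <- make_ellipsoid(1, 1, 1)
  co2 <- shape_cohort(surfaces, subject_ids = c("a", "b", "c"))
  ps2 <- analytic_system(co2, M = 2L)
  expect_lt(max(abs(disentangled_gradient(ps2, 1, 0.1))), 1e-10)
  # missing cells are rejected
  co3 <- generate_cohort(ellipsoid_cohort_spec(4, 4, missing_fraction = 0.2,
                                               rng_seed = 2))
  ps3 <- analytic_system(co3, M = 2L)
  expect_error(disentangled_gradient(ps3, 1, 0.1), "unsupported-design")
})
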