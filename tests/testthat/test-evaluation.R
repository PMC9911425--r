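test_that("pca_modes: variance fractions, isotropic cloud, oracle eigenvalues", {
  set.seed(1)
  Z <- matrix(rnorm(500 * 9), 500, 9)
  rep_ <- pca_modes(Z)
  vf <- vapply(rep_$modes, `[[`, numeric(1), "variance_fraction")
  expect_equal(sum(vf), 1, tolerance = 1e-10)
  expect_true(all(abs(vf - 1 / 9) < 0.05))   # isotropic: roughly equal
  ev_dense <- sort(eigen(stats::cov(Z), symmetric = TRUE)$values,
                   decreasing = TRUE)
  expect_equal(rep_$eigenvalues, ev_dense[seq_along(rep_$eigenvalues)],
               tolerance = 1e-9)
})

test_that("mode 1 of the analytic ellipsoid cohort is x-dominated per time point", {
  co <- tiny_cohort(n_subjects = 12L, n_timepoints = 4L, seed = 8L)
  ps <- analytic_system(co, M = 16L)
  Z <- as_shape_matrix(ps)
  cells <- attr(Z, "cells")
  for (tt in 1:4) {
    mt <- pca_modes(Z[cells$t == tt, , drop = FALSE])
    d <- mt$modes[[1]]$displacement_plus - mt$mean
    expect_gt(axis_displacement_fraction(d, 1), 0.95)
  }
})

test_that("fit_sine recovers parameters and handles edge cases", {
  t <- 1:8
  y <- 0.6 + 0.4 * sin(2 * pi * t / 8)
  fit <- fit_sine(y, t)
  expect_equal(fit$model$offset, 0.6, tolerance = 1e-8)
  expect_equal(fit$model$amplitude, 0.4, tolerance = 1e-8)
  expect_lt(fit$sse, 1e-12)
  fitc <- fit_sine(rep(2.5, 8), t)
  expect_equal(fitc$model$amplitude, 0)
  expect_equal(fitc$model$offset, 2.5)
  expect_error(fit_sine(1:3, 1:3), "4 distinct")
})

test_that("fit_sine parameter recovery under noise is unbiased (simulation)", {
  t <- 1:8
  truth <- c(o = 0.6, A = 0.4, f = 1 / 8)
  ests <- t(vapply(1:50, function(r) {
    set.seed(2000 + r)
    y <- truth["o"] + truth["A"] * sin(2 * pi * truth["f"] * t) +
      rnorm(8, sd = 0.01)
    fit <- fit_sine(y, t)
    c(fit$model$offset, fit$model$amplitude, abs(fit$model$frequency))
  }, numeric(3)))
  for (j in 1:3) {
    mc_sd <- stats::sd(ests[, j])
    expect_lt(abs(mean(ests[, j]) - truth[j]), 3 * mc_sd + 1e-6)
  }
})

test_that("sine goodness of fit: exact trajectories give R2 = 1, shuffling destroys it", {
  co <- tiny_cohort(n_subjects = 8L, n_timepoints = 8L, seed = 9L)
  ps <- analytic_system(co, M = 8L)     # y-coords follow the exact sinusoid
  gof <- sine_goodness_of_fit(ps)
  expect_gt(gof$r2, 1 - 1e-8)
  expect_lt(gof$mean_sse, 1e-12)
  # independent-noise trajectories: R2 near zero
  set.seed(10)
  psn <- ps
  psn$particles <- psn$particles + rnorm(length(psn$particles)) * 0.5
  # (particles no longer on surfaces; goodness of fit only reads positions)
  # pure noise leaves the sine's overfitting floor (~0.6 at T = 8: three
  # parameters plus a freely profiled frequency are flexible)
  gofn <- sine_goodness_of_fit(psn)
  expect_lt(gofn$r2, 0.65)
})

test_that("R2 is at most 1 and equals 1 iff residuals vanish", {
  co <- tiny_cohort(n_subjects = 4L, n_timepoints = 8L)
  ps <- analytic_system(co, M = 4L)
  gof <- sine_goodness_of_fit(ps)
  expect_lte(gof$r2, 1)
  expect_equal(gof$r2, 1, tolerance = 1e-9)
})

test_that("time-dependency test: strong effect detected, type-I error controlled", {
  # strong injected time effect
  set.seed(11)
  N <- 10L; T <- 5L; M <- 4L
  co <- tiny_cohort(n_subjects = N, n_timepoints = T)
  arr <- array(rnorm(N * T * M * 3, sd = 0.05), c(N, T, M, 3))
  shift <- array(rep(seq(0, 2, length.out = T), each = N), c(N, T, M, 3))
  ps_eff <- particle_system(arr + shift, co)
  r_eff <- time_dependency_test(ps_eff, n_coords = 10L, rng_seed = 1L)
  expect_lt(r_eff$p_value, 1e-3)
  # type-I error under a pure-noise null, 200 seeded replicates
  rej <- vapply(1:200, function(r) {
    set.seed(3000 + r)
    arr0 <- array(rnorm(N * T * M * 3), c(N, T, M, 3))
    ps0 <- particle_system(arr0, co)
    time_dependency_test(ps0, n_coords = 10L, rng_seed = 1L)$p_value < 0.05
  }, logical(1))
  rate <- mean(rej)
  ci_half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), ci_half + 1e-12)
  expect_error(time_dependency_test(
    particle_system(array(rnorm(2 * 2 * 4 * 3), c(2, 2, 4, 3)),
                    tiny_cohort(2L, 2L))), "insufficient-data")
})

test_that("mesh volume, orientation, area, sphericity", {
  m <- ellipsoid_mesh(1, 1, 1, subdivisions = 4L)
  expect_equal(mesh_volume(m), pi / 6, tolerance = 0.005)
  m2 <- ellipsoid_mesh(0.6, 0.8, 1.0, subdivisions = 4L)
  expect_equal(mesh_volume(m2), pi / 6 * 0.48, tolerance = 0.005)
  # flipping orientation negates the signed volume
  flip <- make_mesh_surface(m2$vertices, m2$faces[, c(1L, 3L, 2L)])
  expect_equal(mesh_volume(flip), -mesh_volume(m2))
  expect_equal(sphericity(m), 1, tolerance = 0.005)
  # exact unit cube: 12 triangles, sphericity (pi/6)^(1/3)
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1,3,2), c(2,3,4), c(5,6,7), c(6,8,7),
             c(1,2,5), c(2,6,5), c(3,7,4), c(4,7,8),
             c(1,5,3), c(3,5,7), c(2,4,6), c(4,8,6))
  cube <- make_mesh_surface(v, f)
  expect_equal(abs(mesh_volume(cube)), 1, tolerance = 1e-12)
  expect_equal(sphericity(cube), (pi / 6)^(1 / 3), tolerance = 1e-3)
  # elongating an ellipsoid strictly decreases sphericity
  sp <- vapply(c(1, 1.5, 2.5, 4), function(s)
    sphericity(ellipsoid_mesh(1, 1, s, subdivisions = 3L)), numeric(1))
  expect_true(all(diff(sp) < 0))
  # open mesh warns
  open_mesh <- make_mesh_surface(m$vertices, m$faces[-1, ])
  expect_warning(mesh_volume(open_mesh), "not closed")
})
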