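# Scheme-level behavior of optimize_spatiotemporal at reduced scale
# (full Table-1-scale behavior is covered in test-acceptance.R).

test_that("cross_sectional method delegates exactly to the core optimizer", {
  co <- tiny_cohort()
  cfg <- optimizer_config(target_particles = 4L, iterations = 30L,
                          rng_seed = 21L)
  ps <- optimize_cross_sectional(co, cfg)
  res <- optimize_spatiotemporal(co, "cross_sectional", cfg)
  expect_identical(res$system$particles, ps$particles)
})

test_that("unknown method and disentangled-with-missing-cells are rejected", {
  co <- tiny_cohort()
  expect_error(optimize_spatiotemporal(co, "banana"), "should be one of")
  com <- generate_cohort(ellipsoid_cohort_spec(4, 4, missing_fraction = 0.2,
                                               rng_seed = 2))
  expect_error(optimize_spatiotemporal(com, "disentangled"),
               "unsupported-design")
})

test_that("linear-regression scheme beats cross-sectional residual entropy on linearly scaling shapes", {
  # cohort whose only temporal change is a linear scaling of the y-diameter
  N <- 4L; T <- 5L
  surfaces <- matrix(vector("list", N * T), N, T)
  set.seed(22)
  xs <- runif(N, 0.5, 0.9)
  for (n in 1:N) for (t in 1:T)
    surfaces[[n, t]] <- make_ellipsoid(xs[n], 0.4 + 0.1 * t, 1)
  co <- shape_cohort(surfaces, subject_ids = sprintf("s%d", 1:N))
  cfg <- optimizer_config(target_particles = 8L, iterations = 80L,
                          rng_seed = 23L)
  res_lin <- optimize_spatiotemporal(co, "linear_regression", cfg)
  res_cs <- optimize_spatiotemporal(co, "cross_sectional", cfg)
  a <- 1e-4
  Zl <- as_shape_matrix(res_lin$system)
  Zc <- as_shape_matrix(res_cs$system)
  times <- attr(Zl, "cells")$time_value
  # residual entropy of each scheme's own residuals, same regularizer
  Yl <- residual_matrix(Zl, res_lin$model, times)
  Yc <- sweep(Zc, 2, colMeans(Zc))
  expect_lt(dynshape:::residual_entropy(Yl, a),
            dynshape:::residual_entropy(Yc, a))
})

test_that("pc-polynomial with P=1, r=0 matches the linear scheme's residual SSE", {
  N <- 4L; T <- 4L
  surfaces <- matrix(vector("list", N * T), N, T)
  set.seed(24)
  xs <- runif(N, 0.5, 0.9)
  for (n in 1:N) for (t in 1:T)
    surfaces[[n, t]] <- make_ellipsoid(xs[n], 0.4 + 0.12 * t, 1)
  co <- shape_cohort(surfaces, subject_ids = sprintf("s%d", 1:N))
  ps <- analytic_system(co, M = 8L)
  Z <- as_shape_matrix(ps)
  times <- attr(Z, "cells")$time_value
  lin <- fit_linear_regression(Z, times)
  sse_lin <- sum(residual_matrix(Z, lin, times)^2)
  sub <- fit_pca_subspace(Z)
  q <- project_scores(sub, Z)
  pm <- fit_polynomial_elastic_net(q, times, degree = 1L, r1 = 0, r2 = 0,
                                   subspace = sub)
  sse_pc <- sum(residual_matrix(Z, pm, times)^2)
  expect_lt(abs(sse_pc - sse_lin), 0.05 * max(sse_lin, 1e-12))
})

test_that("missing cells are tolerated by regression methods", {
  com <- generate_cohort(ellipsoid_cohort_spec(6, 6, missing_fraction = 0.1,
                                               rng_seed = 25))
  cfg <- optimizer_config(target_particles = 8L, iterations = 80L,
                          rng_seed = 26L)
  res <- optimize_spatiotemporal(com, "pc_polynomial", cfg)
  expect_equal(nrow(as_shape_matrix(res$system)), sum(com$observed))
  gof <- sine_goodness_of_fit(res$system)
  expect_true(is.finite(gof$r2))
})

test_that("disentangled scheme runs on a complete grid and keeps particles on-surface", {
  co <- tiny_cohort(n_subjects = 4L, n_timepoints = 3L)
  cfg <- optimizer_config(target_particles = 4L, iterations = 40L,
                          rng_seed = 27L)
  res <- optimize_spatiotemporal(co, "disentangled", cfg)
  expect_lt(max_surface_residual(res$system), 1e-6)
  tr <- res$trace
  expect_true(all(tr$Q_post <= tr$Q_pre + 1e-8 * (1 + abs(tr$Q_pre))))
})

test_that("fitted pc-polynomial trajectories vary smoothly over time", {
  co <- tiny_cohort(n_subjects = 6L, n_timepoints = 8L, seed = 28L)
  cfg <- optimizer_config(target_particles = 8L, iterations = 150L,
                          rng_seed = 29L)
  res <- optimize_spatiotemporal(co, "pc_polynomial", cfg)
  g <- vapply(1:8, function(t) predict_shape(res$model, t),
              numeric(3L * n_particles(res$system)))
  # per-particle second-difference norms across t: no particle's fitted
  # trajectory is much rougher than typical (spatial regularity induced by
  # the principal-subspace coupling)
  d2 <- g[, 3:8] - 2 * g[, 2:7] + g[, 1:6]
  M <- n_particles(res$system)
  pn <- vapply(seq_len(M), function(m)
    max(sqrt(colSums(d2[3 * (m - 1) + 1:3, , drop = FALSE]^2))), numeric(1))
  expect_lt(max(pn), 3 * stats::median(pn) + 1e-8)
})
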