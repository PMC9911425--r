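test_that("shape-space entropy: zero covariance, determinant oracle, scaling", {
  a <- 0.5
  Z0 <- rbind(1:6, 1:6)
  expect_equal(shape_space_entropy(Z0, a), (6 / 2) * log(a))
  set.seed(1)
  Z <- matrix(rnorm(60), 10, 6)
  expect_equal(shape_space_entropy(Z, 0.1),
               0.5 * log(det(stats::cov(Z) + 0.1 * diag(6))),
               tolerance = 1e-12)
  # scaling all rows by c adds dM * log|c| (at negligible regularization)
  cc <- 2.5
  expect_equal(shape_space_entropy(Z * cc, 1e-12) - shape_space_entropy(Z, 1e-12),
               6 * log(cc), tolerance = 1e-4)
  expect_error(shape_space_entropy(Z[1, , drop = FALSE], 0.1),
               "insufficient-samples")
})

test_that("correspondence gradient equals finite differences and dual form", {
  set.seed(2)
  for (rep in 1:3) {
    K <- 4L; dM <- 6L; a <- 10^stats::runif(1, -3, -1)
    Z <- matrix(rnorm(K * dM), K, dM)
    G <- correspondence_gradient(Z, colMeans(Z), a)
    FD <- matrix(fd_gradient(function(z) shape_space_entropy(z, a), Z), K, dM)
    expect_lt(max(abs(G - FD)) / max(abs(FD)), 1e-5)
    # dual K x K solve agrees with the dM x dM primal expression
    Y <- sweep(Z, 2, colMeans(Z))
    Gp <- Y %*% solve(crossprod(Y) + (K - 1) * a * diag(dM))
    expect_equal(G, Gp, tolerance = 1e-10)
  }
})

test_that("correspondence gradient: zero residual and shrinkage limits", {
  set.seed(3)
  Z <- matrix(rnorm(24), 4, 6)
  expect_equal(correspondence_gradient(Z, Z, 0.1), matrix(0, 4, 6))
  g1 <- sqrt(sum(correspondence_gradient(Z, colMeans(Z), 1)^2))
  g2 <- sqrt(sum(correspondence_gradient(Z, colMeans(Z), 1e4)^2))
  expect_lt(g2, g1)
  expect_lt(g2, 1e-3)
})

test_that("sampling gradient: no neighbors, symmetry, finite differences", {
  expect_equal(sampling_gradient(matrix(c(1, 2, 3), 1, 3), 0.5),
               matrix(0, 1, 3))
  X2 <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0))
  g2 <- sampling_gradient(X2, 0.3)
  expect_equal(g2[1, ], -g2[2, ])
  expect_gt(g2[1, 1], 0)            # repulsion along +x
  expect_equal(g2[1, 2:3], c(0, 0))
  set.seed(4)
  X <- matrix(rnorm(15), 5, 3) * 0.5
  sig <- 0.4
  G <- sampling_gradient(X, sig)
  FD <- matrix(fd_gradient(function(x) parzen_entropy(matrix(x, 5, 3), sig),
                           X), 5, 3)
  expect_lt(max(abs(G - FD)) / max(abs(FD)), 1e-5)
})

test_that("particle splitting doubles M, keeps surfaces, bounds the shift", {
  co <- tiny_cohort()
  ps <- init_particles(co)
  expect_equal(n_particles(ps), 1L)
  ps2 <- split_particles(ps, offset = 0.05, rng_seed = 9)
  expect_equal(n_particles(ps2), 2L)
  expect_lt(max_surface_residual(ps2), 1e-8)
  # mean particle position moves less than the offset
  for (n in 1:2) for (t in 1:2) {
    m1 <- colMeans(matrix(ps$particles[n, t, , ], ncol = 3))
    m2 <- colMeans(matrix(ps2$particles[n, t, , ], ncol = 3))
    expect_lt(sqrt(sum((m2 - m1)^2)), 0.05 * 1.01)
  }
  # repeated splitting reaches the ellipsoid configuration of 128
  m <- 2L
  psk <- ps2
  while (m < 128L) {
    psk <- split_particles(psk, offset = 0.02, rng_seed = m)
    m <- m * 2L
  }
  expect_equal(n_particles(psk), 128L)
  expect_lt(max_surface_residual(psk), 1e-8)
})

test_that("identical shapes give identical particles and ~zero eigenvalues", {
  surfaces <- matrix(vector("list", 4), 2, 2)
  for (i in seq_along(surfaces)) surfaces[[i]] <- make_ellipsoid(1, 1, 1)
  co <- shape_cohort(surfaces, subject_ids = c("a", "b"))
  cfg <- optimizer_config(target_particles = 8L, iterations = 40L,
                          rng_seed = 1L)
  ps <- optimize_cross_sectional(co, cfg)
  Z <- as_shape_matrix(ps)
  expect_lt(max(abs(sweep(Z, 2, colMeans(Z)))), 1e-9)
  ev <- fit_pca_subspace(Z)$eigenvalues
  expect_lt(sum(ev), 1e-6 * max(sum(Z[1, ]^2), 1))
})

test_that("objective is non-increasing over accepted steps and particles stay on-surface", {
  co <- tiny_cohort()
  cfg <- optimizer_config(target_particles = 8L, iterations = 60L,
                          rng_seed = 2L)
  ps <- optimize_cross_sectional(co, cfg)
  tr <- attr(ps, "trace")
  expect_true(all(tr$Q_post <= tr$Q_pre + 1e-8 * (1 + abs(tr$Q_pre))))
  expect_lt(max_surface_residual(ps), 1e-6)
})

test_that("optimization is bitwise deterministic under a fixed seed", {
  co <- tiny_cohort()
  cfg <- optimizer_config(target_particles = 4L, iterations = 30L,
                          rng_seed = 123L)
  ps1 <- optimize_cross_sectional(co, cfg)
  ps2 <- optimize_cross_sectional(co, cfg)
  expect_identical(ps1$particles, ps2$particles)
})

test_that("disabling the sampling term collapses particles (documented failure mode)", {
  co <- tiny_cohort(n_subjects = 3L, n_timepoints = 2L)
  spread <- function(ps) {
    cells <- observed_cells(ps$cohort)
    mean(vapply(seq_len(nrow(cells)), function(k) {
      P <- matrix(ps$particles[cells$n[k], cells$t[k], , ], ncol = 3)
      mean(sqrt(rowSums(sweep(P, 2, colMeans(P))^2)))
    }, numeric(1)))
  }
  # same budget with and without the per-shape spread term: without it,
  # particles stay clumped near a single location on each shape
  cfg_on <- optimizer_config(target_particles = 4L, iterations = 150L,
                             rng_seed = 3L)
  cfg_off <- optimizer_config(target_particles = 4L, iterations = 150L,
                              sampling_weight = 0, rng_seed = 3L)
  s_on <- spread(optimize_cross_sectional(co, cfg_on))
  s_off <- spread(optimize_cross_sectional(co, cfg_off))
  expect_lt(s_off, 0.5 * s_on)
})
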