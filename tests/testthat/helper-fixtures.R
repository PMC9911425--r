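# Shared fixtures, built in code at test time.

# tiny complete ellipsoid cohort (subject x-diameters fixed, sinusoidal y)
tiny_cohort <- function(n_subjects = 3L, n_timepoints = 4L, seed = 5L) {
  generate_cohort(ellipsoid_cohort_spec(n_subjects = n_subjects,
                                        n_timepoints = n_timepoints,
                                        rng_seed = seed))
}

# deterministic particle system placed analytically on ellipsoid surfaces:
# a fixed set of unit-sphere directions scaled by each shape's semi-axes,
# i.e. perfect affine correspondence (no optimization involved)
analytic_system <- function(cohort, M = 8L, seed = 3L) {
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * M), M, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  N <- nrow(cohort$observed); T <- ncol(cohort$observed)
  arr <- array(NA_real_, c(N, T, M, 3))
  for (n in seq_len(N)) for (t in seq_len(T)) {
    if (!cohort$observed[n, t]) next
    a <- cohort$surfaces[[n, t]]$semiaxes
    arr[n, t, , ] <- sweep(dirs, 2L, a, `*`)
  }
  particle_system(arr, cohort)
}

fd_gradient <- function(f, X, h = 1e-6) {
  G <- if (is.null(dim(X))) numeric(length(X)) else array(0, dim(X))
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- X[i] + h
    Xm <- X; Xm[i] <- X[i] - h
    G[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# dense surface point sample of an ellipsoid (oracle for projections)
dense_ellipsoid_points <- function(surface, n = 20000L, seed = 1L) {
  set.seed(seed)
  d <- matrix(stats::rnorm(3 * n), n, 3)
  d <- d / sqrt(rowSums(d^2))
  sweep(d, 2L, surface$semiaxes, `*`)
}
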