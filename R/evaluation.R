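# Evaluation protocol: PCA modes of variation, subject-wise sinusoidal
# regression (SSE / pooled R^2), a repeated-measures time-dependency test,
# and mesh shape descriptors (volume, area, sphericity).

#' PCA modes of variation of a shape-space sample
#'
#' @param z_samples K x dM matrix of vectorized particle systems.
#' @param n_modes number of modes to report (default: all).
#' @return object of class `mode_report`: list with `mean`, `eigenvalues`
#'   (all), and a list `modes`, each holding `mode_index`, `eigenvalue`,
#'   `variance_fraction`, and `displacement_plus` / `displacement_minus`
#'   (mean +/- sqrt(lambda) * u).
#' @export
pca_modes <- function(z_samples, n_modes = NULL) {
  sub <- fit_pca_subspace(z_samples)
  ev <- sub$eigenvalues
  tot <- sum(ev)
  if (is.null(n_modes)) n_modes <- length(ev)
  n_modes <- min(n_modes, length(ev))
  modes <- lapply(seq_len(n_modes), function(i) {
    d <- sqrt(ev[i]) * sub$eigenvectors[, i]
    list(mode_index = i, eigenvalue = ev[i],
         variance_fraction = if (tot > 0) ev[i] / tot else 0,
         displacement_plus = sub$mean + d,
         displacement_minus = sub$mean - d)
  })
  structure(list(mean = sub$mean, eigenvalues = ev, modes = modes),
            class = "mode_report")
}

#' @export
print.mode_report <- function(x, ...) {
  vf <- vapply(x$modes, `[[`, numeric(1), "variance_fraction")
  cat(sprintf("<mode_report> %d modes; leading variance fractions: %s\n",
              length(x$modes),
              paste(sprintf("%.3f", utils::head(vf, 5L)), collapse = " ")))
  invisible(x)
}

#' Fraction of a displacement vector carried by one coordinate axis
#'
#' Particle-major vectorization means axis 1 (x) occupies components
#' 1, 4, 7, ...; useful to check which axis a mode is concentrated on.
#' @param displacement dM-vector (e.g. mode displacement minus the mean).
#' @param axis 1, 2 or 3.
#' @return scalar in [0, 1]: |d[axis components]| / |d|.
#' @export
axis_displacement_fraction <- function(displacement, axis = 1L) {
  idx <- seq(axis, length(displacement), by = 3L)
  sqrt(sum(displacement[idx]^2)) / sqrt(sum(displacement^2))
}

#' Fit a phase-free sinusoid by least squares
#'
#' Fits \eqn{s(t) = o + A \sin(2\pi f t)} over (o, A, f).  For fixed f the
#' model is linear in (o, A), so the fit profiles the SSE over a frequency
#' grid and then polishes all three parameters by Gauss-Newton iteration.
#' The amplitude is reported non-negative (sign absorbed by flipping the
#' frequency sign).
#'
#' @param values T observed values.
#' @param times T observation times (>= 4 distinct).
#' @param f_grid_n size of the initialization frequency grid.
#' @return list with `model` (class `sine_model`: offset, amplitude,
#'   frequency, angular_frequency), `sse`, and `converged`.
#' @export
fit_sine <- function(values, times, f_grid_n = 200L) {
  y <- as.numeric(values); t <- as.numeric(times)
  stopifnot(length(y) == length(t))
  if (length(unique(t)) < 4L) stop("need at least 4 distinct times")
  if (stats::sd(y) == 0) {
    return(list(model = sine_model(mean(y), 0, 0), sse = 0, converged = TRUE))
  }
  span <- max(t) - min(t)
  dt <- min(diff(sort(unique(t))))
  f_grid <- seq(0.25 / span, 0.5 / dt, length.out = f_grid_n)
  prof <- vapply(f_grid, function(f) sine_profile_sse(y, t, f)$sse, numeric(1))
  f0 <- f_grid[which.min(prof)]
  fit <- sine_profile_sse(y, t, f0)
  par <- c(fit$o, fit$A, 2 * pi * f0)
  sse <- fit$sse
  converged <- FALSE
  for (i in seq_len(100L)) {
    r <- par[1L] + par[2L] * sin(par[3L] * t) - y
    J <- cbind(1, sin(par[3L] * t), par[2L] * t * cos(par[3L] * t))
    JtJ <- crossprod(J)
    step <- tryCatch(solve(JtJ + 1e-12 * diag(3L), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    lam <- 1
    for (h in seq_len(20L)) {
      cand <- par - lam * drop(step)
      sc <- sum((cand[1L] + cand[2L] * sin(cand[3L] * t) - y)^2)
      if (is.finite(sc) && sc <= sse) { par <- cand; sse_new <- sc; ok <- TRUE; break }
      lam <- lam / 2
    }
    if (!ok) { converged <- TRUE; break }
    if (abs(sse - sse_new) < 1e-14 * (1 + sse)) { sse <- sse_new; converged <- TRUE; break }
    sse <- sse_new
  }
  o <- par[1L]; A <- par[2L]; w <- par[3L]
  if (A < 0) { A <- -A; w <- -w }
  list(model = sine_model(o, A, w / (2 * pi)), sse = sse, converged = converged)
}

sine_model <- function(offset, amplitude, frequency) {
  structure(list(offset = offset, amplitude = amplitude,
                 frequency = frequency,
                 angular_frequency = 2 * pi * frequency),
            class = "sine_model")
}

#' @export
predict.sine_model <- function(object, times, ...) {
  object$offset + object$amplitude * sin(object$angular_frequency * times)
}

# linear (o, A) profile for fixed frequency
sine_profile_sse <- function(y, t, f) {
  s <- sin(2 * pi * f * t)
  X <- cbind(1, s)
  cf <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                 error = function(e) c(mean(y), 0))
  r <- y - X %*% cf
  list(o = cf[1L], A = cf[2L], sse = sum(r^2))
}

# vectorized sine fits for many series sharing the same times.
# Y: T x J matrix (each column a series).  Returns list(sse, sst, par 3 x J).
sine_fit_batch <- function(Y, t, f_grid_n = 240L, gn_iter = 30L) {
  T <- length(t); J <- ncol(Y)
  span <- max(t) - min(t)
  dt <- min(diff(sort(unique(t))))
  f_grid <- seq(0.25 / span, 0.5 / dt, length.out = f_grid_n)
  best_sse <- rep(Inf, J); best_f <- rep(f_grid[1L], J)
  best_o <- colMeans(Y); best_A <- rep(0, J)
  sy <- colSums(Y)
  for (f in f_grid) {
    s <- sin(2 * pi * f * t)
    s1 <- sum(s); s2 <- sum(s^2)
    det <- T * s2 - s1^2
    if (abs(det) < 1e-12) next
    sYs <- drop(crossprod(Y, s))                # t(Y) %*% s
    A <- (T * sYs - s1 * sy) / det
    o <- (sy - A * s1) / T
    # SSE = sum(Y^2) - 2 o sy - 2 A sYs + o^2 T + 2 o A s1 + A^2 s2
    sse <- colSums(Y^2) - 2 * o * sy - 2 * A * sYs +
      o^2 * T + 2 * o * A * s1 + A^2 * s2
    upd <- sse < best_sse
    best_sse[upd] <- sse[upd]; best_f[upd] <- f
    best_o[upd] <- o[upd]; best_A[upd] <- A[upd]
  }
  par <- rbind(best_o, best_A, 2 * pi * best_f)
  sse <- pmax(best_sse, 0)
  # Gauss-Newton polish, vectorized across series (each its own frequency)
  for (i in seq_len(gn_iter)) {
    S <- sin(outer(t, par[3L, ]))               # T x J
    Cs <- cos(outer(t, par[3L, ]))
    R <- sweep(S * rep(par[2L, ], each = T), 2L, par[1L, ], `+`) - Y
    J1 <- matrix(1, T, J); J2 <- S; J3 <- (t * Cs) * rep(par[2L, ], each = T)
    a11 <- rep(T, J); a12 <- colSums(J2); a13 <- colSums(J3)
    a22 <- colSums(J2^2); a23 <- colSums(J2 * J3); a33 <- colSums(J3^2) + 1e-12
    b1 <- colSums(R); b2 <- colSums(J2 * R); b3 <- colSums(J3 * R)
    # closed-form 3x3 symmetric solve per column
    d <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    d[abs(d) < 1e-300] <- 1e-300
    x1 <- (b1 * (a22 * a33 - a23^2) - a12 * (b2 * a33 - a23 * b3) +
             a13 * (b2 * a23 - a22 * b3)) / d
    x2 <- (a11 * (b2 * a33 - a23 * b3) - b1 * (a12 * a33 - a13 * a23) +
             a13 * (a12 * b3 - b2 * a13)) / d
    x3 <- (a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b2 * a13) +
             b1 * (a12 * a23 - a22 * a13)) / d
    cand <- par - rbind(x1, x2, x3)
    Sc <- sin(outer(t, cand[3L, ]))
    Rc <- sweep(Sc * rep(cand[2L, ], each = T), 2L, cand[1L, ], `+`) - Y
    sse_c <- colSums(Rc^2)
    upd <- is.finite(sse_c) & sse_c <= sse
    par[, upd] <- cand[, upd]
    sse[upd] <- sse_c[upd]
  }
  sst <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  list(sse = sse, sst = sst, par = par)
}

#' Subject-wise sinusoidal goodness of fit of a particle system
#'
#' Fits a phase-free sinusoid to every particle coordinate trajectory of
#' every subject (coordinates of one subject share observation times) and
#' summarizes the residuals: subject-wise SSE (both summed over coordinates
#' and per-coordinate mean) and the pooled coefficient of determination
#' \eqn{R^2 = 1 - \sum SS_{res} / \sum SS_{tot}} over all fits.
#'
#' @param system a `particle_system` whose subjects each have >= 4 observed
#'   time points (subjects with fewer are skipped with a warning).
#' @return list with `mean_sse`, `sd_sse` (per-subject coordinate-summed
#'   SSE), `mean_sse_per_coordinate`, `r2`, and `per_subject` data.frame.
#' @export
sine_goodness_of_fit <- function(system) {
  Z <- as_shape_matrix(system)
  cells <- attr(Z, "cells")
  subs <- unique(cells$subject_id)
  sse_subject <- numeric(0); sst_total <- 0; sse_total <- 0
  rows <- list()
  for (s in subs) {
    rk <- which(cells$subject_id == s)
    tv <- cells$time_value[rk]
    if (length(unique(tv)) < 4L) {
      warning(sprintf("subject %s has fewer than 4 observed time points; skipped", s))
      next
    }
    Y <- t(Z[rk, , drop = FALSE])             # dM x T_obs -> series in columns
    fit <- sine_fit_batch(t(Y), tv)
    sse_subject <- c(sse_subject, sum(fit$sse))
    sse_total <- sse_total + sum(fit$sse)
    sst_total <- sst_total + sum(fit$sst)
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = s, n_times = length(rk),
                 sse = sum(fit$sse), sse_per_coordinate = mean(fit$sse))
  }
  if (!length(rows)) stop("no subject had enough time points")
  list(mean_sse = mean(sse_subject), sd_sse = stats::sd(sse_subject),
       mean_sse_per_coordinate = mean(vapply(rows, `[[`, numeric(1),
                                             "sse_per_coordinate")),
       r2 = 1 - sse_total / sst_total,
       per_subject = do.call(rbind, rows))
}

#' Repeated-measures time-dependency test
#'
#' Tests the null hypothesis that mean particle positions do not differ
#' across time points, using an ANOVA-type statistic on a fixed random
#' subset of particle coordinates with time and coordinate index as
#' within-subject factors.  The hypothesis projector is
#' \eqn{M = (I_T - J_T/T) \otimes I_C} (no time effect within any
#' coordinate); the statistic \eqn{F = N \bar y^\top M \bar y /
#' \mathrm{tr}(M \hat\Sigma)} is referred to an F distribution with
#' Box/Satterthwaite degrees of freedom
#' \eqn{f_1 = \mathrm{tr}^2(M\hat\Sigma) / \mathrm{tr}((M\hat\Sigma)^2)}
#' and \eqn{f_0 = (N-1) f_1} (exact F(r, r(N-1)) under sphericity).
#'
#' @param system a `particle_system`; subjects with complete observation
#'   grids are used (>= 3 required).
#' @param n_coords number of particle coordinates sampled (default 100,
#'   capped at dM).
#' @param rng_seed seed for the coordinate subset.
#' @return list with `statistic`, `p_value`, `df1`, `df2`, `n_subjects`,
#'   `coords` (the sampled coordinate indices).
#' @export
time_dependency_test <- function(system, n_coords = 100L, rng_seed = 1L) {
  Z <- as_shape_matrix(system)
  cells <- attr(Z, "cells")
  T <- length(unique(cells$t))
  complete <- names(which(table(cells$subject_id) == T))
  keep <- cells$subject_id %in% complete
  cells <- cells[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]
  N <- length(complete)
  if (N < 3L) stop("insufficient-data: need >= 3 subjects with complete sequences")
  dM <- ncol(Z)
  n_coords <- min(as.integer(n_coords), dM)
  coords <- with_seed(rng_seed, sort(sample.int(dM, n_coords)))
  # N x (T*C) matrix: per subject, time-major blocks of the C coordinates
  D <- matrix(0, N, T * n_coords)
  for (i in seq_along(complete)) {
    rk <- which(cells$subject_id == complete[i])
    rk <- rk[order(cells$t[rk])]
    D[i, ] <- as.vector(t(Z[rk, coords, drop = FALSE]))
  }
  mu <- colMeans(D)
  Yc <- sweep(D, 2L, mu)
  # M = (I_T - J/T) (x) I_C applied implicitly: center over time blocks
  Mv <- function(v) {
    V <- matrix(v, nrow = n_coords)          # C x T (time in columns)
    as.vector(V - rowMeans(V))
  }
  Mmu <- Mv(mu)
  YM <- t(apply(Yc, 1L, Mv))                 # rows = M (Y_n - Ybar)
  A <- tcrossprod(YM)                        # = YM YM' ; M idempotent
  trMS <- sum(diag(A)) / (N - 1)
  trMSMS <- sum(A^2) / (N - 1)^2
  stat <- N * sum(mu * Mmu) / trMS
  # Box/Satterthwaite df with the standard bias corrections for estimated
  # traces (plug-in tr^2/tr(.^2) is biased low, making the test
  # over-conservative at small N)
  n <- N - 1
  t2 <- max((n^2 / ((n + 2) * (n - 1))) * (trMSMS - trMS^2 / n), 1e-300)
  t1sq <- max(trMS^2 - 2 * t2 / n, t2)
  f1 <- t1sq / t2
  f0 <- n * f1
  p <- stats::pf(stat, f1, f0, lower.tail = FALSE)
  list(statistic = stat, p_value = p, df1 = f1, df2 = f0,
       n_subjects = N, coords = coords)
}

#' Shuffle time indices within each subject (time-dependency control)
#'
#' Destroys the temporal structure of a particle system while preserving
#' each subject's set of shapes; used as the negative control for
#' [time_dependency_test()].
#'
#' @param system a `particle_system`.
#' @param rng_seed seed for the per-subject permutations.
#' @return a `particle_system` with permuted time slots.
#' @export
shuffle_times <- function(system, rng_seed = 1L) {
  N <- dim(system$particles)[1L]; T <- dim(system$particles)[2L]
  arr <- system$particles
  with_seed(rng_seed, {
    for (n in seq_len(N)) {
      obs <- which(system$observed[n, ])
      perm <- sample(obs)
      arr[n, obs, , ] <- system$particles[n, perm, , , drop = FALSE]
    }
  })
  out <- system
  out$particles <- arr
  out
}

#' Signed volume of a closed triangle mesh
#'
#' Sum of signed tetrahedra against the origin; positive for outward
#' orientation.  An open mesh (any edge not shared by exactly two faces)
#' triggers a warning and the absolute value is returned.
#'
#' @param mesh a `mesh_surface`.
#' @return scalar volume.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "mesh_surface"))
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1L], , drop = FALSE]
  b <- V[F[, 2L], , drop = FALSE]
  c <- V[F[, 3L], , drop = FALSE]
  vol <- sum(rowSums(cross3(a, b) * c)) / 6   # sum of det(a,b,c)/6
  if (!mesh_is_closed(mesh)) {
    warning("mesh is not closed; returning absolute volume")
    return(abs(vol))
  }
  vol
}

mesh_is_closed <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Total surface area of a triangle mesh
#' @param mesh a `mesh_surface`.
#' @return scalar area.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "mesh_surface"))
  sum(mesh$face_areas)
}

#' Sphericity of a closed mesh
#'
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}: 1 for a perfect sphere, smaller for less
#' round shapes.
#'
#' @param mesh a `mesh_surface` with positive area.
#' @return scalar in (0, 1] (up to discretization error).
#' @export
sphericity <- function(mesh) {
  A <- mesh_area(mesh)
  if (A <= 0) stop("invalid-input: mesh has zero surface area")
  V <- abs(mesh_volume(mesh))
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}
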