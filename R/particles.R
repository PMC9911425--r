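#' Particle systems
#'
#' A particle system holds, for every observed (subject, time) cell of a
#' cohort, M corresponding particles constrained to that cell's surface.
#' Vectorization to shape space concatenates particle coordinates in
#' particle-major order: x1 y1 z1 x2 y2 z2 ...
#'
#' @param particles N x T x M x 3 array (NA in unobserved cells).
#' @param cohort the `shape_cohort` the particles live on.
#' @return an object of class `particle_system`.
#' @export
particle_system <- function(particles, cohort) {
  stopifnot(inherits(cohort, "shape_cohort"))
  d <- dim(particles)
  stopifnot(length(d) == 4L, d[4L] == 3L,
            d[1L] == n_subjects(cohort), d[2L] == n_timepoints(cohort))
  structure(list(particles = particles,
                 subject_ids = cohort$subject_ids,
                 time_values = cohort$time_values,
                 observed = cohort$observed,
                 cohort = cohort),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d x %d shapes, M = %d particles\n",
              dim(x$particles)[1L], dim(x$particles)[2L], n_particles(x)))
  invisible(x)
}

#' Number of particles per shape
#' @param system a `particle_system`.
#' @export
n_particles <- function(system) dim(system$particles)[3L]

get_particles <- function(system, n, t) {
  matrix(system$particles[n, t, , ], ncol = 3L)
}

set_particles <- function(system, n, t, P) {
  system$particles[n, t, , ] <- P
  system
}

#' Vectorize a particle system to the shape-space sample matrix
#'
#' @param system a `particle_system`.
#' @return K x dM matrix whose rows are the observed shapes in the canonical
#'   order of [observed_cells()], columns in particle-major order.
#' @export
as_shape_matrix <- function(system) {
  cells <- observed_cells(system$cohort)
  M <- n_particles(system)
  Z <- matrix(0, nrow(cells), 3L * M)
  for (k in seq_len(nrow(cells))) {
    Z[k, ] <- as.vector(t(get_particles(system, cells$n[k], cells$t[k])))
  }
  attr(Z, "cells") <- cells
  Z
}

# inverse of as_shape_matrix: write rows of Z back into the system
set_shape_matrix <- function(system, Z) {
  cells <- observed_cells(system$cohort)
  for (k in seq_len(nrow(cells))) {
    system$particles[cells$n[k], cells$t[k], , ] <-
      matrix(Z[k, ], ncol = 3L, byrow = TRUE)
  }
  system
}

#' Initialize one particle per shape
#'
#' The seed particle is the projection of a deterministic off-surface point
#' (centroid + bounding diagonal along (1,1,1)/sqrt(3)), which is
#' correspondence-consistent for pre-aligned cohorts.
#'
#' @param cohort a `shape_cohort`.
#' @return a `particle_system` with M = 1.
#' @export
init_particles <- function(cohort) {
  N <- n_subjects(cohort); T <- n_timepoints(cohort)
  arr <- array(NA_real_, c(N, T, 1L, 3L))
  dir <- c(1, 1, 1) / sqrt(3)
  for (n in seq_len(N)) for (t in seq_len(T)) {
    if (!cohort$observed[n, t]) next
    s <- cohort$surfaces[[n, t]]
    seed <- surface_centroid(s) + surface_diagonal(s) * dir
    arr[n, t, 1L, ] <- project_to_surface(seed, s)
  }
  particle_system(arr, cohort)
}

#' Split every particle into two (coarse-to-fine refinement)
#'
#' Each particle spawns a child at `offset` along a random tangent
#' direction; the same random direction is used for the m-th particle on
#' every shape so correspondence is preserved through the split, and the
#' child is re-projected onto its surface.
#'
#' @param system a `particle_system`.
#' @param offset positive split distance (small relative to surface extent).
#' @param rng_seed integer seed for the shared random directions.
#' @return a `particle_system` with 2M particles.
#' @export
split_particles <- function(system, offset, rng_seed) {
  stopifnot(offset > 0)
  M <- n_particles(system)
  dirs <- with_seed(rng_seed, {
    d <- matrix(stats::rnorm(3L * M), M, 3L)
    d / sqrt(rowSums(d^2))
  })
  N <- dim(system$particles)[1L]; T <- dim(system$particles)[2L]
  arr <- array(NA_real_, c(N, T, 2L * M, 3L))
  for (n in seq_len(N)) for (t in seq_len(T)) {
    if (!system$observed[n, t]) next
    s <- system$cohort$surfaces[[n, t]]
    P <- get_particles(system, n, t)
    nor <- surface_normal(P, s, tol = Inf)
    if (is.null(dim(nor))) nor <- matrix(nor, 1L, 3L)
    tang <- dirs - rowSums(dirs * nor) * nor
    nn <- sqrt(rowSums(tang^2))
    deg <- nn < 1e-8
    if (any(deg)) {  # direction parallel to normal: fall back to any tangent
      alt <- cbind(-nor[deg, 2L], nor[deg, 1L], 0)
      alt_n <- sqrt(rowSums(alt^2))
      alt[alt_n < 1e-8, ] <- matrix(c(0, 0, 1), sum(alt_n < 1e-8), 3L, byrow = TRUE)
      tang[deg, ] <- alt
      nn <- sqrt(rowSums(tang^2))
    }
    tang <- tang / nn
    child <- project_to_surface(P + offset * tang, s)
    if (is.null(dim(child))) child <- matrix(child, 1L, 3L)
    arr[n, t, seq_len(M), ] <- P
    arr[n, t, M + seq_len(M), ] <- child
  }
  particle_system(arr, system$cohort)
}

# evaluate expr with a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-particle nearest-neighbor distances on one shape
nearest_neighbor_dists <- function(P) {
  M <- nrow(P)
  if (M < 2L) return(rep(1, M))
  D2 <- pairwise_sq_dists(P)
  diag(D2) <- Inf
  sqrt(D2[cbind(seq_len(M), max.col(-D2, ties.method = "first"))])
}

#' Maximum implicit/surface residual of the particles
#'
#' @param system a `particle_system`.
#' @return largest absolute implicit value (ellipsoids) or surface distance
#'   (meshes) over all observed particles.
#' @export
max_surface_residual <- function(system) {
  cells <- observed_cells(system$cohort)
  res <- 0
  for (k in seq_len(nrow(cells))) {
    s <- system$cohort$surfaces[[cells$n[k], cells$t[k]]]
    v <- implicit_value(s, get_particles(system, cells$n[k], cells$t[k]))
    res <- max(res, max(abs(v)))
  }
  res
}
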