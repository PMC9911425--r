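#' Synthetic dynamic-ellipsoid cohort specification
#'
#' The benchmark cohort is a grid of axis-aligned ellipsoids: the x-diameter
#' is a subject-dependent Gaussian draw (constant over time), the y-diameter
#' follows a shared sinusoid over the cycle, and the z-diameter is fixed, so
#' every shape fits in the unit cube and two generative factors (one
#' inter-subject, one temporal) exist by construction.
#'
#' @param n_subjects number of subjects (default 30).
#' @param n_timepoints time points per subject (default 8; also the sinusoid
#'   period).
#' @param x_mean,x_std mean and sd of the subject x-diameter distribution
#'   (defaults 0.6 and 0.4/3, so 99.7% of draws fall in (0.2, 1)).
#' @param y_offset,y_amplitude parameters of the temporal sinusoid
#'   y(t) = y_offset + y_amplitude * sin(2*pi*t/T) (defaults 0.6, 0.4:
#'   y varies cyclically between 0.2 and 1).
#' @param z_diameter fixed z-diameter (default 1).
#' @param missing_fraction fraction of (subject, time) cells marked
#'   unobserved uniformly at random (never an entire subject sequence).
#' @param rng_seed integer seed.
#' @param mesh_subdivisions if non-NULL, surfaces are triangle meshes
#'   (icospheres at this subdivision level scaled anisotropically) instead
#'   of implicit ellipsoids.
#' @return an object of class `ellipsoid_cohort_spec`.
#' @export
ellipsoid_cohort_spec <- function(n_subjects = 30L, n_timepoints = 8L,
                                  x_mean = 0.6, x_std = 0.4 / 3,
                                  y_offset = 0.6, y_amplitude = 0.4,
                                  z_diameter = 1.0,
                                  missing_fraction = 0,
                                  rng_seed = 1L,
                                  mesh_subdivisions = NULL) {
  stopifnot(n_subjects >= 1L, n_timepoints >= 2L, x_std > 0, z_diameter > 0,
            missing_fraction >= 0, missing_fraction < 1)
  if (y_offset - abs(y_amplitude) <= 0)
    stop("invalid-parameter: y-diameter would be non-positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 x_mean = x_mean, x_std = x_std,
                 y_offset = y_offset, y_amplitude = y_amplitude,
                 z_diameter = z_diameter,
                 missing_fraction = missing_fraction,
                 rng_seed = as.integer(rng_seed),
                 mesh_subdivisions = mesh_subdivisions),
            class = "ellipsoid_cohort_spec")
}

#' Sample subject x-diameters
#'
#' Seeded draws from Normal(x_mean, x_std); draws outside (0, 1.2] are
#' rejected and resampled to guarantee strictly positive physical diameters.
#'
#' @param spec an [ellipsoid_cohort_spec()].
#' @return numeric vector of length `n_subjects`.
#' @export
sample_x_diameters <- function(spec) {
  with_seed(spec$rng_seed, {
    x <- stats::rnorm(spec$n_subjects, spec$x_mean, spec$x_std)
    bad <- which(x <= 0 | x > 1.2)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), spec$x_mean, spec$x_std)
      bad <- bad[x[bad] <= 0 | x[bad] > 1.2]
    }
    x
  })
}

#' Time-dependent y-diameter
#'
#' \eqn{y(t) = 0.6 + 0.4 \sin(2\pi t / T)} with the default offset and
#' amplitude; identical for every subject.
#'
#' @param t time index (or vector of indices) in [1, T].
#' @param T number of time points (= sinusoid period).
#' @param y_offset,y_amplitude sinusoid parameters.
#' @return numeric vector.
#' @export
y_diameter <- function(t, T, y_offset = 0.6, y_amplitude = 0.4) {
  stopifnot(T >= 2)
  y_offset + y_amplitude * sin(2 * pi * t / T)
}

#' Generate the synthetic dynamic-ellipsoid cohort
#'
#' @param spec an [ellipsoid_cohort_spec()].
#' @return a `shape_cohort` with ground-truth diameters attached
#'   (`$diameters`, an N x T x 3 array) for downstream evaluation.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ellipsoid_cohort_spec"))
  N <- spec$n_subjects; T <- spec$n_timepoints
  x <- sample_x_diameters(spec)
  y <- y_diameter(seq_len(T), T, spec$y_offset, spec$y_amplitude)
  observed <- matrix(TRUE, N, T)
  if (spec$missing_fraction > 0) {
    observed <- with_seed(spec$rng_seed + 1L, {
      n_mask <- round(spec$missing_fraction * N * T)
      obs <- matrix(TRUE, N, T)
      cand <- sample(N * T)
      masked <- 0L
      for (i in cand) {
        if (masked >= n_mask) break
        nn <- (i - 1L) %% N + 1L; tt <- (i - 1L) %/% N + 1L
        if (sum(obs[nn, ]) > 1L) {  # never remove an entire sequence
          obs[nn, tt] <- FALSE
          masked <- masked + 1L
        }
      }
      obs
    })
  }
  surfaces <- matrix(vector("list", N * T), N, T)
  diameters <- array(NA_real_, c(N, T, 3L))
  for (n in seq_len(N)) for (t in seq_len(T)) {
    diameters[n, t, ] <- c(x[n], y[t], spec$z_diameter)
    if (!observed[n, t]) next
    surfaces[[n, t]] <-
      if (is.null(spec$mesh_subdivisions))
        make_ellipsoid(x[n], y[t], spec$z_diameter)
      else
        ellipsoid_mesh(x[n], y[t], spec$z_diameter,
                       subdivisions = spec$mesh_subdivisions)
  }
  shape_cohort(surfaces,
               subject_ids = sprintf("s%02d", seq_len(N)),
               time_values = seq_len(T),
               observed = observed,
               diameters = diameters)
}
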