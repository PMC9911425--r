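#' Shape cohorts
#'
#' A shape cohort is an N-subject x T-time-point grid of surfaces with an
#' observed/missing mask.  Regression-based optimization methods tolerate
#' missing cells; the disentangled baseline requires a complete grid.
#'
#' @param surfaces N x T list-matrix of `surface` objects (may hold NULL in
#'   unobserved cells).
#' @param subject_ids character vector of length N.
#' @param time_values numeric vector of length T (defaults to 1..T).
#' @param observed N x T logical matrix; defaults to non-NULL cells.
#' @param diameters optional N x T x 3 array of ground-truth ellipsoid
#'   diameters (synthetic cohorts).
#' @return an object of class `shape_cohort`.
#' @export
shape_cohort <- function(surfaces, subject_ids, time_values = NULL,
                         observed = NULL, diameters = NULL) {
  stopifnot(is.matrix(surfaces) || is.list(surfaces))
  if (!is.matrix(surfaces)) stop("surfaces must be an N x T list-matrix")
  N <- nrow(surfaces); T <- ncol(surfaces)
  if (length(subject_ids) != N) stop("subject_ids length must match nrow(surfaces)")
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (is.null(time_values)) time_values <- seq_len(T)
  if (length(time_values) != T) stop("time_values length must match ncol(surfaces)")
  if (is.null(observed))
    observed <- matrix(vapply(surfaces, Negate(is.null), logical(1)), N, T)
  stopifnot(is.logical(observed), all(dim(observed) == c(N, T)))
  if (any(observed & vapply(surfaces, is.null, logical(1))))
    stop("observed cells must have surfaces")
  if (any(rowSums(observed) == 0)) stop("every subject needs >= 1 observed shape")
  structure(list(surfaces = surfaces,
                 subject_ids = as.character(subject_ids),
                 time_values = as.numeric(time_values),
                 observed = observed,
                 diameters = diameters),
            class = "shape_cohort")
}

#' @export
print.shape_cohort <- function(x, ...) {
  cat(sprintf("<shape_cohort> %d subjects x %d time points, %d/%d observed\n",
              nrow(x$observed), ncol(x$observed), sum(x$observed),
              length(x$observed)))
  invisible(x)
}

n_subjects <- function(cohort) nrow(cohort$observed)
n_timepoints <- function(cohort) ncol(cohort$observed)

#' Indices of observed cells, in canonical row order
#'
#' The canonical ordering of shape-space samples is subject-major: all
#' observed time points of subject 1, then subject 2, ...
#' @param cohort a `shape_cohort`.
#' @return data.frame with columns n, t, subject_id, time_value.
#' @export
observed_cells <- function(cohort) {
  idx <- which(t(cohort$observed))  # t() so time runs fastest within subject
  T <- n_timepoints(cohort)
  tt <- (idx - 1L) %% T + 1L
  nn <- (idx - 1L) %/% T + 1L
  data.frame(n = nn, t = tt,
             subject_id = cohort$subject_ids[nn],
             time_value = cohort$time_values[tt],
             stringsAsFactors = FALSE)
}
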