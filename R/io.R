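# On-disk formats: cohort manifest CSV, ShapeWorks-style ".particles" text
# files with an index CSV, and JSON model/config serialization.  All
# artifacts are human-readable text.

#' Write a cohort manifest CSV
#'
#' Columns: subject_id, time_index, time_value, x_diameter, y_diameter,
#' z_diameter, observed, mesh_path.  Ellipsoid cohorts store their
#' ground-truth diameters; mesh cohorts store mesh paths (written alongside
#' when `mesh_dir` is given).
#'
#' @param cohort a `shape_cohort`.
#' @param path output CSV path.
#' @param mesh_dir if non-NULL, mesh surfaces are written there as PLY and
#'   referenced from the manifest.
#' @return the manifest path, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path, mesh_dir = NULL) {
  N <- n_subjects(cohort); T <- n_timepoints(cohort)
  rows <- list()
  for (n in seq_len(N)) for (t in seq_len(T)) {
    s <- cohort$surfaces[[n, t]]
    di <- if (!is.null(cohort$diameters)) cohort$diameters[n, t, ]
          else if (!is.null(s) && inherits(s, "ellipsoid_surface")) s$diameters
          else c(NA_real_, NA_real_, NA_real_)
    mp <- ""
    if (!is.null(s) && inherits(s, "mesh_surface")) {
      if (is.null(mesh_dir))
        stop("mesh-backed cohort needs mesh_dir to write surfaces")
      dir.create(mesh_dir, recursive = TRUE, showWarnings = FALSE)
      mp <- file.path(mesh_dir,
                      sprintf("%s_t%02d.ply", cohort$subject_ids[n], t))
      write_mesh(s, mp)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = cohort$subject_ids[n], time_index = t,
      time_value = cohort$time_values[t],
      x_diameter = di[1L], y_diameter = di[2L], z_diameter = di[3L],
      observed = cohort$observed[n, t], mesh_path = mp,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' Required columns: subject_id, time_value, observed, and either a usable
#' mesh_path or ellipsoid diameters per observed row.  Mesh paths are
#' resolved relative to the manifest's directory when not absolute.
#'
#' @param path manifest CSV path.
#' @return a `shape_cohort`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "time_value", "observed")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("manifest %s is missing required columns: %s", path,
                 paste(miss, collapse = ", ")))
  has_mesh <- "mesh_path" %in% names(df)
  has_diam <- all(c("x_diameter", "y_diameter", "z_diameter") %in% names(df))
  if (!has_mesh && !has_diam)
    stop(sprintf("manifest %s needs mesh_path or ellipsoid diameter columns", path))
  key <- paste(df$subject_id, df$time_value)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("manifest %s: duplicate (subject, time) at row %d (%s)",
                 path, dup[1L] + 1L, key[dup[1L]]))
  subs <- unique(df$subject_id)
  tvs <- sort(unique(df$time_value))
  N <- length(subs); T <- length(tvs)
  surfaces <- matrix(vector("list", N * T), N, T)
  observed <- matrix(FALSE, N, T)
  diameters <- if (has_diam) array(NA_real_, c(N, T, 3L)) else NULL
  base <- dirname(normalizePath(path))
  for (i in seq_len(nrow(df))) {
    n <- match(df$subject_id[i], subs)
    t <- match(df$time_value[i], tvs)
    obs <- isTRUE(as.logical(df$observed[i]))
    observed[n, t] <- obs
    if (has_diam && is.finite(df$x_diameter[i]))
      diameters[n, t, ] <- c(df$x_diameter[i], df$y_diameter[i], df$z_diameter[i])
    if (!obs) next
    mp <- if (has_mesh) df$mesh_path[i] else ""
    if (!is.na(mp) && nzchar(mp)) {
      if (!file.exists(mp)) mp <- file.path(base, df$mesh_path[i])
      if (!file.exists(mp))
        stop(sprintf("manifest %s row %d: mesh file not found: %s",
                     path, i + 1L, df$mesh_path[i]))
      surfaces[[n, t]] <- read_mesh(mp)
    } else if (has_diam && is.finite(df$x_diameter[i])) {
      surfaces[[n, t]] <- make_ellipsoid(df$x_diameter[i], df$y_diameter[i],
                                         df$z_diameter[i])
    } else {
      stop(sprintf("manifest %s row %d: observed shape has neither mesh nor diameters",
                   path, i + 1L))
    }
  }
  shape_cohort(surfaces, subject_ids = subs, time_values = tvs,
               observed = observed, diameters = diameters)
}

#' Write a particle system to text files
#'
#' One whitespace-separated text file per observed (subject, time) cell
#' named `{subject}_{timeindex}.particles` (M rows x 3 columns, 17
#' significant digits), plus an `index.csv` with per-file metadata.
#'
#' @param system a `particle_system`.
#' @param directory output directory (created if needed).
#' @return the index CSV path, invisibly.
#' @export
write_particles <- function(system, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (file.access(directory, 2L) != 0L)
    stop(sprintf("directory not writable: %s", directory))
  cells <- observed_cells(system$cohort)
  rows <- list()
  for (k in seq_len(nrow(cells))) {
    fn <- sprintf("%s_%02d.particles", cells$subject_id[k], cells$t[k])
    P <- get_particles(system, cells$n[k], cells$t[k])
    writeLines(apply(P, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")),
      file.path(directory, fn))
    rows[[k]] <- data.frame(subject_id = cells$subject_id[k],
                            time_index = cells$t[k],
                            time_value = cells$time_value[k],
                            file = fn, n_particles = nrow(P),
                            stringsAsFactors = FALSE)
  }
  idx <- file.path(directory, "index.csv")
  utils::write.csv(do.call(rbind, rows), idx, row.names = FALSE)
  invisible(idx)
}

#' Read particle files written by [write_particles()]
#'
#' @param directory directory containing `index.csv` and particle files.
#' @return list with `index` (data.frame) and `particles` (named list of
#'   M x 3 matrices keyed `{subject}_{timeindex}`).
#' @export
read_particles <- function(directory) {
  idx_path <- file.path(directory, "index.csv")
  if (!file.exists(idx_path)) stop(sprintf("no index.csv in %s", directory))
  idx <- utils::read.csv(idx_path, stringsAsFactors = FALSE)
  particles <- lapply(seq_len(nrow(idx)), function(k) {
    lines <- readLines(file.path(directory, idx$file[k]), warn = FALSE)
    do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  })
  names(particles) <- sub("\\.particles$", "", idx$file)
  list(index = idx, particles = particles)
}

# rebuild a particle_system from files + the cohort they were fit on
read_particle_system <- function(directory, cohort) {
  pr <- read_particles(directory)
  M <- pr$index$n_particles[1L]
  N <- n_subjects(cohort); T <- n_timepoints(cohort)
  arr <- array(NA_real_, c(N, T, M, 3L))
  for (k in seq_len(nrow(pr$index))) {
    n <- match(pr$index$subject_id[k], cohort$subject_ids)
    t <- pr$index$time_index[k]
    arr[n, t, , ] <- pr$particles[[k]]
  }
  particle_system(arr, cohort)
}

#' Serialize a fitted temporal model to JSON
#'
#' Stores the model class and, for principal-component polynomial models,
#' the subspace mean, eigenvectors (row-major), eigenvalues, coefficient
#' matrix, elastic-net weights and time transform.
#'
#' @param model a fitted temporal model.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "st_polynomial_model")) {
    list(type = "pc_polynomial", degree = model$degree,
         coefficients = unclass(model$coefficients),
         r1 = model$r1, r2 = model$r2,
         basis_alpha = model$basis$alpha, basis_norm2 = model$basis$norm2,
         time_center = model$time_transform$center,
         time_scale = model$time_transform$scale,
         subspace = if (!is.null(model$subspace))
           list(mean = model$subspace$mean,
                eigenvalues = model$subspace$eigenvalues,
                eigenvectors = unclass(model$subspace$eigenvectors)))
  } else if (inherits(model, "st_linear_model")) {
    list(type = "linear", intercept = model$intercept, slope = model$slope)
  } else if (inherits(model, "st_constant_model")) {
    list(type = "constant", mean = model$mean)
  } else if (inherits(model, "st_disentangled_means")) {
    list(type = "disentangled", mu_t = model$mu_t, mu_n = model$mu_n)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a temporal model written by [write_model()]
#' @param path JSON path.
#' @return the model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    pc_polynomial = {
      sub <- if (!is.null(obj$subspace))
        structure(list(mean = obj$subspace$mean,
                       eigenvalues = obj$subspace$eigenvalues,
                       eigenvectors = as.matrix(obj$subspace$eigenvectors)),
                  class = "principal_subspace")
      structure(list(degree = obj$degree,
                     coefficients = as.matrix(obj$coefficients),
                     r1 = obj$r1, r2 = obj$r2,
                     time_transform = list(center = obj$time_center,
                                           scale = obj$time_scale),
                     basis = list(alpha = obj$basis_alpha,
                                  norm2 = obj$basis_norm2),
                     subspace = sub),
                class = "st_polynomial_model")
    },
    linear = structure(list(intercept = obj$intercept, slope = obj$slope),
                       class = "st_linear_model"),
    constant = structure(list(mean = obj$mean), class = "st_constant_model"),
    disentangled = structure(list(mu_t = obj$mu_t, mu_n = obj$mu_n),
                             class = "st_disentangled_means"),
    stop(sprintf("unknown model type in %s", path)))
}
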