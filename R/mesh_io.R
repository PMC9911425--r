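# Minimal ASCII mesh readers/writers (PLY and legacy-VTK polydata).
# Vertices are float64 triples, faces triangles.

#' Read a triangle mesh from PLY (ASCII) or legacy VTK polydata
#'
#' Format is chosen by file extension (`.ply` / `.vtk`).
#' @param path file path.
#' @return a `mesh_surface`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("unreadable mesh file: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         vtk = read_vtk_polydata(path),
         stop(sprintf("unsupported mesh format '.%s' (use .ply or .vtk)", ext)))
}

#' Write a triangle mesh to PLY (ASCII) or legacy VTK polydata
#'
#' @param mesh a `mesh_surface`.
#' @param path output path; extension selects the format.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh_surface"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         vtk = write_vtk_polydata(mesh, path),
         stop(sprintf("unsupported mesh format '.%s' (use .ply or .vtk)", ext)))
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    stop(sprintf("%s: not a PLY file", path))
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop(sprintf("%s: PLY header not terminated", path))
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop(sprintf("%s: only ASCII PLY is supported", path))
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element\\s+face", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stop(sprintf("%s: missing vertex/face elements", path))
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- do.call(rbind, lapply(frows, function(x) {
    cnt <- as.integer(x[1L])
    if (cnt != 3L) stop(sprintf("%s: non-triangular face", path))
    as.integer(x[2:4]) + 1L
  }))
  make_mesh_surface(V, F)
}

write_ply <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(V, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(apply(F - 1L, 1L, function(r) paste(c(3L, r), collapse = " ")), con)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || !grepl("^# vtk DataFile", lines[1L]))
    stop(sprintf("%s: not a legacy VTK file", path))
  if (!grepl("ASCII", toupper(lines[3L])))
    stop(sprintf("%s: only ASCII VTK is supported", path))
  pl <- grep("^POINTS", lines)
  if (!length(pl)) stop(sprintf("%s: no POINTS section", path))
  np <- as.integer(strsplit(trimws(lines[pl[1L]]), "\\s+")[[1L]][2L])
  toks <- function(from, n_values) {
    vals <- numeric(0)
    i <- from
    while (length(vals) < n_values && i <= length(lines)) {
      vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      i <- i + 1L
    }
    vals[seq_len(n_values)]
  }
  V <- matrix(toks(pl[1L] + 1L, np * 3L), ncol = 3L, byrow = TRUE)
  gl <- grep("^POLYGONS", lines)
  if (!length(gl)) stop(sprintf("%s: no POLYGONS section", path))
  hd <- as.integer(strsplit(trimws(lines[gl[1L]]), "\\s+")[[1L]][2:3])
  conn <- as.integer(toks(gl[1L] + 1L, hd[2L]))
  F <- matrix(0L, hd[1L], 3L)
  k <- 1L
  for (i in seq_len(hd[1L])) {
    cnt <- conn[k]
    if (cnt != 3L) stop(sprintf("%s: non-triangular polygon", path))
    F[i, ] <- conn[(k + 1L):(k + 3L)] + 1L
    k <- k + cnt + 1L
  }
  make_mesh_surface(V, F)
}

write_vtk_polydata <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "dynshape mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(V))), con)
  writeLines(apply(V, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(F), 4L * nrow(F)), con)
  writeLines(apply(F - 1L, 1L, function(r) paste(c(3L, r), collapse = " ")), con)
}
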