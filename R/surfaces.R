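#' @title Shape surfaces
#' @description Surfaces are the domains particles are constrained to during
#'   optimization.  Two kinds are supported: axis-aligned implicit ellipsoids
#'   (used by the synthetic cohort generator) and triangle meshes.
#' @name surfaces
NULL

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be 3-dimensional")
  storage.mode(points) <- "double"
  points
}

#' Create an axis-aligned implicit ellipsoid surface
#'
#' The surface is origin-centered with implicit function
#' \eqn{F(p) = (2 p_x / d_x)^2 + (2 p_y / d_y)^2 + (2 p_z / d_z)^2 - 1},
#' zero on the surface, negative inside.
#'
#' @param x_diameter,y_diameter,z_diameter strictly positive diameters.
#' @return an object of class `c("ellipsoid_surface", "surface")`.
#' @export
make_ellipsoid <- function(x_diameter, y_diameter, z_diameter) {
  d <- c(x_diameter, y_diameter, z_diameter)
  if (length(d) != 3L || !all(is.finite(d)) || any(d <= 0))
    stop("invalid-parameter: ellipsoid diameters must be finite and strictly positive")
  structure(list(kind = "implicit-ellipsoid",
                 diameters = as.numeric(d),
                 semiaxes = as.numeric(d) / 2),
            class = c("ellipsoid_surface", "surface"))
}

#' Create a triangle-mesh surface
#'
#' @param vertices V x 3 numeric matrix of vertex coordinates.
#' @param faces F x 3 integer matrix of 1-based vertex indices per triangle.
#' @return an object of class `c("mesh_surface", "surface")`.
#' @export
make_mesh_surface <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  dimnames(faces) <- NULL
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be triangles (3 columns)")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  v0 <- vertices[faces[, 1L], , drop = FALSE]
  v1 <- vertices[faces[, 2L], , drop = FALSE]
  v2 <- vertices[faces[, 3L], , drop = FALSE]
  fn <- cross3(v1 - v0, v2 - v0)          # un-normalized face normals
  areas <- 0.5 * sqrt(rowSums(fn^2))
  bb_lo <- pmin(v0, pmin(v1, v2))
  bb_hi <- pmax(v0, pmax(v1, v2))
  structure(list(kind = "triangle-mesh",
                 vertices = vertices, faces = faces,
                 face_normals = fn, face_areas = areas,
                 bb_lo = bb_lo, bb_hi = bb_hi),
            class = c("mesh_surface", "surface"))
}

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Implicit function value of a surface at points
#'
#' For ellipsoids this is the quadric \eqn{F(p)}; for meshes the (unsigned)
#' distance to the closest triangle is returned instead.
#' @param surface a surface object.
#' @param points 3-vector or n x 3 matrix.
#' @return numeric vector of length n.
#' @export
implicit_value <- function(surface, points) UseMethod("implicit_value")

#' @export
implicit_value.ellipsoid_surface <- function(surface, points) {
  p <- as_point_matrix(points)
  a <- surface$semiaxes
  (p[, 1L] / a[1L])^2 + (p[, 2L] / a[2L])^2 + (p[, 3L] / a[3L])^2 - 1
}

#' @export
implicit_value.mesh_surface <- function(surface, points) {
  p <- as_point_matrix(points)
  q <- project_to_surface(p, surface)
  sqrt(rowSums((p - q)^2))
}

surface_centroid <- function(surface) {
  if (inherits(surface, "ellipsoid_surface")) c(0, 0, 0)
  else colMeans(surface$vertices)
}

surface_diagonal <- function(surface) {
  if (inherits(surface, "ellipsoid_surface")) sqrt(sum(surface$diameters^2))
  else {
    r <- apply(surface$vertices, 2L, range)
    sqrt(sum((r[2L, ] - r[1L, ])^2))
  }
}

#' Project points onto a surface
#'
#' Returns, for each row of `points`, the nearest point on the surface.
#' Ellipsoid projection solves the Lagrangian closest-point condition
#' \eqn{q_i = a_i^2 p_i / (a_i^2 + t)} by a safeguarded (bracketed) Newton /
#' bisection iteration on the scalar multiplier t, vectorized over points.
#' Mesh projection computes exact point-triangle distances, pruning faces
#' with a nearest-vertex bound on their bounding boxes.
#'
#' @param points 3-vector or n x 3 matrix of finite coordinates.
#' @param surface a surface object.
#' @param tol convergence tolerance on the implicit residual.
#' @param max_iter maximum iterations for the ellipsoid root find.
#' @return n x 3 matrix (or 3-vector if a single point was given).
#' @export
project_to_surface <- function(points, surface, tol = 1e-10, max_iter = 100L)
  UseMethod("project_to_surface", surface)

#' @export
project_to_surface.ellipsoid_surface <- function(points, surface, tol = 1e-10,
                                                 max_iter = 100L) {
  single <- is.null(dim(points))
  p <- as_point_matrix(points)
  if (!all(is.finite(p))) stop("points must be finite")
  a <- surface$semiaxes
  a2 <- a^2
  n <- nrow(p)
  # degenerate: points at (or numerically at) the center project to the
  # nearest pole (shortest axis)
  ctr <- rowSums(p^2) < (1e-14 * min(a2))
  s <- sqrt(p[, 1L]^2 * a2[1L] + p[, 2L]^2 * a2[2L] + p[, 3L]^2 * a2[3L])
  phi <- function(t) {
    (a2[1L] * p[, 1L]^2) / (a2[1L] + t)^2 +
    (a2[2L] * p[, 2L]^2) / (a2[2L] + t)^2 +
    (a2[3L] * p[, 3L]^2) / (a2[3L] + t)^2 - 1
  }
  lo <- rep(-min(a2) * (1 - 1e-12), n)
  hi <- pmax(s, 1e-12)                     # phi(s) <= 0 for all points
  ok <- !ctr & phi(lo) > 0
  # bracketed bisection: robust, vectorized; ~60 halvings reach machine eps
  t <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    f <- phi(t)
    up <- f > 0
    lo[up] <- t[up]
    hi[!up] <- t[!up]
    t <- (lo + hi) / 2
    if (max(hi - lo) < 1e-13 * max(1, max(abs(t)))) break
  }
  q <- cbind(a2[1L] * p[, 1L] / (a2[1L] + t),
             a2[2L] * p[, 2L] / (a2[2L] + t),
             a2[3L] * p[, 3L] / (a2[3L] + t))
  # fallbacks for rows without a valid bracket (degenerate interior points):
  # radial scaling onto the surface, exact for the generic use here
  if (any(!ok)) {
    bad <- which(!ok & !ctr)
    if (length(bad)) {
      r <- sqrt((p[bad, 1L] / a[1L])^2 + (p[bad, 2L] / a[2L])^2 +
                (p[bad, 3L] / a[3L])^2)
      q[bad, ] <- p[bad, , drop = FALSE] / r
    }
    if (any(ctr)) {
      pole <- c(0, 0, 0); pole[which.min(a)] <- a[which.min(a)]
      q[ctr, ] <- matrix(pole, sum(ctr), 3L, byrow = TRUE)
    }
  }
  res <- abs(implicit_value(surface, q))
  if (max(res) > 1e-6)
    stop(sprintf("numerical error: ellipsoid projection did not converge (max residual %.3e)",
                 max(res)))
  if (single) drop(q) else q
}

#' @export
project_to_surface.mesh_surface <- function(points, surface, tol = 1e-10,
                                            max_iter = 100L) {
  single <- is.null(dim(points))
  p <- as_point_matrix(points)
  if (!all(is.finite(p))) stop("points must be finite")
  out <- matrix(0, nrow(p), 3L)
  fid <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    r <- mesh_closest_point(surface, p[i, ])
    out[i, ] <- r$point
    fid[i] <- r$face
  }
  attr(out, "face") <- fid
  if (single) { v <- drop(out); attr(v, "face") <- fid; v } else out
}

# closest point on a mesh for a single query point; prunes faces by
# bounding-box distance against the nearest-vertex upper bound
mesh_closest_point <- function(surface, p) {
  V <- surface$vertices
  dv2 <- (V[, 1L] - p[1L])^2 + (V[, 2L] - p[2L])^2 + (V[, 3L] - p[3L])^2
  best <- sqrt(min(dv2))
  lo <- surface$bb_lo; hi <- surface$bb_hi
  dx <- pmax(lo[, 1L] - p[1L], 0, p[1L] - hi[, 1L])
  dy <- pmax(lo[, 2L] - p[2L], 0, p[2L] - hi[, 2L])
  dz <- pmax(lo[, 3L] - p[3L], 0, p[3L] - hi[, 3L])
  cand <- which(dx^2 + dy^2 + dz^2 <= best^2 * (1 + 1e-9) + 1e-300)
  F <- surface$faces[cand, , drop = FALSE]
  A <- V[F[, 1L], , drop = FALSE]
  B <- V[F[, 2L], , drop = FALSE]
  C <- V[F[, 3L], , drop = FALSE]
  cp <- closest_point_on_triangles(p, A, B, C)
  d2 <- rowSums((cp - matrix(p, nrow(cp), 3L, byrow = TRUE))^2)
  j <- which.min(d2)
  list(point = cp[j, ], face = cand[j], dist = sqrt(d2[j]))
}

# vectorized closest point on triangles (A,B,C rows) to a single point p:
# candidates are the unconstrained plane foot (when its barycentrics are
# admissible) and the three clamped edge projections
closest_point_on_triangles <- function(p, A, B, C) {
  n <- nrow(A)
  P <- matrix(p, n, 3L, byrow = TRUE)
  E0 <- B - A; E1 <- C - A; D <- P - A
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  d <- rowSums(E0 * D);  e <- rowSums(E1 * D)
  det <- pmax(a * c - b^2, 1e-300)
  s <- (c * d - b * e) / det
  t <- (a * e - b * d) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  edge_pt <- function(U, W) {           # clamp p onto segment U->W
    E <- W - U
    tt <- rowSums((P - U) * E) / pmax(rowSums(E * E), 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    U + E * tt
  }
  q1 <- edge_pt(A, B); q2 <- edge_pt(A, C); q3 <- edge_pt(B, C)
  d1 <- rowSums((q1 - P)^2); d2 <- rowSums((q2 - P)^2); d3 <- rowSums((q3 - P)^2)
  q <- q1; dmin <- d1
  w <- d2 < dmin; q[w, ] <- q2[w, , drop = FALSE]; dmin[w] <- d2[w]
  w <- d3 < dmin; q[w, ] <- q3[w, , drop = FALSE]; dmin[w] <- d3[w]
  if (any(inside)) {
    qi <- A + E0 * s + E1 * t
    di <- rowSums((qi - P)^2)
    w <- inside & di <= dmin
    q[w, ] <- qi[w, , drop = FALSE]
  }
  q
}

#' Unit outward surface normal at on-surface points
#'
#' For ellipsoids the normal is the normalized implicit-function gradient;
#' for meshes the normal of the face containing the projection of the point.
#'
#' @param points 3-vector or n x 3 matrix of points on (or within `tol` of)
#'   the surface.
#' @param surface a surface object.
#' @param tol off-surface tolerance (implicit residual for ellipsoids,
#'   distance for meshes).
#' @return unit normal(s), same shape as `points`.
#' @export
surface_normal <- function(points, surface, tol = 1e-6)
  UseMethod("surface_normal", surface)

#' @export
surface_normal.ellipsoid_surface <- function(points, surface, tol = 1e-6) {
  single <- is.null(dim(points))
  p <- as_point_matrix(points)
  if (max(abs(implicit_value(surface, p))) > tol)
    stop("precondition error: point is not on the surface (implicit residual exceeds tol)")
  a2 <- surface$semiaxes^2
  g <- cbind(p[, 1L] / a2[1L], p[, 2L] / a2[2L], p[, 3L] / a2[3L])
  g <- g / sqrt(rowSums(g^2))
  if (single) drop(g) else g
}

#' @export
surface_normal.mesh_surface <- function(points, surface, tol = 1e-6) {
  single <- is.null(dim(points))
  p <- as_point_matrix(points)
  q <- project_to_surface(p, surface)
  d <- sqrt(rowSums((p - as_point_matrix(q))^2))
  if (max(d) > tol)
    stop("precondition error: point is not on the surface (distance exceeds tol)")
  fid <- attr(q, "face")
  g <- surface$face_normals[fid, , drop = FALSE]
  g <- g / sqrt(rowSums(g^2))
  if (single) drop(g) else g
}

#' Triangulated ellipsoid (anisotropically scaled icosphere)
#'
#' @param x_diameter,y_diameter,z_diameter positive diameters.
#' @param subdivisions icosahedron subdivision level (>= 0).
#' @return a `mesh_surface`.
#' @export
ellipsoid_mesh <- function(x_diameter, y_diameter, z_diameter, subdivisions = 3L) {
  if (any(c(x_diameter, y_diameter, z_diameter) <= 0))
    stop("invalid-parameter: ellipsoid diameters must be strictly positive")
  m <- icosphere(subdivisions)
  v <- m$vertices
  v[, 1L] <- v[, 1L] * x_diameter / 2
  v[, 2L] <- v[, 2L] * y_diameter / 2
  v[, 3L] <- v[, 3L] * z_diameter / 2
  make_mesh_surface(v, m$faces)
}

# unit icosphere: subdivided icosahedron with vertices pushed to the sphere
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
    mid_env <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      k <- key(i, j)
      id <- mid_env[[k]]
      if (!is.null(id)) return(id)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      mid_env[[k]] <- id
      id
    }
    nf <- matrix(0L, 0L, 3L)
    for (r in seq_len(nrow(f))) {
      i <- f[r, 1L]; j <- f[r, 2L]; k <- f[r, 3L]
      a <- midpoint(i, j); b <- midpoint(j, k); c <- midpoint(k, i)
      nf <- rbind(nf, c(i, a, c), c(j, b, a), c(k, c, b), c(a, b, c))
    }
    v <- verts; f <- nf
  }
  list(vertices = v, faces = f)
}
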