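#' Triangulated surface mesh container
#'
#' A minimal indexed triangle mesh: an n x 3 numeric matrix of vertex
#' coordinates (mm) and an m x 3 integer matrix of 1-based vertex indices.
#' Faces are wound counter-clockwise seen from outside the valve cylinder,
#' so face normals point radially outward.
#'
#' @param vertices Numeric matrix, n x 3 (columns x, y, z in mm).
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @return An object of class `valve_mesh`.
#' @export
valve_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  colnames(vertices) <- c("x", "y", "z")
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "valve_mesh")
}

#' @export
print.valve_mesh <- function(x, ...) {
  cat(sprintf("Triangulated surface mesh: %d vertices, %d faces, area %.4f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh
#'
#' Sum of the triangle areas, each half the norm of the edge cross product.
#'
#' @param mesh A [valve_mesh()] object.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "valve_mesh"))
  if (nrow(mesh$faces) == 0L) return(0)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1L], , drop = FALSE]
  b <- v[mesh$faces[, 2L], , drop = FALSE]
  c_ <- v[mesh$faces[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# per-face areas, used to drop degenerate triangles
face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0L))
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c_ <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# merge vertices closer than `tol` (mm) and drop the degenerate faces that
# the merge produces
clean_mesh <- function(vertices, faces, tol = 1e-9) {
  key <- apply(round(vertices / tol) * tol, 1L, paste, collapse = ",")
  map <- match(key, key)                # first occurrence index per vertex
  keep <- !duplicated(map)
  newid <- cumsum(keep)
  remap <- newid[map]
  vertices <- vertices[keep, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3L)
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  faces <- faces[!degen, , drop = FALSE]
  areas <- face_areas(vertices, faces)
  faces <- faces[areas > tol^2, , drop = FALSE]
  valve_mesh(vertices, faces)
}

#' Triangulated mesh of a single cusp
#'
#' Discretizes the cusp surface on a structured grid over
#' `(theta, zfrac) in [0, 2*pi/n] x [0, 1]`, splitting each quad into two
#' triangles. Grid columns at the commissures collapse to a point (the free
#' edge height is zero there); the coincident vertices are merged and the
#' resulting zero-area triangles removed.
#'
#' @param cusp A [pv_cusp()] object.
#' @param n_theta Angular subdivisions (>= 2).
#' @param n_z Height subdivisions (>= 1).
#' @return A [valve_mesh()].
#' @examples
#' m <- cusp_mesh(pv_cusp(20.211, 14.20), 64, 32)
#' mesh_area(m) # ~182.7 mm^2
#' @export
cusp_mesh <- function(cusp, n_theta = 128L, n_z = 64L) {
  stopifnot(inherits(cusp, "pv_cusp"))
  n_theta <- as.integer(n_theta); n_z <- as.integer(n_z)
  if (is.na(n_theta) || n_theta < 2L) stop("n_theta must be >= 2")
  if (is.na(n_z) || n_z < 1L) stop("n_z must be >= 1")
  theta <- seq(0, cusp$angular_extent, length.out = n_theta + 1L)
  zfrac <- seq(0, 1, length.out = n_z + 1L)
  hb <- boundary_height(cusp, theta)
  # vertex (i, j) at row index (j - 1) * (n_theta + 1) + i
  th <- rep(theta, times = n_z + 1L)
  zf <- rep(zfrac, each = n_theta + 1L)
  vertices <- cbind(cusp$radius * cos(th), cusp$radius * sin(th),
                    zf * rep(hb, times = n_z + 1L))
  nt1 <- n_theta + 1L
  i <- rep(seq_len(n_theta), times = n_z)
  j <- rep(seq_len(n_z), each = n_theta)
  v00 <- (j - 1L) * nt1 + i
  v10 <- v00 + 1L
  v01 <- v00 + nt1
  v11 <- v01 + 1L
  # (theta, z) ordering gives outward (radial) normals on the cylinder
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  clean_mesh(vertices, faces)
}

#' Rotate a mesh about the valve axis
#'
#' Rigid rotation about the global z axis; z coordinates are unchanged and
#' all pairwise distances preserved.
#'
#' @param mesh A [valve_mesh()].
#' @param angle Rotation angle in radians.
#' @return The rotated [valve_mesh()].
#' @export
rotate_mesh <- function(mesh, angle) {
  stopifnot(inherits(mesh, "valve_mesh"), is.finite(angle))
  v <- mesh$vertices
  ca <- cos(angle); sa <- sin(angle)
  valve_mesh(cbind(ca * v[, 1L] - sa * v[, 2L],
                   sa * v[, 1L] + ca * v[, 2L],
                   v[, 3L]),
             mesh$faces)
}

#' Assemble the full valve from rotated cusps
#'
#' Under the symmetry assumption all cusps are identical; the valve is the
#' union of `n_cusps` copies of the single-cusp mesh rotated by
#' `2*pi*i/n_cusps` about the valve axis. Coincident vertices along the
#' commissure seams are merged (within 1e-9 mm).
#'
#' @param cusp A [pv_cusp()] object.
#' @param n_theta,n_z Per-cusp grid resolution, as [cusp_mesh()].
#' @return A [valve_mesh()] of the assembled valve.
#' @export
assemble_valve <- function(cusp, n_theta = 128L, n_z = 64L) {
  stopifnot(inherits(cusp, "pv_cusp"))
  single <- cusp_mesh(cusp, n_theta, n_z)
  parts <- lapply(seq_len(cusp$n_cusps) - 1L, function(i)
    rotate_mesh(single, 2 * pi * i / cusp$n_cusps))
  nv <- vapply(parts, function(m) nrow(m$vertices), integer(1L))
  offs <- cumsum(c(0L, nv[-length(nv)]))
  vertices <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, parts, offs))
  clean_mesh(vertices, faces)
}
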