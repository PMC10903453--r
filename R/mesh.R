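#' Triangulated surface mesh
#'
#' The container for crista membrane surfaces: a closed, consistently
#' oriented triangulated mesh with vertices in nanometres. Meshes produced
#' by [make_crista_mesh()] are watertight (every edge shared by exactly two
#' faces), oriented with outward normals (positive signed volume) and free
#' of degenerate faces; `validate_mesh()` enforces those invariants.
#'
#' @param vertices Numeric `n x 3` matrix of vertex positions (nm).
#' @param faces Integer `m x 3` matrix of 1-based vertex indices.
#' @param provenance Named list of generator metadata (species preset,
#'   ridge polyline, dimensions); may be empty for imported meshes.
#'
#' @return An object of class `tri_mesh`.
#' @export
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
#' tri_mesh(v, f)
tri_mesh <- function(vertices, faces, provenance = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) abort_param("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) abort_param("`faces` must have 3 columns")
  if (nrow(faces) < 1L) abort_param("mesh has no faces")
  if (any(!is.finite(vertices))) abort_param("vertices contain non-finite values")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    abort_param("face indices out of range")
  }
  structure(
    list(vertices = vertices, faces = faces, provenance = provenance),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$provenance$kind)) {
    cat(sprintf("  provenance: %s", x$provenance$kind))
    if (!is.null(x$provenance$preset_name)) {
      cat(sprintf(" (%s preset)", x$provenance$preset_name))
    }
    cat("\n")
  }
  invisible(x)
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

# Per-face area vectors (0.5 * e1 x e2); outward for an oriented mesh.
face_area_vectors <- function(mesh) {
  v1 <- face_corner(mesh, 1L)
  e1 <- face_corner(mesh, 2L) - v1
  e2 <- face_corner(mesh, 3L) - v1
  0.5 * cross3_rows(e1, e2)
}

face_areas <- function(mesh) {
  av <- face_area_vectors(mesh)
  sqrt(rowSums(av * av))
}

face_normals <- function(mesh) {
  av <- face_area_vectors(mesh)
  a <- sqrt(rowSums(av * av))
  a[a < 1e-15] <- 1
  av / a
}

face_centroids <- function(mesh) {
  (face_corner(mesh, 1L) + face_corner(mesh, 2L) + face_corner(mesh, 3L)) / 3
}

# Signed volume via the divergence theorem (sum of signed tetrahedra from
# the origin). Positive for outward-oriented watertight meshes.
signed_volume <- function(mesh) {
  v1 <- face_corner(mesh, 1L)
  v2 <- face_corner(mesh, 2L)
  v3 <- face_corner(mesh, 3L)
  sum(rowSums(v1 * cross3_rows(v2, v3))) / 6
}

# Number of edges not shared by exactly two faces.
open_edge_count <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- pmin(e[, 1L], e[, 2L]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1L], e[, 2L])
  counts <- rle(sort(key))$lengths
  sum(counts != 2L)
}

#' Check whether a mesh is watertight
#'
#' A mesh is watertight when every edge is shared by exactly two faces.
#'
#' @param mesh A [tri_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  open_edge_count(mesh) == 0L
}

# Flip face winding so the signed volume is positive.
orient_outward <- function(mesh) {
  if (signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  }
  mesh
}

#' Validate mesh invariants
#'
#' Errors unless the mesh is watertight, outward oriented (signed
#' volume > 0) and free of degenerate faces (area > 1e-9 nm^2).
#'
#' @param mesh A [tri_mesh()].
#' @param min_face_area_nm2 Degeneracy threshold.
#' @return The mesh, invisibly.
#' @export
validate_mesh <- function(mesh, min_face_area_nm2 = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  n_open <- open_edge_count(mesh)
  if (n_open > 0L) {
    abort_geometry("mesh is not watertight: %d open or non-manifold edges", n_open)
  }
  if (signed_volume(mesh) <= 0) {
    abort_geometry("mesh is inward-oriented (signed volume <= 0); flip the face winding")
  }
  n_degen <- sum(face_areas(mesh) <= min_face_area_nm2)
  if (n_degen > 0L) {
    abort_geometry("mesh has %d degenerate faces (area <= %g nm^2)", n_degen, min_face_area_nm2)
  }
  invisible(mesh)
}

#' Rigidly transform a mesh
#'
#' Applies a rotation followed by a translation. Used mainly for testing
#' the rigid-motion invariance of the measurement operators.
#'
#' @param mesh A [tri_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (nm).
#' @return The transformed mesh; any ridge polyline in the provenance is
#'   transformed along with the vertices.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "tri_mesh"))
  tr <- function(p) sweep(p %*% t(rotation), 2L, translation, `+`)
  mesh$vertices <- tr(mesh$vertices)
  if (!is.null(mesh$provenance$ridge_polyline)) {
    mesh$provenance$ridge_polyline <- tr(mesh$provenance$ridge_polyline)
  }
  if (!is.null(mesh$provenance$apex_normal)) {
    mesh$provenance$apex_normal <- as.numeric(rotation %*% mesh$provenance$apex_normal)
  }
  if (!is.null(mesh$provenance$cap_axis_point)) {
    mesh$provenance$cap_axis_point <-
      as.numeric(rotation %*% mesh$provenance$cap_axis_point + translation)
    mesh$provenance$cap_axis_dir <-
      as.numeric(rotation %*% mesh$provenance$cap_axis_dir)
  }
  mesh
}
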