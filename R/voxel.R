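# Voxelised label volumes: the bridge between triangulated membrane
# meshes and segmentation-volume workflows.

#' Label volume
#'
#' A 3-D integer array of segmentation labels with an isotropic voxel
#' size and a world-space origin (the centre of voxel \[1,1,1\]).
#'
#' @param grid 3-D integer array (0 = background).
#' @param voxel_nm Voxel edge length, nm.
#' @param origin_nm Length-3 world position of the first voxel centre, nm.
#' @param label_map Named character vector mapping label values to names.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, voxel_nm, origin_nm = c(0, 0, 0),
                         label_map = NULL) {
  if (length(dim(grid)) != 3L) abort_param("`grid` must be a 3-D array")
  check_number(voxel_nm, "voxel_nm", 0, Inf, strict_lower = TRUE)
  storage.mode(grid) <- "integer"
  if (any(grid < 0L)) abort_param("labels must be non-negative")
  labs <- sort(unique(as.integer(grid[grid > 0L])))
  if (is.null(label_map)) {
    label_map <- c("background", sprintf("crista_%d", labs))
    names(label_map) <- c("0", as.character(labs))
  }
  structure(
    list(grid = grid, voxel_nm = voxel_nm, origin_nm = origin_nm,
         label_map = label_map),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<label_volume: %d x %d x %d voxels at %.3g nm, %d label(s)>\n",
              d[1L], d[2L], d[3L], x$voxel_nm,
              length(setdiff(unique(as.integer(x$grid)), 0L))))
  invisible(x)
}

#' Voxelise a watertight mesh into a label volume
#'
#' Interior voxels (centres inside the closed surface, determined by ray
#' parity) receive the crista label; everything else is background. The
#' grid covers the mesh bounding box plus a one-voxel margin.
#'
#' @param mesh A watertight [tri_mesh()].
#' @param voxel_nm Voxel edge length, nm; must not exceed the mesh
#'   bounding box.
#' @param label Integer label for the interior.
#' @return A [label_volume()].
#' @export
#' @examples
#' m <- make_crista_mesh(get_preset("celegans"), face_extent_nm = 50, mesh_step_nm = 4)
#' v <- voxelize(m, voxel_nm = 4)
#' sum(v$grid > 0) * v$voxel_nm^3 / enclosed_volume(m)
voxelize <- function(mesh, voxel_nm, label = 1L) {
  stopifnot(inherits(mesh, "tri_mesh"))
  check_number(voxel_nm, "voxel_nm", 0, Inf, strict_lower = TRUE)
  bb_min <- apply(mesh$vertices, 2L, min)
  bb_max <- apply(mesh$vertices, 2L, max)
  if (voxel_nm > max(bb_max - bb_min)) {
    abort_param("voxel_nm = %g exceeds the mesh bounding box (%.3g nm)",
                voxel_nm, max(bb_max - bb_min))
  }
  n_open <- open_edge_count(mesh)
  if (n_open > 0L) {
    abort_geometry("voxelisation requires a watertight mesh: %d open edges", n_open)
  }
  h <- voxel_nm
  origin <- bb_min - h / 2            # centre of voxel [1,1,1]
  dims <- pmax(1L, ceiling((bb_max - origin + h / 2) / h) + 1L)
  xs <- origin[1L] + (seq_len(dims[1L]) - 1L) * h
  ys <- origin[2L] + (seq_len(dims[2L]) - 1L) * h
  zs <- origin[3L] + (seq_len(dims[3L]) - 1L) * h

  # Column-parity scan: one ray along +x per (y, z) voxel column. Each
  # triangle is projected to the (y, z) plane; the x-crossing of the column
  # line inside the projected triangle toggles inside/outside parity.
  v1 <- face_corner(mesh, 1L)
  v2 <- face_corner(mesh, 2L)
  v3 <- face_corner(mesh, 3L)
  fy <- cbind(v1[, 2L], v2[, 2L], v3[, 2L])
  fz <- cbind(v1[, 3L], v2[, 3L], v3[, 3L])
  fymin <- pmin(fy[, 1L], fy[, 2L], fy[, 3L]); fymax <- pmax(fy[, 1L], fy[, 2L], fy[, 3L])
  fzmin <- pmin(fz[, 1L], fz[, 2L], fz[, 3L]); fzmax <- pmax(fz[, 1L], fz[, 2L], fz[, 3L])

  grid <- array(0L, dim = dims)
  dir <- c(1, 0, 0)
  for (k in seq_len(dims[3L])) {
    z0 <- zs[k]
    cand_z <- which(fzmin <= z0 & fzmax >= z0)
    if (length(cand_z) == 0L) next
    for (j in seq_len(dims[2L])) {
      y0 <- ys[j]
      cand <- cand_z[fymin[cand_z] <= y0 & fymax[cand_z] >= y0]
      if (length(cand) == 0L) next
      t <- ray_triangle_hits(c(origin[1L] - h, y0, z0), dir,
                             mesh$vertices, mesh$faces[cand, , drop = FALSE],
                             eps = 0)
      tx <- sort(t[!is.na(t)]) + (origin[1L] - h)
      # A ray through a shared triangle edge reports the same crossing
      # once per triangle; collapse coincident crossings.
      if (length(tx) > 1L) tx <- tx[c(TRUE, diff(tx) > 1e-9 * max(h, 1))]
      if (length(tx) < 2L) next
      inside <- rep(FALSE, dims[1L])
      # Toggle parity between successive crossings.
      for (q in seq(1L, length(tx) - 1L, by = 2L)) {
        inside <- inside | (xs > tx[q] & xs < tx[q + 1L])
      }
      grid[, j, k] <- ifelse(inside, as.integer(label), grid[, j, k])
    }
  }
  label_volume(grid, voxel_nm, origin_nm = origin)
}

# 3^3 box smoothing of a numeric 3-D array (edge-replicated).
smooth3 <- function(a) {
  sh <- function(arr, d, by) {
    idx <- seq_len(dim(arr)[d])
    src <- clamp(idx + by, 1L, dim(arr)[d])
    switch(d, arr[src, , , drop = FALSE], arr[, src, , drop = FALSE], arr[, , src, drop = FALSE])
  }
  for (d in 1:3) a <- (sh(a, d, -1L) + a + sh(a, d, 1L)) / 3
  a
}

# Central-difference gradient of a 3-D array, as a list of three arrays.
grad3 <- function(a) {
  sh <- function(arr, d, by) {
    idx <- seq_len(dim(arr)[d])
    src <- clamp(idx + by, 1L, dim(arr)[d])
    switch(d, arr[src, , , drop = FALSE], arr[, src, , drop = FALSE], arr[, , src, drop = FALSE])
  }
  lapply(1:3, function(d) (sh(a, d, 1L) - sh(a, d, -1L)) / 2)
}

# Exposed-face surface area of a binary mask. method "normal_weighted"
# weights each exposed voxel face by |n . e_face|, with the local surface
# normal n estimated from the gradient of a twice box-smoothed mask;
# this removes the systematic staircase overcount of raw face counting.
voxel_surface_area <- function(mask, h, method = c("normal_weighted", "face_count"),
                               face_correction = 1) {
  method <- match.arg(method)
  dims <- dim(mask)
  pad <- array(0, dims + 2L)
  pad[2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L)] <- mask
  if (method == "face_count") {
    n_faces <- 0
    for (d in 1:3) {
      idx1 <- lapply(dim(pad), seq_len)
      idx2 <- idx1
      idx1[[d]] <- idx1[[d]][-length(idx1[[d]])]
      idx2[[d]] <- idx2[[d]][-1L]
      a <- do.call(`[`, c(list(pad), idx1, list(drop = FALSE)))
      b <- do.call(`[`, c(list(pad), idx2, list(drop = FALSE)))
      n_faces <- n_faces + sum(a != b)
    }
    return(face_correction * n_faces * h^2)
  }
  sm <- smooth3(smooth3(pad))
  g <- grad3(sm)
  gn <- sqrt(g[[1L]]^2 + g[[2L]]^2 + g[[3L]]^2)
  gn[gn < 1e-12] <- 1
  area <- 0
  for (d in 1:3) {
    idx1 <- lapply(dim(pad), seq_len)
    idx2 <- idx1
    idx1[[d]] <- idx1[[d]][-length(idx1[[d]])]
    idx2[[d]] <- idx2[[d]][-1L]
    a <- do.call(`[`, c(list(pad), idx1, list(drop = FALSE)))
    b <- do.call(`[`, c(list(pad), idx2, list(drop = FALSE)))
    exposed <- a != b
    if (!any(exposed)) next
    # Unit-normal component along this axis, sampled at the interior voxel
    # of each exposed face.
    w_lo <- abs(do.call(`[`, c(list(g[[d]] / gn), idx1, list(drop = FALSE))))
    w_hi <- abs(do.call(`[`, c(list(g[[d]] / gn), idx2, list(drop = FALSE))))
    w <- ifelse(a == 1, w_lo, w_hi)
    area <- area + sum(w[exposed]) * h^2
  }
  area
}

#' Morphometrics from a segmented label volume
#'
#' Per-label volume (voxel count times voxel volume) and surface area from
#' exposed voxel faces. The default `"normal_weighted"` estimator weights
#' each exposed face by the local surface-normal component along the face
#' axis (normals from a smoothed-mask gradient), correcting the systematic
#' staircase overcount of raw face counting; `"face_count"` is the naive
#' count, optionally scaled by `face_correction`.
#'
#' @param volume A [label_volume()] with at least one crista label.
#' @param method Surface-area estimator (see Details).
#' @param face_correction Multiplier applied in `"face_count"` mode
#'   (classical choices are 1 or ~0.7); default 1 (off).
#' @return A tibble of class `crista_morphometry`, one row per label, with
#'   `crista_id`, `surface_area_nm2`, `volume_nm3`, `sa_to_v_per_nm`.
#' @export
volume_morphometrics <- function(volume, method = c("normal_weighted", "face_count"),
                                 face_correction = 1) {
  stopifnot(inherits(volume, "label_volume"))
  method <- match.arg(method)
  labs <- sort(setdiff(unique(as.integer(volume$grid)), 0L))
  if (length(labs) == 0L) abort_param("label volume contains no crista labels")
  h <- volume$voxel_nm
  purrr::map_dfr(labs, function(lab) {
    mask <- array(as.numeric(volume$grid == lab), dim = dim(volume$grid))
    vol <- sum(mask) * h^3
    area <- voxel_surface_area(mask, h, method = method,
                               face_correction = face_correction)
    nm <- unname(volume$label_map[as.character(lab)])
    tibble::tibble(
      crista_id = if (is.null(nm) || is.na(nm)) sprintf("label_%d", lab) else nm,
      surface_area_nm2 = area,
      volume_nm3 = vol,
      sa_to_v_per_nm = area / vol
    )
  }) |>
    structure(class = c("crista_morphometry", class(tibble::tibble())))
}
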