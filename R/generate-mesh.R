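# Crista mesh generator. The lamellar sac is built as an extrusion of a
# closed convex 2-D profile: two flat faces separated by the crista width,
# joined on one side by a wedge of the preset's membrane-curvature angle
# with a circular fillet at the apex (the dimer-decorated ridge), and on
# the other side by a half-cylindrical rim cap. The extrusion runs along
# y; the ridge apex polyline is recorded in the provenance.

# Sample a straight segment from a to b (2-D), excluding the end point.
.seg_pts <- function(a, b, step) {
  len <- sqrt(sum((b - a)^2))
  n <- max(1L, ceiling(len / step))
  t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  cbind(a[1L] + t * (b[1L] - a[1L]), a[2L] + t * (b[2L] - a[2L]))
}

# Sample an arc of radius r about centre, from angle a1 to a2 (radians,
# traversed linearly), excluding the end point. Forced to an even segment
# count so the midpoint (the apex tip) is included exactly.
.arc_pts <- function(centre, r, a1, a2, step, min_seg = 8L) {
  n <- max(min_seg, ceiling(abs(a2 - a1) * r / step))
  if (n %% 2L == 1L) n <- n + 1L
  ang <- seq(a1, a2, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1L] + r * cos(ang), centre[2L] + r * sin(ang))
}

# Closed 2-D cross-section profile (x = depth direction, z = thickness).
# Returns the profile points (counter-clockwise or clockwise; orientation
# is fixed after extrusion) plus key frame data.
crista_profile <- function(width_nm, extent_nm, wedge_angle_deg, apex_radius_nm, step_nm) {
  w2 <- width_nm / 2
  e2 <- extent_nm / 2
  cap_c <- c(-e2 + w2, 0)

  rounded_slab <- wedge_angle_deg >= 180 - 1e-9
  if (rounded_slab) {
    # Flat membrane continuation: the ridge side closes with a half-cylinder
    # of radius width/2 (the wedge flanks degenerate at 180 degrees).
    ridge_c <- c(e2 - w2, 0)
    if (ridge_c[1L] - cap_c[1L] < step_nm) {
      abort_param("face_extent_nm too small for the requested width")
    }
    pts <- rbind(
      .seg_pts(c(cap_c[1L], w2), c(ridge_c[1L], w2), step_nm),
      .arc_pts(ridge_c, w2, pi / 2, -pi / 2, step_nm),
      .seg_pts(c(ridge_c[1L], -w2), c(cap_c[1L], -w2), step_nm),
      .arc_pts(cap_c, w2, -pi / 2, -3 * pi / 2, step_nm)
    )
    tip_x <- e2
  } else {
    alpha <- deg2rad(wedge_angle_deg) / 2
    if (apex_radius_nm * cos(alpha) >= w2) {
      abort_param(paste0("apex_radius_nm = %g too large for wedge angle %g deg and ",
                         "width %g nm"), apex_radius_nm, wedge_angle_deg, width_nm)
    }
    # Virtual (unrounded) wedge apex position such that the filleted tip
    # lands exactly at x = extent/2.
    x_v <- e2 + apex_radius_nm * (1 / sin(alpha) - 1)
    fil_c <- c(x_v - apex_radius_nm / sin(alpha), 0)
    # Tangent points of the fillet on the two flank lines.
    p_u <- fil_c + apex_radius_nm * c(sin(alpha), cos(alpha))
    x_j <- x_v - w2 / tan(alpha)               # flank / face junction
    if (x_j - cap_c[1L] < step_nm) {
      abort_param("face_extent_nm too small for the requested width and wedge angle")
    }
    phi <- atan2(p_u[2L] - fil_c[2L], p_u[1L] - fil_c[1L])
    pts <- rbind(
      .seg_pts(c(cap_c[1L], w2), c(x_j, w2), step_nm),        # top face
      .seg_pts(c(x_j, w2), p_u, step_nm),                     # upper flank
      .arc_pts(fil_c, apex_radius_nm, phi, -phi, step_nm),    # apex fillet
      .seg_pts(c(p_u[1L], -p_u[2L]), c(x_j, -w2), step_nm),   # lower flank
      .seg_pts(c(x_j, -w2), c(cap_c[1L], -w2), step_nm),      # bottom face
      .arc_pts(cap_c, w2, -pi / 2, -3 * pi / 2, step_nm)      # rim cap
    )
    tip_x <- e2
  }
  # Drop any duplicated consecutive points (including the wrap-around).
  keep <- c(TRUE, rowSums((pts[-1L, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-16)
  pts <- pts[keep, , drop = FALSE]
  if (sum((pts[1L, ] - pts[nrow(pts), ])^2) < 1e-16) pts <- pts[-nrow(pts), , drop = FALSE]
  list(points = pts, tip_x = tip_x, cap_centre = cap_c, rounded_slab = rounded_slab)
}

#' Generate a synthetic crista membrane mesh
#'
#' Builds a watertight, outward-oriented triangulated mesh of a lamellar
#' crista: two planar faces separated by the preset's crista width, joined
#' along one long edge by a ridge whose cross-section is a wedge with the
#' preset's membrane-curvature angle, rounded at the apex, and closed on
#' the opposite rim by a half-cylindrical cap. The ridge apex polyline —
#' where rows of ATP synthase dimers sit — is recorded in the mesh
#' provenance together with the local frame needed to place dimer rows.
#'
#' @param preset A [species_preset()] (or preset name).
#' @param face_extent_nm Extent of the lamellar faces, nm; used both for
#'   the ridge length (extrusion direction) and the face depth. Must
#'   exceed the crista width.
#' @param apex_radius_nm Fillet radius of the ridge apex, nm; must be less
#'   than half the crista width.
#' @param mesh_step_nm Target edge length of the triangulation, nm.
#' @param width_nm Optional override of the preset crista width, nm.
#'
#' @return A [tri_mesh()] with provenance fields `ridge_polyline`,
#'   `apex_normal`, `cap_axis_point`/`cap_axis_dir`, `y_range`,
#'   `width_nm`, `apex_radius_nm` and `preset_name`.
#' @export
#' @examples
#' m <- make_crista_mesh(get_preset("celegans"), face_extent_nm = 60, mesh_step_nm = 2)
#' is_watertight(m)
make_crista_mesh <- function(preset, face_extent_nm = 100, apex_radius_nm = 2,
                             mesh_step_nm = 1, width_nm = NULL) {
  preset <- as_preset(preset)
  width <- width_nm %||% preset$crista_width_nm
  check_number(width, "width_nm", 0, Inf, strict_lower = TRUE)
  check_number(face_extent_nm, "face_extent_nm", width, Inf, strict_lower = TRUE)
  check_number(apex_radius_nm, "apex_radius_nm", 0, width / 2,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(mesh_step_nm, "mesh_step_nm", 0, Inf, strict_lower = TRUE)

  prof <- crista_profile(width, face_extent_nm, preset$wedge_angle_deg,
                         apex_radius_nm, mesh_step_nm)
  # Euclidean distance from the ridge apex to the flank/face junction:
  # surface points closer to the ridge than this are on the wedge flanks
  # or fillet rather than on the lamellar faces.
  wedge_zone <- if (prof$rounded_slab) {
    width / sqrt(2)
  } else {
    alpha <- deg2rad(preset$wedge_angle_deg) / 2
    x_v <- face_extent_nm / 2 + apex_radius_nm * (1 / sin(alpha) - 1)
    x_j <- x_v - (width / 2) / tan(alpha)
    sqrt((face_extent_nm / 2 - x_j)^2 + (width / 2)^2)
  }
  px <- prof$points[, 1L]
  pz <- prof$points[, 2L]
  np <- length(px)

  e2 <- face_extent_nm / 2
  ny <- max(1L, ceiling(face_extent_nm / mesh_step_nm))
  ys <- seq(-e2, e2, length.out = ny + 1L)

  # Vertex rings: profile replicated at each y station.
  vertices <- cbind(
    rep(px, times = ny + 1L),
    rep(ys, each = np),
    rep(pz, times = ny + 1L)
  )
  idx <- function(i, j) (j - 1L) * np + i   # i profile index, j ring index

  i1 <- seq_len(np)
  i2 <- c(seq_len(np)[-1L], 1L)
  side_faces <- vector("list", ny)
  for (j in seq_len(ny)) {
    a <- idx(i1, j); b <- idx(i2, j); cc <- idx(i2, j + 1L); d <- idx(i1, j + 1L)
    side_faces[[j]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  faces <- do.call(rbind, side_faces)

  # End caps: triangle fans from the profile centroid (profile is convex).
  ctr <- c(mean(px), mean(pz))
  v_start <- c(ctr[1L], -e2, ctr[2L])
  v_end <- c(ctr[1L], e2, ctr[2L])
  vertices <- rbind(vertices, v_start, v_end)
  c_start <- nrow(vertices) - 1L
  c_end <- nrow(vertices)
  faces <- rbind(
    faces,
    cbind(rep(c_start, np), idx(i2, 1L), idx(i1, 1L)),
    cbind(rep(c_end, np), idx(i1, ny + 1L), idx(i2, ny + 1L))
  )

  ridge <- cbind(prof$tip_x, ys, 0)
  dimnames(ridge) <- NULL
  dimnames(vertices) <- NULL
  mesh <- tri_mesh(
    vertices, faces,
    provenance = list(
      kind = "crista",
      preset_name = preset$name,
      preset = unclass(preset),
      width_nm = width,
      face_extent_nm = face_extent_nm,
      apex_radius_nm = apex_radius_nm,
      mesh_step_nm = mesh_step_nm,
      wedge_angle_deg = preset$wedge_angle_deg,
      rounded_slab = prof$rounded_slab,
      wedge_zone_nm = wedge_zone,
      ridge_polyline = ridge,
      apex_normal = c(1, 0, 0),
      cap_axis_point = c(prof$cap_centre[1L], 0, 0),
      cap_axis_dir = c(0, 1, 0),
      cap_radius_nm = width / 2,
      y_range = c(-e2, e2)
    )
  )
  mesh <- orient_outward(mesh)
  validate_mesh(mesh)
  mesh
}

# Truncated-normal draw: rejection sampling within mean +- 50% of mean
# (guarantees strictly positive dimensions while keeping the mean).
rtrunc_pop <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- 0.5 * mean
  hi <- 1.5 * mean
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a population of crista meshes
#'
#' Draws `n_cristae` cristae whose face extent and width vary as truncated
#' Gaussians (truncated at 50% of the mean, so all dimensions stay
#' positive) around the preset values, emulating the per-crista variation
#' seen in segmented tomograms of whole mitochondria.
#'
#' @param preset A [species_preset()] (or preset name).
#' @param n_cristae Number of cristae to generate.
#' @param extent_mean_nm,extent_sd_nm Mean and SD of the face extent, nm.
#' @param width_sd_nm SD of the crista width around the preset value, nm.
#' @param seed Integer seed; the same seed reproduces the population.
#' @param apex_radius_nm,mesh_step_nm Passed to [make_crista_mesh()].
#'
#' @return A list of [tri_mesh()] objects (class `crista_population`).
#' @export
#' @examples
#' pop <- make_population(get_preset("celegans"), n_cristae = 3,
#'                        extent_mean_nm = 80, extent_sd_nm = 8, seed = 1,
#'                        mesh_step_nm = 4)
#' length(pop)
make_population <- function(preset, n_cristae, extent_mean_nm = 400,
                            extent_sd_nm = 60, width_sd_nm = 2, seed = 1,
                            apex_radius_nm = 2, mesh_step_nm = 5) {
  preset <- as_preset(preset)
  n_cristae <- check_count(n_cristae, "n_cristae")
  check_number(extent_mean_nm, "extent_mean_nm", 0, Inf, strict_lower = TRUE)
  check_number(extent_sd_nm, "extent_sd_nm", 0, Inf)
  check_number(width_sd_nm, "width_sd_nm", 0, Inf)
  seed <- check_seed(seed)

  dims <- withr::with_seed(seed, {
    list(
      extent = rtrunc_pop(n_cristae, extent_mean_nm, extent_sd_nm),
      width = rtrunc_pop(n_cristae, preset$crista_width_nm, width_sd_nm)
    )
  })
  meshes <- purrr::map(seq_len(n_cristae), function(i) {
    m <- make_crista_mesh(
      preset,
      face_extent_nm = dims$extent[i],
      apex_radius_nm = apex_radius_nm,
      mesh_step_nm = mesh_step_nm,
      width_nm = dims$width[i]
    )
    m$provenance$crista_id <- sprintf("%s_%03d", preset$name, i)
    m
  })
  structure(meshes, class = c("crista_population", "list"))
}
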