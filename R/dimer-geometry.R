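# Per-dimer and per-row geometric metrics: the quantities used to
# characterise ATP synthase dimer architecture in membranes.

check_pose_table <- function(poses) {
  if (!is.data.frame(poses)) abort_param("`poses` must be a data frame of dimer poses")
  missing <- setdiff(setdiff(pose_cols(), c("crista_id", "row_id", "dimer_id")), names(poses))
  if (length(missing) > 0L) {
    abort_param("pose table is missing columns: %s", paste(missing, collapse = ", "))
  }
  invisible(poses)
}

#' Angle between the two monomer axes of each dimer
#'
#' The dimer-head angle: `acos(axis_a . axis_b)` in degrees, in
#' \[0, 180\]. Symmetric under swapping the two monomers and invariant
#' under rigid motions of the scene.
#'
#' @param poses A pose table (one row per dimer), e.g. from
#'   [place_dimer_row()].
#' @return Numeric vector of angles (degrees), one per dimer.
#' @export
#' @examples
#' m <- make_crista_mesh(get_preset("celegans"), face_extent_nm = 80, mesh_step_nm = 2)
#' row <- place_dimer_row(m, "celegans", 3, seed = 1)
#' dimer_angle(row)
dimer_angle <- function(poses) {
  check_pose_table(poses)
  a <- mat3(poses, "axis_a")
  b <- mat3(poses, "axis_b")
  na <- sqrt(rowSums(a * a))
  nb <- sqrt(rowSums(b * b))
  if (any(na < 1e-9) || any(nb < 1e-9)) {
    abort_geometry("zero-length monomer axis in pose table")
  }
  if (any(abs(na - 1) > 1e-6) || any(abs(nb - 1) > 1e-6)) {
    rlang::warn("monomer axes are not unit-norm; normalising")
  }
  rad2deg(acos(clamp(rowSums(a * b) / (na * nb), -1, 1)))
}

#' Distance between the two central-stalk base points of each dimer
#'
#' Euclidean distance between the membrane-midplane feet of the two
#' central stalks; translation and rotation invariant.
#'
#' @inheritParams dimer_angle
#' @return Numeric vector of separations (nm), one per dimer.
#' @export
stalk_separation <- function(poses) {
  check_pose_table(poses)
  a <- mat3(poses, "base_a")
  b <- mat3(poses, "base_b")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort_param("non-finite base coordinates in pose table")
  }
  sqrt(rowSums((a - b)^2))
}

#' Membrane curvature (wedge) angle at a crista ridge
#'
#' Measures the interior angle between the two membrane flanks meeting at
#' a ridge, the way a protractor overlay on a cross-section would: mesh
#' faces whose centroids lie between `probe_inner_nm` and `probe_outer_nm`
#' of the ridge point are partitioned into the two flanks by their offset
#' across the ridge, a least-squares plane is fitted to each flank, and
#' the interior angle between the planes (measured on the side containing
#' the apex) is returned in degrees. A flat membrane gives 180; sharper
#' folds give smaller angles. The probe window excludes the rounded apex
#' fillet, so the angle reflects the flank planes, not the fillet.
#'
#' @param mesh A [tri_mesh()].
#' @param ridge_point Point on the ridge (length-3, nm). Defaults to the
#'   midpoint of the provenance ridge polyline.
#' @param probe_inner_nm,probe_outer_nm Probe annulus radii, nm.
#' @param ridge_tangent Optional local ridge tangent (length-3). Defaults
#'   to the tangent of the provenance ridge polyline at `ridge_point`.
#' @return Wedge angle in degrees, in (0, 180\].
#' @export
#' @examples
#' m <- make_crista_mesh(get_preset("scerevisiae"), face_extent_nm = 80, mesh_step_nm = 1)
#' membrane_wedge_angle(m)
membrane_wedge_angle <- function(mesh, ridge_point = NULL, probe_inner_nm = 3,
                                 probe_outer_nm = 10, ridge_tangent = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  check_number(probe_inner_nm, "probe_inner_nm", 0, Inf)
  check_number(probe_outer_nm, "probe_outer_nm", probe_inner_nm, Inf, strict_lower = TRUE)

  polyline <- mesh$provenance$ridge_polyline
  if (is.null(ridge_point)) {
    if (is.null(polyline)) {
      abort_param("no `ridge_point` given and mesh provenance has no ridge polyline")
    }
    mid <- polyline_arclength(polyline)
    mid <- mid[length(mid)] / 2
    loc <- polyline_at(polyline, mid)
    ridge_point <- as.numeric(loc$points[1L, ])
    if (is.null(ridge_tangent)) ridge_tangent <- as.numeric(loc$tangents[1L, ])
  }
  if (is.null(ridge_tangent)) {
    if (is.null(polyline)) {
      abort_param("no `ridge_tangent` given and mesh provenance has no ridge polyline")
    }
    s <- polyline_at(polyline, polyline_arclength(polyline)[length(polyline_arclength(polyline))] / 2)
    ridge_tangent <- as.numeric(s$tangents[1L, ])
  }
  tangent <- unit_vec(ridge_tangent)

  ctr <- face_centroids(mesh)
  d <- sweep(ctr, 2L, ridge_point)
  # Distance from the ridge *line*, so that apex-fillet faces at other
  # positions along the ridge cannot leak into the probe annulus; the
  # along-ridge window keeps the measurement local to the probe point.
  dist <- if (!is.null(polyline)) {
    dist_to_polyline(ctr, polyline)
  } else {
    along0 <- as.numeric(d %*% tangent)
    sqrt(pmax(rowSums(d * d) - along0^2, 0))
  }
  along <- abs(as.numeric(d %*% tangent))
  sel <- which(dist >= probe_inner_nm & dist <= probe_outer_nm &
                 along <= probe_outer_nm)
  if (length(sel) < 6L) {
    abort_support("only %d faces inside the probe annulus; need at least 3 per flank",
                  length(sel))
  }
  dperp <- d[sel, , drop = FALSE] - outer(as.numeric(d[sel, , drop = FALSE] %*% tangent), tangent)

  # Cross-ridge direction: perpendicular to the tangent and to the mean
  # in-plane offset (which points into the wedge interior). Falls back to
  # the principal offset direction when the offsets are balanced (flat
  # membrane), where any perpendicular split works.
  m <- colMeans(dperp)
  if (vec_norm(m) > 0.05 * probe_outer_nm) {
    cdir <- unit_vec(cross3(tangent, m))
  } else {
    sv <- svd(dperp, nu = 0L)
    cdir <- sv$v[, 1L]
  }
  side <- as.numeric(dperp %*% cdir)
  flank1 <- sel[side > 0]
  flank2 <- sel[side <= 0]
  if (length(flank1) < 3L || length(flank2) < 3L) {
    abort_support("insufficient support: %d / %d faces on the two flanks (need >= 3 each)",
                  length(flank1), length(flank2))
  }

  nrm <- face_normals(mesh)
  flank_normal <- function(idx) {
    fp <- fit_plane(ctr[idx, , drop = FALSE])
    n <- fp$normal
    outward <- colMeans(nrm[idx, , drop = FALSE])
    if (sum(n * outward) < 0) n <- -n
    n
  }
  n1 <- flank_normal(flank1)
  n2 <- flank_normal(flank2)
  # Interior angle on the apex side: outward normals of a wedge of interior
  # angle theta meet at 180 - theta.
  180 - angle_between_deg(n1, n2)
}

#' Row metrics: inter-dimer spacing and yaw offset
#'
#' For each ridge row with at least two dimers, computes the mean and SD
#' of the consecutive centre-to-centre distances and of the in-plane yaw
#' offsets between consecutive head-head axes. The head-head axis
#' (`base_b - base_a`) is projected onto the plane perpendicular to the
#' local membrane normal; because the axes are undirected lines, the
#' yaw offset is folded into \[0, 90\] degrees.
#'
#' @param poses A pose table; rows are grouped by `crista_id` + `row_id`
#'   when those columns are present.
#' @return A tibble with one row per ridge row: `inter_dimer_nm`,
#'   `inter_dimer_sd_nm`, `yaw_offset_deg`, `yaw_offset_sd_deg`, `n_pairs`.
#' @export
row_metrics <- function(poses) {
  check_pose_table(poses)
  key <- if (all(c("crista_id", "row_id") %in% names(poses))) {
    paste(poses$crista_id, poses$row_id, sep = "\r")
  } else {
    rep("row", nrow(poses))
  }
  groups <- split(seq_len(nrow(poses)), key)
  if (any(lengths(groups) < 2L)) {
    abort_param("row metrics need at least 2 dimers per row; got a row with %d",
                min(lengths(groups)))
  }
  res <- purrr::map_dfr(groups, function(idx) {
    p <- poses[idx, , drop = FALSE]
    ctr <- mat3(p, "centre")
    spacing <- sqrt(rowSums(diff(ctr)^2))
    h <- mat3(p, "base_b") - mat3(p, "base_a")
    nrm <- mat3(p, "normal")
    n <- nrow(p)
    yaws <- vapply(seq_len(n - 1L), function(i) {
      nn <- nrm[i, ]
      if (angle_between_deg(nrm[i, ], nrm[i + 1L, ]) > 30) {
        rlang::warn("consecutive membrane normals differ by > 30 deg; using the first dimer's tangent plane")
      }
      h1 <- h[i, ] - sum(h[i, ] * nn) * nn
      h2 <- h[i + 1L, ] - sum(h[i + 1L, ] * nn) * nn
      ang <- angle_between_deg(h1, h2)
      min(ang, 180 - ang)   # undirected lines
    }, numeric(1))
    tibble::tibble(
      crista_id = p$crista_id[1L] %||% NA_character_,
      row_id = p$row_id[1L] %||% NA_character_,
      inter_dimer_nm = mean(spacing),
      inter_dimer_sd_nm = if (length(spacing) > 1L) sd(spacing) else 0,
      yaw_offset_deg = mean(yaws),
      yaw_offset_sd_deg = if (length(yaws) > 1L) sd(yaws) else 0,
      n_pairs = n - 1L
    )
  })
  tibble::as_tibble(res)
}

#' Measure all dimer and row metrics of a scene
#'
#' Computes per-dimer metrics (dimer angle, stalk separation), per-row
#' metrics (inter-dimer spacing, yaw offset) and, when a mesh is
#' supplied, the membrane wedge angle at the ridge. Returns the three
#' tables bundled with a summary block.
#'
#' @param poses A pose table covering one or more ridge rows.
#' @param mesh Optional [tri_mesh()]; when absent the wedge angle is
#'   omitted (not an error).
#' @param probe_inner_nm,probe_outer_nm Probe radii for
#'   [membrane_wedge_angle()].
#' @return A list of class `dimer_measurements` with elements `per_dimer`,
#'   `per_row`, `summary` (tibbles) and `wedge_angle_deg` (scalar or NA).
#' @export
measure_dimers <- function(poses, mesh = NULL, probe_inner_nm = 3, probe_outer_nm = 10) {
  if (is.null(poses) || nrow(poses) == 0L) {
    rlang::warn("empty pose table; returning empty measurements")
    empty <- tibble::tibble()
    return(structure(list(per_dimer = empty, per_row = empty,
                          summary = empty, wedge_angle_deg = NA_real_),
                     class = "dimer_measurements"))
  }
  check_pose_table(poses)
  per_dimer <- tibble::tibble(
    crista_id = poses$crista_id %||% NA_character_,
    row_id = poses$row_id %||% NA_character_,
    dimer_id = poses$dimer_id %||% seq_len(nrow(poses)),
    dimer_angle_deg = dimer_angle(poses),
    stalk_sep_nm = stalk_separation(poses)
  )
  key <- paste(per_dimer$crista_id, per_dimer$row_id, sep = "\r")
  per_row <- if (min(table(key)) >= 2L) row_metrics(poses) else tibble::tibble()
  wedge <- if (!is.null(mesh)) {
    membrane_wedge_angle(mesh, probe_inner_nm = probe_inner_nm,
                         probe_outer_nm = probe_outer_nm)
  } else {
    NA_real_
  }
  summary <- tibble::tibble(
    n_dimers = nrow(per_dimer),
    n_rows = length(unique(key)),
    dimer_angle_mean_deg = mean(per_dimer$dimer_angle_deg),
    dimer_angle_sd_deg = if (nrow(per_dimer) > 1L) sd(per_dimer$dimer_angle_deg) else 0,
    stalk_sep_mean_nm = mean(per_dimer$stalk_sep_nm),
    stalk_sep_sd_nm = if (nrow(per_dimer) > 1L) sd(per_dimer$stalk_sep_nm) else 0,
    inter_dimer_mean_nm = if (nrow(per_row) > 0L) mean(per_row$inter_dimer_nm) else NA_real_,
    yaw_offset_mean_deg = if (nrow(per_row) > 0L) mean(per_row$yaw_offset_deg) else NA_real_,
    wedge_angle_deg = wedge
  )
  structure(
    list(per_dimer = per_dimer, per_row = per_row, summary = summary,
         wedge_angle_deg = wedge),
    class = "dimer_measurements"
  )
}

#' @export
print.dimer_measurements <- function(x, ...) {
  cat("<dimer_measurements>\n")
  if (nrow(x$summary) > 0L) {
    s <- x$summary
    cat(sprintf("  %d dimers in %d rows\n", s$n_dimers, s$n_rows))
    cat(sprintf("  dimer angle  %7.2f +- %.2f deg\n", s$dimer_angle_mean_deg, s$dimer_angle_sd_deg))
    cat(sprintf("  stalk sep    %7.2f +- %.2f nm\n", s$stalk_sep_mean_nm, s$stalk_sep_sd_nm))
    if (is.finite(s$inter_dimer_mean_nm)) {
      cat(sprintf("  inter-dimer  %7.2f nm   yaw %.2f deg\n",
                  s$inter_dimer_mean_nm, s$yaw_offset_mean_deg))
    }
    if (is.finite(s$wedge_angle_deg)) {
      cat(sprintf("  wedge angle  %7.2f deg\n", s$wedge_angle_deg))
    }
  } else {
    cat("  (empty)\n")
  }
  invisible(x)
}
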