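# Dimer row generator. Dimer poses are stored tidyverse-style: one row per
# dimer in a tibble whose columns hold the centre, the two central-stalk
# base points, the two unit monomer axes (base -> F1 head) and the local
# ridge frame (tangent, membrane normal). Lengths in nm.

pose_cols <- function() {
  v3 <- function(stem) paste0(stem, c("_x", "_y", "_z"))
  c("crista_id", "row_id", "dimer_id",
    v3("centre"), v3("base_a"), v3("base_b"),
    v3("axis_a"), v3("axis_b"), v3("ridge_tangent"), v3("normal"))
}

mat3 <- function(df, stem) {
  as.matrix(df[paste0(stem, c("_x", "_y", "_z"))])
}

# Arclength-parameterised point + tangent lookup on a polyline.
polyline_arclength <- function(polyline) {
  seg <- diff(polyline)
  c(0, cumsum(sqrt(rowSums(seg * seg))))
}

polyline_at <- function(polyline, s) {
  cum <- polyline_arclength(polyline)
  total <- cum[length(cum)]
  s <- clamp(s, 0, total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(polyline) - 1L)
  frac <- (s - cum[i]) / pmax(cum[i + 1L] - cum[i], 1e-15)
  pts <- polyline[i, , drop = FALSE] +
    (polyline[i + 1L, , drop = FALSE] - polyline[i, , drop = FALSE]) * frac
  tans <- polyline[i + 1L, , drop = FALSE] - polyline[i, , drop = FALSE]
  tans <- tans / sqrt(rowSums(tans * tans))
  list(points = pts, tangents = tans)
}

# Gaussian perturbation of unit axes in the tangent plane of the sphere
# (small-angle isotropic model), sd_rad per tangent component.
jitter_axes <- function(axes, sd_rad) {
  if (sd_rad == 0) return(axes)
  n <- nrow(axes)
  # Orthonormal frame per axis.
  ref <- matrix(rep(c(1, 0, 0), n), ncol = 3L, byrow = TRUE)
  swap <- abs(rowSums(axes * ref)) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), sum(swap)), ncol = 3L, byrow = TRUE)
  e1 <- cross3_rows(axes, ref)
  e1 <- e1 / sqrt(rowSums(e1 * e1))
  e2 <- cross3_rows(axes, e1)
  g1 <- rnorm(n, 0, sd_rad)
  g2 <- rnorm(n, 0, sd_rad)
  out <- axes + e1 * g1 + e2 * g2
  out / sqrt(rowSums(out * out))
}

#' Place a row of ATP synthase dimer poses along a crista ridge
#'
#' Dimer centres are spaced at the preset inter-dimer distance along the
#' ridge apex polyline recorded in the mesh provenance. Each dimer's two
#' monomer axes are splayed symmetrically about the local membrane normal
#' by the preset dimer angle, its two central-stalk bases sit across the
#' ridge separated by the preset stalk separation, and consecutive dimers
#' are rotated by the preset yaw offset about the local normal. Optional
#' zero-mean Gaussian jitter perturbs the axis directions (SD
#' `jitter_deg`, applied in the tangent plane of the unit sphere) and the
#' base positions (SD `jitter_nm` per coordinate). The same seed
#' reproduces the row exactly.
#'
#' @param mesh A [tri_mesh()] from [make_crista_mesh()] (must carry a ridge
#'   polyline in its provenance).
#' @param preset A [species_preset()] (or preset name).
#' @param n_dimers Number of dimers in the row.
#' @param jitter_deg Angular jitter SD, degrees (0 = noiseless).
#' @param jitter_nm Positional jitter SD, nm (0 = noiseless).
#' @param seed Integer seed.
#' @param row_id,crista_id Identifiers stored in the pose table.
#'
#' @return A tibble of class `dimer_row`, one row per dimer, with the
#'   ridge polyline attached as attribute `ridge_polyline`.
#' @export
#' @examples
#' m <- make_crista_mesh(get_preset("celegans"), face_extent_nm = 80, mesh_step_nm = 2)
#' row <- place_dimer_row(m, get_preset("celegans"), n_dimers = 5, seed = 1)
#' dimer_angle(row)
place_dimer_row <- function(mesh, preset, n_dimers, jitter_deg = 0, jitter_nm = 0,
                            seed = 1, row_id = "row_1", crista_id = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  preset <- as_preset(preset)
  n_dimers <- check_count(n_dimers, "n_dimers")
  check_number(jitter_deg, "jitter_deg", 0, Inf)
  check_number(jitter_nm, "jitter_nm", 0, Inf)
  seed <- check_seed(seed)

  polyline <- mesh$provenance$ridge_polyline
  if (is.null(polyline)) {
    abort_param("mesh provenance carries no ridge polyline; was it made by make_crista_mesh()?")
  }
  normal0 <- mesh$provenance$apex_normal %||% c(1, 0, 0)

  total <- polyline_arclength(polyline)
  total <- total[length(total)]
  row_len <- (n_dimers - 1L) * preset$inter_dimer_nm
  if (row_len > total + 1e-9) {
    abort_param("row of %d dimers (%.1f nm) exceeds the ridge length %.1f nm; maximum n_dimers = %d",
                n_dimers, row_len, total, floor(total / preset$inter_dimer_nm) + 1L)
  }
  s0 <- (total - row_len) / 2
  s <- s0 + (seq_len(n_dimers) - 1L) * preset$inter_dimer_nm
  loc <- polyline_at(polyline, s)
  centres <- loc$points
  tangents <- loc$tangents

  half <- deg2rad(preset$dimer_angle_deg) / 2
  yaw <- deg2rad(preset$yaw_offset_deg)
  sep2 <- preset$stalk_sep_nm / 2

  normals <- matrix(normal0, n_dimers, 3L, byrow = TRUE)
  # Cross-ridge direction, then per-dimer accumulated yaw about the normal.
  base_u <- cross3_rows(normals, tangents)
  base_u <- base_u / sqrt(rowSums(base_u * base_u))
  u <- base_u
  for (i in seq_len(n_dimers)) {
    if (i > 1L) u[i, ] <- rotate_about(base_u[i, ], normals[i, ], (i - 1L) * yaw)
  }

  base_a <- centres + sep2 * u
  base_b <- centres - sep2 * u
  axis_a <- normals * cos(half) + u * sin(half)
  axis_b <- normals * cos(half) - u * sin(half)

  if (jitter_deg > 0 || jitter_nm > 0) {
    jit <- withr::with_seed(seed, {
      list(
        axis_a = jitter_axes(axis_a, deg2rad(jitter_deg)),
        axis_b = jitter_axes(axis_b, deg2rad(jitter_deg)),
        da = matrix(rnorm(3L * n_dimers, 0, jitter_nm), ncol = 3L),
        db = matrix(rnorm(3L * n_dimers, 0, jitter_nm), ncol = 3L)
      )
    })
    axis_a <- jit$axis_a
    axis_b <- jit$axis_b
    base_a <- base_a + jit$da
    base_b <- base_b + jit$db
  }
  # Centre is defined as the midpoint between the two stalk bases.
  centres <- (base_a + base_b) / 2

  out <- tibble::tibble(
    crista_id = crista_id %||% (mesh$provenance$crista_id %||% "crista_1"),
    row_id = row_id,
    dimer_id = seq_len(n_dimers),
    centre_x = centres[, 1L], centre_y = centres[, 2L], centre_z = centres[, 3L],
    base_a_x = base_a[, 1L], base_a_y = base_a[, 2L], base_a_z = base_a[, 3L],
    base_b_x = base_b[, 1L], base_b_y = base_b[, 2L], base_b_z = base_b[, 3L],
    axis_a_x = axis_a[, 1L], axis_a_y = axis_a[, 2L], axis_a_z = axis_a[, 3L],
    axis_b_x = axis_b[, 1L], axis_b_y = axis_b[, 2L], axis_b_z = axis_b[, 3L],
    ridge_tangent_x = tangents[, 1L], ridge_tangent_y = tangents[, 2L],
    ridge_tangent_z = tangents[, 3L],
    normal_x = normals[, 1L], normal_y = normals[, 2L], normal_z = normals[, 3L]
  )
  structure(out,
    ridge_polyline = polyline,
    class = c("dimer_row", class(out))
  )
}

#' Simulate a population of jittered dimer poses
#'
#' Convenience wrapper that builds as many ridge rows (on fresh crista
#' meshes) as needed to reach `n_poses` dimers, with per-row derived
#' seeds, and binds them into one pose table. Used for angle-recovery
#' experiments where hundreds of poses are required.
#'
#' @param preset A [species_preset()] (or preset name).
#' @param n_poses Total number of dimer poses wanted.
#' @param jitter_deg,jitter_nm Jitter SDs passed to [place_dimer_row()].
#' @param seed Integer seed.
#' @param dimers_per_row Dimers per ridge row.
#' @param mesh_step_nm Mesh step for the carrier meshes (the mesh only
#'   supplies the ridge polyline here, so a coarse step is fine).
#'
#' @return A `dimer_row` tibble with `n_poses` rows.
#' @export
#' @examples
#' poses <- simulate_dimer_poses(get_preset("celegans"), 50, jitter_deg = 5, seed = 1)
#' mean(dimer_angle(poses))
simulate_dimer_poses <- function(preset, n_poses, jitter_deg = 0, jitter_nm = 0,
                                 seed = 1, dimers_per_row = 25, mesh_step_nm = 5) {
  preset <- as_preset(preset)
  n_poses <- check_count(n_poses, "n_poses")
  dimers_per_row <- check_count(dimers_per_row, "dimers_per_row")
  seed <- check_seed(seed)
  extent <- (dimers_per_row + 1) * preset$inter_dimer_nm
  extent <- max(extent, preset$crista_width_nm * 2)
  mesh <- make_crista_mesh(preset, face_extent_nm = extent,
                           mesh_step_nm = mesh_step_nm)
  n_rows <- ceiling(n_poses / dimers_per_row)
  sizes <- rep(dimers_per_row, n_rows)
  sizes[n_rows] <- n_poses - (n_rows - 1L) * dimers_per_row
  if (n_rows > 1L && sizes[n_rows] == 1L) {
    # Avoid a single-dimer trailing row (row metrics need pairs).
    sizes[n_rows - 1L] <- sizes[n_rows - 1L] - 1L
    sizes[n_rows] <- 2L
  }
  rows <- purrr::map(seq_len(n_rows), function(k) {
    n_k <- sizes[k]
    place_dimer_row(mesh, preset, n_k, jitter_deg = jitter_deg,
                    jitter_nm = jitter_nm, seed = derive_seed(seed, k),
                    row_id = sprintf("row_%03d", k),
                    crista_id = sprintf("%s_%03d", preset$name, k))
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    ridge_polyline = attr(rows[[1L]], "ridge_polyline"),
    class = c("dimer_row", class(tibble::tibble()))
  )
}
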