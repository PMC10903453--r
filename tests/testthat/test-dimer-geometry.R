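# Construct a minimal pose table by hand.
pose_row <- function(axis_a, axis_b, base_a = c(0, 0, 0), base_b = c(0, 0, 0),
                     normal = c(0, 0, 1), tangent = c(1, 0, 0)) {
  tibble::tibble(
    crista_id = "c", row_id = "r", dimer_id = 1L,
    centre_x = (base_a[1] + base_b[1]) / 2,
    centre_y = (base_a[2] + base_b[2]) / 2,
    centre_z = (base_a[3] + base_b[3]) / 2,
    base_a_x = base_a[1], base_a_y = base_a[2], base_a_z = base_a[3],
    base_b_x = base_b[1], base_b_y = base_b[2], base_b_z = base_b[3],
    axis_a_x = axis_a[1], axis_a_y = axis_a[2], axis_a_z = axis_a[3],
    axis_b_x = axis_b[1], axis_b_y = axis_b[2], axis_b_z = axis_b[3],
    ridge_tangent_x = tangent[1], ridge_tangent_y = tangent[2],
    ridge_tangent_z = tangent[3],
    normal_x = normal[1], normal_y = normal[2], normal_z = normal[3]
  )
}

test_that("dimer_angle handles parallel, orthogonal and degenerate axes", {
  expect_equal(dimer_angle(pose_row(c(0, 0, 1), c(0, 0, 1))), 0)
  expect_equal(dimer_angle(pose_row(c(0, 0, 1), c(1, 0, 0))), 90)
  expect_error(dimer_angle(pose_row(c(0, 0, 0), c(1, 0, 0))),
               class = "cristamorph_geometry_error")
})

test_that("dimer_angle is exactly symmetric under swapping the monomers", {
  a <- c(0.3, -0.4, sqrt(1 - 0.25))
  b <- c(-0.1, 0.7, sqrt(1 - 0.5))
  expect_identical(dimer_angle(pose_row(a, b)), dimer_angle(pose_row(b, a)))
})

test_that("stalk_separation is the base-point distance", {
  p <- pose_row(c(0, 0, 1), c(0, 0, 1), base_a = c(0, 0, 0), base_b = c(0, 16.5, 0))
  expect_equal(stalk_separation(p), 16.5)
  p0 <- pose_row(c(0, 0, 1), c(0, 0, 1), base_a = c(1, 2, 3), base_b = c(1, 2, 3))
  expect_equal(stalk_separation(p0), 0)
})

test_that("noiseless poses recover the preset stalk separations exactly", {
  m <- make_crista_mesh("celegans", 60, mesh_step_nm = 2)
  expect_equal(stalk_separation(place_dimer_row(m, "celegans", 1, seed = 1)),
               16.5, tolerance = 1e-9)
  m2 <- make_crista_mesh("scerevisiae", 60, mesh_step_nm = 2)
  expect_equal(stalk_separation(place_dimer_row(m2, "scerevisiae", 1, seed = 1)),
               20, tolerance = 1e-9)
})

test_that("all dimer metrics are invariant under rigid motions", {
  m <- make_crista_mesh("celegans", 80, mesh_step_nm = 1)
  row <- place_dimer_row(m, "celegans", 5, jitter_deg = 4, jitter_nm = 0.5, seed = 3)
  rt <- random_rigid(17)
  row_t <- transform_poses(row, rt$rotation, rt$translation)
  expect_equal(dimer_angle(row_t), dimer_angle(row), tolerance = 1e-6)
  expect_equal(stalk_separation(row_t), stalk_separation(row), tolerance = 1e-6)
  rm0 <- row_metrics(row)
  rm1 <- row_metrics(row_t)
  expect_equal(rm1$inter_dimer_nm, rm0$inter_dimer_nm, tolerance = 1e-6)
  expect_equal(rm1$yaw_offset_deg, rm0$yaw_offset_deg, tolerance = 1e-6)

  m_t <- transform_mesh(m, rt$rotation, rt$translation)
  expect_equal(membrane_wedge_angle(m_t), membrane_wedge_angle(m), tolerance = 1e-6)
})

test_that("membrane_wedge_angle reports 180 for a flat membrane", {
  pm <- plane_mesh(half = 12, n = 24)
  ang <- membrane_wedge_angle(pm, ridge_point = c(0, 0, 0),
                              ridge_tangent = c(0, 1, 0),
                              probe_inner_nm = 2, probe_outer_nm = 8)
  expect_equal(ang, 180, tolerance = 0.5)
})

test_that("membrane_wedge_angle recovers a constructed 90-degree wedge", {
  wm <- wedge_mesh(90, length = 30, flank = 20, n = 30)
  ang <- membrane_wedge_angle(wm, ridge_point = c(0, 0, 0),
                              ridge_tangent = c(0, 1, 0),
                              probe_inner_nm = 3, probe_outer_nm = 10)
  expect_equal(ang, 90, tolerance = 0.5)
})

test_that("membrane_wedge_angle recovers the species wedge angles on noiseless meshes", {
  worm <- make_crista_mesh("celegans", 100, 2, 1)
  yeast <- make_crista_mesh("scerevisiae", 100, 2, 1)
  expect_equal(membrane_wedge_angle(worm), 50, tolerance = 1)
  expect_equal(membrane_wedge_angle(yeast), 74, tolerance = 1)
})

test_that("membrane_wedge_angle fails cleanly with insufficient flank support", {
  wm <- wedge_mesh(90, length = 30, flank = 20, n = 30)
  expect_error(
    membrane_wedge_angle(wm, ridge_point = c(0, 0, 0), ridge_tangent = c(0, 1, 0),
                         probe_inner_nm = 0.001, probe_outer_nm = 0.002),
    class = "cristamorph_support_error"
  )
})

test_that("row metrics require pairs and handle simple two-dimer rows", {
  p1 <- pose_row(c(0, 0, 1), c(0, 0, 1), base_a = c(-1, 0, 0), base_b = c(1, 0, 0))
  expect_error(row_metrics(p1), class = "cristamorph_parameter_error")
  p2 <- p1
  p2$dimer_id <- 2L
  for (col in c("centre_y", "base_a_y", "base_b_y")) p2[[col]] <- p2[[col]] + 10
  two <- dplyr::bind_rows(p1, p2)
  rm <- row_metrics(two)
  expect_equal(rm$inter_dimer_nm, 10)
  expect_equal(rm$yaw_offset_deg, 0)
})

test_that("measure_dimers summarises scenes and tolerates missing meshes", {
  m <- make_crista_mesh("celegans", 150, mesh_step_nm = 2)
  rows <- dplyr::bind_rows(purrr::map(1:3, function(k) {
    place_dimer_row(m, "celegans", 10, jitter_deg = 5, seed = 30 + k,
                    row_id = paste0("row_", k))
  }))
  meas <- measure_dimers(rows, mesh = m)
  expect_equal(nrow(meas$per_dimer), 30L)
  expect_equal(nrow(meas$per_row), 3L)
  expect_equal(meas$summary$dimer_angle_mean_deg, 105, tolerance = 2.5)
  expect_false(is.na(meas$wedge_angle_deg))

  no_mesh <- measure_dimers(rows)
  expect_true(is.na(no_mesh$wedge_angle_deg))
  expect_equal(nrow(no_mesh$per_dimer), 30L)

  expect_warning(empty <- measure_dimers(tibble::tibble()), "empty")
  expect_equal(nrow(empty$per_dimer), 0L)
})

test_that("per-row summaries of mixed presets match independent brute-force means", {
  m <- make_crista_mesh("celegans", 120, mesh_step_nm = 2)
  worm_row <- place_dimer_row(m, "celegans", 6, jitter_deg = 3, seed = 1, row_id = "worm")
  yeast_row <- place_dimer_row(m, "scerevisiae", 6, jitter_deg = 3, seed = 2, row_id = "yeast")
  mixed <- dplyr::bind_rows(worm_row, yeast_row)
  meas <- measure_dimers(mixed)

  # Independent oracle: mean of acos of dot products, computed directly.
  brute <- function(tab) {
    a <- as.matrix(tab[c("axis_a_x", "axis_a_y", "axis_a_z")])
    b <- as.matrix(tab[c("axis_b_x", "axis_b_y", "axis_b_z")])
    mean(acos(pmin(1, pmax(-1, rowSums(a * b)))) * 180 / pi)
  }
  by_row <- meas$per_dimer |>
    dplyr::group_by(row_id) |>
    dplyr::summarise(mean_angle = mean(dimer_angle_deg))
  expect_equal(by_row$mean_angle[by_row$row_id == "worm"], brute(worm_row), tolerance = 1e-9)
  expect_equal(by_row$mean_angle[by_row$row_id == "yeast"], brute(yeast_row), tolerance = 1e-9)
  expect_gt(by_row$mean_angle[by_row$row_id == "worm"],
            by_row$mean_angle[by_row$row_id == "yeast"])
})
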