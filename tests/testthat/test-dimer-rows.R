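worm_mesh <- make_crista_mesh("celegans", face_extent_nm = 80, mesh_step_nm = 2)

test_that("a noiseless dimer reproduces the preset geometry exactly", {
  row <- place_dimer_row(worm_mesh, "celegans", n_dimers = 1, seed = 1)
  expect_equal(nrow(row), 1L)
  expect_equal(dimer_angle(row), 105, tolerance = 1e-12)
  expect_equal(stalk_separation(row), 16.5, tolerance = 1e-12)
  # Axes are unit length and the local frame is orthogonal.
  expect_equal(sqrt(sum(c(row$axis_a_x, row$axis_a_y, row$axis_a_z)^2)), 1,
               tolerance = 1e-9)
  expect_lt(abs(row$ridge_tangent_x * row$normal_x +
                  row$ridge_tangent_y * row$normal_y +
                  row$ridge_tangent_z * row$normal_z), 1e-6)
})

test_that("noiseless rows have exact regular spacing and yaw", {
  row <- place_dimer_row(worm_mesh, "celegans", n_dimers = 5, seed = 1)
  ctr <- as.matrix(row[c("centre_x", "centre_y", "centre_z")])
  spacing <- sqrt(rowSums(diff(ctr)^2))
  expect_equal(spacing, rep(12.5, 4), tolerance = 1e-9)
  rm <- row_metrics(row)
  expect_equal(rm$inter_dimer_nm, 12.5, tolerance = 1e-9)
  expect_equal(rm$yaw_offset_deg, 20, tolerance = 1e-9)
  expect_equal(rm$n_pairs, 4L)
})

test_that("the same seed reproduces a jittered row bitwise", {
  r1 <- place_dimer_row(worm_mesh, "celegans", 6, jitter_deg = 5, jitter_nm = 1, seed = 99)
  r2 <- place_dimer_row(worm_mesh, "celegans", 6, jitter_deg = 5, jitter_nm = 1, seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- place_dimer_row(worm_mesh, "celegans", 6, jitter_deg = 5, jitter_nm = 1, seed = 100)
  expect_false(identical(r1$axis_a_x, r3$axis_a_x))
})

test_that("rows longer than the ridge are rejected with the maximum count", {
  err <- expect_error(
    place_dimer_row(worm_mesh, "celegans", n_dimers = 50, seed = 1),
    class = "cristamorph_parameter_error"
  )
  # 80 nm ridge at 12.5 nm spacing holds at most 7 dimers.
  expect_match(conditionMessage(err), "maximum n_dimers = 7")
  expect_no_error(place_dimer_row(worm_mesh, "celegans", n_dimers = 7, seed = 1))
})

test_that("measured dimer-angle spread follows the sqrt(2) jitter law", {
  sigma <- 6
  poses <- simulate_dimer_poses("celegans", 400, jitter_deg = sigma, seed = 5)
  s <- sd(dimer_angle(poses))
  # Each axis is perturbed independently, so the angle SD tends to sigma*sqrt(2).
  expect_equal(s, sigma * sqrt(2), tolerance = 0.12)
})

test_that("angular jitter leaves the mean dimer angle centred on the preset", {
  poses <- simulate_dimer_poses("scerevisiae", 300, jitter_deg = 5, seed = 8)
  expect_equal(mean(dimer_angle(poses)), 86, tolerance = 0.02)
})
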