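test_that("generated crista meshes satisfy the mesh invariants", {
  for (sp in c("celegans", "scerevisiae")) {
    for (step in c(1, 3)) {
      m <- make_crista_mesh(sp, face_extent_nm = 60, apex_radius_nm = 2,
                            mesh_step_nm = step)
      expect_true(is_watertight(m))
      expect_no_error(validate_mesh(m))
      expect_gt(enclosed_volume(m), 0)
      expect_false(is.null(m$provenance$ridge_polyline))
    }
  }
})

test_that("a 180-degree wedge gives a rounded slab with the preset width", {
  flat <- species_preset("flat", 105, 180, 16.5, 12.5, 20, 20)
  m <- make_crista_mesh(flat, face_extent_nm = 100, apex_radius_nm = 2,
                        mesh_step_nm = 2)
  expect_no_error(validate_mesh(m))
  w <- crista_width(m, n_samples = 25, seed = 1)
  expect_equal(unname(w), rep(20, length(w)), tolerance = 1e-6)
})

test_that("inconsistent generator dimensions raise parameter errors", {
  expect_error(make_crista_mesh("celegans", face_extent_nm = 100, mesh_step_nm = 0),
               class = "cristamorph_parameter_error")
  expect_error(make_crista_mesh("celegans", face_extent_nm = 10),
               class = "cristamorph_parameter_error")  # extent < width
  expect_error(make_crista_mesh("celegans", face_extent_nm = 100, apex_radius_nm = 10),
               class = "cristamorph_parameter_error")  # fillet >= width/2
})

test_that("mesh generation is deterministic and populations reproduce under seed", {
  p1 <- make_population("celegans", 4, extent_mean_nm = 80, extent_sd_nm = 10,
                        width_sd_nm = 2, seed = 42, mesh_step_nm = 4)
  p2 <- make_population("celegans", 4, extent_mean_nm = 80, extent_sd_nm = 10,
                        width_sd_nm = 2, seed = 42, mesh_step_nm = 4)
  expect_identical(purrr::map(p1, "vertices"), purrr::map(p2, "vertices"))
  p3 <- make_population("celegans", 4, extent_mean_nm = 80, extent_sd_nm = 10,
                        width_sd_nm = 2, seed = 43, mesh_step_nm = 4)
  expect_false(identical(p1[[1]]$vertices, p3[[1]]$vertices))
})

test_that("population dimensions follow the truncated Gaussian model", {
  pop <- make_population("celegans", 30, extent_mean_nm = 100, extent_sd_nm = 40,
                         width_sd_nm = 8, seed = 7, mesh_step_nm = 5)
  expect_length(pop, 30)
  extents <- purrr::map_dbl(pop, ~ .x$provenance$face_extent_nm)
  widths <- purrr::map_dbl(pop, ~ .x$provenance$width_nm)
  # Truncation at 50% of the mean keeps all dimensions in [0.5, 1.5] x mean.
  expect_true(all(extents >= 50 & extents <= 150))
  expect_true(all(widths >= 10 & widths <= 30))
  expect_true(all(purrr::map_lgl(pop, is_watertight)))
})

test_that("zero-SD populations are congruent and n_cristae is validated", {
  pop <- make_population("celegans", 3, extent_mean_nm = 60, extent_sd_nm = 0,
                         width_sd_nm = 0, seed = 1, mesh_step_nm = 4)
  expect_identical(pop[[1]]$vertices, pop[[2]]$vertices)
  expect_identical(pop[[2]]$vertices, pop[[3]]$vertices)
  expect_error(make_population("celegans", 0, seed = 1),
               class = "cristamorph_parameter_error")
})
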