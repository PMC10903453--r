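test_that("surface area and enclosed volume match the analytic cube", {
  cube <- cube_mesh(1)
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)
  far <- cube_mesh(1, centre = c(1000, 1000, 1000))
  expect_equal(enclosed_volume(far), 1, tolerance = 1e-9)
})

test_that("surface area and enclosed volume match the analytic sphere", {
  s <- icosphere(10, subdiv = 4)
  expect_equal(surface_area(s), 4 * pi * 100, tolerance = 0.005)
  expect_equal(enclosed_volume(s), 4 / 3 * pi * 1000, tolerance = 0.01)
})

test_that("area, volume, SA:V and widths follow the uniform scaling laws", {
  base <- icosphere(8, subdiv = 3)
  a0 <- surface_area(base)
  v0 <- enclosed_volume(base)
  w0 <- mean(crista_width(base, 20, seed = 1))
  for (s in c(0.5, 3)) {
    scaled <- tri_mesh(base$vertices * s, base$faces)
    expect_equal(surface_area(scaled), a0 * s^2, tolerance = 1e-9)
    expect_equal(enclosed_volume(scaled), v0 * s^3, tolerance = 1e-9)
    expect_equal(surface_area(scaled) / enclosed_volume(scaled), (a0 / v0) / s,
                 tolerance = 1e-9)
    ws <- mean(crista_width(scaled, 20, seed = 1))
    expect_equal(ws, w0 * s, tolerance = 1e-9)
  }
})

test_that("non-watertight and inward-oriented meshes are rejected informatively", {
  cube <- cube_mesh(1)
  holed <- tri_mesh(cube$vertices, cube$faces[-1, ])
  err <- expect_error(enclosed_volume(holed), class = "cristamorph_geometry_error")
  expect_match(conditionMessage(err), "3 open")
  flipped <- tri_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_error(enclosed_volume(flipped), class = "cristamorph_geometry_error",
               regexp = "flip")
})

test_that("width sampling returns the slab thickness and the sphere diameter", {
  slab <- slab_mesh(100, 100, 20, n = 12)
  w <- crista_width(slab, n_samples = 40, seed = 2)
  # Samples on the thin side walls see the 100 nm span; the dominant faces
  # see the 20 nm thickness. Check the face samples.
  expect_gt(mean(w < 50), 0.6)
  expect_equal(unname(stats::median(w)), 20, tolerance = 0.005)

  s <- icosphere(20, subdiv = 3)
  ws <- crista_width(s, n_samples = 25, seed = 3, exclusion_nm = 0)
  expect_equal(mean(ws), 40, tolerance = 0.02)
})

test_that("width sampling on a slab is unbiased in the sample count", {
  slab <- slab_mesh(100, 100, 20, n = 12)
  m1 <- stats::median(crista_width(slab, 15, seed = 4))
  m2 <- stats::median(crista_width(slab, 60, seed = 5))
  expect_equal(m1, m2, tolerance = 0.005)
})

test_that("slab-limit SA:V approaches 2/width and population ratios invert widths", {
  # Generated cristae at large extent behave as slabs: SA:V ~ 2/w.
  m_worm <- make_crista_mesh("celegans", 400, mesh_step_nm = 5)
  m_yeast <- make_crista_mesh("scerevisiae", 400, mesh_step_nm = 5)
  sav_w <- surface_area(m_worm) / enclosed_volume(m_worm)
  sav_y <- surface_area(m_yeast) / enclosed_volume(m_yeast)
  expect_equal(sav_w, 2 / 20, tolerance = 0.1)
  expect_equal(sav_y, 2 / 30, tolerance = 0.1)
  # The SA:V ratio tracks the inverse width ratio (1.5 in the slab limit).
  expect_equal(sav_w / sav_y, 1.5, tolerance = 0.07)

  w_ratio <- mean(crista_width(m_worm, 25, seed = 6)) /
    mean(crista_width(m_yeast, 25, seed = 7))
  expect_equal(w_ratio, 1 / 1.5, tolerance = 0.02)
})

test_that("morphometrics produces one record per crista and isolates failures", {
  pop <- make_population("celegans", 3, extent_mean_nm = 70, extent_sd_nm = 5,
                         seed = 9, mesh_step_nm = 4)
  tab <- morphometrics(pop, n_width_samples = 8, seed = 1)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$sa_to_v_per_nm, tab$surface_area_nm2 / tab$volume_nm3)
  expect_true(all(tab$volume_nm3 > 0))
  expect_true(all(unlist(tab$widths) > 0))

  cube <- cube_mesh(1)
  rec <- morphometrics(list(cube), n_width_samples = 5, seed = 1)
  expect_equal(rec$sa_to_v_per_nm, 6)

  broken <- tri_mesh(cube$vertices, cube$faces[-1, ])
  expect_warning(
    mixed <- morphometrics(list(pop[[1]], broken, pop[[2]]), n_width_samples = 5, seed = 1),
    "failed"
  )
  expect_equal(nrow(mixed), 2L)
  expect_length(attr(mixed, "errors"), 1L)
})

test_that("morphometrics is deterministic under seed", {
  pop <- make_population("celegans", 2, extent_mean_nm = 70, extent_sd_nm = 5,
                         seed = 10, mesh_step_nm = 4)
  t1 <- morphometrics(pop, n_width_samples = 6, seed = 5)
  t2 <- morphometrics(pop, n_width_samples = 6, seed = 5)
  expect_identical(t1$widths, t2$widths)
})
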