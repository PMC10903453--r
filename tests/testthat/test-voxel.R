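test_that("voxelisation of a box recovers the analytic interior count", {
  box <- box_mesh(20, 20, 20)
  vol <- voxelize(box, voxel_nm = 1)
  n_inside <- sum(vol$grid > 0)
  expect_equal(n_inside, 8000, tolerance = 0.05)
  expect_equal(n_inside * vol$voxel_nm^3, enclosed_volume(box), tolerance = 0.05)
})

test_that("voxelisation of a sphere matches the analytic volume within 5%", {
  s <- icosphere(20, subdiv = 3)
  vol <- voxelize(s, voxel_nm = 1)
  expect_equal(sum(vol$grid > 0) * 1, 4 / 3 * pi * 20^3, tolerance = 0.05)
})

test_that("voxelize validates its inputs", {
  box <- box_mesh(20, 20, 20)
  expect_error(voxelize(box, voxel_nm = 0), class = "cristamorph_parameter_error")
  expect_error(voxelize(box, voxel_nm = 100), class = "cristamorph_parameter_error")
  holed <- tri_mesh(box$vertices, box$faces[-1, ])
  expect_error(voxelize(holed, voxel_nm = 1), class = "cristamorph_geometry_error")
})

test_that("volume morphometrics agree with closed forms and the mesh route", {
  # Sphere: SA:V should be within 10% of 3/r with the refined estimator.
  s <- icosphere(20, subdiv = 3)
  vol <- voxelize(s, voxel_nm = 1)
  rec <- volume_morphometrics(vol)
  expect_equal(rec$sa_to_v_per_nm, 3 / 20, tolerance = 0.10)

  # Box at 1 nm voxels.
  box <- box_mesh(20, 20, 20)
  recb <- volume_morphometrics(voxelize(box, voxel_nm = 1))
  expect_equal(recb$volume_nm3, 8000, tolerance = 0.05)

  # Crista mesh: voxel route within 10% of the mesh route at voxel <= width/10.
  m <- make_crista_mesh("celegans", 50, mesh_step_nm = 2)
  recm <- volume_morphometrics(voxelize(m, voxel_nm = 2))
  expect_equal(recm$volume_nm3, enclosed_volume(m), tolerance = 0.10)
  expect_equal(recm$sa_to_v_per_nm, surface_area(m) / enclosed_volume(m),
               tolerance = 0.10)
})

test_that("raw face counting overestimates curved surfaces as expected", {
  s <- icosphere(20, subdiv = 3)
  vol <- voxelize(s, voxel_nm = 1)
  raw <- volume_morphometrics(vol, method = "face_count")
  refined <- volume_morphometrics(vol)
  # The staircase overcount of a smooth surface is ~1.5x.
  expect_gt(raw$surface_area_nm2 / (4 * pi * 400), 1.3)
  expect_lt(abs(refined$surface_area_nm2 / (4 * pi * 400) - 1), 0.10)
})

test_that("label volumes without crista labels are rejected", {
  lv <- label_volume(array(0L, c(4, 4, 4)), voxel_nm = 1)
  expect_error(volume_morphometrics(lv), class = "cristamorph_parameter_error")
})
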