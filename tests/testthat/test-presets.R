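test_that("packaged presets carry the reported dimer and membrane geometry", {
  worm <- get_preset("celegans")
  expect_equal(worm$dimer_angle_deg, 105)
  expect_equal(worm$wedge_angle_deg, 50)
  expect_equal(worm$stalk_sep_nm, 16.5)
  expect_equal(worm$inter_dimer_nm, 12.5)
  expect_equal(worm$yaw_offset_deg, 20)

  yeast <- get_preset("scerevisiae")
  expect_equal(yeast$dimer_angle_deg, 86)
  expect_equal(yeast$wedge_angle_deg, 74)
  expect_equal(yeast$stalk_sep_nm, 20)

  # Width calibration: yeast = 1.5x worm so the slab-limit SA:V ratio is 1.5.
  expect_equal(yeast$crista_width_nm / worm$crista_width_nm, 1.5)

  tab <- species_presets()
  expect_s3_class(tab, "tbl_df")
  expect_setequal(tab$name, c("celegans", "scerevisiae"))
})

test_that("preset invariants are enforced", {
  expect_error(species_preset("bad", 0, 50, 16.5, 12.5, 20, 20),
               class = "cristamorph_parameter_error")
  expect_error(species_preset("bad", 181, 50, 16.5, 12.5, 20, 20),
               class = "cristamorph_parameter_error")
  expect_error(species_preset("bad", 105, 0, 16.5, 12.5, 20, 20),
               class = "cristamorph_parameter_error")
  expect_error(species_preset("bad", 105, 50, -1, 12.5, 20, 20),
               class = "cristamorph_parameter_error")
  expect_error(species_preset("bad", 105, 50, 16.5, 12.5, 20, 0),
               class = "cristamorph_parameter_error")
  # 180 degrees (flat) is an allowed wedge angle.
  expect_s3_class(species_preset("flat", 105, 180, 16.5, 12.5, 20, 20),
                  "species_preset")
  expect_error(get_preset("axolotl"), class = "cristamorph_parameter_error")
})

test_that("the dimer-angle catalogue includes the cross-species reference values", {
  cat <- dimer_angle_catalogue()
  expect_equal(cat$dimer_angle_deg[cat$species == "potato"], 120)
  bov <- cat[cat$species == "bovine", ]
  expect_equal(c(bov$angle_min_deg, bov$angle_max_deg), c(76, 95))
})
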