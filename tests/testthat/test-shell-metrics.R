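test_that("mean_attenuation is the arithmetic mean over the mask", {
  vol <- ct_volume(array(-400, c(6, 6, 6)))
  all_mask <- voxel_mask(array(TRUE, c(6, 6, 6)))
  expect_equal(mean_attenuation(vol, all_mask), -400)

  two <- ct_volume(array(c(-1000, 0), c(2, 1, 1)))
  expect_equal(mean_attenuation(two, voxel_mask(array(TRUE, c(2, 1, 1)))), -500)

  set.seed(5)
  v <- ct_volume(array(runif(1000, -1000, 0), c(10, 10, 10)))
  m <- voxel_mask(array(runif(1000) < 0.4, c(10, 10, 10)))
  expect_equal(mean_attenuation(v, m),
               sum(v$data[m$data]) / sum(m$data), tolerance = 1e-9)
  expect_error(mean_attenuation(v, voxel_mask(array(FALSE, c(10, 10, 10)))),
               "empty")
})

test_that("normalized PBA follows 1 - (PBA/TLA) exactly", {
  expect_equal(normalized_pba(-420, -500), 0.16, tolerance = 1e-12)
  expect_equal(normalized_pba(-500, -500), 0)
  expect_error(normalized_pba(-400, 0), "zero")
})

test_that("image normalization has the right fixed points and commutes with masking", {
  vol <- ct_volume(array(c(-500, 0, -250), c(3, 1, 1)))
  norm <- normalize_image(vol, -500)
  expect_equal(norm$data[1, 1, 1], 0, tolerance = 1e-12)   # x = TLA
  expect_equal(norm$data[2, 1, 1], 1, tolerance = 1e-12)   # x = 0
  expect_false(norm$hu_calibrated)
  expect_error(normalize_image(vol, 0), "zero")

  # shell mean of the normalized image equals normalized_pba(PBA, TLA)
  ph <- generate_phantom(tube_phantom_spec(noise_sd_hu = 20))
  lum <- segment_lumen(ph$volume, matrix(ph$truth$seed_lumen, 1))
  shell <- peribronchial_shell(ph$volume, lum,
                               exclusion = ph$truth$trachea_exclusion_mask)
  lung <- segment_lung(ph$volume, matrix(ph$truth$seed_lung, 1))
  tla <- mean_attenuation(ph$volume, lung)
  pba <- mean_attenuation(ph$volume, shell)
  expect_equal(mean_attenuation(normalize_image(ph$volume, tla), shell),
               normalized_pba(pba, tla), tolerance = 1e-9)
})

test_that("the shell equals the truth-mask geometric oracle on a noise-free tube", {
  ph <- generate_phantom(tube_phantom_spec())
  shell <- peribronchial_shell(ph$volume, ph$truth$lumen_mask,
                               dilation_radius_voxels = 8,
                               exclusion = ph$truth$trachea_exclusion_mask)
  expect_identical(shell$data, ph$truth$shell_oracle_mask$data)
  expect_equal(attr(shell, "dilation_radius_voxels"), 8)
})

test_that("shell construction enforces its contracts", {
  ph <- generate_phantom(tube_phantom_spec())
  # degenerate: lumen covering the whole volume leaves nothing to keep
  whole <- voxel_mask(array(TRUE, dim(ph$volume$data)))
  vol_air <- ct_volume(array(-1000, dim(ph$volume$data)))
  expect_error(peribronchial_shell(vol_air, whole), "empty")
  # exclusion contract: no shell voxel inside the exclusion mask
  shell <- peribronchial_shell(ph$volume, ph$truth$lumen_mask,
                               exclusion = ph$truth$trachea_exclusion_mask)
  expect_false(any(shell$data & ph$truth$trachea_exclusion_mask$data))
  # the shell never contains lumen-band voxels and stays inside the dilation
  expect_false(any(shell$data &
                     (ph$volume$data >= -1024 & ph$volume$data <= -900)))
  dil <- dilate_mask(ph$truth$lumen_mask, 8)
  expect_true(all(!shell$data | dil$data))
})

test_that("PBA recovers the wall attenuation exactly when the shell is all wall", {
  # wall thicker than the dilation radius: a single straight tube whose shell
  # is pure wall (no trachea exclusion here, or nothing would remain)
  spec <- phantom_spec(grid_shape = c(112, 112, 112), tree_depth = 1,
                       root_radius_voxels = 3, wall_thickness_voxels = 9,
                       noise_sd_hu = 0, include_standards = FALSE)
  ph <- generate_phantom(spec)
  shell <- peribronchial_shell(ph$volume, ph$truth$lumen_mask,
                               dilation_radius_voxels = 8)
  expect_true(all(ph$truth$wall_mask$data[shell$data]))
  expect_equal(mean_attenuation(ph$volume, shell), spec$wall_hu)
})

test_that("PBA and normalized PBA increase strictly with wall attenuation", {
  res <- sapply(c(-450, -300, -200), function(whu) {
    ph <- generate_phantom(tube_phantom_spec(wall_hu = whu))
    s <- summarize_attenuation(
      ph$volume,
      segment_lung(ph$volume, matrix(ph$truth$seed_lung, 1)),
      peribronchial_shell(ph$volume, ph$truth$lumen_mask,
                          exclusion = ph$truth$trachea_exclusion_mask))
    c(s$pba_hu, s$normalized_pba)
  })
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("summarize_attenuation is internally consistent and matches the phantom oracle", {
  ph <- generate_phantom(tube_phantom_spec())
  lung <- segment_lung(ph$volume, matrix(ph$truth$seed_lung, 1))
  shell <- peribronchial_shell(ph$volume, ph$truth$lumen_mask,
                               exclusion = ph$truth$trachea_exclusion_mask)
  s <- summarize_attenuation(ph$volume, lung, shell)
  expect_equal(s$normalized_pba, 1 - s$pba_hu / s$tla_hu, tolerance = 1e-12)
  expect_equal(s$pba_hu, ph$truth$expected_pba_hu, tolerance = 1e-9)
  expect_equal(s$tla_hu, ph$truth$expected_tla_hu, tolerance = 1e-9)
  expect_equal(s$lung_voxels, voxel_count(lung))
  # lung mask used as shell: PBA = TLA so the normalized statistic vanishes
  same <- summarize_attenuation(ph$volume, lung, lung)
  expect_equal(same$normalized_pba, 0)
})
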