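test_that("an all-in-band volume grows to the full grid from one seed", {
  vol <- ct_volume(array(-1000, c(5, 5, 5)))
  mask <- grow_region(vol, c(3, 3, 3), c(-1024, -900))
  expect_equal(voxel_count(mask), 125)
})

test_that("out-of-band and out-of-bounds seeds are rejected with context", {
  vol <- ct_volume(array(-1000, c(5, 5, 5)))
  expect_error(grow_region(vol, c(3, 3, 3), c(-900, -100)),
               "-1000.*outside band")
  expect_error(grow_region(vol, c(9, 3, 3), c(-1024, -900)), "bounds")
  expect_error(grow_region(vol, matrix(numeric(0), 0, 3), c(-1024, -900)),
               "seeds")
})

test_that("grow_region matches a breadth-first flood-fill oracle on random volumes", {
  set.seed(7)
  for (i in 1:12) {
    d <- sample(6:12, 3, replace = TRUE)
    vals <- array(sample(c(-1000, -500), prod(d), replace = TRUE,
                         prob = c(0.6, 0.4)), d)
    vol <- ct_volume(vals)
    in_air <- which(vals == -1000, arr.ind = TRUE)
    seed <- in_air[sample(nrow(in_air), 1), , drop = FALSE]
    for (conn in c("face6", "full26")) {
      got <- grow_region(vol, seed, c(-1024, -900), conn)
      want <- flood_fill_oracle(vals >= -1024 & vals <= -900, seed, conn)
      expect_identical(got$data, want)
    }
  }
})

test_that("grown regions sit between the seed set and the in-band set, and face6 is within full26", {
  set.seed(8)
  for (i in 1:8) {
    d <- c(10, 10, 10)
    vals <- array(sample(c(-1000, -500), prod(d), replace = TRUE), d)
    vol <- ct_volume(vals)
    in_air <- which(vals == -1000, arr.ind = TRUE)
    seeds <- in_air[sample(nrow(in_air), 2), , drop = FALSE]
    m6 <- grow_region(vol, seeds, c(-1024, -900), "face6")
    m26 <- grow_region(vol, seeds, c(-1024, -900), "full26")
    inband <- vals >= -1024 & vals <= -900
    expect_true(all(m6$data[seeds]))                # superset of seeds
    expect_true(all(!m6$data | inband))             # subset of in-band set
    expect_true(all(!m6$data | m26$data))           # face6 within full26
    # idempotence: re-growing a single component from any of its own voxels
    # reproduces that component
    one <- grow_region(vol, seeds[1, , drop = FALSE], c(-1024, -900), "face6")
    out_vox <- which(one$data, arr.ind = TRUE)
    reseed <- out_vox[sample(nrow(out_vox), 1), , drop = FALSE]
    expect_identical(grow_region(vol, reseed, c(-1024, -900), "face6")$data,
                     one$data)
  }
})

test_that("lumen segmentation recovers the phantom tube exactly and excludes the wall", {
  ph <- generate_phantom(tube_phantom_spec())
  lum <- segment_lumen(ph$volume, matrix(ph$truth$seed_lumen, 1))
  expect_identical(lum$data, ph$truth$lumen_mask$data)
  expect_false(any(lum$data & ph$truth$wall_mask$data))
  expect_equal(attr(lum, "band"), c(-1024, -900))
})

test_that("lung segmentation collects wall and parenchyma but not lumen or body", {
  ph <- generate_phantom(tube_phantom_spec())
  lung <- segment_lung(ph$volume, matrix(ph$truth$seed_lung, 1))
  expect_equal(attr(lung, "band"), c(-900, -100))
  expect_true(all(lung$data[ph$truth$parenchyma_mask$data]))
  expect_true(all(lung$data[ph$truth$wall_mask$data]))
  expect_false(any(lung$data & ph$truth$lumen_mask$data))
  expect_false(any(lung$data & ph$truth$body_mask$data))
})

test_that("two disconnected components are segmented as the union of their seeds' growths", {
  vals <- array(0, c(12, 12, 12))
  vals[2:4, 2:4, 2:4] <- -550
  vals[8:10, 8:10, 8:10] <- -550
  vol <- ct_volume(vals)
  both <- segment_lung(vol, rbind(c(3, 3, 3), c(9, 9, 9)))
  expect_equal(voxel_count(both), 54)
  one <- segment_lung(vol, matrix(c(3, 3, 3), 1))
  expect_equal(voxel_count(one), 27)
})

test_that("segmentation refuses uncalibrated volumes", {
  raw <- ct_volume(array(-1000, c(4, 4, 4)), hu_calibrated = FALSE)
  expect_error(segment_lumen(raw, c(2, 2, 2)), "not HU-calibrated")
})

test_that("suggest_seed proposes a voxel in the most cranial in-band component", {
  vals <- array(0, c(10, 10, 10))
  vals[5:6, 5:6, 7:9] <- -1000   # cranial airway
  vals[2:3, 2:3, 1:3] <- -1000   # caudal pocket
  seed <- suggest_seed(ct_volume(vals), lumen_band())
  expect_equal(seed[3], 9)
  expect_true(vals[seed[1], seed[2], seed[3]] == -1000)
  expect_error(suggest_seed(ct_volume(array(0, c(4, 4, 4))), lumen_band()),
               "no in-band")
})
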