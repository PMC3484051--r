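random_volume <- function(dims = c(8, 8, 8), lo = -1000, hi = 0) {
  ct_volume(array(round(runif(prod(dims), lo, hi), 3), dims), spacing_um = 46)
}

test_that("NIfTI and MetaImage round-trips are voxelwise exact and keep spacing", {
  set.seed(11)
  vol <- random_volume()
  for (ext in c("nii", "nii.gz", "mha", "mhd")) {
    path <- file.path(withr::local_tempdir(), paste0("vol.", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(back$data, vol$data, label = ext)
    # NIfTI stores pixdim as float32; spacing round-trips to single precision
    expect_equal(back$spacing_um, c(46, 46, 46), tolerance = 1e-5)
  }
})

test_that("constant volumes round-trip through both writers", {
  vol <- ct_volume(array(-500, c(8, 8, 8)))
  for (fmt in c("nifti", "metaimage")) {
    path <- file.path(withr::local_tempdir(),
                      if (fmt == "nifti") "v.nii" else "v.mha")
    write_volume(vol, path, format = fmt)
    expect_true(all(read_volume(path)$data == -500))
  }
})

test_that("writing into a missing directory fails", {
  vol <- random_volume(c(4, 4, 4))
  expect_error(write_volume(vol, "/nonexistent-dir-xyz/v.nii"),
               "directory does not exist")
})

test_that("reading a missing path fails with the path named", {
  expect_error(read_volume("/no/such/file.nii"), "no/such/file")
})

test_that("a synthetic DICOM series reads back with spacing and rescale applied", {
  dir <- withr::local_tempdir()
  set.seed(21)
  raw_px <- array(sample(0:2000, 6 * 5 * 3, replace = TRUE), c(6, 5, 3))
  write_test_dicom_series(dir, raw_px, pixel_spacing_mm = 0.046,
                          slice_spacing_mm = 0.046,
                          slope = 2, intercept = -1024, rescale_type = "HU")
  vol <- read_volume(dir)
  expect_equal(vol$spacing_um, c(46, 46, 46), tolerance = 1e-6)
  expect_true(vol$hu_calibrated)
  expected <- pmax(raw_px * 2 - 1024, -1024)  # padding floor applies
  expect_equal(vol$data, array(as.numeric(expected), dim(expected)))
})

test_that("DICOM slices with mismatched in-plane dimensions are rejected", {
  dir <- withr::local_tempdir()
  write_test_dicom_slice(file.path(dir, "s1.dcm"), rep(0L, 16), 4, 4, 0.046)
  write_test_dicom_slice(file.path(dir, "s2.dcm"), rep(0L, 25), 5, 5, 0.092)
  expect_error(read_volume(dir), "inconsistent slice geometry")
})

test_that("a single-slice directory is not a series", {
  dir <- withr::local_tempdir()
  write_test_dicom_slice(file.path(dir, "s1.dcm"), rep(0L, 16), 4, 4, 0.046)
  expect_error(read_volume(dir), "at least 2")
})

test_that("undefined voxels are an error; sub-floor values map to -1024", {
  dir <- withr::local_tempdir()
  bad <- array(0, c(4, 4, 4)); bad[2, 2, 2] <- NaN
  path <- file.path(dir, "bad.nii")
  RNifti::writeNifti(RNifti::asNifti(bad, datatype = "double"), path)
  expect_error(read_volume(path), "undefined")

  vol <- ct_volume(array(-1100, c(4, 4, 4)))
  p2 <- file.path(dir, "pad.nii")
  write_volume(vol, p2)
  expect_message(back <- read_volume(p2), "-1024")
  expect_true(all(back$data == -1024))
})

test_that("masks round-trip and non-binary mask files are rejected", {
  dir <- withr::local_tempdir()
  set.seed(31)
  m <- voxel_mask(array(runif(216) > 0.5, c(6, 6, 6)))
  path <- file.path(dir, "mask.nii.gz")
  write_mask(m, path)
  expect_identical(read_mask(path)$data, m$data)

  write_volume(ct_volume(array(7, c(4, 4, 4))), file.path(dir, "notmask.nii"))
  expect_error(read_mask(file.path(dir, "notmask.nii")), "other than")
})

test_that("volume and mask constructors enforce their invariants", {
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2))), "undefined")
  expect_error(ct_volume(array(0, c(2, 2)), 46), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing_um = c(46, -1, 46)),
               "positive")
  v <- ct_volume(array(0, c(4, 4, 4)))
  expect_error(voxel_mask(array(TRUE, c(3, 3, 3)), v), "do not match")
  m <- voxel_mask(array(c(TRUE, FALSE), c(4, 4, 4)), v)
  expect_equal(voxel_count(m), 32)
})

test_that("anisotropic volumes are rejected by distance-dependent operations", {
  v <- ct_volume(array(-550, c(8, 8, 8)), spacing_um = c(46, 46, 92))
  lum <- voxel_mask(array(FALSE, c(8, 8, 8)))
  lum$data[4, 4, 4] <- TRUE
  expect_error(peribronchial_shell(v, lum, 2), "anisotropic")
})
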