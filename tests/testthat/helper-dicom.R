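# Writes minimal explicit-VR little-endian DICOM slices so the series reader
# can be exercised without binary fixtures in the repository.

dicom_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dicom_ds <- function(group, elem, ...) {
  dicom_element(group, elem, "DS", charToRaw(paste(..., sep = "\\")))
}

write_test_dicom_slice <- function(path, pixels, rows, cols, z_mm,
                                   pixel_spacing_mm = 0.046,
                                   slope = 1, intercept = 0,
                                   rescale_type = "HU", instance = 1L) {
  stopifnot(length(pixels) == rows * cols)
  body <- c(
    dicom_element(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1")),
    dicom_ds(0x0018, 0x0050, format(pixel_spacing_mm)),
    dicom_element(0x0020, 0x0013, "IS", charToRaw(as.character(instance))),
    dicom_ds(0x0020, 0x0032, "0", "0", format(z_mm)),
    dicom_element(0x0028, 0x0010, "US",
                  writeBin(as.integer(rows), raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0011, "US",
                  writeBin(as.integer(cols), raw(), size = 2, endian = "little")),
    dicom_ds(0x0028, 0x0030, format(pixel_spacing_mm), format(pixel_spacing_mm)),
    dicom_element(0x0028, 0x0100, "US",
                  writeBin(16L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0103, "US",
                  writeBin(1L, raw(), size = 2, endian = "little")),
    dicom_ds(0x0028, 0x1052, format(intercept)),
    dicom_ds(0x0028, 0x1053, format(slope)),
    dicom_element(0x0028, 0x1054, "LO", charToRaw(rescale_type)),
    dicom_element(0x7FE0, 0x0010, "OW",
                  writeBin(as.integer(pixels), raw(), size = 2, endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
}

# data: 3D integer array of *raw* pixel values, stored arr[x, y, z].
write_test_dicom_series <- function(dir, data, pixel_spacing_mm = 0.046,
                                    slice_spacing_mm = 0.046,
                                    slope = 1, intercept = 0,
                                    rescale_type = "HU") {
  d <- dim(data)
  for (z in seq_len(d[3])) {
    # reader expects row-major pixel order (x fastest), which is exactly
    # column-major order of the arr[x, y] plane
    write_test_dicom_slice(
      file.path(dir, sprintf("slice_%03d.dcm", z)),
      pixels = as.vector(data[, , z]),
      rows = d[2], cols = d[1], z_mm = z * slice_spacing_mm,
      pixel_spacing_mm = pixel_spacing_mm,
      slope = slope, intercept = intercept,
      rescale_type = rescale_type, instance = z)
  }
  invisible(dir)
}
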