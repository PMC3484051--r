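#' Read a 3D attenuation volume
#'
#' Supported containers: a DICOM series directory (uncompressed little-endian
#' monochrome slices; rescale slope/intercept honored), NIfTI
#' (`.nii`/`.nii.gz`) and MetaImage (`.mha`, or `.mhd` + raw).  Spacing is
#' taken from file metadata (NIfTI/MetaImage headers store millimetres and
#' are converted to micrometres).  Voxels below -1024 HU (out-of-field air
#' padding) are mapped to -1024; undefined (`NA`/`NaN`) values are an error.
#'
#' @param path file (NIfTI/MetaImage) or DICOM series directory.
#' @param format_hint optional; one of `"dicom_series"`, `"nifti"`,
#'   `"metaimage"`.  Inferred from the path when omitted.
#' @param assume_hu logical; NIfTI and MetaImage carry no HU declaration, so
#'   volumes read from them are flagged HU-calibrated when `TRUE` (default).
#'   DICOM series are flagged calibrated only when the rescale type declares
#'   HU.
#' @return A [ct_volume].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, format_hint = NULL, assume_hu = TRUE) {
  if (!file.exists(path))
    stop(sprintf("input path does not exist: %s", path))
  fmt <- if (is.null(format_hint)) sniff_format(path)
         else match.arg(format_hint, c("dicom_series", "nifti", "metaimage"))
  vol <- switch(fmt,
    nifti = read_nifti_volume(path, assume_hu),
    metaimage = read_metaimage_volume(path, assume_hu),
    dicom_series = read_dicom_series(path))
  if (anyNA(vol$data))
    stop(sprintf("volume %s contains undefined voxel values", path))
  n_pad <- sum(vol$data < -1024)
  if (n_pad > 0) {
    message(sprintf("%d voxels below -1024 HU mapped to -1024 (air padding)", n_pad))
    vol$data[vol$data < -1024] <- -1024
  }
  vol
}

sniff_format <- function(path) {
  if (dir.exists(path)) return("dicom_series")
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lower)) return("metaimage")
  stop(sprintf("cannot infer volume format from path: %s", path))
}

#' Write a 3D attenuation volume
#'
#' Round-trips exactly through [read_volume()]: voxel data and spacing are
#' preserved bit-for-bit (values are stored as 64-bit floats).
#'
#' @param volume a [ct_volume].
#' @param path output file; extension selects the format when `format` is
#'   omitted.
#' @param format `"nifti"` or `"metaimage"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("output directory does not exist: %s", dirname(path)))
  fmt <- if (is.null(format)) sniff_format(path)
         else match.arg(format, c("nifti", "metaimage"))
  switch(fmt,
    nifti = write_nifti_volume(volume, path),
    metaimage = write_metaimage_volume(volume, path),
    stop(sprintf("unsupported write format: %s", fmt)))
  invisible(path)
}

#' Read / write a voxel mask
#'
#' Masks use the same containers as volumes with values in `{0, 1}`.
#'
#' @param path mask file.
#' @param volume optional reference [ct_volume] for grid validation.
#' @return [read_mask()]: a [voxel_mask]; [write_mask()]: `path`, invisibly.
#' @rdname mask_io
#' @export
read_mask <- function(path, volume = NULL) {
  v <- read_volume(path, assume_hu = FALSE)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1)))
    stop(sprintf("mask file %s contains values other than {0, 1}", path))
  voxel_mask(v$data != 0, volume)
}

#' @param mask a [voxel_mask].
#' @param format `"nifti"` or `"metaimage"`.
#' @rdname mask_io
#' @export
write_mask <- function(mask, path, format = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  v <- ct_volume(array(as.numeric(mask$data), dim(mask$data)),
                 spacing_um = 46, hu_calibrated = FALSE, provenance = "mask")
  write_volume(v, path, format)
}

## ---- NIfTI (via RNifti; header stores mm) ----

read_nifti_volume <- function(path, assume_hu) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L) dat <- dat[, , , 1L]
  if (length(dim(dat)) != 3L)
    stop(sprintf("NIfTI file %s is not a 3D volume", path))
  spacing_mm <- RNifti::pixdim(img)[1:3]
  ct_volume(array(as.numeric(dat), dim(dat)), spacing_um = spacing_mm * 1000,
            hu_calibrated = assume_hu, provenance = path)
}

write_nifti_volume <- function(volume, path) {
  # pixdim is the full 8-element NIfTI field: qfac then spatial steps in mm
  img <- RNifti::asNifti(volume$data,
                         reference = list(pixdim = c(-1, volume$spacing_um / 1000,
                                                     0, 0, 0, 0)),
                         datatype = "double")
  RNifti::writeNifti(img, path)
}

## ---- MetaImage (.mha embedded / .mhd + .raw; header stores mm) ----

read_metaimage_volume <- function(path, assume_hu) {
  hdr <- read_metaimage_header(path)
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(hdr$fields))
  if (length(miss))
    stop(sprintf("MetaImage header %s lacks required fields: %s",
                 path, paste(miss, collapse = ", ")))
  if (as.integer(hdr$fields[["NDims"]]) != 3L)
    stop(sprintf("MetaImage %s is not 3D", path))
  dims <- as.integer(strsplit(trimws(hdr$fields[["DimSize"]]), "\\s+")[[1]])
  spacing_mm <- if ("ElementSpacing" %in% names(hdr$fields))
    as.numeric(strsplit(trimws(hdr$fields[["ElementSpacing"]]), "\\s+")[[1]])
  else c(1, 1, 1)
  type <- trimws(hdr$fields[["ElementType"]])
  spec <- switch(type,
    MET_DOUBLE = list(what = "double", size = 8, signed = TRUE),
    MET_FLOAT  = list(what = "double", size = 4, signed = TRUE),
    MET_SHORT  = list(what = "integer", size = 2, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
    MET_UCHAR  = list(what = "integer", size = 1, signed = FALSE),
    stop(sprintf("unsupported MetaImage ElementType: %s", type)))
  msb <- identical(trimws(hdr$fields[["ElementByteOrderMSB"]]), "True")
  endian <- if (isTRUE(msb)) "big" else "little"
  n <- prod(dims)
  datafile <- trimws(hdr$fields[["ElementDataFile"]])
  if (identical(datafile, "LOCAL")) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", hdr$data_offset)
    vals <- readBin(con, spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("MetaImage data file not found: %s", rawpath))
    con <- file(rawpath, "rb")
    on.exit(close(con))
    vals <- readBin(con, spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  }
  if (length(vals) != n)
    stop(sprintf("MetaImage %s: expected %d voxels, read %d", path, n, length(vals)))
  ct_volume(array(as.numeric(vals), dims), spacing_um = spacing_mm * 1000,
            hu_calibrated = assume_hu, provenance = path)
}

# Header lines are "Key = Value"; for .mha the raw data follows the
# ElementDataFile = LOCAL line.
read_metaimage_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  offset <- 0L
  repeat {
    line_bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) break
      offset <- offset + 1L
      if (b == as.raw(0x0a)) break
      line_bytes <- c(line_bytes, b)
    }
    if (length(b) == 0L && length(line_bytes) == 0L) break
    line <- rawToChar(line_bytes[line_bytes != as.raw(0x0d)])
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[kv[2]]] <- kv[3]
    if (length(kv) == 3L && kv[2] == "ElementDataFile") break
    if (length(b) == 0L) break
  }
  list(fields = fields, data_offset = offset)
}

write_metaimage_volume <- function(volume, path) {
  dims <- dim(volume$data)
  embedded <- grepl("\\.mha$", tolower(path))
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            volume$spacing_um[1] / 1000, volume$spacing_um[2] / 1000,
            volume$spacing_um[3] / 1000),
    "ElementByteOrderMSB = False")
  if (embedded) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(header, "ElementDataFile = LOCAL"), con, sep = "\n")
    writeBin(as.vector(volume$data), con, size = 8, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(header, sprintf("ElementDataFile = %s", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(as.vector(volume$data), con, size = 8, endian = "little")
  }
}
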