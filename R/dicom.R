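# Minimal DICOM series reader: uncompressed little-endian single-frame
# monochrome slices, implicit or explicit VR.  Covers micro-CT exports; not a
# general DICOM implementation (no sequences beyond skipping, no big-endian,
# no compressed transfer syntaxes).

DICOM_TAGS <- list(
  rows          = c(0x0028L, 0x0010L),
  cols          = c(0x0028L, 0x0011L),
  bits          = c(0x0028L, 0x0100L),
  pixrep        = c(0x0028L, 0x0103L),
  pixel_spacing = c(0x0028L, 0x0030L),
  position      = c(0x0020L, 0x0032L),
  slice_thick   = c(0x0018L, 0x0050L),
  instance      = c(0x0020L, 0x0013L),
  rescale_int   = c(0x0028L, 0x1052L),
  rescale_slope = c(0x0028L, 0x1053L),
  rescale_type  = c(0x0028L, 0x1054L),
  pixel_data    = c(0x7FE0L, 0x0010L))

read_dicom_series <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  slices <- lapply(files, function(f) {
    s <- tryCatch(read_dicom_slice(f), error = function(e)
      stop(sprintf("unreadable DICOM slice %s: %s", f, conditionMessage(e))))
    s$file <- f
    s
  })
  slices <- Filter(Negate(is.null), slices)
  if (length(slices) < 2L)
    stop(sprintf("DICOM series directory %s must contain at least 2 readable slices", path))
  dims <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop(sprintf("inconsistent slice geometry in %s: in-plane dimensions differ", path))
  ps <- vapply(slices, function(s) s$pixel_spacing, numeric(2))
  if (max(ps) / min(ps) - 1 > 1e-6 && (any(ps[1, ] != ps[1, 1]) || any(ps[2, ] != ps[2, 1])))
    stop(sprintf("inconsistent slice geometry in %s: pixel spacing differs", path))
  zpos <- vapply(slices, function(s)
    if (is.null(s$position)) NA_real_ else s$position[3], numeric(1))
  ord <- if (!anyNA(zpos)) order(zpos)
         else order(vapply(slices, function(s) s$instance %||% 0, numeric(1)))
  slices <- slices[ord]
  zpos <- zpos[ord]
  dz_mm <- if (!anyNA(zpos) && length(zpos) > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * max(dz))
      stop(sprintf("inconsistent slice geometry in %s: irregular slice positions", path))
    mean(dz)
  } else slices[[1]]$slice_thick %||% 1
  nx <- slices[[1]]$cols
  ny <- slices[[1]]$rows
  dat <- array(0, c(nx, ny, length(slices)))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    # pixel data is row-major (x fastest within each row), so a matrix with
    # nrow = cols is already arr[x, y]
    dat[, , i] <- matrix(s$pixels, nrow = s$cols, ncol = s$rows) *
      s$rescale_slope + s$rescale_int
  }
  hu <- any(vapply(slices, function(s)
    grepl("HU", toupper(s$rescale_type %||% "")), logical(1)))
  ct_volume(dat,
            spacing_um = c(slices[[1]]$pixel_spacing[2],
                           slices[[1]]$pixel_spacing[1], dz_mm) * 1000,
            hu_calibrated = hu, provenance = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_dicom_slice <- function(file) {
  raw_all <- readBin(file, "raw", file.size(file))
  if (length(raw_all) < 140L || rawToChar(raw_all[129:132]) != "DICM")
    stop("missing DICM magic (not a DICOM part-10 file)")
  pos <- 133L  # after preamble + magic
  u16 <- function(at) readBin(raw_all[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw_all[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  out <- list(rescale_slope = 1, rescale_int = 0, rescale_type = NULL,
              slice_thick = NULL, position = NULL, instance = NULL)
  explicit <- TRUE  # file meta group is always explicit VR
  transfer_syntax <- "1.2.840.10008.1.2.1"
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw_all)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (group != 0x0002L && explicit && transfer_syntax == "1.2.840.10008.1.2") {
      explicit <- FALSE  # switch to dataset transfer syntax after meta group
    }
    use_explicit <- if (group == 0x0002L) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    vstart <- pos + hdr
    if (len < 0 || vstart + len - 1L > length(raw_all))
      stop("truncated DICOM element")
    val_raw <- if (len > 0) raw_all[vstart:(vstart + len - 1L)] else raw(0)
    tag <- c(group, elem)
    txt <- function() trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
    nums <- function() as.numeric(strsplit(txt(), "\\\\")[[1]])
    if (group == 0x0002L && elem == 0x0010L) {
      transfer_syntax <- txt()
      if (!transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop(sprintf("unsupported transfer syntax: %s", transfer_syntax))
    } else if (identical(tag, DICOM_TAGS$rows)) {
      out$rows <- u16(vstart)
    } else if (identical(tag, DICOM_TAGS$cols)) {
      out$cols <- u16(vstart)
    } else if (identical(tag, DICOM_TAGS$bits)) {
      out$bits <- u16(vstart)
    } else if (identical(tag, DICOM_TAGS$pixrep)) {
      out$pixrep <- u16(vstart)
    } else if (identical(tag, DICOM_TAGS$pixel_spacing)) {
      out$pixel_spacing <- nums()
    } else if (identical(tag, DICOM_TAGS$position)) {
      out$position <- nums()
    } else if (identical(tag, DICOM_TAGS$slice_thick)) {
      out$slice_thick <- nums()[1]
    } else if (identical(tag, DICOM_TAGS$instance)) {
      out$instance <- nums()[1]
    } else if (identical(tag, DICOM_TAGS$rescale_int)) {
      out$rescale_int <- nums()[1]
    } else if (identical(tag, DICOM_TAGS$rescale_slope)) {
      out$rescale_slope <- nums()[1]
    } else if (identical(tag, DICOM_TAGS$rescale_type)) {
      out$rescale_type <- txt()
    } else if (identical(tag, DICOM_TAGS$pixel_data)) {
      if (is.null(out$rows) || is.null(out$cols) || is.null(out$bits))
        stop("pixel data before image dimensions")
      npix <- out$rows * out$cols
      size <- out$bits %/% 8L
      if (!size %in% c(1L, 2L)) stop(sprintf("unsupported BitsAllocated: %d", out$bits))
      signed <- isTRUE(out$pixrep == 1L)
      if (size == 1L) signed <- FALSE
      out$pixels <- readBin(val_raw, "integer", n = npix, size = size,
                            signed = signed, endian = "little")
      if (length(out$pixels) != npix) stop("truncated pixel data")
      break
    }
    pos <- vstart + len
  }
  if (is.null(out$pixels)) stop("no pixel data element found")
  if (is.null(out$pixel_spacing)) out$pixel_spacing <- c(1, 1)
  out
}
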