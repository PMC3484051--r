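#' Construct a CT attenuation volume
#'
#' A `ct_volume` wraps a 3D numeric array of attenuation values together with
#' its voxel spacing and Hounsfield-unit calibration state.  Arrays are stored
#' R-natively as `data[x, y, z]` with the third index the cranio-caudal (z)
#' axis; all masks inherit this layout.
#'
#' @param data 3D numeric array of attenuation values.  Must contain no
#'   `NA`/`NaN` values.
#' @param spacing_um numeric length-3 vector of voxel edge lengths in
#'   micrometres, one per axis; all strictly positive.  A scalar is recycled
#'   (isotropic grid).
#' @param hu_calibrated logical; `TRUE` when `data` is on the Hounsfield
#'   scale (air = -1000, water = 0).
#' @param provenance free-text source descriptor.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(-500, c(8, 8, 8)), spacing_um = 46)
#' v
#' @export
ct_volume <- function(data, spacing_um = 46, hu_calibrated = TRUE,
                      provenance = "in-memory") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (anyNA(data))
    stop("volume contains undefined (NA/NaN) voxel values")
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 3L)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("`spacing_um` must be three strictly positive voxel edge lengths")
  structure(list(data = data, spacing_um = spacing_um,
                 hu_calibrated = isTRUE(hu_calibrated),
                 provenance = as.character(provenance)[1L]),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s um, %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_um, trim = TRUE), collapse = " x "),
              if (x$hu_calibrated) "HU-calibrated" else "raw (uncalibrated)"))
  cat(sprintf("  range [%.1f, %.1f], source: %s\n",
              min(x$data), max(x$data), x$provenance))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# Distance-dependent operations need near-isotropic voxels; the attenuation
# statistics themselves do not.
check_isotropic <- function(volume, tol = 0.01) {
  s <- volume$spacing_um
  if (max(s) / min(s) - 1 > tol)
    stop(sprintf(paste0("voxel spacing (%s um) is anisotropic beyond %g%% relative ",
                        "tolerance; resample before distance-dependent operations"),
                 paste(format(s, trim = TRUE), collapse = " x "), tol * 100))
  invisible(TRUE)
}

check_calibrated <- function(volume) {
  if (!volume$hu_calibrated)
    stop("volume is not HU-calibrated; run calibrate_to_hu() first")
  invisible(TRUE)
}

#' Construct a voxel mask
#'
#' A binary 3D selection (VOI) on a CT volume grid.
#'
#' @param data 3D logical array, or numeric array coerced by `!= 0`.
#' @param volume optional `ct_volume` the mask indexes; dimensions must agree.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, volume = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array")
  if (!is.logical(data)) {
    d <- dim(data)
    data <- array(data != 0, d)
  }
  if (anyNA(data)) stop("mask contains undefined values")
  if (!is.null(volume) && !identical(dim(data), dim(volume$data)))
    stop("mask dimensions do not match its reference volume")
  structure(list(data = data), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_mask> %d x %d x %d voxels, %d selected (%.2f%%)\n",
              d[1], d[2], d[3], voxel_count(x),
              100 * voxel_count(x) / prod(d)))
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$data)

#' Number of selected voxels in a mask
#' @param mask a `voxel_mask`.
#' @return Integer count of `TRUE` voxels.
#' @export
voxel_count <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$data)
}

#' Dice overlap between two masks
#'
#' `2|A n B| / (|A| + |B|)`, the standard segmentation-similarity score.
#'
#' @param a,b `voxel_mask` objects on the same grid.
#' @return Dice coefficient in `[0, 1]`; `NaN` when both masks are empty.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("masks are on different grids")
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}

check_same_grid <- function(mask, volume) {
  if (!identical(dim(mask$data), dim(volume$data)))
    stop("mask and volume are on different grids")
  invisible(TRUE)
}
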