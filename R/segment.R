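#' Inclusive HU threshold band
#'
#' @param lo,hi lower and upper bounds in HU, both inclusive; `lo < hi`.
#' @return An object of class `threshold_band`.
#' @export
threshold_band <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("threshold band requires finite lo < hi")
  structure(list(lo = lo, hi = hi), class = "threshold_band")
}

#' @export
print.threshold_band <- function(x, ...) {
  cat(sprintf("<threshold_band> [%g, %g] HU (inclusive)\n", x$lo, x$hi))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "threshold_band")) return(band)
  if (is.numeric(band) && length(band) == 2L) return(threshold_band(band[1], band[2]))
  stop("`band` must be a threshold_band or a numeric pair (lo, hi)")
}

# Default bands of the published protocol: the lumen is everything from the
# scanner floor up to -900 HU; the aerated lung field is -900 to -100 HU.
#' @rdname threshold_band
#' @export
lumen_band <- function() threshold_band(-1024, -900)

#' @rdname threshold_band
#' @export
lung_band <- function() threshold_band(-900, -100)

validate_seeds <- function(seeds, volume) {
  if (is.numeric(seeds) && is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  if (is.list(seeds) && !is.data.frame(seeds)) seeds <- do.call(rbind, seeds)
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 3L || nrow(seeds) == 0L)
    stop("`seeds` must be one or more (x, y, z) voxel index triples")
  storage.mode(seeds) <- "integer"
  d <- dim(volume$data)
  ok <- seeds[, 1] >= 1L & seeds[, 1] <= d[1] &
        seeds[, 2] >= 1L & seeds[, 2] <= d[2] &
        seeds[, 3] >= 1L & seeds[, 3] <= d[3]
  if (!all(ok))
    stop(sprintf("seed out of volume bounds: (%s)",
                 paste(seeds[which(!ok)[1], ], collapse = ", ")))
  seeds
}

seed_linear_index <- function(seeds, d) {
  as.integer(seeds[, 1] + (seeds[, 2] - 1) * d[1] +
             (seeds[, 3] - 1) * d[1] * d[2])
}

#' Seeded bi-threshold volume growing
#'
#' Grows connected regions from seed voxels through voxels whose attenuation
#' lies inside an inclusive HU band.  The result is exactly the union of the
#' connected components of in-band voxels that contain at least one seed;
#' deterministic for fixed inputs.
#'
#' @param volume a [ct_volume].
#' @param seeds matrix (or list) of 1-based `(x, y, z)` voxel indices; every
#'   seed's value must lie inside `band`.
#' @param band a [threshold_band] or numeric pair `(lo, hi)`, bounds
#'   inclusive.
#' @param connectivity `"face6"` (6 face neighbors; default, conservative
#'   against diagonal leakage through thin walls) or `"full26"`.
#' @return A [voxel_mask].
#' @seealso [segment_lumen()], [segment_lung()]
#' @export
grow_region <- function(volume, seeds, band, connectivity = c("face6", "full26")) {
  stopifnot(inherits(volume, "ct_volume"))
  connectivity <- match.arg(connectivity)
  band <- as_band(band)
  seeds <- validate_seeds(seeds, volume)
  d <- dim(volume$data)
  vals <- volume$data[seeds]
  bad <- which(vals < band$lo | vals > band$hi)
  if (length(bad))
    stop(sprintf("seed (%s) has value %.1f HU, outside band [%g, %g]",
                 paste(seeds[bad[1], ], collapse = ", "), vals[bad[1]],
                 band$lo, band$hi))
  inband <- volume$data >= band$lo & volume$data <= band$hi
  grown <- region_grow_cpp(as.vector(inband), as.integer(d),
                           seed_linear_index(seeds, d),
                           if (connectivity == "face6") 6L else 26L)
  voxel_mask(array(grown, d), volume)
}

#' Segment the bronchial lumen
#'
#' Bi-threshold volume growing in the lumen band (default -1024 to -900 HU)
#' from seeds placed in the airway lumen.
#'
#' @inheritParams grow_region
#' @param band lumen HU band; default [lumen_band()], -1024 to -900 HU.
#' @return A non-empty [voxel_mask]; attributes `band` and `connectivity`
#'   echo the parameters used.
#' @export
segment_lumen <- function(volume, seeds, band = lumen_band(),
                          connectivity = c("face6", "full26")) {
  check_calibrated(volume)
  connectivity <- match.arg(connectivity)
  band <- as_band(band)
  mask <- grow_region(volume, seeds, band, connectivity)
  if (voxel_count(mask) == 0L)
    stop("empty lumen segmentation; check seed placement and HU calibration")
  attr(mask, "band") <- c(band$lo, band$hi)
  attr(mask, "connectivity") <- connectivity
  mask
}

#' Segment the aerated lung field
#'
#' Bi-threshold volume growing in the lung band (default -900 to -100 HU).
#' The resulting mask is the support of the total lung attenuation (TLA).
#'
#' @inheritParams grow_region
#' @param band lung HU band; default [lung_band()], -900 to -100 HU.
#' @return A non-empty [voxel_mask] with `band`/`connectivity` attributes.
#' @export
segment_lung <- function(volume, seeds, band = lung_band(),
                         connectivity = c("face6", "full26")) {
  check_calibrated(volume)
  connectivity <- match.arg(connectivity)
  band <- as_band(band)
  mask <- grow_region(volume, seeds, band, connectivity)
  if (voxel_count(mask) == 0L)
    stop("empty lung segmentation; check seed placement and HU calibration")
  attr(mask, "band") <- c(band$lo, band$hi)
  attr(mask, "connectivity") <- connectivity
  mask
}

#' Propose a seed in the most cranial in-band component
#'
#' Scans from the cranial end (largest z index) for the first slice
#' containing in-band voxels and returns the in-band voxel of that slice
#' closest to their centroid — for airway work this is normally a tracheal
#' voxel, mimicking the obvious manual seed choice.
#'
#' @param volume a [ct_volume].
#' @param band a [threshold_band] or numeric pair.
#' @return A 1-based `(x, y, z)` integer triple.
#' @export
suggest_seed <- function(volume, band = lumen_band()) {
  stopifnot(inherits(volume, "ct_volume"))
  band <- as_band(band)
  d <- dim(volume$data)
  for (z in rev(seq_len(d[3]))) {
    slice <- volume$data[, , z]
    hits <- which(slice >= band$lo & slice <= band$hi, arr.ind = TRUE)
    if (nrow(hits) > 0L) {
      centroid <- colMeans(hits)
      i <- which.min((hits[, 1] - centroid[1])^2 + (hits[, 2] - centroid[2])^2)
      return(as.integer(c(hits[i, 1], hits[i, 2], z)))
    }
  }
  stop("no in-band voxel found in the volume")
}
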