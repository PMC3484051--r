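#' In-field calibration standards
#'
#' Mean raw scanner values measured over the air and water standards placed in
#' the scan chamber, used to anchor the Hounsfield scale (air = -1000 HU,
#' water = 0 HU).  A bone standard, when present, is used only as a linearity
#' diagnostic: its mapped HU is reported but does not affect the calibration.
#'
#' @param air_raw,water_raw mean raw values over the air and water standard
#'   regions; `air_raw` must be strictly less than `water_raw` (raw
#'   attenuation increases with density).
#' @param bone_raw optional mean raw value over the bone standard.
#' @param air_hu,water_hu reference HU values (defaults -1000 and 0).
#' @return An object of class `calibration_standards`.
#' @export
calibration_standards <- function(air_raw, water_raw, bone_raw = NULL,
                                  air_hu = -1000, water_hu = 0) {
  if (!is.finite(air_raw) || !is.finite(water_raw))
    stop("standard means must be finite")
  if (air_raw == water_raw)
    stop("degenerate calibration: air and water standards have equal raw values")
  if (air_raw > water_raw)
    stop("air standard raw value must be below the water standard (raw attenuation increases with density)")
  structure(list(air_raw = air_raw, water_raw = water_raw,
                 bone_raw = bone_raw, air_hu = air_hu, water_hu = water_hu),
            class = "calibration_standards")
}

#' Read calibration standards from CSV
#'
#' Expects columns `standard` (values `air`, `water`, optionally `bone`) and
#' `mean_raw`.
#'
#' @param path CSV file.
#' @return A [calibration_standards] object.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("standard", "mean_raw") %in% names(df)))
    stop(sprintf("calibration CSV %s must have columns standard, mean_raw", path))
  get <- function(s) {
    v <- df$mean_raw[tolower(df$standard) == s]
    if (length(v) == 0L) NULL else v[1]
  }
  air <- get("air"); water <- get("water")
  if (is.null(air) || is.null(water))
    stop(sprintf("calibration CSV %s must list air and water standards", path))
  calibration_standards(air, water, bone_raw = get("bone"))
}

#' Calibrate a raw volume to Hounsfield units
#'
#' Applies the two-point affine map sending the air-standard mean to
#' `air_hu` and the water-standard mean to `water_hu` voxelwise.  If a bone
#' standard is supplied its mapped HU is attached as attribute
#' `"bone_mapped_hu"` (linearity diagnostic; it does not influence the map).
#'
#' @param volume a raw (not yet HU-calibrated) [ct_volume].
#' @param standards a [calibration_standards] object.
#' @return The HU-calibrated [ct_volume].
#' @examples
#' raw <- ct_volume(array(350, c(4, 4, 4)), hu_calibrated = FALSE)
#' std <- calibration_standards(air_raw = 100, water_raw = 600)
#' calibrate_to_hu(raw, std)$data[1]  # -500 HU
#' @export
calibrate_to_hu <- function(volume, standards) {
  stopifnot(inherits(volume, "ct_volume"), inherits(standards, "calibration_standards"))
  if (volume$hu_calibrated)
    stop("volume is already HU-calibrated")
  slope <- (standards$water_hu - standards$air_hu) /
    (standards$water_raw - standards$air_raw)
  intercept <- standards$air_hu - slope * standards$air_raw
  out <- ct_volume(volume$data * slope + intercept,
                   spacing_um = volume$spacing_um, hu_calibrated = TRUE,
                   provenance = volume$provenance)
  if (!is.null(standards$bone_raw))
    attr(out, "bone_mapped_hu") <- standards$bone_raw * slope + intercept
  out
}
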