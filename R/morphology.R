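#' 3D morphological dilation of a voxel mask
#'
#' In the default `"euclidean"` mode the result is the set of voxels whose
#' Euclidean distance (in voxel units) to the nearest selected voxel is at
#' most `radius_voxels`, computed with a separable squared distance
#' transform.  `"iterated_face"` mode instead applies `radius_voxels`
#' (rounded) iterations of the face-connected unit structuring element (a
#' city-block ball), bracketing the behavior of morphology tools that
#' iterate a 6-neighbor element.
#'
#' @param mask a non-empty [voxel_mask].
#' @param radius_voxels dilation radius in voxel units; positive.
#' @param mode `"euclidean"` (default) or `"iterated_face"`.
#' @return A [voxel_mask]; always a superset of the input.
#' @export
dilate_mask <- function(mask, radius_voxels, mode = c("euclidean", "iterated_face")) {
  stopifnot(inherits(mask, "voxel_mask"))
  mode <- match.arg(mode)
  if (!is.finite(radius_voxels) || radius_voxels <= 0)
    stop("`radius_voxels` must be positive")
  if (voxel_count(mask) == 0L)
    stop("cannot dilate an empty mask")
  d <- dim(mask$data)
  out <- if (mode == "euclidean") {
    sq <- sedt_cpp(as.vector(mask$data), as.integer(d))
    # compare squared distances; +1e-9 guards against FP jitter at exactly r
    array(sq <= radius_voxels^2 + 1e-9, d)
  } else {
    array(dilate_face_cpp(as.vector(mask$data), as.integer(d),
                          as.integer(round(radius_voxels))), d)
  }
  voxel_mask(out)
}

#' Euclidean distance map to a mask
#'
#' Distance (voxel units) from every voxel to the nearest selected voxel.
#'
#' @param mask a [voxel_mask].
#' @return 3D numeric array of distances (0 on the mask itself).
#' @keywords internal
#' @export
distance_to_mask <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  d <- dim(mask$data)
  array(sqrt(sedt_cpp(as.vector(mask$data), as.integer(d))), d)
}
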