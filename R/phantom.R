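#' Synthetic thorax-phantom specification
#'
#' Parameters of a micro-CT-like murine thorax phantom: a dichotomous
#' airway tree of air-filled cylinders (lumen) sleeved by bronchial wall,
#' embedded in aerated parenchyma inside a soft-tissue body, with optional
#' peribronchial "inflammation" halos, in-field air/water calibration
#' cylinders, and additive Gaussian noise.  Defaults emulate a
#' respiratory-gated mouse thorax at isotropic 46 um voxels.
#'
#' The airway tree is sealed inside the lung (the trachea does not open into
#' the chamber air, which shares the lumen HU band) so that seeded lumen
#' growth cannot leak out of the airway — the phantom analogue of an
#' intubated, gated animal.  Painted-plus-noise values are floored at
#' -1024 HU, the scanner dynamic-range minimum.
#'
#' @param grid_shape voxel dimensions, default `c(192, 192, 192)`.
#' @param spacing_um isotropic voxel size in micrometres, default 46.
#' @param tree_depth branching generations including the trachea, default 4.
#' @param root_radius_voxels tracheal lumen radius in voxels, default 5.
#' @param radius_decay per-generation lumen radius factor, default 0.8.
#' @param wall_thickness_voxels bronchial wall thickness, default 2.
#' @param lumen_hu,wall_hu,parenchyma_hu,body_hu tissue attenuations in HU
#'   (defaults -1000, -200, -550, 0); must satisfy
#'   `lumen_hu < parenchyma_hu < body_hu`.
#' @param inflammation_halo `NULL` (default) or
#'   `list(extent_voxels =, delta_hu =)`: raises parenchymal attenuation by
#'   `delta_hu` within `extent_voxels` of the outer airway wall.  The
#'   default halo (see [inflammation_series()]) is deliberately broad
#'   (32 voxels, about 1.5 mm) because murine allergic inflammation is
#'   diffuse, extending well beyond the bronchial wall into the
#'   parenchyma.
#' @param noise_sd_hu additive Gaussian noise SD in HU, default 20.
#' @param rng_seed integer seed; phantoms are deterministic given the seed.
#' @param include_standards paint air and water calibration cylinders in the
#'   chamber air, default `TRUE`.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(192, 192, 192), spacing_um = 46,
                         tree_depth = 4, root_radius_voxels = 5,
                         radius_decay = 0.8, wall_thickness_voxels = 2,
                         lumen_hu = -1000, wall_hu = -200,
                         parenchyma_hu = -550, body_hu = 0,
                         inflammation_halo = NULL, noise_sd_hu = 20,
                         rng_seed = 1, include_standards = TRUE) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 32L))
  if (!(lumen_hu < parenchyma_hu && parenchyma_hu < body_hu))
    stop("phantom requires lumen_hu < parenchyma_hu < body_hu")
  if (wall_thickness_voxels < 1) stop("wall thickness must be >= 1 voxel")
  if (root_radius_voxels < 1) stop("airway radii must be >= 1 voxel")
  if (tree_depth < 1) stop("tree_depth must be >= 1")
  if (radius_decay <= 0 || radius_decay > 1) stop("radius_decay must be in (0, 1]")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  if (!is.null(inflammation_halo)) {
    stopifnot(is.list(inflammation_halo),
              all(c("extent_voxels", "delta_hu") %in% names(inflammation_halo)),
              inflammation_halo$extent_voxels > 0)
  }
  structure(list(grid_shape = grid_shape, spacing_um = spacing_um,
                 tree_depth = tree_depth,
                 root_radius_voxels = root_radius_voxels,
                 radius_decay = radius_decay,
                 wall_thickness_voxels = wall_thickness_voxels,
                 lumen_hu = lumen_hu, wall_hu = wall_hu,
                 parenchyma_hu = parenchyma_hu, body_hu = body_hu,
                 inflammation_halo = inflammation_halo,
                 noise_sd_hu = noise_sd_hu, rng_seed = as.integer(rng_seed),
                 include_standards = isTRUE(include_standards)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

rotate_about <- function(v, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  cr <- c(axis[2] * v[3] - axis[3] * v[2],
          axis[3] * v[1] - axis[1] * v[3],
          axis[1] * v[2] - axis[2] * v[1])
  v * cos(theta) + cr * sin(theta) + axis * sum(axis * v) * (1 - cos(theta))
}

# Dichotomous airway tree: straight trachea along -z splitting into child
# branches with fixed 35-degree divergence; the branching plane alternates
# between x-z and y-z with generation.
phantom_tree <- function(spec) {
  n <- spec$grid_shape
  ctr <- (n + 1) / 2
  segs <- list()
  len0 <- 0.20 * n[3]
  p0 <- c(ctr[1], ctr[2], ctr[3] + 0.26 * n[3])
  build <- function(p0, dir, len, radius, depth) {
    p1 <- p0 + dir * len
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, radius = radius,
                                       depth = depth)
    if (depth < spec$tree_depth) {
      axis <- if (depth %% 2 == 1) c(0, 1, 0) else c(1, 0, 0)
      for (sgn in c(-1, 1)) {
        child_dir <- rotate_about(dir, axis, sgn * 35 * pi / 180)
        build(p1, child_dir, len * 0.75, radius * spec$radius_decay, depth + 1L)
      }
    }
  }
  build(p0, c(0, 0, -1), len0, spec$root_radius_voxels, 1L)
  segs
}

lung_semiaxes <- function(n) c(0.34 * n[1], 0.34 * n[2], 0.38 * n[3])
body_semiaxes <- function(n) c(0.43 * n[1], 0.43 * n[2], 0.46 * n[3])

ellipsoid_mask <- function(n, ctr, semi) {
  ex <- ((seq_len(n[1]) - ctr[1]) / semi[1])^2
  ey <- ((seq_len(n[2]) - ctr[2]) / semi[2])^2
  ez <- ((seq_len(n[3]) - ctr[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

# Voxels within `radius` of the axis segment p0-p1, restricted to a bounding
# box; returns linear indices.
segment_tube_indices <- function(n, p0, p1, radius) {
  lo <- pmax(1L, floor(pmin(p0, p1) - radius - 1))
  hi <- pmin(n, ceiling(pmax(p0, p1) + radius + 1))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  v <- p1 - p0
  vv <- sum(v^2)
  wx <- g$x - p0[1]; wy <- g$y - p0[2]; wz <- g$z - p0[3]
  t <- (wx * v[1] + wy * v[2] + wz * v[3]) / vv
  t <- pmin(pmax(t, 0), 1)
  d2 <- (wx - t * v[1])^2 + (wy - t * v[2])^2 + (wz - t * v[3])^2
  keep <- d2 <= radius^2
  (g$x[keep] - 1) + (g$y[keep] - 1) * n[1] + (g$z[keep] - 1) * n[1] * n[2] + 1
}

tree_indices <- function(n, segs, extra_radius) {
  idx <- unlist(lapply(segs, function(s)
    segment_tube_indices(n, s$p0, s$p1, s$radius + extra_radius)))
  unique(idx)
}

# Reference dilation oracle: the union of Euclidean balls placed on every
# selected voxel, realized by explicit offset shifts.  Shares no code with
# the distance-transform implementation.
brute_dilate <- function(mask_arr, radius) {
  n <- dim(mask_arr)
  r <- ceiling(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2 + 1e-9, ]
  coords <- which(mask_arr, arr.ind = TRUE)
  out <- array(FALSE, n)
  for (i in seq_len(nrow(offs))) {
    xx <- coords[, 1] + offs$dx[i]
    yy <- coords[, 2] + offs$dy[i]
    zz <- coords[, 3] + offs$dz[i]
    ok <- xx >= 1L & xx <= n[1] & yy >= 1L & yy <= n[2] & zz >= 1L & zz <= n[3]
    out[(xx[ok] - 1) + (yy[ok] - 1) * n[1] + (zz[ok] - 1) * n[1] * n[2] + 1] <- TRUE
  }
  out
}

nearest_true_voxel <- function(mask_arr, target) {
  coords <- which(mask_arr, arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("mask is empty")
  d2 <- (coords[, 1] - target[1])^2 + (coords[, 2] - target[2])^2 +
        (coords[, 3] - target[3])^2
  as.integer(coords[which.min(d2), ])
}

#' Generate a synthetic thorax phantom with ground truth
#'
#' Paints the phantom described by a [phantom_spec] and returns both the
#' (noisy) CT volume and a truth object: tissue masks, suggested lumen/lung
#' seeds, a trachea exclusion mask, and oracle attenuation values.  The
#' oracle applies the published shell definition to the *ground-truth* lumen
#' mask using a brute-force ball dilation and the noise-free painted
#' attenuations, so it is independent of the segmentation and
#' distance-transform code under test.
#'
#' @param spec a [phantom_spec].
#' @param shell_radius_voxels dilation radius used for the oracle shell and
#'   exclusion mask, default 8 (the published optimum).
#' @return A list with elements `volume` (a [ct_volume]) and `truth`, a
#'   `phantom_truth` list carrying `lumen_mask`, `wall_mask`,
#'   `parenchyma_mask`, `body_mask`, `halo_mask`,
#'   `trachea_exclusion_mask`, `air_standard_mask`, `water_standard_mask`
#'   ([voxel_mask] objects), `seed_lumen`, `seed_lung`, `expected_tla_hu`,
#'   `expected_pba_hu`, `expected_normalized_pba`, `shell_oracle_mask`, and
#'   the generating `spec`.
#' @export
generate_phantom <- function(spec, shell_radius_voxels = 8) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape
  ctr <- (n + 1) / 2
  segs <- phantom_tree(spec)
  lung_semi <- lung_semiaxes(n)
  wt <- spec$wall_thickness_voxels
  # fit check: every segment endpoint, inflated by its outer radius, must
  # stay inside the lung ellipsoid
  for (s in segs) {
    for (p in list(s$p0, s$p1)) {
      margin <- s$radius + wt + 1
      if (sum(((p - ctr) / (lung_semi - margin))^2) > 1)
        stop("airway tree does not fit inside the lung: reduce tree_depth or root_radius_voxels")
    }
  }
  nvox <- prod(n)
  vol <- array(-1000, n)                     # chamber air
  body <- ellipsoid_mask(n, ctr, body_semiaxes(n))
  vol[body] <- spec$body_hu
  lung <- ellipsoid_mask(n, ctr, lung_semi)
  vol[lung] <- spec$parenchyma_hu
  wall_idx <- tree_indices(n, segs, wt)
  lumen_idx <- tree_indices(n, segs, 0)
  vol[wall_idx] <- spec$wall_hu
  vol[lumen_idx] <- spec$lumen_hu
  lumen_arr <- array(FALSE, n); lumen_arr[lumen_idx] <- TRUE
  wall_arr <- array(FALSE, n); wall_arr[wall_idx] <- TRUE
  wall_arr <- wall_arr & !lumen_arr
  paren_arr <- lung & !wall_arr & !lumen_arr
  body_arr <- body & !lung
  halo_arr <- array(FALSE, n)
  if (!is.null(spec$inflammation_halo)) {
    halo_idx <- tree_indices(n, segs, wt + spec$inflammation_halo$extent_voxels)
    halo_arr[halo_idx] <- TRUE
    halo_arr <- halo_arr & paren_arr
    vol[halo_arr] <- vol[halo_arr] + spec$inflammation_halo$delta_hu
  }
  air_std <- array(FALSE, n); water_std <- array(FALSE, n)
  if (spec$include_standards) {
    std_r <- 5
    zs <- round(0.35 * n[3]):round(0.65 * n[3])
    paint_cyl <- function(cx, cy) {
      xs <- max(1, round(cx - std_r)):min(n[1], round(cx + std_r))
      ys <- max(1, round(cy - std_r)):min(n[2], round(cy + std_r))
      g <- expand.grid(x = xs, y = ys)
      g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= std_r^2, ]
      m <- array(FALSE, n)
      for (z in zs) m[cbind(g$x, g$y, z)] <- TRUE
      m
    }
    air_std <- paint_cyl(0.06 * n[1], 0.06 * n[2])
    water_std <- paint_cyl(0.94 * n[1], 0.06 * n[2])
    if (any(air_std & body) || any(water_std & body))
      stop("calibration standards overlap the body; enlarge the grid")
    vol[air_std] <- -1000
    vol[water_std] <- 0
  }
  noisefree <- vol
  if (spec$noise_sd_hu > 0)
    vol <- vol + with_seed(spec$rng_seed,
                           array(rnorm(nvox, 0, spec$noise_sd_hu), n))
  vol[vol < -1024] <- -1024                  # scanner dynamic-range floor
  volume <- ct_volume(vol, spacing_um = spec$spacing_um, hu_calibrated = TRUE,
                      provenance = sprintf("synthetic thorax phantom (seed %d)",
                                           spec$rng_seed))
  # seeds: trachea midpoint (lumen) and a parenchymal point lateral to it
  trachea <- segs[[1]]
  seed_lumen <- nearest_true_voxel(lumen_arr,
                                   round((trachea$p0 + trachea$p1) / 2))
  seed_lung <- nearest_true_voxel(paren_arr & !halo_arr,
                                  round(c(ctr[1] + 0.2 * n[1], ctr[2], ctr[3])))
  # trachea exclusion: everything the shell dilation can reach from the
  # tracheal lumen (geometric cylinder, generous by half a voxel)
  excl <- array(FALSE, n)
  excl[segment_tube_indices(n, trachea$p0, trachea$p1,
                            trachea$radius + shell_radius_voxels + 0.5)] <- TRUE
  # oracle shell from truth masks and noise-free attenuations
  dil <- brute_dilate(lumen_arr, shell_radius_voxels)
  in_lumen_band <- noisefree >= -1024 & noisefree <= -900
  shell_oracle <- dil & !in_lumen_band & !excl
  # a tree with no branches beyond the trachea has no peribronchial shell
  # left after the exclusion; its oracle attenuation is undefined
  expected_pba <- if (any(shell_oracle)) mean(noisefree[shell_oracle]) else NA_real_
  lung_in_band <- noisefree >= -900 & noisefree <= -100 & (wall_arr | paren_arr)
  expected_tla <- mean(noisefree[lung_in_band])
  truth <- structure(list(
    lumen_mask = voxel_mask(lumen_arr), wall_mask = voxel_mask(wall_arr),
    parenchyma_mask = voxel_mask(paren_arr), body_mask = voxel_mask(body_arr),
    halo_mask = voxel_mask(halo_arr),
    trachea_exclusion_mask = voxel_mask(excl),
    air_standard_mask = voxel_mask(air_std),
    water_standard_mask = voxel_mask(water_std),
    shell_oracle_mask = voxel_mask(shell_oracle),
    seed_lumen = seed_lumen, seed_lung = seed_lung,
    expected_tla_hu = expected_tla, expected_pba_hu = expected_pba,
    expected_normalized_pba = normalized_pba(expected_pba, expected_tla),
    shell_radius_voxels = shell_radius_voxels,
    spec = spec), class = "phantom_truth")
  list(volume = volume, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> grid %s, %d airway generations\n",
              paste(x$spec$grid_shape, collapse = "x"), x$spec$tree_depth))
  cat(sprintf("  expected TLA %.2f HU, PBA %.2f HU, normalized PBA %.4f\n",
              x$expected_tla_hu, x$expected_pba_hu, x$expected_normalized_pba))
  invisible(x)
}

#' Phantom series with varying wall thickness
#'
#' Generates phantoms identical in geometry, attenuations and noise seed
#' except for the bronchial wall thickness — the phantom analogue of airway
#' remodeling (smooth-muscle/wall mass increase without inflammation).
#'
#' @param spec base [phantom_spec].
#' @param wall_thickness_list wall thicknesses in voxels, each `>= 1`.
#' @param shell_radius_voxels passed to [generate_phantom()].
#' @return List of `generate_phantom()` results, one per thickness.
#' @export
remodeling_series <- function(spec, wall_thickness_list, shell_radius_voxels = 8) {
  stopifnot(inherits(spec, "phantom_spec"), length(wall_thickness_list) >= 1)
  if (any(wall_thickness_list < 1)) stop("wall thicknesses must be >= 1 voxel")
  lapply(wall_thickness_list, function(wt) {
    s <- spec
    s$wall_thickness_voxels <- wt
    generate_phantom(s, shell_radius_voxels)
  })
}

#' Phantom series with varying inflammation halo
#'
#' Generates phantoms identical except for a diffuse peribronchial
#' inflammation halo of increasing intensity at fixed wall thickness — the
#' phantom analogue of airway inflammation without remodeling.
#'
#' @param spec base [phantom_spec].
#' @param delta_hu_list halo attenuation increments in HU (0 = no halo).
#' @param extent_voxels halo extent beyond the outer wall, default 32
#'   voxels (about 1.5 mm at 46 um): murine allergic inflammation is
#'   diffuse, reaching well into the parenchyma.
#' @param shell_radius_voxels passed to [generate_phantom()].
#' @return List of `generate_phantom()` results, one per increment.
#' @export
inflammation_series <- function(spec, delta_hu_list, extent_voxels = 32,
                                shell_radius_voxels = 8) {
  stopifnot(inherits(spec, "phantom_spec"), length(delta_hu_list) >= 1)
  lapply(delta_hu_list, function(dh) {
    s <- spec
    s$inflammation_halo <- if (dh == 0) NULL
      else list(extent_voxels = extent_voxels, delta_hu = dh)
    generate_phantom(s, shell_radius_voxels)
  })
}
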