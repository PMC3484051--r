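#' Pipeline configuration
#'
#' Bundles every parameter of the end-to-end analysis.  All numeric settings
#' are echoed into the run report so that each reported number is
#' reproducible from the report alone.
#'
#' @param input path to a volume (NIfTI/MetaImage/DICOM directory) or an
#'   in-memory [ct_volume].
#' @param calibration `NULL` (input already in HU), a
#'   [calibration_standards] object, a `list(air_raw=, water_raw=, ...)`, or
#'   a path to a standards CSV (see [read_calibration_csv()]).
#' @param seeds_lumen,seeds_lung seed voxel triples for the two
#'   segmentations; either may be `NULL` when `auto_seed = TRUE`.
#' @param auto_seed propose missing seeds with [suggest_seed()].
#' @param lumen_band,lung_band HU bands; defaults [lumen_band()] and
#'   [lung_band()].
#' @param connectivity `"face6"` or `"full26"`.
#' @param dilation_radius_voxels shell dilation radius, default 8.
#' @param dilation_mode `"euclidean"` or `"iterated_face"`.
#' @param exclusion_mask `NULL`, a [voxel_mask], or a mask file path
#'   (trachea/mediastinum removal).
#' @param restrict_shell_to_lung intersect the shell with the lung mask,
#'   default `FALSE` (the two VOIs are independent in the reference
#'   protocol).
#' @param output_dir `NULL` (no files) or a directory receiving
#'   `report.json`, `summary.csv` and, when `write_masks = TRUE`, the lumen,
#'   lung and shell masks as NIfTI.
#' @param write_masks write segmentation masks, default `FALSE`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, calibration = NULL,
                            seeds_lumen = NULL, seeds_lung = NULL,
                            auto_seed = FALSE,
                            lumen_band = c(-1024, -900),
                            lung_band = c(-900, -100),
                            connectivity = "face6",
                            dilation_radius_voxels = 8,
                            dilation_mode = "euclidean",
                            exclusion_mask = NULL,
                            restrict_shell_to_lung = FALSE,
                            output_dir = NULL, write_masks = FALSE) {
  cfg <- list(input = input, calibration = calibration,
              seeds_lumen = seeds_lumen, seeds_lung = seeds_lung,
              auto_seed = isTRUE(auto_seed),
              lumen_band = as.numeric(lumen_band),
              lung_band = as.numeric(lung_band),
              connectivity = match.arg(connectivity, c("face6", "full26")),
              dilation_radius_voxels = dilation_radius_voxels,
              dilation_mode = match.arg(dilation_mode,
                                        c("euclidean", "iterated_face")),
              exclusion_mask = exclusion_mask,
              restrict_shell_to_lung = isTRUE(restrict_shell_to_lung),
              output_dir = output_dir, write_masks = isTRUE(write_masks))
  as_band(cfg$lumen_band); as_band(cfg$lung_band)
  if (cfg$dilation_radius_voxels <= 0) stop("dilation radius must be positive")
  if (is.character(input) && !file.exists(input))
    stop(sprintf("config error: input path does not exist: %s", input))
  if (is.character(cfg$exclusion_mask) && !file.exists(cfg$exclusion_mask))
    stop(sprintf("config error: exclusion mask not found: %s", cfg$exclusion_mask))
  if (is.null(seeds_lumen) && !cfg$auto_seed)
    stop("config error: supply seeds_lumen or set auto_seed = TRUE")
  if (is.null(seeds_lung) && !cfg$auto_seed)
    stop("config error: supply seeds_lung or set auto_seed = TRUE")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; seed lists are given as
#' lists of `(x, y, z)` triples and `calibration` as a block with
#' `air_raw`/`water_raw`/`bone_raw` or a `csv` path.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  calib <- y$calibration
  if (!is.null(calib)) {
    calib <- if (!is.null(calib$csv)) read_calibration_csv(calib$csv)
    else calibration_standards(calib$air_raw, calib$water_raw,
                               bone_raw = calib$bone_raw)
  }
  as_seeds <- function(s) if (is.null(s)) NULL else do.call(rbind, lapply(s, as.integer))
  pipeline_config(
    input = y$input, calibration = calib,
    seeds_lumen = as_seeds(y$seeds_lumen), seeds_lung = as_seeds(y$seeds_lung),
    auto_seed = isTRUE(y$auto_seed),
    lumen_band = y$lumen_band %||% c(-1024, -900),
    lung_band = y$lung_band %||% c(-900, -100),
    connectivity = y$connectivity %||% "face6",
    dilation_radius_voxels = y$dilation_radius_voxels %||% 8,
    dilation_mode = y$dilation_mode %||% "euclidean",
    exclusion_mask = y$exclusion_mask,
    restrict_shell_to_lung = isTRUE(y$restrict_shell_to_lung),
    output_dir = y$output_dir, write_masks = isTRUE(y$write_masks))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full peribronchial-attenuation pipeline
#'
#' Executes calibrate (when standards are supplied) -> lumen segmentation ->
#' lung segmentation -> peribronchial shell -> attenuation summary, and
#' optionally writes the report (JSON), a one-row summary CSV and the masks.
#' Deterministic: identical configuration and inputs give identical numeric
#' outputs and byte-identical CSV reports.
#'
#' @param config a [pipeline_config] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return An object of class `pipeline_report`: the [attenuation
#'   summary][summarize_attenuation], the full parameter echo, voxel counts,
#'   seeds actually used, package version and input checksum.  The lumen,
#'   lung and shell masks are attached in `$masks`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  volume <- stage("read", {
    if (inherits(config$input, "ct_volume")) config$input
    else read_volume(config$input)
  })
  checksum <- if (is.character(config$input) && file.exists(config$input) &&
                  !dir.exists(config$input))
    unname(tools::md5sum(config$input)) else NA_character_
  if (!is.null(config$calibration)) {
    standards <- if (inherits(config$calibration, "calibration_standards"))
      config$calibration
    else if (is.character(config$calibration))
      read_calibration_csv(config$calibration)
    else do.call(calibration_standards, config$calibration)
    volume <- stage("calibrate", calibrate_to_hu(volume, standards))
  }
  check_calibrated(volume)
  seeds_lumen <- config$seeds_lumen
  seeds_lung <- config$seeds_lung
  if (is.null(seeds_lumen)) {
    if (!config$auto_seed) stop("pipeline stage 'seed': no lumen seeds")
    seeds_lumen <- stage("seed", matrix(
      suggest_seed(volume, as_band(config$lumen_band)), nrow = 1))
  }
  if (is.null(seeds_lung)) {
    if (!config$auto_seed) stop("pipeline stage 'seed': no lung seeds")
    seeds_lung <- stage("seed", matrix(
      suggest_seed(volume, as_band(config$lung_band)), nrow = 1))
  }
  lumen <- stage("segment_lumen",
    segment_lumen(volume, seeds_lumen, as_band(config$lumen_band),
                  config$connectivity))
  lung <- stage("segment_lung",
    segment_lung(volume, seeds_lung, as_band(config$lung_band),
                 config$connectivity))
  exclusion <- config$exclusion_mask
  if (is.character(exclusion)) exclusion <- stage("read", read_mask(exclusion, volume))
  shell <- stage("shell",
    peribronchial_shell(volume, lumen,
                        dilation_radius_voxels = config$dilation_radius_voxels,
                        band = as_band(config$lumen_band),
                        exclusion = exclusion,
                        lung = if (config$restrict_shell_to_lung) lung else NULL,
                        dilation_mode = config$dilation_mode))
  summary <- stage("summarize", summarize_attenuation(volume, lung, shell))
  report <- structure(list(
    summary = summary,
    parameters = list(
      lumen_band = config$lumen_band, lung_band = config$lung_band,
      connectivity = config$connectivity,
      dilation_radius_voxels = config$dilation_radius_voxels,
      dilation_mode = config$dilation_mode,
      seeds_lumen = unname(apply(seeds_lumen, 1, paste, collapse = ",")),
      seeds_lung = unname(apply(seeds_lung, 1, paste, collapse = ",")),
      exclusion_applied = !is.null(exclusion),
      restrict_shell_to_lung = config$restrict_shell_to_lung),
    voxel_counts = list(lumen = voxel_count(lumen), lung = voxel_count(lung),
                        shell = voxel_count(shell)),
    input = if (is.character(config$input)) config$input else "in-memory volume",
    input_md5 = checksum,
    software_version = as.character(packageVersion("airwayct")),
    masks = list(lumen = lumen, lung = lung, shell = shell)),
    class = "pipeline_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_report(report, config$output_dir, config$write_masks)
  }
  report
}

write_pipeline_report <- function(report, dir, write_masks = FALSE) {
  json <- report[setdiff(names(report), "masks")]
  json$summary <- unclass(json$summary)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(as.data.frame(report$summary), file.path(dir, "summary.csv"),
            row.names = FALSE)
  if (write_masks) {
    write_mask(report$masks$lumen, file.path(dir, "lumen_mask.nii.gz"))
    write_mask(report$masks$lung, file.path(dir, "lung_mask.nii.gz"))
    write_mask(report$masks$shell, file.path(dir, "shell_mask.nii.gz"))
  }
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (airwayct %s)\n", x$software_version))
  cat(sprintf("  input: %s\n", x$input))
  print(x$summary)
  p <- x$parameters
  cat(sprintf("  bands: lumen [%g, %g], lung [%g, %g] HU; dilation %g voxels (%s); %s\n",
              p$lumen_band[1], p$lumen_band[2], p$lung_band[1], p$lung_band[2],
              p$dilation_radius_voxels, p$dilation_mode, p$connectivity))
  invisible(x)
}

#' Agreement analysis from a measurements CSV
#'
#' Accepts either long format (columns `id`, `method`, `value` with exactly
#' two method levels) or wide format (columns `method_a`, `method_b`), runs
#' [bland_altman()], and optionally writes the report as JSON plus the
#' (mean, difference) plot data as CSV.
#'
#' @param pairs_csv input CSV path.
#' @param output_dir optional directory for `agreement.json` and
#'   `bland_altman_points.csv`.
#' @return An `agreement_report`.
#' @export
run_agreement <- function(pairs_csv, output_dir = NULL) {
  if (!file.exists(pairs_csv)) stop(sprintf("CSV not found: %s", pairs_csv))
  df <- read.csv(pairs_csv, stringsAsFactors = FALSE)
  pairs <- if (all(c("method_a", "method_b") %in% names(df))) {
    paired_measurements(df$method_a, df$method_b)
  } else if (all(c("id", "method", "value") %in% names(df))) {
    bad <- which(!complete.cases(df[, c("id", "method", "value")]))
    if (length(bad))
      stop(sprintf("malformed CSV %s: missing values on line %d", pairs_csv,
                   bad[1] + 1L))
    methods <- sort(unique(df$method))
    if (length(methods) != 2L)
      stop(sprintf("CSV %s must contain exactly 2 methods, found %d",
                   pairs_csv, length(methods)))
    wide <- merge(df[df$method == methods[1], c("id", "value")],
                  df[df$method == methods[2], c("id", "value")],
                  by = "id", suffixes = c("_a", "_b"))
    if (nrow(wide) * 2L != nrow(df))
      stop(sprintf("CSV %s has unpaired measurements", pairs_csv))
    paired_measurements(wide$value_a, wide$value_b)
  } else {
    stop(sprintf("CSV %s must have columns id,method,value or method_a,method_b",
                 pairs_csv))
  }
  report <- bland_altman(pairs)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report), "points")],
                         file.path(output_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(report$points, file.path(output_dir, "bland_altman_points.csv"),
              row.names = FALSE)
  }
  report
}
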