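#' Single-channel intensity image
#'
#' Container for one fluorescence channel: a rectangular non-negative raster
#' plus acquisition metadata. All image-processing steps of the pipeline take
#' and return this class. Rasters are stored as base R matrices indexed
#' `[row, col]`; values may be integral (camera counts) or real (intermediate
#' results), but never negative and, for integral rasters, never above
#' `2^bit_depth - 1`.
#'
#' @param pixels numeric matrix, the raster. Must be non-empty with all
#'   values >= 0.
#' @param bit_depth integer, nominal bit depth of the acquisition (16 for the
#'   usual camera TIFFs; the camera itself may use only 12 of those bits,
#'   i.e. counts 0--4095).
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#'   The default 0.647 um/px is the ruler-calibrated factor for a 10x
#'   objective on the reference microscope.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, bit_depth = 16L, pixel_size_um = 0.647) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0)
    stop("pixel values must be finite and >= 0")
  bit_depth <- as.integer(bit_depth)
  maxval <- 2^bit_depth - 1
  intish <- all(pixels == floor(pixels))
  if (intish && max(pixels) > maxval)
    stop("integer raster exceeds 2^bit_depth - 1 = ", maxval)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(
    list(pixels = pixels, bit_depth = bit_depth, pixel_size_um = pixel_size_um),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "<intensity_image> %d x %d px, %d-bit, %.4g um/px, range [%.6g, %.6g]\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

#' Read one channel from an uncompressed single-plane TIFF
#'
#' Reads a grayscale TIFF as acquired by the microscope (8- or 16-bit, one
#' plane). The bit depth is taken from the file; the physical pixel size is
#' deliberately *not* read from TIFF tags — scanner metadata is often stale —
#' but passed in from the analysis configuration.
#'
#' @param path path to the TIFF file.
#' @param pixel_size_um pixel calibration to stamp on the image (um/px).
#' @return An [intensity_image] with raw integer counts.
#' @export
read_channel_image <- function(path, pixel_size_um = 0.647) {
  if (!file.exists(path)) stop("image file not found: ", path)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) stop("cannot read TIFF '", path, "': ",
                                            conditionMessage(e)))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 1L)
    stop("'", path, "' has ", length(pages),
         " pages; the pipeline requires single-plane channel images")
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) != 2L)
    stop("'", path, "' is not single-channel (dims: ",
         paste(dim(raw), collapse = "x"), "); split RGB/stacks upstream")
  bits <- as.integer(info$bits.per.sample[1])
  storage.mode(raw) <- "double"
  intensity_image(raw, bit_depth = bits, pixel_size_um = pixel_size_um)
}

#' Write a channel image as an uncompressed TIFF
#'
#' Inverse of [read_channel_image()]: integral rasters round-trip bit-exactly.
#'
#' @param img an [intensity_image] with integral pixel values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(img, path) {
  stopifnot(inherits(img, "intensity_image"))
  maxval <- 2^img$bit_depth - 1
  tiff::writeTIFF(img$pixels / maxval, path,
                  bits.per.sample = img$bit_depth, compression = "none")
  invisible(path)
}

#' Discover C1/C2 sample pairs in a folder
#'
#' Mirrors the folder-driven batch behaviour of the original macro: every
#' sample is expected as two files `<sample><c1_suffix>.tif` (membrane) and
#' `<sample><c2_suffix>.tif` (MyHC). Suffix matching is case-insensitive and
#' accepts `.tif`/`.tiff`. Files with only one channel present are reported
#' as warnings, never silently dropped.
#'
#' @param folder directory to scan.
#' @param c1_suffix,c2_suffix file-name suffixes (before the extension)
#'   identifying the membrane and MyHC channels.
#' @return A data.frame with columns `sample_id`, `c1_path`, `c2_path`,
#'   sorted by `sample_id`. Unpaired sample ids are attached as the
#'   `"unpaired"` attribute (character vector, possibly empty).
#' @export
discover_sample_pairs <- function(folder, c1_suffix = "_C1", c2_suffix = "_C2") {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  files <- list.files(folder, pattern = "\\.tiff?$", ignore.case = TRUE)
  base <- sub("\\.tiff?$", "", files, ignore.case = TRUE)
  lc <- tolower(base)
  s1 <- tolower(c1_suffix); s2 <- tolower(c2_suffix)
  is_c1 <- endsWith(lc, s1)
  is_c2 <- endsWith(lc, s2)
  id1 <- substr(base[is_c1], 1L, nchar(base[is_c1]) - nchar(c1_suffix))
  id2 <- substr(base[is_c2], 1L, nchar(base[is_c2]) - nchar(c2_suffix))
  paired <- intersect(id1, id2)
  unpaired <- c(setdiff(id1, id2), setdiff(id2, id1))
  if (length(unpaired))
    warning("unpaired channel files for sample(s): ",
            paste(sort(unpaired), collapse = ", "), " — skipped")
  paired <- sort(paired)
  out <- data.frame(
    sample_id = paired,
    c1_path = file.path(folder, files[is_c1][match(paired, id1)]),
    c2_path = file.path(folder, files[is_c2][match(paired, id2)]),
    stringsAsFactors = FALSE
  )
  attr(out, "unpaired") <- sort(unpaired)
  out
}

.fiber_table_columns <- c(
  "fiber_id", "csa_um2", "perimeter_um", "major_diameter_um",
  "minor_diameter_um", "circularity", "fiber_type",
  "centroid_x_px", "centroid_y_px"
)

#' Write the per-fiber result tables
#'
#' Writes three CSV tables — all fibers, type I only, type II only — with one
#' row per fiber. The row counts always satisfy |all| = |type I| + |type II|.
#'
#' @param records per-fiber data.frame as returned by [measure_fibers()] with
#'   a `fiber_type` column (values `"I"`/`"II"`).
#' @param out_dir output directory (created if absent).
#' @param sample_id prefix for the three file names.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fiber_tables <- function(records, out_dir, sample_id = "sample") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cols <- intersect(c(.fiber_table_columns,
                      "feret_max_um", "feret_min_um"), names(records))
  if (nrow(records) == 0L) {
    records <- records[, cols, drop = FALSE]
  } else {
    stopifnot(all(.fiber_table_columns %in% names(records)))
    records <- records[, cols, drop = FALSE]
  }
  paths <- c(
    all    = file.path(out_dir, paste0(sample_id, "_fibers_all.csv")),
    typeI  = file.path(out_dir, paste0(sample_id, "_fibers_typeI.csv")),
    typeII = file.path(out_dir, paste0(sample_id, "_fibers_typeII.csv"))
  )
  utils::write.csv(records, paths[["all"]], row.names = FALSE)
  utils::write.csv(records[records$fiber_type == "I", , drop = FALSE],
                   paths[["typeI"]], row.names = FALSE)
  utils::write.csv(records[records$fiber_type == "II", , drop = FALSE],
                   paths[["typeII"]], row.names = FALSE)
  invisible(paths)
}

#' Write the per-sample run log
#'
#' Plain-text `key: value` log echoing the section summary (tissue area,
#' counts) and the full analysis configuration, so that every number in the
#' output tables can be traced to the parameters that produced it.
#'
#' @param summary a `section_summary` from [summarize_section()].
#' @param config an `analysis_config` (echoed in full).
#' @param out_dir output directory.
#' @param sample_id log file name prefix.
#' @param extra optional named character vector of extra lines (e.g. removed
#'   fiber ids, warnings).
#' @return Path of the log file, invisibly.
#' @export
write_run_log <- function(summary, config, out_dir, sample_id = "sample",
                          extra = character()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, paste0(sample_id, "_log.txt"))
  num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  lines <- c(
    paste0("software: musclemorph ",
           as.character(utils::packageVersion("musclemorph"))),
    paste0("sample_id: ", sample_id),
    paste0("tissue_area_um2: ", num(summary$tissue_area_um2)),
    paste0("n_total: ", num(summary$n_total)),
    paste0("n_type1: ", num(summary$n_type1)),
    paste0("n_type2: ", num(summary$n_type2)),
    paste0("fibers_per_10mm2: ", num(summary$fibers_per_10mm2)),
    paste0("min_area_um2: ", num(config$exclusion$min_area_um2)),
    paste0("max_area_um2: ", num(config$exclusion$max_area_um2)),
    paste0("min_circularity: ", num(config$exclusion$min_circularity)),
    paste0("min_minor_diameter_um: ", num(config$exclusion$min_minor_diameter_um)),
    paste0("pixel_size_um: ", num(config$pixel_size_um)),
    paste0("config: ", jsonlite::toJSON(.config_flat(config), auto_unbox = TRUE))
  )
  if (length(extra))
    lines <- c(lines, paste0(names(extra), ": ", unname(extra)))
  writeLines(lines, path)
  invisible(path)
}

# flatten a config for one-line JSON echo
.config_flat <- function(config) {
  lapply(config, function(x) if (is.list(x)) lapply(x, identity) else x)
}
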