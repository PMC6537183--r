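# --- configuration ------------------------------------------------------

.config_defaults <- function() {
  list(
    pixel_size_um = 0.647,
    preset = "deltoid",
    exclusion = unclass(exclusion_preset("deltoid")),
    despeckle = TRUE,
    saturated_fraction = 0.0035,
    ball_radius_px = 50,
    closing_radius_px = 7,
    tissue_close_radius_px = 20,
    exclude_edge = TRUE,
    positive_fraction_cutoff = 0.5,
    erosion_px = 2,
    c1_suffix = "_C1",
    c2_suffix = "_C2",
    feret = FALSE
  )
}

.merge_config <- function(base, new, origin) {
  for (k in names(new)) {
    if (!k %in% names(base))
      stop("unknown configuration key '", k, "' (", origin, ")")
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], as.list(new[[k]]),
                                 paste0(origin, ":", k))
    } else {
      base[[k]] <- new[[k]]
    }
  }
  base
}

#' Analysis configuration
#'
#' All tunable parameters of the pipeline with their reference defaults:
#' deltoid exclusion bounds (200/13000 um^2, circularity 0.4, minor
#' diameter 1.5 um), 0.647 um/px calibration, 0.35% contrast saturation,
#' 50 px background ball, 7 px gap closing, 20 px tissue closing, MyHC
#' positivity by >= 50% positive interior pixels after 2 px erosion.
#' `preset = "pectoral"` switches the exclusion bounds to 200/20000/0.4/8
#' for the larger pectoral fibers.
#'
#' @param ... overrides of any default (nested lists for `exclusion`).
#' @param preset `"deltoid"` (default) or `"pectoral"`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(..., preset = c("deltoid", "pectoral")) {
  preset <- match.arg(preset)
  cfg <- .config_defaults()
  cfg$preset <- preset
  cfg$exclusion <- unclass(exclusion_preset(preset))
  cfg <- .merge_config(cfg, list(...), "arguments")
  cfg$exclusion <- do.call(exclusion_params, cfg$exclusion)
  structure(cfg, class = "analysis_config")
}

#' Load a configuration with file and flag overrides
#'
#' Precedence, lowest to highest: built-in defaults, preset, YAML config
#' file, explicit overrides (e.g. parsed CLI flags). Unknown keys anywhere
#' are fatal, protecting against typos silently reverting to defaults.
#'
#' @param path optional YAML file with any subset of configuration keys.
#' @param preset optional preset name applied before the file.
#' @param overrides named list applied last.
#' @return An [analysis_config()].
#' @export
load_config <- function(path = NULL, preset = NULL, overrides = list()) {
  cfg <- .config_defaults()
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("deltoid", "pectoral"))
    cfg$preset <- preset
    cfg$exclusion <- unclass(exclusion_preset(preset))
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    if (!is.null(file_cfg)) cfg <- .merge_config(cfg, file_cfg, path)
  }
  cfg <- .merge_config(cfg, overrides, "overrides")
  cfg$exclusion <- do.call(exclusion_params, cfg$exclusion)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>", x$preset, "preset\n")
  ex <- x$exclusion
  cat(sprintf("  exclusion: CSA [%g, %g] um2, circularity >= %g, minor >= %g um\n",
              ex$min_area_um2, ex$max_area_um2, ex$min_circularity,
              ex$min_minor_diameter_um))
  cat(sprintf("  pixel size %g um/px | contrast sat %g | ball %g px | closing %g px\n",
              x$pixel_size_um, x$saturated_fraction, x$ball_radius_px,
              x$closing_radius_px))
  invisible(x)
}

# --- single-section pipeline -------------------------------------------

#' Run the full analysis on one image pair
#'
#' The complete per-sample pipeline: membrane preprocessing, automatic
#' thresholding, gap closing, 4-connected fiber labeling, morphometry,
#' exclusion filtering, tissue-area computation, MyHC typing and section
#' summary.
#'
#' @param c1 membrane-channel [intensity_image].
#' @param c2 MyHC-channel [intensity_image], same dimensions.
#' @param config an [analysis_config()].
#' @param keep_masks keep the full-size membrane and tissue masks in the
#'   result (set `FALSE` to bound memory on whole-mosaic images).
#' @return List of class `section_analysis`: `labels` (final label map),
#'   `records` (typed fiber table), `summary` ([summarize_section()]
#'   result), `membrane_mask`, `tissue_mask`, `tissue_area_um2`,
#'   `myhc_threshold`, `membrane_threshold`, `removed` (excluded original
#'   ids), `config`.
#' @export
run_pipeline <- function(c1, c2, config = analysis_config(),
                         keep_masks = TRUE) {
  stopifnot(inherits(c1, "intensity_image"), inherits(c2, "intensity_image"),
            identical(dim(c1$pixels), dim(c2$pixels)))
  c1$pixel_size_um <- config$pixel_size_um
  c2$pixel_size_um <- config$pixel_size_um
  pre <- preprocess_membrane(c1, config)
  mask <- binarize_membrane(pre)
  rm(pre); gc(FALSE)
  thr1 <- attr(mask, "threshold")
  closed <- close_membrane_gaps(mask, config$closing_radius_px)
  rm(mask); gc(FALSE)
  labels0 <- label_fibers(closed, exclude_edge = config$exclude_edge)
  records0 <- measure_fibers(labels0, config$pixel_size_um,
                             feret = isTRUE(config$feret))
  filt <- apply_exclusion_filters(labels0, records0, config$exclusion)
  rm(labels0, records0)
  area <- compute_tissue_area(closed, filt$labels, config$pixel_size_um,
                              config$tissue_close_radius_px)
  tissue_mask <- attr(area, "mask")
  records <- filt$records
  thr2 <- NA_real_
  if (nrow(records) > 0L && any(tissue_mask)) {
    thr2 <- myhc_threshold(c2, tissue_mask)
    types <- classify_fibers(filt$labels, c2, thr2,
                             config$positive_fraction_cutoff,
                             config$erosion_px)
    records$fiber_type <- as.character(types)
  }
  summary <- summarize_section(records, as.numeric(area))
  structure(list(
    labels = filt$labels,
    records = records,
    summary = summary,
    membrane_mask = if (keep_masks) closed,
    tissue_mask = if (keep_masks) tissue_mask,
    tissue_area_um2 = as.numeric(area),
    myhc_threshold = thr2,
    membrane_threshold = thr1,
    removed = filt$removed,
    config = config
  ), class = "section_analysis")
}

#' @export
print.section_analysis <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

# write every per-sample artifact into `out_dir`
.write_sample_outputs <- function(res, out_dir, sample_id) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_fiber_tables(res$records, out_dir, sample_id)
  write_run_log(res$summary, res$config, out_dir, sample_id,
                extra = c(
                  membrane_threshold = as.character(res$membrane_threshold),
                  myhc_threshold = as.character(res$myhc_threshold),
                  removed_fiber_ids = paste(res$removed, collapse = " ")
                ))
  write_label_tiff(res$labels, file.path(out_dir, paste0(sample_id, "_labels.tif")))
  ps <- res$config$pixel_size_um
  save_png(render_color_map(res$labels, res$records, "area", ps),
           file.path(out_dir, paste0(sample_id, "_map_area.png")))
  save_png(render_color_map(res$labels, res$records, "minor", ps),
           file.path(out_dir, paste0(sample_id, "_map_minor.png")))
  types <- res$records$fiber_type[order(res$records$fiber_id)]
  save_png(render_segmentation_overlay(res$labels, types, "all"),
           file.path(out_dir, paste0(sample_id, "_seg_all.png")))
  save_png(render_segmentation_overlay(res$labels, types, "typeI"),
           file.path(out_dir, paste0(sample_id, "_seg_typeI.png")))
  save_png(render_segmentation_overlay(res$labels, types, "typeII"),
           file.path(out_dir, paste0(sample_id, "_seg_typeII.png")))
  invisible(out_dir)
}

#' Analyze one sample from its channel files
#'
#' Reads the C1/C2 TIFF pair, runs [run_pipeline()] and (optionally) writes
#' the full per-sample output set: three fiber tables, run log, 16-bit
#' label TIFF, two colour-coded size maps and three segmentation overlays.
#'
#' @param c1_path,c2_path channel image paths.
#' @param config an [analysis_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param sample_id sample name for file prefixes.
#' @return The `section_analysis`, invisibly.
#' @export
analyze_sample <- function(c1_path, c2_path, config = analysis_config(),
                           out_dir = NULL, sample_id = "sample") {
  c1 <- read_channel_image(c1_path, config$pixel_size_um)
  c2 <- read_channel_image(c2_path, config$pixel_size_um)
  if (!identical(dim(c1$pixels), dim(c2$pixels)))
    stop("channel dimensions differ for sample '", sample_id, "'")
  res <- run_pipeline(c1, c2, config)
  if (!is.null(out_dir)) .write_sample_outputs(res, out_dir, sample_id)
  invisible(res)
}

# --- batch --------------------------------------------------------------

#' Analyze every sample pair in a folder
#'
#' The one-shot batch mode: discovers all C1/C2 pairs, analyzes each sample
#' in turn, writes each sample's outputs into its own subfolder of
#' `out_dir`, and finishes with a JSON batch report. One failing sample is
#' recorded as failed and does not abort the rest.
#'
#' @param folder input folder with channel TIFFs.
#' @param config an [analysis_config()].
#' @param out_dir output root (default: the input folder).
#' @return data.frame batch report (per-sample status, counts, timing),
#'   invisibly; also written as `batch_report.json`. Attribute
#'   `"n_failed"` carries the failure count.
#' @export
run_batch <- function(folder, config = analysis_config(), out_dir = folder) {
  pairs <- discover_sample_pairs(folder, config$c1_suffix, config$c2_suffix)
  if (nrow(pairs) == 0L)
    stop("no sample pairs found in '", folder, "'; expected files named ",
         "<sample>", config$c1_suffix, ".tif + <sample>", config$c2_suffix,
         ".tif")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    id <- pairs$sample_id[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      analyze_sample(pairs$c1_path[i], pairs$c2_path[i], config,
                     out_dir = file.path(out_dir, id), sample_id = id),
      error = function(e) e
    )
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(sample_id = id, status = "failed",
                              n_total = NA_integer_, n_type1 = NA_integer_,
                              n_type2 = NA_integer_,
                              tissue_area_um2 = NA_real_,
                              seconds = round(el, 2),
                              message = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      sm <- res$summary
      rows[[i]] <- data.frame(sample_id = id, status = "ok",
                              n_total = sm$n_total, n_type1 = sm$n_type1,
                              n_type2 = sm$n_type2,
                              tissue_area_um2 = sm$tissue_area_um2,
                              seconds = round(el, 2), message = "",
                              stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  jsonlite::write_json(report, file.path(out_dir, "batch_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  n_failed <- sum(report$status == "failed")
  message("batch complete: ", nrow(report) - n_failed, "/", nrow(report),
          " samples analyzed", if (n_failed) paste0(" (", n_failed, " failed)"))
  attr(report, "n_failed") <- n_failed
  invisible(report)
}
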