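# --- palette ------------------------------------------------------------

.palette_hex <- c(
  dark_orchid    = "#9932CC",
  night_blue     = "#191970",
  cyan_blue      = "#00B7EB",
  dark_cyan      = "#008B8B",
  dark_sea_green = "#8FBC8F",
  yellow         = "#FFFF00",
  orange         = "#FFA500",
  red            = "#FF0000"
)

.area_breaks  <- c(0, 1000, 1500, 2000, 2500, 3000, 3500, 4000, Inf)
.minor_breaks <- c(0, 10, 20, 30, 40, 50, 60, 70, Inf)

#' The eight-colour fiber-size palette
#'
#' The colour-coded size maps bin each fiber by cross-sectional area
#' (<= 1000 to > 4000 um^2) or minor diameter (<= 10 to > 70 um) into eight
#' fixed colours, from dark orchid (smallest) to red (largest). Named
#' colours are realised as the nearest standard RGB values.
#'
#' @return data.frame with columns `name`, `hex`, `area_max_um2`,
#'   `minor_max_um` (upper inclusive bin edges; `Inf` for the last bin).
#' @export
fiber_palette <- function() {
  data.frame(
    name = names(.palette_hex),
    hex = unname(.palette_hex),
    area_max_um2 = .area_breaks[-1],
    minor_max_um = .minor_breaks[-1],
    stringsAsFactors = FALSE
  )
}

#' Size-bin colour assignment
#'
#' `area_color_bin()` maps a CSA through the area bins (<= 1000,
#' (1000, 1500], ..., > 4000 um^2); `diameter_color_bin()` maps a minor
#' diameter through (<= 10, (10, 20], ..., > 70 um). Both are total on
#' (0, Inf), piecewise constant and monotone in bin index. A value exactly
#' at 1000 um^2 takes the first bin (dark orchid).
#'
#' @param csa fiber CSA in um^2, > 0. Vectorised.
#' @return Character vector of palette colour names.
#' @export
area_color_bin <- function(csa) {
  if (any(csa <= 0)) stop("'csa' must be positive")
  names(.palette_hex)[findInterval(csa, .area_breaks[-1], left.open = TRUE) + 1L]
}

#' @rdname area_color_bin
#' @param minor_d fiber minor diameter in um, > 0. Vectorised.
#' @export
diameter_color_bin <- function(minor_d) {
  if (any(minor_d <= 0)) stop("'minor_d' must be positive")
  names(.palette_hex)[findInterval(minor_d, .minor_breaks[-1], left.open = TRUE) + 1L]
}

# --- rendering ----------------------------------------------------------

.hex_to_rgb <- function(hex) grDevices::col2rgb(hex) / 255

#' Render the colour-coded fiber-size map
#'
#' Paints each fiber's pixels in its size-bin colour over a black background
#' (membrane and excluded regions stay black), appends a legend strip of the
#' eight bin colours on the right, and draws a white scale bar (default
#' 500 um) in the lower-left corner.
#'
#' @param labels fiber label map.
#' @param records per-fiber records covering every label (columns `fiber_id`
#'   and `csa_um2`/`minor_diameter_um`).
#' @param metric `"area"` or `"minor"`.
#' @param pixel_size_um calibration used for the scale bar.
#' @param legend append the legend strip.
#' @param scale_bar_um scale-bar length (um); `0` suppresses it.
#' @return RGB array (height x width x 3, values in `[0, 1]`).
#' @export
render_color_map <- function(labels, records, metric = c("area", "minor"),
                             pixel_size_um = 0.647, legend = TRUE,
                             scale_bar_um = 500) {
  metric <- match.arg(metric)
  n <- max(0L, max(labels))
  if (n > 0L) {
    if (!setequal(records$fiber_id, seq_len(n)))
      stop("records do not cover label ids 1..", n)
    records <- records[order(records$fiber_id), , drop = FALSE]
    cols <- if (metric == "area") area_color_bin(records$csa_um2)
            else diameter_color_bin(records$minor_diameter_um)
    rgb <- .hex_to_rgb(.palette_hex[cols])
  }
  H <- nrow(labels); W <- ncol(labels)
  img <- array(0, c(H, W, 3L))
  if (n > 0L) {
    for (ch in 1:3) {
      plane <- matrix(c(0, rgb[ch, ])[labels + 1L], H, W)
      img[, , ch] <- plane
    }
  }
  if (scale_bar_um > 0) {
    len <- round(scale_bar_um / pixel_size_um)
    hgt <- max(3L, round(H / 150))
    if (len + 40 < W && hgt + 40 < H) {
      rows <- (H - 20 - hgt):(H - 20)
      colsx <- 21:(20 + len)
      img[rows, colsx, ] <- 1
    }
  }
  if (legend) img <- .append_legend(img)
  img
}

# vertical strip of the 8 palette colours, appended at the right
.append_legend <- function(img) {
  H <- dim(img)[1]
  strip_w <- max(8L, round(dim(img)[2] / 40))
  strip <- array(0, c(H, strip_w + 4L, 3L))
  block <- floor(H / 9)
  rgb <- .hex_to_rgb(.palette_hex)
  for (i in seq_along(.palette_hex)) {
    rows <- ((i - 1L) * block + i):(i * block + i - 1L)
    rows <- rows[rows <= H]
    for (ch in 1:3) strip[rows, 3:(2 + strip_w), ch] <- rgb[ch, i]
  }
  out <- array(0, c(H, dim(img)[2] + dim(strip)[2], 3L))
  out[, seq_len(dim(img)[2]), ] <- img
  out[, dim(img)[2] + seq_len(dim(strip)[2]), ] <- strip
  out
}

# boundary pixels of labeled regions: label != 0 and some 4-neighbour differs
.region_boundaries <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(-1L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- labels
  ctr <- pad[2:(H + 1L), 2:(W + 1L)]
  diff <- (pad[1:H, 2:(W + 1L)] != ctr) | (pad[3:(H + 2L), 2:(W + 1L)] != ctr) |
          (pad[2:(H + 1L), 1:W] != ctr) | (pad[2:(H + 1L), 3:(W + 2L)] != ctr)
  diff & labels > 0L
}

#' Render a flattened segmentation overlay
#'
#' Draws the outlines of the selected fiber class over a dark background:
#' the reviewable "flattened image" of the segmentation. Modes: `"all"`
#' (white outlines), `"typeII"` (red), `"typeI"` (green).
#'
#' @param labels fiber label map.
#' @param types per-fiber type vector (`"I"`/`"II"`), required for the
#'   type-specific modes.
#' @param mode which fibers to outline.
#' @return RGB array (height x width x 3).
#' @export
render_segmentation_overlay <- function(labels, types = NULL,
                                        mode = c("all", "typeI", "typeII")) {
  mode <- match.arg(mode)
  n <- max(0L, max(labels))
  sel_ids <- switch(mode,
    all = seq_len(n),
    typeI = which(types == "I"),
    typeII = which(types == "II")
  )
  if (mode != "all" && n > 0L) stopifnot(length(types) == n)
  sel <- matrix(FALSE, nrow(labels), ncol(labels))
  if (n > 0L && length(sel_ids)) {
    keep <- logical(n); keep[sel_ids] <- TRUE
    lsel <- labels
    pos <- lsel > 0L
    v <- lsel[pos]
    v[!keep[v]] <- 0L
    lsel[pos] <- v
    sel <- .region_boundaries(lsel)
  }
  col <- switch(mode, all = c(1, 1, 1), typeI = c(0.1, 0.9, 0.1),
                typeII = c(0.95, 0.15, 0.15))
  img <- array(0, c(nrow(labels), ncol(labels), 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

# --- writers ------------------------------------------------------------

#' Write an RGB array as PNG
#' @param img RGB array from a render function.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Write the label map as a 16-bit TIFF
#'
#' Fiber ids are stored verbatim as 16-bit integer pixel values so the
#' segmentation can be re-analysed later.
#'
#' @param labels integer label map (max label <= 65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read back a 16-bit label TIFF
#' @param path path written by [write_label_tiff()].
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
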