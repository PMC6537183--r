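# --- 3x3 median ---------------------------------------------------------

# Exact median of 9 via a 19-comparator sorting network (Paeth).
# p: list of 9 equal-length numeric vectors. Returns the per-element median.
.median9 <- function(p) {
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    p[[j]] <<- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

# median-of-9 for the interior of a strip of rows (first/last row of `m`
# are context rows; result covers rows 2..(nrow-1), all interior columns)
.despeckle_strip <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- 2:(H - 1L); ci <- 2:(W - 1L)
  p <- vector("list", 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    p[[k]] <- as.vector(m[ri + dr, ci + dc])
  }
  matrix(.median9(p), nrow = length(ri))
}

#' Despeckle (3x3 median filter)
#'
#' Replaces every pixel by the median of its 3x3 neighbourhood; pixels on the
#' image edge use only the in-bounds part of the neighbourhood (6 values on
#' an edge, 4 in a corner). This is the classical "despeckle" noise filter:
#' isolated hot/cold pixels vanish, edges and ridges are preserved.
#'
#' Large images are processed in row strips so memory stays bounded.
#'
#' @param img an [intensity_image].
#' @param strip_rows rows per processing strip (performance knob only; the
#'   result is independent of it).
#' @return Filtered [intensity_image] of identical dimensions.
#' @export
despeckle <- function(img, strip_rows = 1024L) {
  stopifnot(inherits(img, "intensity_image"))
  m <- img$pixels
  H <- nrow(m); W <- ncol(m)
  out <- m
  if (H >= 3L && W >= 3L) {
    starts <- seq(2L, H - 1L, by = strip_rows)
    for (a in starts) {
      b <- min(a + strip_rows - 1L, H - 1L)
      out[a:b, 2:(W - 1L)] <- .despeckle_strip(m[(a - 1L):(b + 1L), , drop = FALSE])
      if (length(m) > 3e7) gc(FALSE)
    }
  }
  # in-bounds medians for the border ring
  edge_idx <- unique(c(
    seq_len(W) * 0L + 1L + (seq_len(W) - 1L) * H,            # row 1
    H + (seq_len(W) - 1L) * H,                               # row H
    seq_len(H),                                              # col 1
    seq_len(H) + (W - 1L) * H                                # col W
  ))
  med_edge <- numeric(length(edge_idx))
  for (i in seq_along(edge_idx)) {
    ij <- edge_idx[i]
    r <- ((ij - 1L) %% H) + 1L
    cc <- ((ij - 1L) %/% H) + 1L
    rs <- max(1L, r - 1L):min(H, r + 1L)
    cs <- max(1L, cc - 1L):min(W, cc + 1L)
    med_edge[i] <- stats::median(m[rs, cs])
  }
  # in-bounds medians of 4 or 6 values can be half-integers
  if (is.integer(out) && any(med_edge != floor(med_edge)))
    storage.mode(out) <- "double"
  out[edge_idx] <- med_edge
  intensity_image(out, img$bit_depth, img$pixel_size_um)
}

# --- contrast -----------------------------------------------------------

#' Automatic percentile contrast stretch
#'
#' Linear rescale of the intensity range so that the lowest and highest
#' `saturated_fraction / 2` of pixels clip to 0 and `2^bit_depth - 1`.
#' With `saturated_fraction = 0` the min/max map exactly to the extremes.
#' The mapping is monotone non-decreasing; output values are rounded to
#' integer counts. A constant image cannot be stretched and is returned
#' unchanged with a warning.
#'
#' @param img an [intensity_image].
#' @param saturated_fraction total fraction of pixels allowed to saturate
#'   (split evenly between the two tails); must be in `[0, 0.5)`. The default
#'   0.0035 (0.35%) is the conventional automatic-enhancement setting.
#' @return Contrast-stretched [intensity_image].
#' @export
enhance_contrast <- function(img, saturated_fraction = 0.0035) {
  stopifnot(inherits(img, "intensity_image"),
            saturated_fraction >= 0, saturated_fraction < 0.5)
  x <- img$pixels
  maxval <- 2^img$bit_depth - 1
  if (saturated_fraction == 0) {
    lo <- min(x); hi <- max(x)
  } else if (is.integer(x) && min(x) >= 0L) {
    # exact order statistics from the histogram (no full sort/copy)
    counts <- tabulate(x + 1L, nbins = max(x) + 1L)
    cum <- cumsum(counts)
    k_lo <- ceiling(saturated_fraction / 2 * length(x))
    k_hi <- ceiling((1 - saturated_fraction / 2) * length(x))
    lo <- which(cum >= max(k_lo, 1L))[1L] - 1L
    hi <- which(cum >= k_hi)[1L] - 1L
  } else {
    q <- stats::quantile(x, c(saturated_fraction / 2, 1 - saturated_fraction / 2),
                         names = FALSE, type = 1)
    lo <- q[1]; hi <- q[2]
  }
  if (hi <= lo) {
    warning("constant image: contrast stretch is a no-op")
    return(img)
  }
  H <- nrow(x)
  out <- matrix(0L, H, ncol(x))
  gain <- maxval / (hi - lo)
  slab <- max(1L, as.integer(2^22 %/% ncol(x)))
  for (a in seq(1L, H, by = slab)) {
    b <- min(a + slab - 1L, H)
    y <- round((x[a:b, , drop = FALSE] - lo) * gain)
    y[y < 0] <- 0
    y[y > maxval] <- maxval
    out[a:b, ] <- as.integer(y)
    if (length(x) > 3e7) gc(FALSE)
  }
  intensity_image(out, img$bit_depth, img$pixel_size_um)
}

# --- background ---------------------------------------------------------

# grayscale opening with a disc, computed on a min-pooled image for large
# radii (the background is smooth by construction, so pooling is lossless in
# practice and keeps the morphology cheap); bilinear upsampling back.
.background_estimate <- function(m, radius) {
  H <- nrow(m); W <- ncol(m)
  # EBImage grayscale morphology operates on [0, 1]; normalisation happens
  # on the (small) pooled image so no full-size scaled copy is needed
  scale <- max(m, 1)
  shrink <- max(1L, as.integer(ceiling(radius / 16)))
  if (shrink > 1L) {
    Hs <- ceiling(H / shrink); Ws <- ceiling(W / shrink)
    small <- matrix(Inf, Hs, Ws)
    for (di in seq_len(shrink)) for (dj in seq_len(shrink)) {
      ir <- pmin(seq(di, by = shrink, length.out = Hs), H)
      ic <- pmin(seq(dj, by = shrink, length.out = Ws), W)
      small <- pmin(small, m[ir, ic])
    }
    r_s <- max(1L, as.integer(round(radius / shrink)))
    bg_s <- EBImage::opening(small / scale,
                             EBImage::makeBrush(2L * r_s + 1L, "disc")) * scale
    bg <- EBImage::imageData(EBImage::resize(EBImage::Image(bg_s),
                                             w = H, h = W))
  } else {
    bg <- EBImage::opening(m / scale,
                           EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                              "disc")) * scale
    bg <- EBImage::imageData(bg)
  }
  bg
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a disc structuring element of the given radius and
#' subtracts it (clipping at 0). Illumination gradients on spatial scales
#' much larger than the radius are flattened; ridges and spots narrower than
#' the ball survive at (close to) full height.
#'
#' @param img an [intensity_image].
#' @param ball_radius_px ball radius in pixels (>= 1). The default 50 px sits
#'   below the typical myofiber diameter at 0.647 um/px, so membrane ridges
#'   are preserved while slide-scale shading is removed.
#' @return Background-subtracted [intensity_image].
#' @export
subtract_background <- function(img, ball_radius_px = 50) {
  stopifnot(inherits(img, "intensity_image"), ball_radius_px >= 1)
  bg <- .background_estimate(img$pixels, ball_radius_px)
  x <- img$pixels
  H <- nrow(x)
  int_in <- is.integer(x)
  out <- if (int_in) matrix(0L, H, ncol(x)) else x
  slab <- max(1L, as.integer(2^22 %/% ncol(x)))
  for (a in seq(1L, H, by = slab)) {
    b <- min(a + slab - 1L, H)
    y <- x[a:b, , drop = FALSE] - bg[a:b, , drop = FALSE]
    y[y < 0] <- 0
    out[a:b, ] <- if (int_in) as.integer(round(y)) else y
  }
  intensity_image(out, img$bit_depth, img$pixel_size_um)
}

#' Membrane-channel preprocessing
#'
#' The enhancement chain applied to the sarcolemma channel before
#' segmentation, in fixed order: despeckle, then contrast stretch, then
#' background subtraction.
#'
#' @param img the raw membrane-channel [intensity_image].
#' @param config an [analysis_config()] (uses `saturated_fraction` and
#'   `ball_radius_px`; `despeckle = FALSE` skips the median step).
#' @return Preprocessed [intensity_image], ready for [binarize_membrane()].
#' @export
preprocess_membrane <- function(img, config = analysis_config()) {
  stopifnot(inherits(img, "intensity_image"))
  out <- img
  if (isTRUE(config$despeckle)) out <- despeckle(out)
  out <- enhance_contrast(out, config$saturated_fraction)
  subtract_background(out, config$ball_radius_px)
}
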