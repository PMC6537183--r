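# --- automatic threshold ------------------------------------------------

# Otsu's criterion on an integer-valued sample: returns the threshold t
# (foreground = value > t) maximising the between-class variance of the
# histogram split. Ties (plateaus across empty bins or a two-valued image)
# resolve to the smallest maximising t — the standard convention, and the
# classification is identical anywhere on the plateau.
.otsu_threshold <- function(values) {
  v <- if (is.integer(values)) values else as.integer(round(values))
  L <- max(v)
  if (L == min(v)) return(L)
  counts <- tabulate(v + 1L, nbins = L + 1L)
  n <- length(v)
  p <- counts / n
  lev <- 0:L
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[L + 1L]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / denom
  sigma_b[denom <= 0 | !is.finite(sigma_b)] <- -Inf
  sigma_b[L + 1L] <- -Inf  # t = L leaves no foreground
  which.max(sigma_b) - 1L
}

#' Binarize the preprocessed membrane channel
#'
#' Computes a global automatic threshold by the maximal between-class
#' variance criterion (Otsu) on the image histogram; membrane pixels are
#' those strictly above the threshold.
#'
#' @param img preprocessed membrane [intensity_image].
#' @return Logical matrix (TRUE = membrane) with the chosen cut attached as
#'   attribute `"threshold"`. A constant image yields an empty mask and a
#'   warning.
#' @export
binarize_membrane <- function(img) {
  stopifnot(inherits(img, "intensity_image"))
  x <- img$pixels
  if (min(x) == max(x)) {
    warning("constant image: no membrane detected")
    mask <- matrix(FALSE, nrow(x), ncol(x))
    attr(mask, "threshold") <- max(x)
    return(mask)
  }
  t <- .otsu_threshold(x)
  mask <- x > t
  attr(mask, "threshold") <- t
  mask
}

# bounding box (with margin) of the TRUE/positive entries of a mask;
# NULL when empty. Lets local morphology run on a crop, exactly.
.bbox <- function(pos, margin, H, W) {
  rs <- range(which(rowSums(pos) > 0))
  cs <- range(which(colSums(pos) > 0))
  if (!is.finite(rs[1])) return(NULL)
  list(r = max(1L, rs[1] - margin):min(H, rs[2] + margin),
       c = max(1L, cs[1] - margin):min(W, cs[2] + margin))
}

# --- gap closing --------------------------------------------------------

#' Close gaps in the membrane network
#'
#' Morphological closing of the binary membrane mask with a disc of the
#' given radius: staining gaps up to about twice the radius in the membrane
#' skeleton are sealed so that fiber interiors become closed regions. The
#' result always contains the input (closing is extensive; the union with
#' the input additionally guards the image border, where padding would
#' otherwise erode original pixels).
#'
#' The default radius of 7 px (~4.5 um at 0.647 um/px) seals gap clusters
#' well below the fiber scale (minor diameters are 40--80 px) while leaving
#' solid membrane unchanged; small radii leave compound staining gaps open
#' and let neighbouring fibers merge.
#'
#' @param mask logical membrane mask.
#' @param closing_radius_px disc radius in pixels (default 7).
#' @return Logical matrix, superset of `mask`.
#' @export
close_membrane_gaps <- function(mask, closing_radius_px = 7) {
  stopifnot(is.logical(mask), is.matrix(mask))
  r <- as.integer(closing_radius_px)
  if (r < 1L || !any(mask)) return(mask)
  # closing only acts within r of foreground: run it on the bounding-box
  # crop (identical result, bounded temporaries on whole-mosaic rasters)
  bb <- .bbox(mask, r + 1L, nrow(mask), ncol(mask))
  sub <- mask[bb$r, bb$c, drop = FALSE]
  m <- matrix(as.numeric(sub), nrow(sub), ncol(sub))
  closed_sub <- EBImage::imageData(
    EBImage::closing(m, EBImage::makeBrush(2L * r + 1L, "disc"))) > 0.5
  out <- mask
  out[bb$r, bb$c] <- closed_sub | sub
  out
}

# --- labeling -----------------------------------------------------------

#' Label individual fibers from the closed membrane mask
#'
#' Fiber interiors are the 4-connected components of the complement of the
#' membrane network. The exterior background — every component touching the
#' image border — is discarded (with `exclude_edge = TRUE`, the default,
#' this also drops genuinely cut-off fibers at the frame edge, the standard
#' particle-analysis convention). Internal holes (organelle-scale unstained
#' spots) are filled into their enclosing fiber before the final
#' renumbering, which follows column-major scan order of each region's first
#' pixel so that ids are reproducible.
#'
#' @param mask closed membrane mask (logical matrix).
#' @param exclude_edge drop components touching the image border. The
#'   exterior background always touches the border and is always dropped.
#' @return Integer matrix; 0 = background/membrane, k = fiber k. The number
#'   of fibers is attached as attribute `"n_labels"`.
#' @export
label_fibers <- function(mask, exclude_edge = TRUE) {
  stopifnot(is.logical(mask), is.matrix(mask))
  big <- length(mask) > 3e7
  free <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(free))  # 4-connected components
  rm(free)
  storage.mode(lab) <- "integer"
  if (big) gc(FALSE)
  nmax <- max(lab)
  if (nmax == 0L) {
    attr(lab, "n_labels") <- 0L
    return(lab)
  }
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  # exterior background always touches the border; exclude_edge additionally
  # removes edge-cut fibers (same mechanism)
  drop <- if (exclude_edge) border else {
    # keep edge fibers: drop only the single largest border component
    # (the exterior); a fully tissue-filled frame has no exterior
    sizes <- tabulate(lab, nmax)
    border[which.max(sizes[border])]
  }
  keep <- rep(TRUE, nmax)
  keep[drop] <- FALSE
  lab[!keep[pmax(lab, 1L)] & lab > 0L] <- 0L
  if (big) gc(FALSE)
  # fill internal holes; fillHull is local to each object, so run it on the
  # crop around the remaining labels
  pos <- lab > 0L
  if (any(pos)) {
    bb <- .bbox(pos, 1L, nrow(lab), ncol(lab))
    sub <- EBImage::fillHull(lab[bb$r, bb$c, drop = FALSE])
    sub <- EBImage::imageData(sub)
    storage.mode(sub) <- "integer"
    lab[bb$r, bb$c] <- sub
  }
  # renumber 1..n by first occurrence in column-major scan order
  u <- unique(as.vector(lab))
  u <- u[u > 0L]
  map <- integer(nmax)
  map[u] <- seq_along(u)
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  attr(lab, "n_labels") <- length(u)
  if (big) gc(FALSE)
  lab
}

# --- exclusion filters --------------------------------------------------

#' Exclusion parameters for fiber filtering
#'
#' The user-adjustable bounds that remove segmentation artifacts: fibers
#' with cross-sectional area, circularity or minor diameter outside these
#' limits are discarded. Comparisons are strict, so a fiber exactly at a
#' bound survives. The `"deltoid"` preset (200, 13000, 0.4, 1.5) is the
#' reference parameter set for deltoid biopsies; `"pectoral"` (200, 20000,
#' 0.4, 8) accommodates the larger pectoral fibers.
#'
#' @param min_area_um2,max_area_um2 CSA bounds in um^2.
#' @param min_circularity dimensionless lower bound in `[0, 1]`.
#' @param min_minor_diameter_um minor-diameter lower bound in um.
#' @return An object of class `exclusion_params`.
#' @export
exclusion_params <- function(min_area_um2 = 200, max_area_um2 = 13000,
                             min_circularity = 0.4,
                             min_minor_diameter_um = 1.5) {
  stopifnot(min_area_um2 >= 0, max_area_um2 > min_area_um2,
            min_circularity >= 0, min_circularity <= 1,
            min_minor_diameter_um >= 0)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_circularity = min_circularity,
                 min_minor_diameter_um = min_minor_diameter_um),
            class = "exclusion_params")
}

#' @rdname exclusion_params
#' @param preset `"deltoid"` or `"pectoral"`.
#' @export
exclusion_preset <- function(preset = c("deltoid", "pectoral")) {
  switch(match.arg(preset),
         deltoid  = exclusion_params(200, 13000, 0.4, 1.5),
         pectoral = exclusion_params(200, 20000, 0.4, 8))
}

#' Apply the exclusion filters to measured fibers
#'
#' Removes every fiber violating any of the four bounds (strict
#' comparisons: CSA < min or > max, circularity < min, minor diameter <
#' min). Survivors are renumbered consecutively in both the label map and
#' the records; removed original ids are returned for the run log.
#'
#' @param labels fiber label map (integer matrix from [label_fibers()]).
#' @param records per-fiber measurements from [measure_fibers()], one row
#'   per label 1..n.
#' @param params an [exclusion_params()].
#' @return List with `labels` (renumbered), `records` (renumbered, with
#'   original ids in `orig_id`), and `removed` (original ids of excluded
#'   fibers).
#' @export
apply_exclusion_filters <- function(labels, records,
                                    params = exclusion_params()) {
  stopifnot(inherits(params, "exclusion_params"))
  n <- max(0L, max(labels))
  stopifnot(nrow(records) == n)
  if (n == 0L) {
    attr(labels, "n_labels") <- 0L
    return(list(labels = labels, records = records, removed = integer()))
  }
  keep <- !(records$csa_um2 < params$min_area_um2 |
            records$csa_um2 > params$max_area_um2 |
            records$circularity < params$min_circularity |
            records$minor_diameter_um < params$min_minor_diameter_um)
  removed <- records$fiber_id[!keep]
  map <- integer(n)
  map[records$fiber_id[keep]] <- seq_len(sum(keep))
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  out <- records[keep, , drop = FALSE]
  out$orig_id <- out$fiber_id
  out$fiber_id <- map[out$fiber_id]
  out <- out[order(out$fiber_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(labels, "n_labels") <- sum(keep)
  list(labels = labels, records = out, removed = removed)
}

# --- tissue area --------------------------------------------------------

# tissue mask: closing of (membrane network + labeled fibers), holes filled.
# For whole-mosaic rasters the closing runs on a max-pooled image — the
# envelope is smooth at the closing scale, and pooling keeps the transient
# memory of the morphology bounded.
.tissue_mask <- function(membrane_mask, labels, tissue_close_radius_px = 20) {
  tissue <- membrane_mask | labels > 0L
  if (!any(tissue)) return(tissue)
  r <- as.integer(tissue_close_radius_px)
  H <- nrow(tissue); W <- ncol(tissue)
  if (r >= 1L) {
    shrink <- if (length(tissue) > 3e7 && r >= 8L) max(1L, r %/% 5L) else 1L
    if (shrink > 1L) {
      Hs <- ceiling(H / shrink); Ws <- ceiling(W / shrink)
      small <- matrix(FALSE, Hs, Ws)
      for (di in seq_len(shrink)) for (dj in seq_len(shrink)) {
        ir <- pmin(seq(di, by = shrink, length.out = Hs), H)
        ic <- pmin(seq(dj, by = shrink, length.out = Ws), W)
        small <- small | tissue[ir, ic]
      }
      r_s <- max(1L, as.integer(round(r / shrink)))
      cl <- EBImage::closing(matrix(as.numeric(small), Hs, Ws),
                             EBImage::makeBrush(2L * r_s + 1L, "disc"))
      cl <- EBImage::imageData(EBImage::fillHull(cl > 0.5))
      big <- cl[pmin((seq_len(H) - 1L) %/% shrink + 1L, Hs),
                pmin((seq_len(W) - 1L) %/% shrink + 1L, Ws)]
      return(big > 0.5 | tissue)
    }
    m <- matrix(as.numeric(tissue), H, W)
    tissue <- EBImage::imageData(
      EBImage::closing(m, EBImage::makeBrush(2L * r + 1L, "disc"))) > 0.5 | tissue
  }
  EBImage::imageData(EBImage::fillHull(tissue)) > 0.5
}

#' Total detected tissue area
#'
#' The analysed surface: membrane network plus all labeled fibers, closed
#' with a generous disc (default radius 20 px) to bridge interstitial space,
#' holes filled, converted to um^2. Always at least the summed fiber area.
#'
#' @param membrane_mask closed membrane mask.
#' @param labels fiber label map.
#' @param pixel_size_um pixel calibration (um/px).
#' @param tissue_close_radius_px closing radius for the tissue envelope.
#' @return Tissue area in um^2 (0 for empty inputs), with the binary tissue
#'   mask attached as attribute `"mask"`.
#' @export
compute_tissue_area <- function(membrane_mask, labels, pixel_size_um = 0.647,
                                tissue_close_radius_px = 20) {
  tissue <- .tissue_mask(membrane_mask, labels, tissue_close_radius_px)
  area <- sum(tissue) * pixel_size_um^2
  attr(area, "mask") <- tissue
  area
}
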