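#' Global MyHC positivity threshold
#'
#' Computes one intensity threshold for the whole section by the maximal
#' between-class variance criterion (Otsu), restricted to tissue pixels of
#' the MyHC channel (C2). A single section-wide cut keeps type calls
#' comparable across the section. If C2 is constant within the tissue the
#' threshold equals that constant (so no pixel is strictly above it and all
#' fibers will be called type I) and a warning is raised.
#'
#' @param c2_img the MyHC-channel [intensity_image].
#' @param tissue_mask logical tissue mask (non-empty), e.g. from
#'   [compute_tissue_area()]'s `"mask"` attribute.
#' @return Numeric threshold; positivity means C2 value strictly above it.
#' @export
myhc_threshold <- function(c2_img, tissue_mask) {
  stopifnot(inherits(c2_img, "intensity_image"),
            is.logical(tissue_mask), any(tissue_mask))
  v <- c2_img$pixels[tissue_mask]
  if (min(v) == max(v)) {
    warning("constant MyHC signal within tissue: all fibers will be type I")
    return(max(v))
  }
  .otsu_threshold(v)
}

#' Classify fibers as type I or type II
#'
#' A fiber is type II (MyHC-positive, fast-twitch) when at least
#' `positive_fraction_cutoff` of its interior pixels exceed the global
#' threshold, and type I otherwise — type I is the complement, so every
#' fiber receives exactly one call. The interior is the fiber region eroded
#' by `erosion_px` to keep membrane bleed-through out of the vote; fibers
#' whose eroded interior is empty fall back to the full region (their ids
#' are attached as attribute `"uneroded"`).
#'
#' @param labels fiber label map.
#' @param c2_img MyHC-channel [intensity_image] of matching dimensions.
#' @param threshold intensity cut from [myhc_threshold()].
#' @param positive_fraction_cutoff fraction of positive interior pixels
#'   required for a type II call (default 0.5).
#' @param erosion_px interior erosion radius in px (default 2).
#' @return Character vector (`"I"`/`"II"`) of length `n_labels`, with the
#'   per-fiber positive fraction as attribute `"positive_fraction"`.
#' @export
classify_fibers <- function(labels, c2_img, threshold,
                            positive_fraction_cutoff = 0.5, erosion_px = 2) {
  stopifnot(inherits(c2_img, "intensity_image"),
            identical(dim(labels), dim(c2_img$pixels)))
  n <- max(0L, max(labels))
  if (n == 0L) return(character(0))
  fg <- labels > 0L
  er <- fg
  if (erosion_px >= 1L && any(fg)) {
    # erosion is local: crop to the labeled region
    bb <- .bbox(fg, as.integer(erosion_px) + 1L, nrow(fg), ncol(fg))
    sub <- fg[bb$r, bb$c, drop = FALSE]
    m <- matrix(as.numeric(sub), nrow(sub), ncol(sub))
    er_sub <- EBImage::imageData(
      EBImage::erode(m, EBImage::makeBrush(2L * as.integer(erosion_px) + 1L,
                                           "disc"))) > 0.5
    er <- matrix(FALSE, nrow(fg), ncol(fg))
    er[bb$r, bb$c] <- er_sub
  }
  pos <- c2_img$pixels > threshold
  count_pos <- function(region) {
    idx <- which(region)
    l <- labels[idx]
    cnt <- tabulate(l, n)
    hit <- rowsum(as.numeric(pos[idx]), factor(l, levels = seq_len(n)))[, 1L]
    list(cnt = cnt, hit = hit)
  }
  e <- count_pos(er & fg)
  uneroded <- which(e$cnt == 0L)
  frac <- ifelse(e$cnt > 0L, e$hit / pmax(e$cnt, 1L), NA_real_)
  if (length(uneroded)) {
    f <- count_pos(fg)
    frac[uneroded] <- f$hit[uneroded] / f$cnt[uneroded]
  }
  type <- ifelse(frac >= positive_fraction_cutoff, "II", "I")
  attr(type, "positive_fraction") <- frac
  attr(type, "uneroded") <- uneroded
  type
}
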