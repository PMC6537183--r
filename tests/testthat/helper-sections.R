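# Shared synthetic fixtures (generated once per test run) and independent
# oracles used across the suite.

.section_cache <- new.env(parent = emptyenv())

# small clean section shared by module tests (fast to generate and analyze)
small_clean_section <- function() {
  if (is.null(.section_cache$small)) {
    .section_cache$small <- generate_section(synthetic_params(
      n_fibers = 60L, image_shape = c(900L, 900L), seed = 101L))
  }
  .section_cache$small
}

small_clean_analysis <- function() {
  if (is.null(.section_cache$small_res)) {
    sec <- small_clean_section()
    .section_cache$small_res <- run_pipeline(sec$c1, sec$c2)
  }
  .section_cache$small_res
}

# --- oracles ------------------------------------------------------------

# brute-force 3x3 in-bounds median
naive_median3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    rs <- max(1, r - 1):min(H, r + 1)
    cs <- max(1, cc - 1):min(W, cc + 1)
    out[r, cc] <- stats::median(m[rs, cs])
  }
  out
}

# exhaustive between-class-variance threshold search over every candidate
# cut value (slow loop, independent of the package implementation)
naive_otsu <- function(values) {
  v <- as.integer(round(values))
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in min(v):(max(v) - 1L)) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# per-pixel colour map oracle: loop every pixel, look its fiber's size up,
# walk the bin table
naive_color_map <- function(labels, csa_by_id, breaks, hex) {
  H <- nrow(labels); W <- ncol(labels)
  out <- array(0, c(H, W, 3))
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    l <- labels[r, cc]
    if (l > 0L) {
      v <- csa_by_id[l]
      b <- 1L
      while (b < length(breaks) - 1L && v > breaks[b + 1L]) b <- b + 1L
      rgb <- grDevices::col2rgb(hex[b]) / 255
      out[r, cc, ] <- rgb
    }
  }
  out
}

# naive boundary oracle: region pixels with any 4-neighbour outside the region
naive_boundary <- function(labels, ids) {
  H <- nrow(labels); W <- ncol(labels)
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    l <- labels[r, cc]
    if (l %in% ids) {
      nb <- c(
        if (r > 1) labels[r - 1, cc] else -1L,
        if (r < H) labels[r + 1, cc] else -1L,
        if (cc > 1) labels[r, cc - 1] else -1L,
        if (cc < W) labels[r, cc + 1] else -1L
      )
      if (any(nb != l)) out[r, cc] <- TRUE
    }
  }
  out
}

# draw a rectangular membrane ring (1 px wide) on a logical mask
draw_ring <- function(mask, r1, r2, c1, c2) {
  mask[r1:r2, c(c1, c2)] <- TRUE
  mask[c(r1, r2), c1:c2] <- TRUE
  mask
}

# rescale an intensity image by a global factor (exposure emulation)
scale_exposure <- function(img, f) {
  intensity_image(pmin(round(img$pixels * f), 2^img$bit_depth - 1),
                  img$bit_depth, img$pixel_size_um)
}
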