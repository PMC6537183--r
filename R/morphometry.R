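# --- boundary tracing ---------------------------------------------------

# Moore (8-connected) boundary trace of a single object in a padded logical
# matrix. Returns the chain of direction codes 0..7 (W, NW, N, NE, E, SE,
# S, SW on (dr, dc)). Empty chain for an isolated pixel.
.trace_chain <- function(m) {
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  H <- nrow(m)
  start <- which(m)[1L]
  sr <- ((start - 1L) %% H) + 1L
  sc <- ((start - 1L) %/% H) + 1L
  maxit <- 4L * sum(m) + 8L
  chain <- integer(maxit)
  nch <- 0L
  cr <- sr; cc <- sc
  b <- 0L                       # search start (backtrack) direction
  for (it in seq_len(maxit)) {
    moved <- FALSE
    for (k in 0:7) {
      d <- (b + k) %% 8L
      nr <- cr + dr[d + 1L]; nc <- cc + dc[d + 1L]
      if (m[nr, nc]) {
        nch <- nch + 1L
        chain[nch] <- d
        cr <- nr; cc <- nc
        b <- (d + 5L) %% 8L
        moved <- TRUE
        break
      }
    }
    if (!moved) return(integer(0))       # isolated pixel
    if (cr == sr && cc == sc && nch > 1L) break
  }
  chain[seq_len(nch)]
}

# perimeter (in px) of one object from its chain code, using the corrected
# chain-length estimator of Vossepoel & Smeulders: 0.980 per straight step,
# 1.406 per diagonal step, -0.091 per direction change. Near-exact on
# digitised disks; an isolated pixel gets the perimeter of its unit square.
.chain_perimeter <- function(chain) {
  n <- length(chain)
  if (n == 0L) return(4)
  odd <- sum(chain %% 2L == 1L)
  corners <- sum(chain != c(chain[-1L], chain[1L]))
  0.980 * (n - odd) + 1.406 * odd - 0.091 * corners
}

# --- per-fiber measurement ----------------------------------------------

#' Measure morphometry of every labeled fiber
#'
#' For each label computes, in calibrated units:
#' * `csa_um2` — pixel count x pixel_size^2;
#' * `perimeter_um` — corrected chain-code boundary length (Moore trace with
#'   Vossepoel--Smeulders weights);
#' * `major_diameter_um`, `minor_diameter_um` — axes of the ellipse with the
#'   same normalised second central moments as the region (pixels treated as
#'   unit squares: a 1/12 term is added to each coordinate variance);
#' * `circularity` — `4*pi*area / perimeter^2`, capped at 1 (digitisation can
#'   push a near-circular region slightly above 1);
#' * `centroid_x_px`, `centroid_y_px` — column/row of the pixel centroid.
#'
#' The moment-ellipse axes are the measurement convention of the ImageJ
#' platform family. They are *not* Feret (caliper) diameters; the narrowest
#' caliper width used in manual myopathology is a different, generally
#' smaller measure. Set `feret = TRUE` to append `feret_max_um` and
#' `feret_min_um` (convex-hull rotating-caliper widths of the boundary pixel
#' centres) for comparison.
#'
#' @param labels integer label map from [label_fibers()].
#' @param pixel_size_um pixel calibration (um/px, default 0.647).
#' @param feret also compute Feret diameters (slower).
#' @return data.frame with one row per label 1..n (fiber type unset).
#' @export
measure_fibers <- function(labels, pixel_size_um = 0.647, feret = FALSE) {
  s <- pixel_size_um
  n <- max(0L, max(labels))
  empty <- data.frame(
    fiber_id = integer(), csa_um2 = numeric(), perimeter_um = numeric(),
    major_diameter_um = numeric(), minor_diameter_um = numeric(),
    circularity = numeric(), fiber_type = character(),
    centroid_x_px = numeric(), centroid_y_px = numeric(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)
  H <- nrow(labels)
  big <- length(labels) > 3e7
  idx <- which(labels > 0L)
  l <- labels[idx]
  if (big) gc(FALSE)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  area_px <- tabulate(l, n)
  if (any(area_px == 0L))
    stop("labels must be consecutive 1..n with no gaps")
  sum_r <- rowsum(as.numeric(r), l)[, 1L]
  sum_c <- rowsum(as.numeric(cc), l)[, 1L]
  sum_rr <- rowsum(as.numeric(r)^2, l)[, 1L]
  sum_cc <- rowsum(as.numeric(cc)^2, l)[, 1L]
  sum_rc <- rowsum(as.numeric(r) * cc, l)[, 1L]
  mr <- sum_r / area_px
  mc <- sum_c / area_px
  # normalised second central moments, +1/12 for the unit-square pixel extent
  vrr <- sum_rr / area_px - mr^2 + 1 / 12
  vcc <- sum_cc / area_px - mc^2 + 1 / 12
  vrc <- sum_rc / area_px - mr * mc
  if (big) gc(FALSE)
  half <- (vrr + vcc) / 2
  spread <- sqrt(((vrr - vcc) / 2)^2 + vrc^2)
  lam1 <- pmax(half + spread, 0)
  lam2 <- pmax(half - spread, 0)
  major_px <- 4 * sqrt(lam1)
  minor_px <- 4 * sqrt(lam2)

  # per-object boundary tracing on bounding-box crops
  o <- order(l)
  ends <- cumsum(area_px)
  starts <- c(1, utils::head(ends, -1L) + 1L)
  perim_px <- numeric(n)
  feret_max <- feret_min <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- o[starts[i]:ends[i]]
    ri <- r[sel]; ci <- cc[sel]
    r0 <- min(ri); c0 <- min(ci)
    sub <- matrix(FALSE, max(ri) - r0 + 3L, max(ci) - c0 + 3L)
    sub[cbind(ri - r0 + 2L, ci - c0 + 2L)] <- TRUE
    chain <- .trace_chain(sub)
    perim_px[i] <- .chain_perimeter(chain)
    if (feret) {
      f <- .feret_diameters(ri, ci)
      feret_max[i] <- f[1L]; feret_min[i] <- f[2L]
    }
  }
  circ <- pmin(1, 4 * pi * area_px / perim_px^2)
  out <- data.frame(
    fiber_id = seq_len(n),
    csa_um2 = area_px * s^2,
    perimeter_um = perim_px * s,
    major_diameter_um = major_px * s,
    minor_diameter_um = minor_px * s,
    circularity = circ,
    fiber_type = NA_character_,
    centroid_x_px = mc,
    centroid_y_px = mr,
    stringsAsFactors = FALSE
  )
  if (feret) {
    out$feret_max_um <- feret_max * s
    out$feret_min_um <- feret_min * s
  }
  out
}

# max/min caliper width of a pixel set (pixel centres, convex hull +
# rotating projections over hull edge directions)
.feret_diameters <- function(r, cc) {
  pts <- unique(cbind(cc, r))
  if (nrow(pts) == 1L) return(c(1, 1))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hp))
  fmax <- max(d2)
  k <- nrow(hp)
  e <- hp[c(2:k, 1L), ] - hp
  ang <- atan2(e[, 2L], e[, 1L])
  fmin <- Inf
  for (a in ang) {
    proj <- hp[, 1L] * -sin(a) + hp[, 2L] * cos(a)
    fmin <- min(fmin, max(proj) - min(proj))
  }
  c(fmax, fmin)
}

# --- scalar formulas ----------------------------------------------------

#' Circularity of a region
#'
#' `4*pi*area / perimeter^2`: 1 for a circle, tending to 0 for elongated
#' shapes. Capped at 1 because discretised near-circles can nominally
#' exceed it.
#'
#' @param csa area (um^2), > 0.
#' @param perimeter perimeter (um), > 0.
#' @return Circularity in (0, 1]. Vectorised.
#' @export
circularity <- function(csa, perimeter) {
  if (any(csa <= 0) || any(perimeter <= 0))
    stop("'csa' and 'perimeter' must be positive")
  pmin(1, 4 * pi * csa / perimeter^2)
}

#' Fibers per 10 mm^2 of tissue
#'
#' Normalises a fiber count by the detected tissue area:
#' `n / area_um2 * 1e7`, i.e. the count expected in a 10-mm^2 section.
#'
#' @param n_fibers fiber count (>= 0).
#' @param tissue_area_um2 tissue area in um^2 (> 0).
#' @return Fibers per 10 mm^2.
#' @export
normalized_fiber_count <- function(n_fibers, tissue_area_um2) {
  if (tissue_area_um2 <= 0) stop("'tissue_area_um2' must be positive")
  n_fibers / tissue_area_um2 * 1e7
}

# CSA score tables. Printed integer bin edges are implemented as half-open
# real intervals so non-integer areas always have a defined score.
.atrophy_score <- function(csa) {
  ifelse(csa <= 500, 20,
  ifelse(csa <= 1000, 10,
  ifelse(csa <= 1500, 5,
  ifelse(csa <= 2000, 1, 0))))
}

.hypertrophy_score <- function(csa) {
  ifelse(csa <= 4500, 0,
  ifelse(csa <= 5500, 1,
  ifelse(csa <= 6500, 5,
  ifelse(csa <= 7500, 10,
  ifelse(csa <= 8500, 20, 30)))))
}

#' Atrophy and hypertrophy factors
#'
#' Section-level scores quantifying how prevalent abnormally small (atrophy)
#' or large (hypertrophy) fibers are: each fiber's CSA is mapped through a
#' fixed score table, the scores are summed and divided by the number of
#' fibers. Atrophy scores: CSA <= 500 um^2 scores 20; (500, 1000] scores 10;
#' (1000, 1500] scores 5; (1500, 2000] scores 1; above 2000 scores 0.
#' Hypertrophy scores: CSA <= 4500 scores 0; (4500, 5500] scores 1;
#' (5500, 6500] scores 5; (6500, 7500] scores 10; (7500, 8500] scores 20;
#' above 8500 scores 30.
#'
#' @param csas numeric vector of fiber CSAs in um^2 (non-empty).
#' @return The mean score (dimensionless).
#' @export
atrophy_factor <- function(csas) {
  if (length(csas) == 0L) stop("atrophy factor is undefined for zero fibers")
  mean(.atrophy_score(csas))
}

#' @rdname atrophy_factor
#' @export
hypertrophy_factor <- function(csas) {
  if (length(csas) == 0L) stop("hypertrophy factor is undefined for zero fibers")
  mean(.hypertrophy_score(csas))
}

# --- section summary ----------------------------------------------------

#' Section-level summary
#'
#' Aggregates typed fiber records into the section report: counts and
#' percentages per type, fibers per 10 mm^2, mean +/- SEM of the four size
#' parameters for all / type I / type II fibers, and atrophy/hypertrophy
#' factors per class. With zero fibers the counts are zero and every
#' class-dependent quantity is NA.
#'
#' @param records measured and typed fiber data.frame.
#' @param tissue_area_um2 detected tissue area (um^2).
#' @return An object of class `section_summary`.
#' @export
summarize_section <- function(records, tissue_area_um2) {
  n_total <- nrow(records)
  type <- records$fiber_type
  n1 <- sum(type == "I"); n2 <- sum(type == "II")
  stopifnot(n1 + n2 == n_total)
  params <- c(csa_um2 = "csa_um2", perimeter_um = "perimeter_um",
              major_diameter_um = "major_diameter_um",
              minor_diameter_um = "minor_diameter_um")
  cls <- list(all = rep(TRUE, n_total), typeI = type == "I",
              typeII = type == "II")
  means <- do.call(rbind, lapply(names(cls), function(cn) {
    sel <- cls[[cn]]
    do.call(rbind, lapply(names(params), function(pn) {
      x <- records[[params[[pn]]]][sel]
      data.frame(class = cn, parameter = pn, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                       else if (length(x) == 1L) 0 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  fac <- function(f, sel) {
    x <- records$csa_um2[sel]
    if (length(x)) f(x) else NA_real_
  }
  structure(list(
    tissue_area_um2 = tissue_area_um2,
    n_total = n_total, n_type1 = n1, n_type2 = n2,
    pct_type1 = if (n_total) 100 * n1 / n_total else NA_real_,
    pct_type2 = if (n_total) 100 * n2 / n_total else NA_real_,
    fibers_per_10mm2 = if (tissue_area_um2 > 0)
      normalized_fiber_count(n_total, tissue_area_um2) else NA_real_,
    atrophy_factor_all = fac(atrophy_factor, cls$all),
    atrophy_factor_1 = fac(atrophy_factor, cls$typeI),
    atrophy_factor_2 = fac(atrophy_factor, cls$typeII),
    hypertrophy_factor_all = fac(hypertrophy_factor, cls$all),
    hypertrophy_factor_1 = fac(hypertrophy_factor, cls$typeI),
    hypertrophy_factor_2 = fac(hypertrophy_factor, cls$typeII),
    means = means
  ), class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat(sprintf("<section_summary> tissue %.0f um2 | %d fibers (I: %d, II: %d)\n",
              x$tissue_area_um2, x$n_total, x$n_type1, x$n_type2))
  if (x$n_total > 0) {
    cat(sprintf("  type I/II: %.1f%% / %.1f%% | %.1f fibers per 10 mm2\n",
                x$pct_type1, x$pct_type2, x$fibers_per_10mm2))
    cat(sprintf("  atrophy factor (all/I/II): %.2f / %.2f / %.2f\n",
                x$atrophy_factor_all, x$atrophy_factor_1, x$atrophy_factor_2))
    cat(sprintf("  hypertrophy factor (all/I/II): %.2f / %.2f / %.2f\n",
                x$hypertrophy_factor_all, x$hypertrophy_factor_1,
                x$hypertrophy_factor_2))
  }
  invisible(x)
}
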