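test_that("membrane binarization separates a two-valued image exactly", {
  m <- matrix(100, 30, 30)
  m[10:20, 10:20] <- 3000
  mask <- binarize_membrane(intensity_image(m))
  expect_identical(mask[, ], m == 3000)
  t <- attr(mask, "threshold")
  expect_true(t >= 100 && t < 3000)
})

test_that("automatic threshold equals the exhaustive-search oracle", {
  set.seed(9)
  # bimodal Gaussian mixture
  v <- c(rnorm(3000, 300, 60), rnorm(1500, 2400, 250))
  v <- pmax(round(v), 0)
  m <- matrix(v, 90, 50)
  mask <- binarize_membrane(intensity_image(m))
  expect_equal(attr(mask, "threshold"), naive_otsu(v))
  # a second, unbalanced mixture
  v2 <- pmax(round(c(rnorm(5000, 150, 40), rnorm(300, 1200, 100))), 0)
  expect_equal(musclemorph:::.otsu_threshold(v2), naive_otsu(v2))
})

test_that("constant image yields an empty mask with a warning", {
  expect_warning(mask <- binarize_membrane(intensity_image(matrix(0, 10, 10))),
                 "constant")
  expect_false(any(mask))
})

thick_ring <- function(n = 40, lo = 10, hi = 30, th = 3) {
  mask <- matrix(FALSE, n, n)
  mask[lo:hi, c(lo:(lo + th - 1), (hi - th + 1):hi)] <- TRUE
  mask[c(lo:(lo + th - 1), (hi - th + 1):hi), lo:hi] <- TRUE
  mask
}

test_that("gap closing seals a broken membrane ring and is extensive + idempotent", {
  mask <- thick_ring()                   # membrane-scale 3 px thick ring
  mask[10:12, 19:21] <- FALSE            # 3 px break
  closed <- close_membrane_gaps(mask, 2)
  expect_true(all(closed[mask]))         # extensive
  # interior is again one enclosed hole: labeling finds exactly 1 fiber
  lab <- label_fibers(closed)
  expect_equal(attr(lab, "n_labels"), 1L)
  # idempotence on the closed result
  again <- close_membrane_gaps(closed, 2)
  expect_identical(again, close_membrane_gaps(again, 2))
  # an intact ring keeps its topology
  lab2 <- label_fibers(close_membrane_gaps(thick_ring(), 2))
  expect_equal(attr(lab2, "n_labels"), 1L)
})

test_that("labeling counts interior cells and drops edge-touching ones", {
  # 2x2 grid of cells drawn fully inside the frame -> 4 fibers
  mask <- matrix(FALSE, 50, 50)
  mask <- draw_ring(mask, 5, 45, 5, 45)
  mask[25, 5:45] <- TRUE
  mask[5:45, 25] <- TRUE
  lab <- label_fibers(mask)
  expect_equal(attr(lab, "n_labels"), 4L)
  expect_equal(sort(unique(as.vector(lab))), 0:4)
  # same grid with the outer frame removed -> cells touch the border -> 0
  mask2 <- matrix(FALSE, 41, 41)
  mask2[21, ] <- TRUE
  mask2[, 21] <- TRUE
  expect_equal(attr(label_fibers(mask2), "n_labels"), 0L)
  # label regions are disjoint and consecutively numbered
  expect_equal(sort(unique(lab[lab > 0])), seq_len(4L))
})

test_that("internal holes are filled into their enclosing fiber", {
  mask <- draw_ring(matrix(FALSE, 30, 30), 5, 25, 5, 25)
  mask[14:16, 14:16] <- TRUE            # organelle-scale blob inside
  lab <- label_fibers(mask)
  expect_equal(attr(lab, "n_labels"), 1L)
  expect_true(all(lab[14:16, 14:16] == 1L))  # swallowed by the fiber
})

test_that("labeling a clean synthetic section matches the generator count", {
  sec <- small_clean_section()
  res <- small_clean_analysis()
  expect_equal(attr(res$labels, "n_labels"), nrow(sec$truth$table))
})

test_that("exclusion filters drop exactly the rule violators", {
  # 50 fibers, 5 violating exactly one rule each
  n <- 50
  rec <- data.frame(
    fiber_id = 1:n,
    csa_um2 = rep(2000, n), perimeter_um = rep(180, n),
    major_diameter_um = rep(60, n), minor_diameter_um = rep(40, n),
    circularity = rep(0.8, n), fiber_type = NA_character_,
    centroid_x_px = 1:n, centroid_y_px = 1:n
  )
  rec$csa_um2[7] <- 150        # below min area
  rec$csa_um2[13] <- 14000     # above max area
  rec$circularity[21] <- 0.39  # below circularity bound
  rec$minor_diameter_um[33] <- 1.2  # below minor-diameter bound
  rec$csa_um2[41] <- 100       # below min area again
  labels <- matrix(0L, 5, n)
  labels[3, ] <- 1:n           # one pixel per fiber, enough for renumbering
  out <- apply_exclusion_filters(labels, rec, exclusion_params())
  expect_equal(nrow(out$records), 45L)
  expect_setequal(out$removed, c(7, 13, 21, 33, 41))
  expect_equal(out$records$fiber_id, 1:45)
  expect_equal(max(out$labels), 45L)
  # ties at the bound survive (strict comparisons)
  rec2 <- rec[1:4, ]
  rec2$csa_um2 <- c(200, 13000, 2000, 2000)
  rec2$circularity <- c(0.8, 0.8, 0.4, 0.8)
  rec2$minor_diameter_um <- c(40, 40, 40, 1.5)
  lab2 <- matrix(0L, 2, 4); lab2[1, ] <- 1:4
  out2 <- apply_exclusion_filters(lab2, rec2, exclusion_params())
  expect_equal(nrow(out2$records), 4L)
})

test_that("relaxing any single exclusion bound never loses survivors", {
  set.seed(31)
  n <- 80
  rec <- data.frame(
    fiber_id = 1:n,
    csa_um2 = exp(runif(n, log(100), log(16000))),
    perimeter_um = runif(n, 50, 400),
    major_diameter_um = runif(n, 10, 120),
    minor_diameter_um = runif(n, 0.5, 80),
    circularity = runif(n, 0.2, 1),
    fiber_type = NA_character_, centroid_x_px = 1:n, centroid_y_px = 1:n
  )
  labels <- matrix(0L, 2, n); labels[1, ] <- 1:n
  base <- exclusion_params()
  n_base <- nrow(apply_exclusion_filters(labels, rec, base)$records)
  relaxed <- list(
    exclusion_params(100, 13000, 0.4, 1.5),
    exclusion_params(200, 20000, 0.4, 1.5),
    exclusion_params(200, 13000, 0.2, 1.5),
    exclusion_params(200, 13000, 0.4, 0.5)
  )
  for (p in relaxed) {
    expect_gte(nrow(apply_exclusion_filters(labels, rec, p)$records), n_base)
  }
})

test_that("tissue area arithmetic and bounds are correct", {
  # solid 1000x1000 block at 0.647 um/px
  mask <- matrix(TRUE, 1000, 1000)
  lab <- matrix(0L, 1000, 1000)
  a <- compute_tissue_area(mask, lab, 0.647, tissue_close_radius_px = 0)
  expect_equal(as.numeric(a), 1e6 * 0.647^2)
  expect_equal(as.numeric(a), 418609)
  # empty inputs -> 0
  expect_equal(as.numeric(compute_tissue_area(matrix(FALSE, 5, 5),
                                              matrix(0L, 5, 5), 0.647)), 0)
  # synthetic section: within 5% of the generator's tissue ellipse,
  # and at least the summed fiber area
  sec <- small_clean_section()
  res <- small_clean_analysis()
  expect_lt(abs(res$tissue_area_um2 / sec$truth$tissue_area_um2 - 1), 0.05)
  expect_gte(res$tissue_area_um2, sum(res$records$csa_um2))
})

test_that("exclusion presets carry the reference parameter sets", {
  d <- exclusion_preset("deltoid")
  expect_equal(unlist(unclass(d)),
               c(min_area_um2 = 200, max_area_um2 = 13000,
                 min_circularity = 0.4, min_minor_diameter_um = 1.5))
  p <- exclusion_preset("pectoral")
  expect_equal(unlist(unclass(p)),
               c(min_area_um2 = 200, max_area_um2 = 20000,
                 min_circularity = 0.4, min_minor_diameter_um = 8))
})
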