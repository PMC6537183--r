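digital_disk <- function(radius, pad = 10L) {
  n <- 2L * radius + 2L * pad
  ctr <- n / 2
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    span <- radius^2 - (i - ctr)^2
    if (span >= 0) {
      j <- which((seq_len(n) - ctr)^2 <= span)
      m[i, j] <- 1L
    }
  }
  m
}

test_that("a single pixel has CSA equal to the calibration square", {
  lab <- matrix(0L, 5, 5); lab[3, 3] <- 1L
  rec <- measure_fibers(lab, 0.647)
  expect_equal(rec$csa_um2, 0.647^2)
  expect_equal(rec$csa_um2, 0.418609)
})

test_that("a rasterised disk reproduces the analytic circle", {
  rec <- measure_fibers(digital_disk(30L), 0.647)
  true_csa <- pi * 30^2 * 0.647^2
  expect_lt(abs(rec$csa_um2 / true_csa - 1), 0.02)
  expect_gte(rec$circularity, 0.95)
  expect_lte(abs(rec$major_diameter_um - rec$minor_diameter_um),
             0.02 * rec$major_diameter_um)
  # perimeter near 2*pi*r
  expect_lt(abs(rec$perimeter_um / (2 * pi * 30 * 0.647) - 1), 0.02)
})

test_that("a 10x40 rectangle has the analytic moment-ellipse axis ratio", {
  lab <- matrix(0L, 60, 60); lab[11:20, 11:50] <- 1L
  rec <- measure_fibers(lab, 1)
  expect_lt(abs(rec$major_diameter_um / rec$minor_diameter_um - 4), 0.02 * 4)
  # centroid at the rectangle centre
  expect_equal(rec$centroid_x_px, 30.5)
  expect_equal(rec$centroid_y_px, 15.5)
})

test_that("Feret diameters bracket the moment-ellipse axes sensibly", {
  rec <- measure_fibers(digital_disk(20L), 1, feret = TRUE)
  expect_lt(abs(rec$feret_max_um - 40) / 40, 0.05)
  expect_lt(abs(rec$feret_min_um - 40) / 40, 0.05)
  lab <- matrix(0L, 30, 70); lab[11:20, 11:60] <- 1L
  r2 <- measure_fibers(lab, 1, feret = TRUE)
  expect_equal(r2$feret_min_um, 9)    # pixel-centre caliper of a 10-row bar
  expect_gte(r2$feret_max_um, 49)
})

test_that("morphometry is exactly scale-equivariant in pixel size", {
  lab <- matrix(0L, 40, 40); lab[5:30, 8:25] <- 1L
  r1 <- measure_fibers(lab, 0.647)
  r2 <- measure_fibers(lab, 1.294)
  expect_equal(r2$csa_um2, 4 * r1$csa_um2)
  expect_equal(r2$perimeter_um, 2 * r1$perimeter_um)
  expect_equal(r2$major_diameter_um, 2 * r1$major_diameter_um)
  expect_equal(r2$minor_diameter_um, 2 * r1$minor_diameter_um)
  expect_equal(r2$circularity, r1$circularity)
})

test_that("stored circularity is consistent with stored CSA and perimeter", {
  res <- small_clean_analysis()
  rec <- res$records
  expect_true(all(abs(pmin(1, 4 * pi * rec$csa_um2 / rec$perimeter_um^2) -
                      rec$circularity) < 1e-6))
  expect_true(all(rec$minor_diameter_um <= rec$major_diameter_um + 1e-9))
})

test_that("circularity formula matches analytic shapes and rejects bad input", {
  expect_equal(circularity(pi, 2 * pi), 1)
  expect_equal(circularity(1, 4), pi / 4)
  expect_lt(circularity(1, 4), 0.4 + 0.4)  # square well above exclusion bound
  expect_error(circularity(0, 1), "positive")
  expect_error(circularity(1, -1), "positive")
  # cap at 1
  expect_equal(circularity(100, 1), 1)
})

test_that("normalized fiber count applies the 1e7 rule", {
  expect_equal(normalized_fiber_count(100, 1e7), 100)
  expect_equal(normalized_fiber_count(500, 2.5e6), 2000)
  expect_equal(normalized_fiber_count(0, 1e6), 0)
  expect_error(normalized_fiber_count(10, 0), "positive")
})

test_that("atrophy factor reproduces the score table", {
  expect_equal(atrophy_factor(c(300, 300)), 20)
  expect_equal(atrophy_factor(c(2500, 2500, 2500)), 0)
  expect_equal(atrophy_factor(c(400, 800, 1200, 1800, 2500)), 7.2)
  # bin edges: 500 scores 20, 500.5 scores 10, 2000 scores 1, 2000.5 scores 0
  expect_equal(atrophy_factor(500), 20)
  expect_equal(atrophy_factor(500.5), 10)
  expect_equal(atrophy_factor(1000), 10)
  expect_equal(atrophy_factor(1500), 5)
  expect_equal(atrophy_factor(2000), 1)
  expect_equal(atrophy_factor(2000.5), 0)
  expect_error(atrophy_factor(numeric(0)), "undefined")
})

test_that("hypertrophy factor reproduces the score table", {
  expect_equal(hypertrophy_factor(5000), 1)
  expect_equal(hypertrophy_factor(c(9000, 9000)), 30)
  expect_equal(hypertrophy_factor(c(4600, 6000, 7000, 8000, 9000, 2000)), 11)
  expect_equal(hypertrophy_factor(4500), 0)
  expect_equal(hypertrophy_factor(5500), 1)
  expect_equal(hypertrophy_factor(6500), 5)
  expect_equal(hypertrophy_factor(7500), 10)
  expect_equal(hypertrophy_factor(8500), 20)
  expect_equal(hypertrophy_factor(8500.5), 30)
  expect_error(hypertrophy_factor(numeric(0)), "undefined")
})

test_that("score factors are monotone when a fiber crosses a bin boundary", {
  base <- c(800, 1800, 3000, 5200)
  f0 <- atrophy_factor(base)
  shifted <- base; shifted[1] <- 450   # moved down across the 500 boundary
  expect_gte(atrophy_factor(shifted), f0)
  h0 <- hypertrophy_factor(base)
  up <- base; up[4] <- 5800            # moved up across the 5500 boundary
  expect_gte(hypertrophy_factor(up), h0)
})

test_that("section summary aggregates counts, means and factors", {
  rec <- data.frame(
    fiber_id = 1:10,
    csa_um2 = c(rep(1000, 4), rep(3000, 6)),
    perimeter_um = rep(150, 10),
    major_diameter_um = rep(50, 10),
    minor_diameter_um = rep(35, 10),
    circularity = rep(0.9, 10),
    fiber_type = c(rep("I", 4), rep("II", 6)),
    centroid_x_px = 1:10, centroid_y_px = 1:10
  )
  sm <- summarize_section(rec, 5e6)
  expect_equal(sm$n_total, 10)
  expect_equal(sm$pct_type1, 40)
  expect_equal(sm$pct_type2, 60)
  expect_equal(sm$pct_type1 + sm$pct_type2, 100)
  expect_equal(sm$fibers_per_10mm2, 10 / 5e6 * 1e7)
  expect_equal(sm$atrophy_factor_1, 10)   # all type I at 1000 um2
  expect_equal(sm$atrophy_factor_2, 0)
  expect_equal(sm$atrophy_factor_all, 4)
  m <- sm$means
  expect_equal(m$mean[m$class == "typeI" & m$parameter == "csa_um2"], 1000)
  expect_equal(m$sem[m$class == "typeI" & m$parameter == "csa_um2"], 0)
  # identical values -> SEM 0; mixed -> SEM > 0
  expect_gt(m$sem[m$class == "all" & m$parameter == "csa_um2"], 0)
  # zero fibers: counts zero, class quantities missing
  sm0 <- summarize_section(rec[0, ], 1e6)
  expect_equal(sm0$n_total, 0)
  expect_true(is.na(sm0$atrophy_factor_all))
  expect_true(is.na(sm0$pct_type1))
})

test_that("per-class means on a synthetic section sit near generator truth", {
  sec <- small_clean_section()
  res <- small_clean_analysis()
  sm <- res$summary
  m <- sm$means
  all_csa <- m[m$class == "all" & m$parameter == "csa_um2", ]
  truth_mean <- mean(sec$truth$table$csa_um2)
  expect_lt(abs(all_csa$mean - truth_mean), 2 * all_csa$sem + 0.02 * truth_mean)
})
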