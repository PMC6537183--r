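test_that("intensity_image validates its raster", {
  expect_s3_class(intensity_image(matrix(0:3, 2, 2)), "intensity_image")
  expect_error(intensity_image(matrix(-1, 2, 2)), ">= 0")
  expect_error(intensity_image(matrix(70000, 2, 2), bit_depth = 16),
               "exceeds")
  expect_error(intensity_image(matrix(numeric(0), 0, 0)), "non-empty")
  # 8-bit bound
  expect_error(intensity_image(matrix(300, 2, 2), bit_depth = 8), "exceeds")
})

test_that("TIFF round-trips are bit-exact for 8- and 16-bit rasters", {
  dir <- withr::local_tempdir()
  m16 <- matrix(sample(0:65535, 100 * 100, TRUE), 100, 100)
  storage.mode(m16) <- "double"
  p <- file.path(dir, "x_C1.tif")
  write_channel_image(intensity_image(m16, 16L), p)
  back <- read_channel_image(p)
  expect_equal(back$pixels, m16)
  expect_identical(back$bit_depth, 16L)

  m8 <- matrix(sample(0:255, 50 * 60, TRUE), 50, 60)
  storage.mode(m8) <- "double"
  p8 <- file.path(dir, "y_C1.tif")
  write_channel_image(intensity_image(m8, 8L), p8)
  back8 <- read_channel_image(p8)
  expect_equal(back8$pixels, m8)
  expect_identical(back8$bit_depth, 8L)
})

test_that("constant 16-bit image reads back verbatim", {
  dir <- withr::local_tempdir()
  m <- matrix(500, 100, 100)
  p <- file.path(dir, "c_C1.tif")
  write_channel_image(intensity_image(m), p)
  expect_true(all(read_channel_image(p)$pixels == 500))
})

test_that("reader rejects missing, RGB and multi-page files", {
  dir <- withr::local_tempdir()
  expect_error(read_channel_image(file.path(dir, "nope.tif")), "not found")
  rgb <- file.path(dir, "rgb_C1.tif")
  tiff::writeTIFF(array(runif(12), c(2, 2, 3)), rgb)
  expect_error(read_channel_image(rgb), "single-channel")
  multi <- file.path(dir, "multi_C1.tif")
  tiff::writeTIFF(list(matrix(0.5, 2, 2), matrix(0.1, 2, 2)), multi)
  expect_error(read_channel_image(multi), "pages")
  bad <- file.path(dir, "bad.tif")
  writeLines("not a tiff", bad)
  expect_error(read_channel_image(bad))
})

test_that("sample pairing matches complete pairs and reports strays", {
  dir <- withr::local_tempdir()
  img <- intensity_image(matrix(1, 4, 4))
  for (f in c("a_C1", "a_C2", "b_C1", "b_C2"))
    write_channel_image(img, file.path(dir, paste0(f, ".tif")))
  pairs <- discover_sample_pairs(dir)
  expect_equal(pairs$sample_id, c("a", "b"))
  expect_true(all(file.exists(pairs$c1_path, pairs$c2_path)))

  # lone C1 -> no pair, one warning
  dir2 <- withr::local_tempdir()
  write_channel_image(img, file.path(dir2, "solo_C1.tif"))
  expect_warning(p2 <- discover_sample_pairs(dir2), "unpaired")
  expect_equal(nrow(p2), 0L)
  expect_equal(attr(p2, "unpaired"), "solo")

  # case-insensitive suffix and .tiff extension
  dir3 <- withr::local_tempdir()
  write_channel_image(img, file.path(dir3, "s_c1.tiff"))
  write_channel_image(img, file.path(dir3, "s_C2.tif"))
  expect_equal(discover_sample_pairs(dir3)$sample_id, "s")

  expect_error(discover_sample_pairs(file.path(dir, "missing")), "not found")
})

test_that("pairing recovers every sample written by the simulator", {
  dir <- withr::local_tempdir()
  manifest <- simulate_batch(dir, n_samples = 3L,
                             params = synthetic_params(n_fibers = 12L,
                                                       image_shape = c(420L, 420L)),
                             seed = 5L)
  pairs <- discover_sample_pairs(dir)
  expect_setequal(pairs$sample_id, manifest$sample_id)
  expect_equal(nrow(pairs), 3L)
})

test_that("fiber tables partition into all = typeI + typeII", {
  dir <- withr::local_tempdir()
  rec <- data.frame(
    fiber_id = 1:5, csa_um2 = c(500, 900, 1500, 2500, 3000),
    perimeter_um = rep(100, 5), major_diameter_um = rep(40, 5),
    minor_diameter_um = rep(25, 5), circularity = rep(0.8, 5),
    fiber_type = c("II", "I", "II", "II", "I"),
    centroid_x_px = 1:5, centroid_y_px = 1:5
  )
  paths <- write_fiber_tables(rec, dir, "s1")
  tabs <- lapply(paths, read.csv)
  expect_equal(nrow(tabs$all), 5L)
  expect_equal(nrow(tabs$typeI), 2L)
  expect_equal(nrow(tabs$typeII), 3L)
  expect_equal(nrow(tabs$all), nrow(tabs$typeI) + nrow(tabs$typeII))

  # empty records -> header-only tables
  paths0 <- write_fiber_tables(rec[0, ], dir, "s0")
  expect_equal(nrow(read.csv(paths0[["all"]])), 0L)
  expect_true(all(c("fiber_id", "csa_um2") %in% names(read.csv(paths0[["all"]]))))
})

test_that("run log echoes the summary and parses back", {
  dir <- withr::local_tempdir()
  rec <- data.frame(
    fiber_id = 1:2, csa_um2 = c(1000, 2000), perimeter_um = c(120, 170),
    major_diameter_um = c(45, 60), minor_diameter_um = c(30, 42),
    circularity = c(0.9, 0.85), fiber_type = c("I", "II"),
    centroid_x_px = 1:2, centroid_y_px = 1:2
  )
  sm <- summarize_section(rec, 1e7)
  path <- write_run_log(sm, analysis_config(), dir, "s1")
  lines <- readLines(path)
  kv <- strsplit(grep("^[a-z0-9_]+: ", lines, value = TRUE), ": ")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  expect_equal(as.numeric(vals[["tissue_area_um2"]]), 1e7)
  expect_equal(as.numeric(vals[["n_total"]]), 2)
  expect_equal(as.numeric(vals[["n_type1"]]), 1)
  expect_equal(as.numeric(vals[["min_area_um2"]]), 200)
  expect_equal(as.numeric(vals[["max_area_um2"]]), 13000)
  expect_equal(as.numeric(vals[["pixel_size_um"]]), 0.647)
  expect_match(vals[["software"]], "musclemorph")
})
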