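noiseless_t1_map <- function(n = 10, t1 = 800, ...) {
  maps <- uniform_maps(n = n, t1 = t1)
  s <- simulate_series(maps, protocol_schedule("T1"))
  fit_map(s, ...)
}

test_that("noiseless uniform series yield flat maps at the true T1", {
  m <- noiseless_t1_map()
  expect_true(all(m$mask))
  expect_true(all(abs(m$time_ms - 800) < 4))
  expect_true(all(m$r_squared > 1 - 1e-9))
  st <- roi_stats(m)
  expect_equal(st$mean_ms, 800, tolerance = 0.005)
  expect_equal(st$n_pixels, 100)
})

test_that("mask and zero are coupled exactly, and noise background is masked", {
  spec <- phantom_spec(fov_mm = 20, matrix = 32,
                       tube_inner_diameter_mm = 10, capillary_count = 4)
  maps <- build_phantom(spec)
  s <- simulate_series(maps, protocol_schedule("T1"), noise_sigma = 0.02,
                       seed = 3)
  m <- fit_map(s)
  # the de-noising rule: below-threshold or invalid pixels replaced with 0
  expect_identical(m$time_ms != 0, m$mask)
  expect_true(all(is.na(m$r_squared[m$mask]) == FALSE))
  expect_true(all(m$r_squared[m$mask] >= 0.4))
  bg <- maps$labels == 0L
  expect_gte(mean(!m$mask[bg]), 0.85)   # pure-noise pixels largely suppressed
  expect_true(all(m$mask[maps$labels == 1L]))  # water interior survives
})

test_that("ROI restriction confines the fit and statistics", {
  maps <- uniform_maps(n = 12, t1 = 700)
  s <- simulate_series(maps, protocol_schedule("T1"))
  roi <- roi_rect(2, 3, 6, 8)
  m <- fit_map(s, roi = roi)
  inroi <- roi_mask(roi, c(12, 12))
  expect_identical(m$mask, inroi)
  expect_true(all(m$time_ms[!inroi] == 0))
  st <- roi_stats(m, roi)
  expect_equal(st$n_pixels, sum(inroi))
  expect_error(fit_map(s, roi = roi_rect(20, 20, 30, 30)), "ROI")
  expect_error(roi_stats(m, roi_rect(8, 0, 12, 3)), "empty ROI")
})

test_that("roi_stats uses the population-SD convention over kept pixels", {
  m <- noiseless_t1_map(n = 8)
  m$time_ms[, 1:4] <- 100
  m$time_ms[, 5:8] <- 300
  st <- roi_stats(m)
  expect_equal(st$mean_ms, 200)
  expect_equal(st$sd_ms, 100)
  m$time_ms[] <- 673
  st2 <- roi_stats(m)
  expect_equal(st2$mean_ms, 673)
  expect_equal(st2$sd_ms, 0)
})

test_that("line profiles rasterize one row of pixels with mask semantics", {
  m <- noiseless_t1_map(n = 10, t1 = 600)
  p <- line_profile(m, c(0, 4), c(9, 4))
  expect_equal(nrow(p), 10)
  expect_true(all(abs(p$time_ms - 600) < 4))
  expect_equal(p$distance_mm, 0:9)  # spacing 1 mm

  # masked band reads back as zeros
  m$mask[, 5:6] <- FALSE
  m$time_ms[, 5:6] <- 0
  p2 <- line_profile(m, c(0, 2), c(9, 2))
  expect_true(all(p2$time_ms[5:6] == 0))
  expect_true(all(p2$time_ms[-(5:6)] != 0))

  # diagonal across a step field agrees with direct indexing
  m$mask[] <- TRUE
  m$time_ms[] <- 100
  m$time_ms[, 6:10] <- 900
  p3 <- line_profile(m, c(0, 0), c(9, 9))
  direct <- vapply(seq_len(nrow(p3)), function(i) {
    m$time_ms[i, i]  # 45-degree diagonal visits (i, i)
  }, numeric(1))
  expect_equal(p3$time_ms, direct)
  expect_error(line_profile(m, c(2, 2), c(2, 2)), "zero-length")
})

test_that("histograms count kept pixels and conserve totals", {
  m <- noiseless_t1_map(n = 8)
  h <- map_histogram(m, bins = 5)
  expect_equal(sum(h$counts), roi_stats(m)$n_pixels)
  expect_equal(sum(h$counts > 0), 1)  # uniform field in a single bin
  m$time_ms[, 1:4] <- 100
  m$time_ms[, 5:8] <- 300
  h2 <- map_histogram(m, bins = 2)
  expect_equal(h2$counts, c(32, 32))
  expect_length(h2$bin_edges_ms, 3)
})

test_that("exports are lossless, deterministic, and carry provenance", {
  m <- noiseless_t1_map(n = 8)
  m$time_ms[2, 2] <- 0; m$mask[2, 2] <- FALSE  # one masked pixel
  d <- withr::local_tempdir()
  csv1 <- file.path(d, "map1.csv"); csv2 <- file.path(d, "map2.csv")
  export_map(m, csv1, "csv")
  export_map(m, csv2, "csv")
  expect_identical(read_map_csv(csv1), m$time_ms)     # bit-exact round trip
  expect_identical(readLines(csv1), readLines(csv2))  # deterministic bytes

  pngf <- file.path(d, "map.png")
  export_map(m, pngf, "png")
  img <- png::readPNG(pngf)
  expect_true(all(img[2, 2, ] == 0))  # masked pixel rendered as reserved black

  rep <- file.path(d, "map.txt")
  export_map(m, rep, "report")
  txt <- readLines(rep)
  expect_true(any(grepl("r2_threshold: 0.4", txt)))
  expect_true(any(grepl("population SD", txt)))
  expect_true(any(grepl("15000", txt)))  # schedule recorded
  expect_error(export_map(m, file.path(d, "x"), "tiff"), "arg")
})

test_that("two maps' ROI populations can be compared", {
  mk <- function(t1, seed) {
    s <- simulate_series(uniform_maps(n = 8, t1 = t1),
                         protocol_schedule("T1"),
                         noise_sigma = 0.01, seed = seed)
    fit_map(s)
  }
  ht <- roi_compare(mk(700, 1), mk(900, 2))
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.05)
})
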