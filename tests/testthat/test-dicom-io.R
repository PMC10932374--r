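make_int_series <- function(matrix = 16, t1 = 2250, noise = 0, seed = 1,
                            spacing = 50 / 512) {
  maps <- parameter_maps(matrix(1, matrix, matrix), t1, 120,
                         pixel_spacing_mm = spacing)
  s <- simulate_series(maps, protocol_schedule("T1"), noise_sigma = noise,
                       seed = seed)
  sch <- series_schedule(s)
  arr <- round(series_array(s) * 10000)  # scanner-like integer counts
  image_series(arr, sch$tr_ms, sch$te_ms, pixel_spacing_mm = spacing)
}

test_that("write -> catalog -> load is the identity on pixels, timing, spacing", {
  s <- make_int_series()
  d <- withr::local_tempdir()
  paths <- write_series(s, d)
  expect_length(paths, 9)
  cat <- catalog_series(d)
  expect_length(cat$groups, 1)
  s2 <- load_series(cat)
  expect_identical(series_array(s2), series_array(s))
  expect_equal(series_schedule(s2)$tr_ms, tr_schedule())
  expect_equal(s2$pixel_spacing_mm, rep(50 / 512, 2))
  expect_identical(s2$mode, "T1")
  expect_equal(s2$fixed_parameter_ms, 3)
})

test_that("loading sorts frames by the varied parameter regardless of file order", {
  s <- make_int_series()
  d <- withr::local_tempdir()
  paths <- write_series(s, d)
  # scramble the lexicographic file order
  scrambled <- file.path(d, sprintf("Z%02d.dcm", rev(seq_along(paths))))
  file.rename(paths, scrambled)
  s2 <- load_series(catalog_series(d))
  expect_equal(series_schedule(s2)$tr_ms, sort(tr_schedule()))
  arr <- series_array(s2)
  # frame intensities must rise with TR in a uniform phantom
  means <- apply(arr, 3, mean)
  expect_true(all(diff(means) > 0))
})

test_that("non-DICOM files are skipped without aborting the catalog", {
  s <- make_int_series()
  d <- withr::local_tempdir()
  write_series(s, d)
  writeLines("not a dicom", file.path(d, "README.txt"))
  writeBin(raw(200), file.path(d, "junk.dcm"))
  expect_message(cat <- catalog_series(d), "skipped")
  expect_equal(nrow(cat$entries), 9)
  expect_length(cat$skipped, 2)
  expect_error(catalog_series(withr::local_tempdir()), "no DICOM input")
})

test_that("a DICOMDIR index drives discovery when present", {
  s <- make_int_series()
  d <- withr::local_tempdir()
  write_series(s, d, dicomdir = TRUE)
  expect_true(file.exists(file.path(d, "DICOMDIR")))
  # decoy that the index does not reference: DICOMDIR wins over the scan
  decoy <- withr::local_tempdir()
  write_series(make_int_series(t1 = 300), decoy)
  file.copy(list.files(decoy, full.names = TRUE)[1], file.path(d, "XX01.dcm"))
  cat <- catalog_series(d)
  expect_equal(nrow(cat$entries), 9)
  s2 <- load_series(cat)
  expect_identical(series_array(s2), series_array(s))
})

test_that("non-integer pixel grids survive the round trip to 16-bit precision", {
  maps <- parameter_maps(matrix(runif(256, 0.2, 1), 16, 16), 800, 100)
  s <- simulate_series(maps, protocol_schedule("T2"))
  d <- withr::local_tempdir()
  write_series(s, d)
  s2 <- load_series(catalog_series(d))
  a1 <- series_array(s); a2 <- series_array(s2)
  expect_equal(series_schedule(s2)$te_ms, te_schedule())
  expect_identical(s2$mode, "T2")
  expect_lt(max(abs(a1 - a2)), max(a1) / 65535)
})

test_that("invariants are enforced before writing", {
  expect_error(
    image_series(array(-1, c(4, 4, 3)), c(500, 1000, 2000), rep(3, 3)),
    "non-negative")
  expect_error(
    image_series(array(1, c(4, 4, 2)), c(500, 1000), c(3, 3)),
    "3 frames")
  expect_error(
    image_series(array(1, c(4, 4, 3)), c(500, 1000, 2000), c(3, 4, 5)),
    "ambiguous")
})

test_that("a frame missing its timing tag is reported as missing metadata", {
  s <- make_int_series()
  d <- withr::local_tempdir()
  paths <- write_series(s, d)
  # strip the RepetitionTime element from one file at the byte level
  raw <- readBin(paths[1], "raw", file.size(paths[1]))
  tr_hdr <- as.raw(c(0x18, 0x00, 0x80, 0x00, 0x44, 0x53))  # (0018,0080) DS
  pos <- which(vapply(seq_len(length(raw) - 5L), function(i) {
    all(raw[i:(i + 5L)] == tr_hdr)
  }, logical(1)))
  expect_length(pos, 1)
  len <- as.integer(raw[pos + 6L]) + 256L * as.integer(raw[pos + 7L])
  raw <- raw[-(pos:(pos + 7L + len))]
  writeBin(raw, paths[1])
  expect_error(load_series(catalog_series(d)), "missing timing metadata")
})

test_that("written files conform to the standard per an independent DICOM reader", {
  s <- make_int_series(matrix = 8)
  d <- withr::local_tempdir()
  paths <- write_series(s, d)
  script <- file.path(d, "check.py")
  writeLines(c(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "px = ds.pixel_array",
    "print(float(ds.RepetitionTime), float(ds.EchoTime),",
    "      float(ds.PixelSpacing[0]), px.shape[0], px.shape[1],",
    "      int(px.sum()))"
  ), script)
  out <- system2("python", c(script, paths[9]), stdout = TRUE)
  vals <- as.numeric(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
  fr <- s$frames[[9]]
  expect_equal(vals[1], fr$tr_ms)
  expect_equal(vals[2], fr$te_ms)
  expect_equal(vals[3], s$pixel_spacing_mm[1], tolerance = 1e-9)
  expect_equal(vals[4:5], dim(fr$pixels))
  expect_equal(vals[6], sum(fr$pixels))
})

test_that("catalog export records path and timing columns", {
  s <- make_int_series(matrix = 8)
  d <- withr::local_tempdir()
  write_series(s, d)
  cat <- catalog_series(d)
  csv <- file.path(d, "catalog.csv")
  export_catalog(cat, csv)
  tab <- read.csv(csv)
  expect_equal(names(tab), c("path", "tr_ms", "te_ms", "rows", "cols"))
  expect_equal(sort(tab$tr_ms), sort(tr_schedule()))
})
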