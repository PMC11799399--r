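test_that("RMS normalization scales to unit root mean square", {
  expect_equal(rms_normalize(c(3, 4)), c(0.8485, 1.1314), tolerance = 1e-4)
  expect_equal(rms_normalize(5), 1)
  z <- rms_normalize(c(0, 0))
  expect_equal(as.numeric(z), c(0, 0))
  expect_true(isTRUE(attr(z, "flagged")))
})

test_that("dataset RMS normalization is idempotent and scale invariant", {
  set.seed(1)
  pk <- data.frame(x = rep(0:2, each = 4), y = rep(0:1, 6),
                   mz = runif(12, 800, 2000), intensity = runif(12, 1, 50))
  d1 <- rms_normalize(tiny_dataset(pk))
  # per-spectrum RMS is 1 after normalization
  g <- paste(d1$peaks$x, d1$peaks$y)
  rms <- tapply(d1$peaks$intensity, g, function(v) sqrt(mean(v^2)))
  expect_equal(as.numeric(rms), rep(1, length(rms)), tolerance = 1e-12)
  d2 <- rms_normalize(d1)
  expect_equal(d2$peaks$intensity, d1$peaks$intensity, tolerance = 1e-12)
  pk2 <- pk; pk2$intensity <- pk2$intensity * 7.3
  d3 <- rms_normalize(tiny_dataset(pk2))
  expect_equal(d3$peaks$intensity, d1$peaks$intensity, tolerance = 1e-12)
})

test_that("ion image extraction respects ppm and mobility windows", {
  pk <- data.frame(x = c(0, 1, 2, 2), y = 0,
                   mz = c(1000, 1000 * (1 + 11e-6), 1000, 1000),
                   mobility = c(1.5, 1.5, 1.8, 1.5),
                   intensity = c(10, 20, 30, 5))
  d <- tiny_dataset(pk, width = 3, height = 1)
  img <- extract_ion_image(d, 1000, 10)
  expect_equal(img[1, 1], 10)          # exact hit
  expect_equal(img[1, 2], 0)           # 11 ppm away at 10 ppm tolerance
  img2 <- extract_ion_image(d, 1000, 10, mobility_window = c(1.4, 1.6))
  expect_equal(img2[1, 3], 5)          # 1.8 excluded, 1.5 kept
  expect_error(extract_ion_image(d, 1000, 10, mobility_window = c(1.6, 1.4)),
               "empty mobility window")
})

test_that("ion images are additive over disjoint mobility windows", {
  set.seed(7)
  pk <- data.frame(x = sample(0:3, 40, TRUE), y = sample(0:3, 40, TRUE),
                   mz = 1200 * (1 + runif(40, -5e-6, 5e-6)),
                   mobility = runif(40, 1.3, 1.7),
                   intensity = runif(40, 1, 10))
  d <- tiny_dataset(pk)
  a <- extract_ion_image(d, 1200, 10, mobility_window = c(1.3, 1.5))
  b <- extract_ion_image(d, 1200, 10, mobility_window = c(1.500001, 1.7))
  ab <- extract_ion_image(d, 1200, 10, mobility_window = c(1.3, 1.7))
  expect_equal(unclass(a) + unclass(b), unclass(ab), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("spatial smoothing averages on-tissue neighbours", {
  pk <- data.frame(x = rep(0:3, each = 4), y = rep(0:3, 4),
                   mz = 1000, intensity = 4)
  d <- tiny_dataset(pk)
  img <- extract_ion_image(d, 1000, 10)
  expect_equal(smooth_image(img, 1), img)               # identity
  expect_equal(unclass(smooth_image(img, 2)),
               unclass(img), ignore_attr = TRUE)        # constant unchanged
  # single bright pixel at (2,2) on a 4x4 grid, 2x2 window with offsets
  # {0,+1}: the four windows covering the pixel each average it over 4
  pk2 <- pk; pk2$intensity <- ifelse(pk2$x == 2 & pk2$y == 2, 16, 0)
  img2 <- smooth_image(extract_ion_image(tiny_dataset(pk2), 1000, 10), 2)
  expected <- matrix(0, 4, 4)
  expected[2:3, 2:3] <- 4
  expect_equal(unclass(img2), expected, ignore_attr = TRUE)
})

test_that("smoothing keeps off-tissue pixels missing", {
  pk <- data.frame(x = c(0, 1), y = c(0, 0), mz = 1000,
                   intensity = c(8, 4))
  d <- tiny_dataset(pk, width = 2, height = 2)   # row y=1 off tissue
  sm <- smooth_image(extract_ion_image(d, 1000, 10), 2)
  expect_true(all(is.na(unclass(sm)[2, ])))
  expect_equal(unclass(sm)[1, ], c(6, 4), ignore_attr = TRUE)
})

test_that("imzML round-trip is lossless", {
  set.seed(5)
  pk <- data.frame(x = rep(0:2, each = 3), y = rep(0:2, 3),
                   mz = sort(runif(9, 800, 2000)),
                   mobility = runif(9, 1.2, 2.1),
                   intensity = runif(9, 1, 100))
  d <- tiny_dataset(pk, width = 3, height = 3)
  f <- file.path(tempdir(), "rt.imzML")
  write_imzml(d, f)
  d2 <- read_imzml(f)
  expect_equal(d2$peaks[c("x", "y", "mz", "mobility", "intensity")],
               d$peaks[c("x", "y", "mz", "mobility", "intensity")],
               tolerance = 1e-12)
  expect_equal(d2$width, d$width)
  expect_equal(d2$metadata$mz_range, d$metadata$mz_range)

  # mobility-free (TIMS off) data round-trips with mobility absent
  pk$mobility <- NULL
  d3 <- tiny_dataset(pk, width = 3, height = 3)
  write_imzml(d3, f)
  expect_true(all(is.na(read_imzml(f)$peaks$mobility)))
})

test_that("imzML round-trip holds on random datasets", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:40, 1)
    pk <- data.frame(x = sample(0:4, n, TRUE), y = sample(0:4, n, TRUE),
                     mz = runif(n, 800, 2000),
                     mobility = runif(n, 1.2, 2.1),
                     intensity = runif(n, 0, 100))
    pk <- pk[!duplicated(pk[c("x", "y", "mz")]), ]
    d <- tiny_dataset(pk, width = 5, height = 5)
    f <- file.path(tempdir(), sprintf("rt%d.imzML", s))
    write_imzml(d, f)
    d2 <- read_imzml(f)
    expect_equal(nrow(d2$peaks), nrow(d$peaks))
    expect_equal(d2$peaks$mz, d$peaks$mz, tolerance = 1e-12)
    expect_equal(d2$peaks[c("x", "y")], d$peaks[c("x", "y")])
  }
})

test_that("imzML reader rejects bad input explicitly", {
  bad <- file.path(tempdir(), "corrupt.imzML")
  writeLines("<mzML><oops", bad)
  expect_error(read_imzml(bad), "corrupt.imzML")

  cont <- file.path(tempdir(), "cont.imzML")
  writeLines(paste0(
    '<?xml version="1.0"?><mzML><fileDescription><fileContent>',
    '<cvParam accession="IMS:1000030" name="continuous"/>',
    '</fileContent></fileDescription></mzML>'), cont)
  file.create(sub("imzML$", "ibd", cont))
  expect_error(read_imzml(cont), "continuous")
})

test_that("MGF export writes one parseable block per spectrum", {
  mk <- function(id, mz, peaks) {
    structure(list(precursor = list(id = id, mz = mz, mobility_low = 1.4,
                                    mobility_high = 1.45),
                   peaks = peaks, n_pixels = 3L), class = "ms2_spectrum")
  }
  sp <- list(mk("p1", 900.5, data.frame(mz = c(175.119, 300.2),
                                        intensity = c(10, 5))),
             mk("p2", 1100.6, data.frame(mz = 400.1, intensity = 2)))
  f <- file.path(tempdir(), "out.mgf")
  write_mgf(sp, f)
  lines <- readLines(f)
  expect_equal(sum(lines == "BEGIN IONS"), 2L)
  back <- read_mgf(f)
  expect_equal(back[[1]]$precursor$id, "p1")
  expect_equal(back[[1]]$peaks$mz, c(175.119, 300.2), tolerance = 1e-6)
  expect_equal(back[[2]]$precursor$mz, 1100.6, tolerance = 1e-6)
  expect_equal(back[[1]]$n_pixels, 3L)

  # empty spectra are skipped with a warning, order of the rest preserved
  sp2 <- c(sp, list(mk("p3", 1200, data.frame(mz = numeric(),
                                              intensity = numeric()))))
  expect_warning(write_mgf(sp2, f), "empty")
  expect_length(read_mgf(f), 2L)
})
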