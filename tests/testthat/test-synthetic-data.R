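test_that("simulated mobility maps mass affinely with clipping", {
  # jitter-free endpoints of the affine map
  g <- peptide("G")
  expect_equal(simulate_mobility(peptide("LGGNEQVTR"), jitter_sd = 0),
               1.3 + (973.506121 - 800) * 0.0005, tolerance = 1e-6)
  # ordering preserved without jitter: heavier peptide, larger 1/K0
  m1 <- simulate_mobility(peptide("LGGNEQVTR"), jitter_sd = 0)
  m2 <- simulate_mobility(peptide("DGLDAASYYAPVR"), jitter_sd = 0)
  expect_lt(m1, m2)
  # jitter is a fixed, seeded property of the peptide
  expect_equal(simulate_mobility("LGGNEQVTR", seed = 5),
               simulate_mobility("LGGNEQVTR", seed = 5))
  expect_true(simulate_mobility("LGGNEQVTR", seed = 5) !=
                simulate_mobility("LGGNEQVTR", seed = 6))
})

test_that("simulated mobilities reproduce the iRT mass-mobility trend", {
  irt <- irt_reference()
  sim <- vapply(irt$sequence, simulate_mobility, numeric(1), jitter_sd = 0)
  # the measured MALDI values and the simulated ones are both monotone
  # in mass for the five calibration peptides
  o <- order(irt$mz_lc)
  expect_true(all(diff(irt$mobility_maldi[o]) > 0))
  expect_true(all(diff(sim[o]) > 0))
})

test_that("MS1 simulation is seed-reproducible and audited", {
  spec <- small_phantom(seed = 20)
  s1 <- simulate_ms1(spec)
  s2 <- simulate_ms1(spec)
  expect_identical(s1$dataset$peaks, s2$dataset$peaks)
  # every non-baseline peak is listed in the ground truth
  expect_equal(nrow(s1$dataset$peaks) - nrow(s1$truth),
               sum(!paste(s1$dataset$peaks$mz) %in% paste(s1$truth$mz)))
  expect_true(all(c("sequence", "region") %in% names(s1$truth)))

  # different seed, different data
  s3 <- simulate_ms1(small_phantom(seed = 21))
  expect_false(identical(s1$dataset$peaks, s3$dataset$peaks))
})

test_that("noise-free pixels carry exactly the panel peaks", {
  spec <- small_phantom(seed = 22, noise = noise_free)
  sim <- simulate_ms1(spec)
  p <- sim$dataset$peaks
  # a cellular pixel: all cellular panel peptides, nothing else
  cpx <- which(spec$region_masks$cellular, arr.ind = TRUE)[1, ]
  pix <- p[p$x == cpx[2] - 1 & p$y == cpx[1] - 1, ]
  cell_panel <- spec$panel[spec$panel$region == "cellular", ]
  expect_setequal(round(pix$mz, 6), round(cell_panel$mz, 6))
  expect_equal(sort(pix$intensity), sort(cell_panel$mean_abundance))
})

test_that("panel masses outside the acquisition window are rejected", {
  spec <- small_phantom(seed = 23)
  spec$panel$mz[1] <- 700
  expect_error(simulate_ms1(spec), "outside the m/z 800-2000")
})

test_that("total signal scales linearly with abundance", {
  spec <- small_phantom(seed = 24, noise = noise_free)
  s1 <- simulate_ms1(spec)
  spec2 <- spec
  spec2$panel$mean_abundance <- spec$panel$mean_abundance * 2
  s2 <- simulate_ms1(spec2)
  expect_equal(sum(s2$dataset$peaks$intensity),
               2 * sum(s1$dataset$peaks$intensity), tolerance = 1e-9)
})

test_that("iprm simulation fragments the windowed peptides", {
  spec <- small_phantom(seed = 25, noise = noise_free)
  i <- which.min(spec$panel$mobility)
  pep <- spec$panel[i, ]
  sched <- data.frame(id = "w1", mz = pep$mz,
                      mobility_low = pep$mobility - 0.01,
                      mobility_high = pep$mobility + 0.01,
                      priority = 1, collision_energy = 100)
  sim <- simulate_iprm(spec, sched)
  avg <- average_spectra(extract_ms2(sim$dataset, sched), precursor = sched)
  theo <- fragment_series(peptide(pep$sequence))
  expect_equal(sort(round(avg$peaks$mz, 4)), sort(round(theo$mz, 4)))

  # empty precursor list yields an empty dataset
  expect_equal(nrow(simulate_iprm(spec, sched[0, ])$dataset$peaks), 0L)
})

test_that("overlapping windows produce chimeric spectra", {
  spec <- small_phantom(seed = 26, noise = noise_free)
  o <- order(spec$panel$mobility)
  # find two panel peptides close in mobility and cover both
  gaps <- diff(spec$panel$mobility[o])
  j <- which.min(gaps)
  p1 <- spec$panel[o[j], ]; p2 <- spec$panel[o[j + 1], ]
  sched <- data.frame(id = "wc", mz = p1$mz,
                      mobility_low = min(p1$mobility, p2$mobility) - 0.005,
                      mobility_high = max(p1$mobility, p2$mobility) + 0.005,
                      priority = 1, collision_energy = 100)
  sim <- simulate_iprm(spec, sched)
  expect_setequal(unique(sim$truth$sequence),
                  c(p1$sequence, p2$sequence))
  avg <- average_spectra(extract_ms2(sim$dataset, sched), precursor = sched)
  both <- sort(unique(round(c(fragment_series(peptide(p1$sequence))$mz,
                              fragment_series(peptide(p2$sequence))$mz), 3)))
  expect_setequal(sort(round(avg$peaks$mz, 3)), both)
})

test_that("noise-free fragment images equal the parent abundance map", {
  spec <- small_phantom(seed = 27, noise = noise_free)
  i <- which.max(spec$panel$mobility)
  pep <- spec$panel[i, ]
  sched <- data.frame(id = "w1", mz = pep$mz,
                      mobility_low = pep$mobility - 0.01,
                      mobility_high = pep$mobility + 0.01,
                      priority = 1, collision_energy = 100)
  sim2 <- simulate_iprm(spec, sched)
  ms1 <- simulate_ms1(spec)$dataset
  parent <- extract_ion_image(ms1, pep$mz, 10)
  theo <- fragment_series(peptide(pep$sequence))
  frag <- extract_ion_image(sim2$dataset, theo$mz[3],
                            tol_ppm = 0.3 / theo$mz[3] * 1e6,
                            mobility_window = c(sched$mobility_low,
                                                sched$mobility_high))
  res <- coloc_to_feature(frag, parent)
  expect_equal(res$r, 1, tolerance = 1e-9)
})
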