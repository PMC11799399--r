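make_spec <- function(mz, int, pre_mz = NA_real_, id = "p1", n_pixels = 1L) {
  structure(list(precursor = list(id = id, mz = pre_mz,
                                  mobility_low = 1.4, mobility_high = 1.45),
                 peaks = data.frame(mz = mz, intensity = int)[order(mz), ],
                 n_pixels = n_pixels), class = "ms2_spectrum")
}

test_that("mobilogram extraction splits precursors cleanly", {
  spec <- small_phantom(seed = 16, noise = noise_free)
  # two windows around two different panel peptides
  o <- order(spec$panel$mobility)
  p1 <- spec$panel[o[1], ]; p2 <- spec$panel[o[nrow(spec$panel)], ]
  sched <- rbind(
    data.frame(id = "w1", mz = p1$mz, mobility_low = p1$mobility - 0.01,
               mobility_high = p1$mobility + 0.01, priority = 1,
               collision_energy = 100),
    data.frame(id = "w2", mz = p2$mz, mobility_low = p2$mobility - 0.01,
               mobility_high = p2$mobility + 0.01, priority = 1,
               collision_energy = 100))
  sim <- simulate_iprm(spec, sched)
  s1 <- extract_ms2(sim$dataset, sched[1, ])
  s2 <- extract_ms2(sim$dataset, sched[2, ])
  home1 <- spec$region_masks[[p1$region]]
  expect_equal(length(s1), sum(home1))   # pixels where the parent lives
  # disjoint windows yield disjoint extractions
  k1 <- vapply(s1, function(s) paste(s$x, s$y), "")
  k2 <- vapply(s2, function(s) paste(s$x, s$y), "")
  expect_length(intersect(paste("w", k1), paste("x", k2)), 0L)
  # a window containing no planted precursor is empty, with a warning
  empty <- data.frame(id = "w0", mz = 900, mobility_low = 2.05,
                      mobility_high = 2.09, priority = 1,
                      collision_energy = 100)
  expect_warning(s0 <- extract_ms2(sim$dataset, empty), "no MS2 frames")
  expect_length(s0, 0L)
})

test_that("spectrum averaging pools, bins and zero-fills", {
  a <- list(x = 0, y = 0, peaks = data.frame(mz = c(100, 200),
                                             intensity = c(4, 6)))
  b <- list(x = 1, y = 0, peaks = data.frame(mz = c(100, 200),
                                             intensity = c(4, 6)))
  avg <- average_spectra(list(a, b))
  expect_equal(avg$peaks$intensity, c(4, 6))   # identical spectra unchanged
  expect_equal(avg$n_pixels, 2L)

  # peak in 1 of 4 pixels at intensity 8 averages to 2
  quiet <- function(i) list(x = i, y = 0,
                            peaks = data.frame(mz = 300, intensity = 1))
  loud <- list(x = 9, y = 0, peaks = data.frame(mz = c(300, 500),
                                                intensity = c(1, 8)))
  avg4 <- average_spectra(c(lapply(1:3, quiet), list(loud)))
  expect_equal(avg4$peaks$intensity[avg4$peaks$mz == 500], 2)

  # merge below tolerance, keep separate above
  c1 <- list(x = 0, y = 0, peaks = data.frame(mz = 400.00, intensity = 2))
  c2 <- list(x = 1, y = 0, peaks = data.frame(mz = 400.02, intensity = 2))
  c3 <- list(x = 2, y = 0, peaks = data.frame(mz = 400.12, intensity = 2))
  expect_equal(nrow(average_spectra(list(c1, c2))$peaks), 1L)
  expect_equal(nrow(average_spectra(list(c1, c3))$peaks), 2L)

  # permutation invariance in pixel order
  set.seed(17)
  px <- lapply(1:6, function(i) list(
    x = i, y = 0, peaks = data.frame(mz = sort(runif(5, 100, 900)),
                                     intensity = runif(5, 1, 10))))
  a1 <- average_spectra(px)
  a2 <- average_spectra(rev(px))
  expect_equal(a1$peaks, a2$peaks, tolerance = 1e-12)
})

test_that("candidate generation respects the precursor tolerance", {
  db <- decoy_database(c(COLX = "AAAKGPAGPQGPRAAAK"))
  idx <- build_peptide_index(db, max_missed = 2, max_mods = 2)
  q <- mh_mz(peptide("GPAGPQGPR"))
  cand <- generate_candidates(idx, q * (1 + 20e-6), tol = 100)
  expect_true("GPAGPQGPR" %in% cand$sequence)
  # 105 ppm off the only matching mass
  cand2 <- generate_candidates(idx, q * (1 + 105e-6), tol = 100)
  expect_false("GPAGPQGPR" %in% cand2$sequence[!cand2$decoy])
  # decoys are flagged
  expect_true(any(idx$decoy))
  expect_true(all(grepl("rev_", idx$proteins[idx$decoy])))
  expect_error(generate_candidates(idx[0, ], 900), "empty")
})

test_that("the binomial score rewards matched ions", {
  pep <- peptide("LGGNEQVTR")
  theo <- fragment_series(pep)
  full <- make_spec(theo$mz, rep(10, nrow(theo)), pre_mz = mh_mz(pep))
  psm <- score_psm(full, pep)
  expect_equal(psm$matched_b + psm$matched_y, nrow(theo))
  expect_gt(psm$score, 50)

  # no matches scores exactly 0 (P(X >= 0) = 1)
  none <- make_spec(c(1000, 1100), c(5, 5), pre_mz = mh_mz(pep))
  expect_equal(score_psm(none, pep)$score, 0)

  # monotone in the number of matched ions
  scores <- vapply(seq_len(nrow(theo)), function(k) {
    sp <- make_spec(c(theo$mz[seq_len(k)], seq(2000, 2400, length.out = 8)),
                    rep(1, k + 8), pre_mz = mh_mz(pep))
    score_psm(sp, pep)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("the chance-match model is calibrated on random spectra", {
  set.seed(18)
  pep <- peptide("LGGNEQVTR")
  trials <- nrow(fragment_series(pep))
  npeaks <- 50
  span_lo <- 150; span_hi <- 1000
  q <- 2 * 0.3 * npeaks / (span_hi - span_lo)
  matched <- vapply(1:200, function(i) {
    sp <- make_spec(runif(npeaks, span_lo, span_hi), rep(1, npeaks))
    p <- score_psm(sp, pep)
    p$matched_b + p$matched_y
  }, numeric(1))
  # mean matched count within the binomial 95% band for the mean of 200
  mu <- trials * q
  se <- sqrt(trials * q * (1 - q) / 200)
  expect_lt(abs(mean(matched) - mu), 1.96 * se * 1.5)
})

test_that("search ranks the true peptide first and controls decoys", {
  db <- make_search_db(50)
  idx <- build_peptide_index(db)
  pep <- peptide("LFPPAGPR")   # bundled collagen-like panel peptide
  theo <- fragment_series(pep)
  sp <- make_spec(theo$mz + rnorm(nrow(theo), 0, 0.01),
                  runif(nrow(theo), 5, 20), pre_mz = mh_mz(pep))
  res <- search_spectrum(sp, idx)
  expect_equal(res$sequence[1], "LFPPAGPR")
  expect_true(res$pass[1])
  # q-values are monotone along the ranking
  expect_true(all(diff(res$q_value) >= -1e-12))

  # decoy-only database: nothing passes the 1% FDR
  decoys_only <- idx[idx$decoy, ]
  res2 <- search_spectrum(sp, decoys_only)
  expect_false(any(res2$pass))

  # isobaric candidates: the one matching more ions ranks higher
  two <- idx[idx$sequence %in% c("LFPPAGPR"), ][1, ]
  # same residue composition (isobaric), different ion series
  fake <- two; fake$sequence <- "PPFLAGPR"
  fake$mass <- mh_mz(peptide("PPFLAGPR"))
  pair <- rbind(two, fake)
  pair <- pair[order(pair$mass), ]
  res3 <- search_spectrum(sp, structure(pair, class = class(idx)))
  expect_equal(res3$sequence[1], "LFPPAGPR")
  expect_gt(res3$score[1], res3$score[2])
})

test_that("annotation reports series completeness", {
  pep9 <- peptide("AGLQFPVGR")
  theo <- fragment_series(pep9)
  ann <- annotate_spectrum(make_spec(theo$mz, rep(1, nrow(theo))), pep9)
  expect_equal(ann$counts$total_b, 8L)
  expect_equal(ann$counts$total_y, 8L)
  expect_equal(unname(ann$completeness), c(1, 1))

  pep17 <- parse_peptide("GSAGPPGATGFP[16]GAAGR")
  ann17 <- annotate_spectrum(make_spec(c(100, 200), c(1, 1)), pep17)
  expect_equal(ann17$counts$total_b, 16L)
  expect_equal(ann17$counts$total_y, 16L)

  # the mirror-style plot renders without error
  f <- file.path(tempdir(), "ann.png")
  grDevices::png(f)
  expect_no_error(plot(ann))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
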