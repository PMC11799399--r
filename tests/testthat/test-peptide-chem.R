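test_that("tryptic digestion cleaves after K/R except before P", {
  d <- digest("AGLQFPVGRK", 0)
  expect_equal(d$sequence, c("AGLQFPVGR", "K"))
  expect_equal(d$start, c(1L, 10L))

  # R followed by P is not a cleavage site
  expect_equal(digest("ARPK", 0)$sequence, "ARPK")

  # single residue, missed cleavages allowed
  expect_equal(digest("R", 2)$sequence, "R")

  # missed cleavages enumerate consecutive segment runs
  d2 <- digest("AAKGGRCCK", 1)
  expect_setequal(d2$sequence,
                  c("AAK", "GGR", "CCK", "AAKGGR", "GGRCCK"))
})

test_that("digestion rejects invalid characters and drops undefined residues", {
  expect_error(digest("AG1K", 0), "position 3")
  expect_warning(d <- digest("AAKBBK", 0), "B/J/O/U/X/Z")
  expect_equal(d$sequence, "AAK")
})

test_that("zero-missed-cleavage digestion partitions the protein", {
  for (s in c(11, 22, 33)) {
    prot <- random_protein(80, s)
    d <- digest(prot, 0)
    d <- d[order(d$start), ]
    expect_equal(paste(d$sequence, collapse = ""), prot)
  }
})

test_that("variable modification expansion enumerates isoforms", {
  hyd <- default_modifications()["hydroxylation"]
  expect_length(expand_variable_mods(peptide("GPR"), hyd, 1), 2L)
  expect_length(expand_variable_mods(peptide("PPK"), hyd, 2), 4L)
  expect_length(expand_variable_mods(peptide("AGK"), hyd, 2), 1L)
  # max_mods caps subset size: PPPK with max 2 -> 1 + 3 + 3
  expect_length(expand_variable_mods(peptide("PPPK"), hyd, 2), 7L)
  # empty mod list returns the unmodified singleton
  expect_length(expand_variable_mods(peptide("PPK"), list(), 2), 1L)
  # masses differ by the delta
  iso <- expand_variable_mods(peptide("GPR"), hyd, 1)
  expect_equal(mh_mz(iso[[2]]), mh_mz(iso[[1]]) + 15.999)
})

test_that("singly protonated masses are monoisotopic", {
  expect_equal(mh_mz(peptide("LGGNEQVTR")), 973.5061, tolerance = 1e-3)
  expect_equal(mh_mz(peptide("G")), 76.0393, tolerance = 1e-3)
  p <- parse_peptide("GVVGLP[16]GQR")
  expect_equal(mh_mz(p), mh_mz(peptide("GVVGLPGQR")) + 15.999)
})

test_that("bracket notation round-trips", {
  for (s in c("GVVGLP[16]GQR", "GAAGPP[16]GATGFP[16]GAAGR", "AGLQFPVGR"))
    expect_equal(format(parse_peptide(s)), s)
  expect_error(parse_peptide("G[16]PR"), "no registered modification")
  expect_error(peptide("GPR", data.frame(position = 5, label = "x",
                                         delta = 1)), "outside")
})

test_that("fragment series has n-1 ions per series with correct masses", {
  fs <- fragment_series(peptide("GPR"))
  expect_equal(fs$mz[fs$label == "y1"], 175.119, tolerance = 1e-3)
  expect_equal(sum(fs$series == "b"), 2L)

  expect_equal(sum(fragment_series(peptide("DNIQGITKPAIR"))$series == "y"),
               11L)
  expect_error(fragment_series(peptide("G")), "length 1")
})

test_that("fragment series equals the prefix/suffix-sum oracle", {
  set.seed(42)
  aas <- names(mass_table()$residues)
  hyd <- default_modifications()$hydroxylation
  for (i in 1:200) {
    n <- sample(2:30, 1)
    s <- paste(sample(aas, n, TRUE), collapse = "")
    mods <- NULL
    ppos <- which(strsplit(s, "")[[1]] == "P")
    if (length(ppos) && runif(1) < 0.5)
      mods <- data.frame(position = ppos[1], label = "Hydroxylation",
                         delta = hyd$delta)
    pep <- peptide(s, mods)
    fs <- fragment_series(pep)
    orc <- oracle_fragments(s, mods)
    expect_equal(fs$mz[fs$series == "b"], orc$b, tolerance = 1e-9)
    expect_equal(fs$mz[fs$series == "y"], orc$y, tolerance = 1e-9)
    # conservation: b_i + y_{n-i} = [M+H]+ + proton
    b <- fs$mz[fs$series == "b"]
    y <- fs$mz[fs$series == "y"]
    expect_equal(b + rev(y), rep(mh_mz(pep) + mass_table()$proton, n - 1),
                 tolerance = 1e-9)
  }
})

test_that("ppm error is signed, vectorised and monotone", {
  expect_equal(ppm_error(973.5055, 973.5061), -0.616, tolerance = 5e-3)
  expect_equal(ppm_error(898.5029, 898.5035), -0.67, tolerance = 5e-3)
  expect_equal(ppm_error(5, 5), 0)
  expect_error(ppm_error(1, 0), "positive")
  deltas <- seq(-0.01, 0.01, length.out = 21)
  errs <- ppm_error(1000 + deltas, 1000)
  expect_true(all(diff(errs) > 0))
})

test_that("fragment matching picks the nearest peak within tolerance", {
  theo <- fragment_series(peptide("GPR"))
  y1 <- theo[theo$label == "y1", ]
  m1 <- match_fragments(data.frame(mz = 175.119, intensity = 10), y1, 0.3)
  expect_equal(nrow(m1$matches), 1L)
  m0 <- match_fragments(data.frame(mz = 180.0, intensity = 10), y1, 0.3)
  expect_equal(nrow(m0$matches), 0L)
  # two peaks in tolerance: nearest by m/z wins
  m2 <- match_fragments(data.frame(mz = c(175.05, 175.13),
                                   intensity = c(100, 1)), y1, 0.3)
  expect_equal(m2$matches$mz_observed, 175.13)
  expect_equal(m2$counts$matched_y, 1L)
})

test_that("decoy generation reverses sequences with rev_ accessions", {
  db <- decoy_database(c(P1 = "AGLK", P2 = "GPR"))
  expect_equal(db[["rev_P1"]], "KLGA")
  expect_equal(names(db), c("P1", "P2", "rev_P1", "rev_P2"))
})

test_that("bundled FASTA reads with accession names", {
  fa <- read_fasta(system.file("extdata", "synthetic_proteins.fasta",
                               package = "iprmtools"))
  expect_equal(names(fa), c("COL1_SYN", "HIST_SYN", "ACTB_SYN"))
  expect_true(all(grepl("^[A-Z]+$", fa)))
})
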