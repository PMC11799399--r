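# deterministic per-sequence RNG substream offset (stable across sessions)
.seq_hash <- function(sequence) {
  v <- utf8ToInt(sequence)
  as.integer(sum(v * (seq_along(v) %% 7L + 1L)) %% 1000003L)
}

#' Simulated inverse reduced ion mobility of a peptide
#'
#' A transparent stand-in for measured 1/K0, not a CCS predictor: the
#' [M+H]+ mass is mapped affinely from [800, 2000] Da onto [1.3, 1.9]
#' V·s/cm², plus a per-peptide Gaussian jitter (sd `jitter_sd`, drawn
#' from a seeded substream so the value is a fixed property of the
#' peptide), clipped to the [1.2, 2.1] acquisition range. Reproduces the
#' qualitative mass-mobility trend of singly charged tryptic peptides.
#'
#' @param pep A `peptide` or sequence string.
#' @param jitter_sd Jitter standard deviation in V·s/cm² (default 0.02;
#'   0 gives the pure affine map).
#' @param seed Base seed combined with the sequence for the jitter draw.
#' @return 1/K0 in V·s/cm².
#' @export
simulate_mobility <- function(pep, jitter_sd = 0.02, seed = 1L) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  base <- 1.3 + (mh_mz(pep) - 800) * (1.9 - 1.3) / (2000 - 800)
  j <- if (jitter_sd > 0)
    .with_seed(seed + .seq_hash(pep$sequence),
               stats::rnorm(1, 0, jitter_sd))
  else 0
  min(max(base + j, 1.2), 2.1)
}

#' Phantom tissue specification
#'
#' Defines the two-region synthetic tissue the simulator emulates: an
#' elliptical cellular compartment inside an extracellular remainder,
#' with a region-specific peptide panel digested in silico from three
#' bundled synthetic protein sequences (collagen-like peptides in the
#' extracellular space, histone-like and actin-like peptides in the
#' cellular compartment).
#'
#' @param width,height Grid size in pixels (default 64 x 48).
#' @param pixel_size Pixel size in micrometre (default 50).
#' @param n_per_region Panel peptides per region (default 12).
#' @param noise List of noise parameters: `sigma` (log-normal intensity
#'   sd on the log scale, default 0.3), `mz_jitter_ppm` (default 3),
#'   `mobility_jitter` (default 0.003 V·s/cm²), `baseline_density`
#'   (mean Poisson count of matrix background peaks per pixel, default
#'   5), `bleed` (out-of-home-region abundance fraction, default 0.05),
#'   `ms2_mz_jitter` (Da, default 0.01), `ms2_rel_threshold` (fragment
#'   peaks below this fraction of the pixel maximum are dropped, default
#'   0.005).
#' @param seed Integer seed governing every random draw.
#' @param fasta Path to the panel FASTA (defaults to the bundled
#'   synthetic proteins).
#' @return Object of class `phantom_spec` with `region_masks` (named
#'   logical matrices, disjoint), `tissue_mask`, and `panel` (data.frame:
#'   `sequence`, `region`, `mean_abundance`, `mobility`, `mz`).
#' @export
phantom_spec <- function(width = 64L, height = 48L, pixel_size = 50,
                         n_per_region = 12L, noise = list(), seed = 1L,
                         fasta = system.file("extdata",
                                             "synthetic_proteins.fasta",
                                             package = "iprmtools")) {
  defaults <- list(sigma = 0.3, mz_jitter_ppm = 3, mobility_jitter = 0.003,
                   baseline_density = 5, bleed = 0.05, ms2_mz_jitter = 0.01,
                   ms2_rel_threshold = 0.005)
  noise <- utils::modifyList(defaults, noise)

  # elliptical cellular core inside the full-grid tissue
  yy <- matrix(seq_len(height), nrow = height, ncol = width)
  xx <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  cellular <- ((xx - width / 2) / (width * 0.28))^2 +
    ((yy - height / 2) / (height * 0.3))^2 <= 1
  tissue <- matrix(TRUE, height, width)
  extracellular <- tissue & !cellular

  prot <- read_fasta(fasta)
  pick <- function(accs, n) {
    peps <- do.call(rbind, lapply(accs, function(a) {
      d <- digest(prot[[a]], max_missed = 0L)
      d$protein <- a
      d
    }))
    peps <- peps[order(peps$protein, peps$start), , drop = FALSE]
    mzs <- vapply(peps$sequence, function(s) mh_mz(peptide(s)), numeric(1))
    ok <- mzs > 800 & mzs < 2000 & nchar(peps$sequence) >= 6
    peps <- peps[ok, , drop = FALSE]
    mzs <- mzs[ok]
    # spread the panel across the mass range: per protein, lowest masses
    sel <- unlist(lapply(split(seq_len(nrow(peps)), peps$protein),
                         function(i) i[order(mzs[i])][seq_len(
                           min(ceiling(n / length(accs)), length(i)))]))
    sel <- sort(sel)[seq_len(min(n, length(sel)))]
    data.frame(sequence = peps$sequence[sel], mz = mzs[sel])
  }
  extr <- pick("COL1_SYN", n_per_region)
  cell <- pick(c("HIST_SYN", "ACTB_SYN"), n_per_region)
  panel <- rbind(
    data.frame(extr, region = "extracellular"),
    data.frame(cell, region = "cellular"))
  panel$mobility <- vapply(panel$sequence, simulate_mobility,
                           numeric(1), seed = seed)
  panel$mean_abundance <- .with_seed(seed + 77L,
                                     stats::runif(nrow(panel), 50, 200))
  rownames(panel) <- NULL
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size,
                 region_masks = list(cellular = cellular,
                                     extracellular = extracellular),
                 tissue_mask = tissue, panel = panel, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d px, %d panel peptides (%s), seed %d\n",
    x$width, x$height, nrow(x$panel),
    paste(names(table(x$panel$region)), table(x$panel$region),
          sep = ":", collapse = ", "), x$seed))
  invisible(x)
}

# per-pixel deterministic abundance of each panel peptide (before noise)
.panel_abundance_map <- function(spec, i) {
  home <- spec$region_masks[[spec$panel$region[i]]]
  ab <- matrix(0, spec$height, spec$width)
  ab[home] <- spec$panel$mean_abundance[i]
  ab[spec$tissue_mask & !home] <-
    spec$panel$mean_abundance[i] * spec$noise$bleed
  ab
}

#' Simulate an MS1 imaging dataset from a phantom
#'
#' Every panel peptide contributes, in each tissue pixel where its
#' abundance is positive, one peak at its [M+H]+ mass with multiplicative
#' ppm jitter, its panel 1/K0 value with additive jitter, and a
#' log-normally perturbed intensity. Peptides appear at full abundance in
#' their home region and at the bleed fraction elsewhere. Matrix
#' background is added as Poisson-count baseline peaks uniform over the
#' acquisition ranges. Fully reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List: `dataset` (MS1 `msi_dataset`) and `truth` (data.frame of
#'   every emitted non-baseline peak: `x`, `y`, `sequence`, `region`,
#'   `mz`, `mobility`, `intensity`).
#' @export
simulate_ms1 <- function(spec) {
  if (any(spec$panel$mz <= 800 | spec$panel$mz >= 2000))
    stop("panel peptide outside the m/z 800-2000 acquisition range")
  .with_seed(spec$seed, {
    no <- spec$noise
    rows <- vector("list", nrow(spec$panel))
    for (i in seq_len(nrow(spec$panel))) {
      ab <- .panel_abundance_map(spec, i)
      idx <- which(ab > 0, arr.ind = TRUE)
      n <- nrow(idx)
      rows[[i]] <- data.frame(
        x = idx[, 2] - 1L, y = idx[, 1] - 1L,
        mz = spec$panel$mz[i] *
          (1 + stats::rnorm(n, 0, no$mz_jitter_ppm) * 1e-6),
        mobility = spec$panel$mobility[i] +
          stats::rnorm(n, 0, no$mobility_jitter),
        intensity = ab[idx] * stats::rlnorm(n, 0, no$sigma),
        sequence = spec$panel$sequence[i],
        region = spec$panel$region[i])
    }
    truth <- do.call(rbind, rows)
    # matrix background: uniform over the acquisition window
    tpix <- which(spec$tissue_mask, arr.ind = TRUE)
    nb <- stats::rpois(nrow(tpix), no$baseline_density)
    bl <- data.frame(
      x = rep(tpix[, 2] - 1L, nb), y = rep(tpix[, 1] - 1L, nb),
      mz = stats::runif(sum(nb), 800, 2000),
      mobility = stats::runif(sum(nb), 1.2, 2.1),
      intensity = stats::rlnorm(sum(nb), log(5), 1))
    peaks <- rbind(truth[, c("x", "y", "mz", "mobility", "intensity")], bl)
    list(dataset = msi_dataset(peaks, spec$width, spec$height,
                               pixel_size = spec$pixel_size, level = "MS1",
                               tissue_mask = spec$tissue_mask),
         truth = truth)
  })
}

#' Simulate an iprm-PASEF MS2 imaging dataset
#'
#' For each precursor entry and tissue pixel, every panel peptide whose
#' simulated 1/K0 falls inside the entry's window contributes its
#' theoretical b/y ions, with intensity proportional to the pixel's
#' parent abundance times a per-ion Uniform(0.2, 1) fragmentation factor
#' (a fixed property of the (peptide, ion) pair) times log-normal pixel
#' noise. Fragment peaks below the relative intensity threshold are
#' dropped. A window overlapping two panel peptides therefore yields
#' chimeric spectra.
#'
#' @param spec A [phantom_spec()].
#' @param precursor_list A `precursor_list` (windows inside [1.2, 2.1]).
#' @return List: `dataset` (MS2 `msi_dataset` with `precursor_id` tags)
#'   and `truth` (data.frame: `precursor_id`, `sequence`, `label`, `x`,
#'   `y`, `mz`, `intensity`).
#' @export
simulate_iprm <- function(spec, precursor_list) {
  if (!nrow(precursor_list)) {
    return(list(dataset = msi_dataset(
      data.frame(x = integer(), y = integer(), mz = numeric(),
                 intensity = numeric()),
      spec$width, spec$height, pixel_size = 2 * spec$pixel_size,
      level = "MS2", tissue_mask = spec$tissue_mask),
      truth = NULL))
  }
  stopifnot(all(precursor_list$mobility_low >= 1.2),
            all(precursor_list$mobility_high <= 2.1))
  no <- spec$noise
  out <- list()
  for (e in seq_len(nrow(precursor_list))) {
    entry <- precursor_list[e, ]
    hit <- which(spec$panel$mobility >= entry$mobility_low &
                   spec$panel$mobility <= entry$mobility_high)
    for (i in hit) {
      pep <- peptide(spec$panel$sequence[i])
      theo <- fragment_series(pep)
      nf <- nrow(theo)
      u <- .with_seed(spec$seed + .seq_hash(pep$sequence) + 13L,
                      stats::runif(nf, 0.2, 1))
      ab <- .panel_abundance_map(spec, i)
      idx <- which(ab > 0, arr.ind = TRUE)
      npx <- nrow(idx)
      noise_block <- .with_seed(
        spec$seed + .seq_hash(pep$sequence) + 1000L * e, {
          list(ln = stats::rlnorm(npx * nf, 0, no$sigma),
               dm = stats::rnorm(npx * nf, 0, no$ms2_mz_jitter),
               dmob = stats::rnorm(npx * nf, 0, no$mobility_jitter))
        })
      df <- data.frame(
        x = rep(idx[, 2] - 1L, each = nf),
        y = rep(idx[, 1] - 1L, each = nf),
        mz = rep(theo$mz, npx) + noise_block$dm,
        mobility = spec$panel$mobility[i] + noise_block$dmob,
        intensity = rep(ab[idx], each = nf) * rep(u, npx) *
          noise_block$ln,
        precursor_id = as.character(entry$id),
        sequence = spec$panel$sequence[i],
        label = rep(theo$label, npx))
      out[[length(out) + 1L]] <- df
    }
  }
  all <- do.call(rbind, out)
  if (is.null(all) || !nrow(all)) {
    warning("no panel peptide falls inside any precursor window")
    return(list(dataset = msi_dataset(
      data.frame(x = integer(), y = integer(), mz = numeric(),
                 intensity = numeric()),
      spec$width, spec$height, pixel_size = 2 * spec$pixel_size,
      level = "MS2", tissue_mask = spec$tissue_mask), truth = NULL))
  }
  # relative intensity floor per (pixel, precursor) spectrum
  key <- paste(all$precursor_id, all$x, all$y)
  mx <- tapply(all$intensity, key, max)
  keep <- all$intensity >= no$ms2_rel_threshold * mx[key]
  all <- all[keep, , drop = FALSE]
  truth <- all[, c("precursor_id", "sequence", "label", "x", "y", "mz",
                   "intensity")]
  list(dataset = msi_dataset(
    all[, c("x", "y", "mz", "mobility", "intensity", "precursor_id")],
    spec$width, spec$height, pixel_size = 2 * spec$pixel_size,
    level = "MS2", tissue_mask = spec$tissue_mask),
    truth = truth)
}
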