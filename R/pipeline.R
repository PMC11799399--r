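#' Default pipeline configuration
#'
#' All stage parameters in one auditable list, at the standard values
#' for tryptic peptide imaging: 10 ppm / 0.01 V·s/cm² feature
#' tolerances, 50% coverage and 1% relative intensity thresholds, |r| >=
#' 0.7 candidate cut-off, 25-entry plex limit, 100 ppm precursor and 0.3
#' Da fragment search tolerances, 1% FDR.
#'
#' @param output_dir Directory stages write into.
#' @param seed Pipeline seed.
#' @return Nested named list.
#' @export
default_config <- function(output_dir = "iprm_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    log_level = "info",
    phantom = list(width = 64L, height = 48L, n_per_region = 12L),
    features = list(mz_tol = 10, mobility_tol = 0.01, min_coverage = 0.5,
                    min_rel_intensity = 0.01, smooth_window = 2L),
    segmentation = list(k = 2L),
    coloc = list(threshold = 0.7, region_label = NA, manual_ids = list()),
    scheduler = list(half_width = 0.025, max_n = 25L),
    search = list(database = NA, precursor_tol = 100, frag_tol = 0.3,
                  fdr = 0.01, max_missed = 2L, max_mods = 2L,
                  decoys = TRUE),
    corroborate = list(lc_table = NA, ppm_bound = 5, mobility_bound = 0.01)
  )
}

#' Write a fresh configuration file
#'
#' @param path YAML path to create.
#' @param ... Passed to [default_config()].
#' @return `path`, invisibly.
#' @export
init_config <- function(path, ...) {
  yaml::write_yaml(default_config(...), path)
  invisible(path)
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

.manifest <- function(stage, config, outputs, inputs = character(0)) {
  list(stage = stage, config_hash = .config_hash(config),
       seed = config$seed,
       inputs = as.list(unname(tools::md5sum(inputs[file.exists(inputs)]))),
       outputs = as.list(outputs))
}

.need <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing input '%s': run the '%s' stage first",
                 path, producer))
  path
}

.log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[iprm] %s", sprintf(...)))
}

#' Run a pipeline stage
#'
#' Orchestrates the phantom-to-identification chain. Subcommands:
#' `simulate` (phantom MS1 imzML + ground truth), `features`
#' (RMS-normalize + feature finding), `segment` (bisecting k-means),
#' `coloc` (co-localization of every feature to a segment), `schedule`
#' (candidate selection + window scheduling), `extract-ms2` (simulated
#' iprm-PASEF acquisition, mobilogram extraction, averaging, MGF
#' export), `search` (PSM with q-values), `corroborate` (cross-platform
#' deltas, if an LC table is configured) and `report` (label map and
#' annotated-spectrum figures). Each stage writes its outputs plus a
#' JSON manifest carrying the config hash, seed and input checksums
#' into `config$output_dir`.
#'
#' @param stage Subcommand name.
#' @param config Configuration list or YAML path (see
#'   [default_config()]).
#' @return Invisible list of produced file paths.
#' @export
run_pipeline <- function(stage = c("simulate", "features", "segment",
                                   "coloc", "schedule", "extract-ms2",
                                   "search", "corroborate", "report"),
                         config = default_config()) {
  stage <- match.arg(stage)
  config <- .load_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$output_dir, f)
  outputs <- character(0)
  inputs <- character(0)

  if (stage == "simulate") {
    spec <- phantom_spec(width = config$phantom$width,
                         height = config$phantom$height,
                         n_per_region = config$phantom$n_per_region,
                         seed = config$seed)
    sim <- simulate_ms1(spec)
    write_imzml(sim$dataset, pth("ms1.imzML"))
    utils::write.table(sim$truth, pth("ms1_truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(spec$panel, pth("panel.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    reg <- which(spec$region_masks$cellular, arr.ind = TRUE)
    utils::write.table(
      data.frame(x = reg[, 2] - 1L, y = reg[, 1] - 1L, region = "cellular"),
      pth("regions.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- pth(c("ms1.imzML", "ms1_truth.tsv", "panel.tsv",
                     "regions.tsv"))
    .log(config, "simulated %d x %d phantom, %d panel peptides",
         spec$width, spec$height, nrow(spec$panel))
  } else if (stage == "features") {
    inputs <- .need(pth("ms1.imzML"), "simulate")
    ds <- rms_normalize(read_imzml(inputs))
    fl <- find_features(ds, config$features$mz_tol,
                        config$features$mobility_tol,
                        config$features$min_coverage,
                        config$features$min_rel_intensity)
    write_features(fl, pth("features.tsv"))
    outputs <- pth("features.tsv")
    .log(config, "found %d features", nrow(fl))
  } else if (stage == "segment") {
    inputs <- c(.need(pth("ms1.imzML"), "simulate"),
                .need(pth("features.tsv"), "features"))
    ds <- rms_normalize(read_imzml(inputs[1]))
    fl <- read_features(inputs[2])
    M <- feature_matrix(ds, fl, config$features$mz_tol,
                        config$features$mobility_tol)
    seg <- bisecting_kmeans(M, k = config$segmentation$k,
                            seed = config$seed)
    px <- seg$pixels
    utils::write.table(
      data.frame(x = px$x, y = px$y, label = seg$labels),
      pth("segmentation.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- pth("segmentation.tsv")
    .log(config, "segmented into %d clusters", seg$k)
  } else if (stage == "coloc") {
    inputs <- c(.need(pth("ms1.imzML"), "simulate"),
                .need(pth("features.tsv"), "features"),
                .need(pth("segmentation.tsv"), "segment"))
    ds <- rms_normalize(read_imzml(inputs[1]))
    fl <- read_features(inputs[2])
    seg <- utils::read.delim(inputs[3])
    lab <- config$coloc$region_label
    if (is.null(lab) || is.na(lab)) lab <- 0L
    region <- matrix(FALSE, ds$height, ds$width)
    sel <- seg$label == lab
    region[cbind(seg$y[sel] + 1L, seg$x[sel] + 1L)] <- TRUE
    res <- do.call(rbind, lapply(seq_len(nrow(fl)), function(j) {
      img <- feature_image(ds, fl[j, ], config$features$mz_tol,
                           config$features$mobility_tol)
      coloc_to_region(img, region, feature_id = fl$id[j])
    }))
    utils::write.table(res, pth("coloc.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- pth("coloc.tsv")
    .log(config, "%d/%d features significantly co-localized",
         sum(res$significant), nrow(res))
  } else if (stage == "schedule") {
    inputs <- c(.need(pth("features.tsv"), "features"),
                .need(pth("coloc.tsv"), "coloc"))
    fl <- read_features(inputs[1])
    res <- utils::read.delim(inputs[2])
    cand <- select_candidates(res, threshold = config$coloc$threshold,
                              manual_ids = unlist(config$coloc$manual_ids))
    if (!nrow(cand)) stop("no candidates passed the co-localization filter")
    entries <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      f <- fl[fl$id == cand$feature_id[i], ]
      assign_window(f, half_width = config$scheduler$half_width,
                    priority = abs(cand$r[i]))
    }))
    sched <- schedule(entries, max_n = config$scheduler$max_n)
    write_precursors(sched, pth("precursors.tsv"))
    outputs <- pth("precursors.tsv")
    .log(config, "scheduled %d of %d candidates", nrow(sched),
         nrow(entries))
  } else if (stage == "extract-ms2") {
    inputs <- .need(pth("precursors.tsv"), "schedule")
    sched <- read_precursors(inputs)
    spec <- phantom_spec(width = config$phantom$width,
                         height = config$phantom$height,
                         n_per_region = config$phantom$n_per_region,
                         seed = config$seed)
    sim <- simulate_iprm(spec, sched)
    write_imzml(sim$dataset, pth("ms2.imzML"))
    spectra <- lapply(seq_len(nrow(sched)), function(e) {
      px <- extract_ms2(sim$dataset, sched[e, ])
      if (!length(px)) return(NULL)
      average_spectra(px, precursor = sched[e, ])
    })
    spectra <- Filter(Negate(is.null), spectra)
    write_mgf(spectra, pth("spectra.mgf"))
    outputs <- pth(c("ms2.imzML", "spectra.mgf"))
    .log(config, "extracted %d averaged MS2 spectra", length(spectra))
  } else if (stage == "search") {
    inputs <- c(.need(pth("spectra.mgf"), "extract-ms2"),
                .need(pth("precursors.tsv"), "schedule"))
    sched <- read_precursors(inputs[2])
    db_path <- config$search$database
    if (is.null(db_path) || is.na(db_path))
      stop("configuration error: search$database must point to a FASTA file")
    seqs <- read_fasta(db_path)
    if (isTRUE(config$search$decoys)) seqs <- decoy_database(seqs)
    idx <- build_peptide_index(seqs, max_missed = config$search$max_missed,
                               max_mods = config$search$max_mods)
    spectra <- read_mgf(inputs[1])
    hits <- do.call(rbind, lapply(spectra, function(s) {
      r <- search_spectrum(s, idx, config$search$precursor_tol,
                           config$search$frag_tol, config$search$fdr)
      if (!nrow(r)) return(NULL)
      e <- sched[sched$id == s$precursor$id, , drop = FALSE]
      cbind(precursor_id = s$precursor$id,
            precursor_mz = s$precursor$mz,
            mobility = if (nrow(e))
              (e$mobility_low + e$mobility_high) / 2 else NA_real_,
            r[1, , drop = FALSE])
    }))
    if (is.null(hits)) hits <- data.frame()
    utils::write.table(hits, pth("psms.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- pth("psms.tsv")
    .log(config, "search produced %d top hits (%d passing FDR)",
         nrow(hits), if (nrow(hits)) sum(hits$pass) else 0L)
  } else if (stage == "corroborate") {
    inputs <- .need(pth("psms.tsv"), "search")
    lc_path <- config$corroborate$lc_table
    if (is.null(lc_path) || is.na(lc_path))
      stop("configuration error: corroborate$lc_table must be a TSV path")
    psms <- utils::read.delim(inputs)
    lc <- utils::read.delim(lc_path)
    maldi <- data.frame(sequence = psms$sequence,
                        mz = psms$precursor_mz,
                        mobility = psms$mobility)
    cmp <- compare_platforms(maldi, lc)
    chk <- check_tolerances(cmp, config$corroborate$ppm_bound,
                            config$corroborate$mobility_bound)
    utils::write.table(chk$per_match, pth("corroboration.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- pth("corroboration.tsv")
    .log(config, "corroborated %d sequences, overall pass: %s",
         nrow(cmp), chk$pass)
  } else if (stage == "report") {
    inputs <- c(.need(pth("segmentation.tsv"), "segment"),
                .need(pth("precursors.tsv"), "schedule"))
    seg <- utils::read.delim(inputs[1])
    w <- max(seg$x) + 1L
    h <- max(seg$y) + 1L
    m <- matrix(NA_integer_, h, w)
    m[cbind(seg$y + 1L, seg$x + 1L)] <- seg$label
    grDevices::png(pth("segmentation.png"), width = 480, height = 360)
    graphics::image(t(m[h:1, , drop = FALSE]), axes = FALSE,
                    main = "segmentation", useRaster = TRUE)
    grDevices::dev.off()
    outputs <- pth("segmentation.png")
    .log(config, "report written")
  }

  manifest <- .manifest(stage, config, as.list(outputs), inputs)
  jsonlite::write_json(manifest,
                       pth(sprintf("manifest_%s.json",
                                   gsub("-", "_", stage))),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outputs)
}
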