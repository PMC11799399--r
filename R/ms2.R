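#' Extract per-pixel MS2 spectra for a precursor
#'
#' Filters an MS2 imaging dataset down to the fragment peaks whose 1/K0
#' lies inside the precursor's mobility window — the mobilogram filter —
#' and returns one spectrum per contributing pixel. When the dataset
#' tags frames by precursor id, the tag is applied first.
#'
#' @param dataset An MS2 `msi_dataset`.
#' @param entry One `precursor_list` row (`id`, `mobility_low`,
#'   `mobility_high`).
#' @return List of per-pixel spectra, each `list(x, y, peaks)` with peaks
#'   sorted by m/z; pixels without signal are omitted. Empty list (with a
#'   warning) when nothing matches.
#' @export
extract_ms2 <- function(dataset, entry) {
  stopifnot(dataset$level == "MS2")
  p <- dataset$peaks
  sel <- rep(TRUE, nrow(p))
  if (!is.null(entry$id) && !is.na(entry$id) &&
      any(!is.na(p$precursor_id)))
    sel <- sel & !is.na(p$precursor_id) & p$precursor_id == entry$id
  if (any(!is.na(p$mobility)))
    sel <- sel & !is.na(p$mobility) &
      p$mobility >= entry$mobility_low & p$mobility <= entry$mobility_high
  p <- p[sel, , drop = FALSE]
  if (!nrow(p)) {
    warning("no MS2 frames match precursor ", entry$id %||% "?",
            " in mobility window [", entry$mobility_low, ", ",
            entry$mobility_high, "]")
    return(list())
  }
  keys <- .pixel_key(dataset, p$x, p$y)
  idx <- split(seq_len(nrow(p)), keys)
  lapply(idx, function(rows) {
    rows <- rows[order(p$mz[rows])]
    list(x = p$x[rows[1]], y = p$y[rows[1]],
         peaks = data.frame(mz = p$mz[rows], intensity = p$intensity[rows]))
  })
}

#' Average per-pixel MS2 spectra
#'
#' Pools the peaks of all contributing pixels, merges them by
#' single-linkage clustering within `bin_tol` (1-D: consecutive peaks
#' closer than the tolerance chain into one bin), and emits the
#' intensity-weighted mean m/z with the zero-filled mean intensity
#' (summed intensity divided by the number of contributing pixels).
#' Deterministic and invariant to pixel order.
#'
#' @param pixel_spectra List from [extract_ms2()] (>= 1 spectrum).
#' @param bin_tol Peak merge tolerance in Da (default 0.05).
#' @param precursor Optional `precursor_list` row stored with the result.
#' @return Object of class `ms2_spectrum`: `precursor`, `peaks`
#'   (data.frame sorted by m/z), `n_pixels`.
#' @export
average_spectra <- function(pixel_spectra, bin_tol = 0.05,
                            precursor = NULL) {
  stopifnot(length(pixel_spectra) >= 1L)
  mz <- unlist(lapply(pixel_spectra, function(s) s$peaks$mz))
  int <- unlist(lapply(pixel_spectra, function(s) s$peaks$intensity))
  n_pix <- length(pixel_spectra)
  o <- order(mz)
  mz <- mz[o]; int <- int[o]
  grp <- cumsum(c(1, diff(mz) > bin_tol))
  mzc <- rowsum(mz * int, grp)[, 1] / rowsum(int, grp)[, 1]
  avg <- rowsum(int, grp)[, 1] / n_pix
  pre <- if (is.null(precursor)) list(id = NA_character_, mz = NA_real_)
  else list(id = as.character(precursor$id), mz = precursor$mz,
            mobility_low = precursor$mobility_low,
            mobility_high = precursor$mobility_high)
  structure(list(precursor = pre,
                 peaks = data.frame(mz = unname(mzc),
                                    intensity = unname(avg)),
                 n_pixels = n_pix),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %s (m/z %.4f), %d peaks from %d pixels\n",
              x$precursor$id, x$precursor$mz %||% NA_real_,
              nrow(x$peaks), x$n_pixels))
  invisible(x)
}

#' Build a searchable peptide index from a protein database
#'
#' Digests every protein (trypsin, up to `max_missed` missed cleavages),
#' expands variable modifications, and stores each isoform with its
#' [M+H]+ mass for fast precursor lookups. Decoys (accessions prefixed
#' `rev_`) are flagged.
#'
#' @param sequences Named character vector of protein sequences, e.g.
#'   from [read_fasta()], typically passed through [decoy_database()].
#' @param mods List of variable [modification()]s (default hydroxylation
#'   + oxidation).
#' @param max_missed Missed cleavages (default 2).
#' @param max_mods Maximum simultaneous variable modifications per
#'   peptide (default 2).
#' @param min_length Minimum peptide length (default 5).
#' @param mz_range Optional `[M+H]+` window to retain.
#' @return data.frame of class `peptide_index`: `sequence`, `mods`
#'   (encoded `pos:delta` string), `mass`, `proteins`, `decoy`.
#' @export
build_peptide_index <- function(sequences,
                                mods = default_modifications(),
                                max_missed = 2L, max_mods = 2L,
                                min_length = 5L, mz_range = NULL) {
  if (!length(sequences)) stop("empty protein database")
  pep_tabs <- lapply(names(sequences), function(acc) {
    d <- suppressWarnings(digest(sequences[[acc]], max_missed))
    d <- d[nchar(d$sequence) >= min_length, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(sequence = d$sequence, protein = acc)
  })
  peps <- do.call(rbind, pep_tabs)
  if (is.null(peps) || !nrow(peps)) stop("database produced no peptides")
  prot <- tapply(peps$protein, peps$sequence,
                 function(x) paste(sort(unique(x)), collapse = ";"))
  uniq <- names(prot)

  mt <- mass_table()
  # base masses, vectorised over all unique sequences
  chars <- strsplit(uniq, "", fixed = TRUE)
  lens <- lengths(chars)
  base <- rowsum(unname(mt$residues[unlist(chars)]),
                 rep(seq_along(uniq), lens))[, 1] +
    mt$water + mt$proton

  # variable-mod expansion, vectorised: a slots table (sequence index,
  # position, delta) drives the size-1 and size-2 subset enumeration;
  # subsets of size > 2 are enumerated per sequence only when requested
  slot_seq <- integer(0); slot_pos <- integer(0); slot_delta <- numeric(0)
  all_res <- unlist(chars)
  seq_of_res <- rep(seq_along(uniq), lens)
  pos_of_res <- unlist(lapply(lens, seq_len))
  for (m in mods) {
    sel <- all_res %in% m$targets
    slot_seq <- c(slot_seq, seq_of_res[sel])
    slot_pos <- c(slot_pos, pos_of_res[sel])
    slot_delta <- c(slot_delta, rep(m$delta, sum(sel)))
  }
  o <- order(slot_seq, slot_pos, slot_delta)
  slot_seq <- slot_seq[o]; slot_pos <- slot_pos[o]
  slot_delta <- slot_delta[o]
  parts <- list(data.frame(seq = seq_along(uniq), mass = base,
                           mods = ""))
  if (length(slot_seq) && max_mods >= 1L) {
    parts[[2]] <- data.frame(
      seq = slot_seq, mass = base[slot_seq] + slot_delta,
      mods = sprintf("%d:%g", slot_pos, slot_delta))
  }
  if (length(slot_seq) && max_mods >= 2L) {
    scount <- tabulate(slot_seq, nbins = length(uniq))
    local_i <- sequence(scount)            # slot index within sequence
    npart <- scount[slot_seq] - local_i    # partners after this slot
    a <- rep(seq_along(slot_seq), npart)
    b <- a + sequence(npart)
    ok <- slot_pos[a] != slot_pos[b]       # one mod per position
    a <- a[ok]; b <- b[ok]
    if (length(a))
      parts[[3]] <- data.frame(
        seq = slot_seq[a],
        mass = base[slot_seq[a]] + slot_delta[a] + slot_delta[b],
        mods = paste0(sprintf("%d:%g", slot_pos[a], slot_delta[a]), ";",
                      sprintf("%d:%g", slot_pos[b], slot_delta[b])))
  }
  if (max_mods >= 3L && length(slot_seq)) {
    # rare request: enumerate larger subsets per sequence
    extra <- list()
    for (i in unique(slot_seq[duplicated(slot_seq)])) {
      w <- which(slot_seq == i)
      if (length(w) < 3L) next
      for (k in 3:min(max_mods, length(w))) {
        cmb <- utils::combn(w, k)
        for (ci in seq_len(ncol(cmb))) {
          s <- cmb[, ci]
          if (anyDuplicated(slot_pos[s])) next
          extra[[length(extra) + 1L]] <- data.frame(
            seq = i, mass = base[i] + sum(slot_delta[s]),
            mods = paste(sprintf("%d:%g", slot_pos[s], slot_delta[s]),
                         collapse = ";"))
        }
      }
    }
    if (length(extra)) parts[[length(parts) + 1L]] <- do.call(rbind, extra)
  }
  expanded <- do.call(rbind, parts)
  out <- data.frame(sequence = uniq[expanded$seq], mods = expanded$mods,
                    mass = expanded$mass)
  out$proteins <- unname(prot[match(out$sequence, uniq)])
  # a peptide shared by target and decoy proteins counts as target
  out$decoy <- !grepl("(^|;)(?!rev_)", out$proteins, perl = TRUE)
  if (!is.null(mz_range))
    out <- out[out$mass >= mz_range[1] & out$mass <= mz_range[2], ,
               drop = FALSE]
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peptide_index", "data.frame"))
}

# rebuild a peptide object from an index row
.index_peptide <- function(row) {
  if (!nzchar(row$mods)) return(peptide(row$sequence))
  parts <- strsplit(strsplit(row$mods, ";", fixed = TRUE)[[1]], ":",
                    fixed = TRUE)
  md <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                   label = "mod",
                   delta = as.numeric(vapply(parts, `[`, "", 2)))
  peptide(row$sequence, md)
}

#' Candidate peptides for a precursor mass
#'
#' @param index A [build_peptide_index()] result.
#' @param precursor_mz Observed singly protonated precursor m/z.
#' @param tol Precursor tolerance in ppm (default 100, matching wide
#'   MALDI precursor windows).
#' @return Subset of the index with |ppm error| <= `tol`.
#' @export
generate_candidates <- function(index, precursor_mz, tol = 100) {
  if (!nrow(index)) stop("empty peptide index")
  lo <- precursor_mz / (1 + tol * 1e-6)
  hi <- precursor_mz * (1 + tol * 1e-6)
  i1 <- findInterval(lo, index$mass) + 1L
  i2 <- findInterval(hi, index$mass)
  if (i2 < i1) return(index[0, , drop = FALSE])
  out <- index[i1:i2, , drop = FALSE]
  out[abs(ppm_error(out$mass, precursor_mz)) <= tol, , drop = FALSE]
}

#' Score a peptide-spectrum match
#'
#' Matches the theoretical b/y series against the spectrum at `frag_tol`
#' and converts the matched-ion count m into a probability score: with N
#' theoretical ions and a per-ion chance hit probability
#' q = min(1, 2 * frag_tol * n_peaks / spectrum span), the score is
#' -10 log10 P(X >= m) for X ~ Binomial(N, q). Zero matches score 0;
#' more matched ions never lower the score.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param pep A `peptide` (length >= 2).
#' @param frag_tol Fragment tolerance in Da (default 0.3).
#' @return Object of class `psm`: peptide, score, precursor ppm error,
#'   matched/total counts per series, match table.
#' @export
score_psm <- function(spectrum, pep, frag_tol = 0.3) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  if (!nrow(spectrum$peaks)) stop("empty spectrum")
  theo <- fragment_series(pep)
  mf <- match_fragments(spectrum$peaks, theo, frag_tol)
  m <- mf$counts$matched_b + mf$counts$matched_y
  trials <- nrow(theo)
  span <- diff(range(spectrum$peaks$mz))
  q <- if (span <= 0) 1 else min(1, 2 * frag_tol * nrow(spectrum$peaks) / span)
  p_match <- stats::pbinom(m - 1L, trials, q, lower.tail = FALSE)
  score <- -10 * log10(max(p_match, .Machine$double.xmin))
  pre_ppm <- if (is.null(spectrum$precursor$mz) ||
                 is.na(spectrum$precursor$mz)) NA_real_
  else ppm_error(spectrum$precursor$mz, mh_mz(pep))
  structure(list(peptide = pep, score = score, precursor_ppm = pre_ppm,
                 matched_b = mf$counts$matched_b,
                 total_b = mf$counts$total_b,
                 matched_y = mf$counts$matched_y,
                 total_y = mf$counts$total_y,
                 matches = mf$matches),
            class = "psm")
}

#' @export
print.psm <- function(x, ...) {
  cat(sprintf("<psm> %s  score %.1f  ppm %.2f  b %d/%d  y %d/%d\n",
              format(x$peptide), x$score, x$precursor_ppm, x$matched_b,
              x$total_b, x$matched_y, x$total_y))
  invisible(x)
}

#' Search a spectrum against a peptide index
#'
#' Scores every candidate within the precursor tolerance, ranks by
#' score, and computes target-decoy q-values: FDR(t) = #decoys >= t /
#' #targets >= t, monotonised from the bottom of the ranking. The top
#' target hit passes at `q <= fdr`.
#'
#' @param spectrum An `ms2_spectrum` with known precursor m/z.
#' @param index A [build_peptide_index()] over targets + decoys.
#' @param precursor_tol ppm tolerance (default 100).
#' @param frag_tol Fragment tolerance in Da (default 0.3).
#' @param fdr Acceptance threshold on the q-value (default 0.01).
#' @return data.frame of ranked PSMs (`sequence` in bracket notation,
#'   `proteins`, `decoy`, `score`, `precursor_ppm`, matched/total counts,
#'   `q_value`, `pass`); zero rows with a `reason` attribute when no
#'   candidates exist.
#' @export
search_spectrum <- function(spectrum, index, precursor_tol = 100,
                            frag_tol = 0.3, fdr = 0.01) {
  cand <- generate_candidates(index, spectrum$precursor$mz, precursor_tol)
  if (!nrow(cand)) {
    out <- data.frame(sequence = character(), proteins = character(),
                      decoy = logical(), score = numeric(),
                      precursor_ppm = numeric(), matched_b = integer(),
                      total_b = integer(), matched_y = integer(),
                      total_y = integer(), q_value = numeric(),
                      pass = logical())
    attr(out, "reason") <- "no candidates within precursor tolerance"
    return(out)
  }
  psms <- lapply(seq_len(nrow(cand)), function(i) {
    p <- score_psm(spectrum, .index_peptide(cand[i, ]), frag_tol)
    data.frame(sequence = format(p$peptide), proteins = cand$proteins[i],
               decoy = cand$decoy[i], score = p$score,
               precursor_ppm = p$precursor_ppm, matched_b = p$matched_b,
               total_b = p$total_b, matched_y = p$matched_y,
               total_y = p$total_y)
  })
  out <- do.call(rbind, psms)
  out <- out[order(-out$score, out$decoy, out$sequence), , drop = FALSE]
  d <- cumsum(out$decoy)
  t <- cumsum(!out$decoy)
  fdr_hat <- d / pmax(t, 1L)
  out$q_value <- rev(cummin(rev(fdr_hat)))
  out$pass <- !out$decoy & out$q_value <= fdr
  rownames(out) <- NULL
  out
}

#' Annotate a spectrum with a peptide's fragment ions
#'
#' @param spectrum An `ms2_spectrum`.
#' @param pep The identified `peptide`.
#' @param frag_tol Fragment tolerance in Da (default 0.3).
#' @return List of class `ms2_annotation`: `ions` (per-ion table with
#'   matched flag and observed m/z), `completeness` (matched fraction per
#'   series), counts.
#' @export
annotate_spectrum <- function(spectrum, pep, frag_tol = 0.3) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  theo <- fragment_series(pep)
  mf <- match_fragments(spectrum$peaks, theo, frag_tol)
  ions <- theo
  ions$matched <- ions$label %in% mf$matches$label
  ions$mz_observed <- mf$matches$mz_observed[match(ions$label,
                                                   mf$matches$label)]
  ions$intensity <- mf$matches$intensity[match(ions$label,
                                               mf$matches$label)]
  structure(list(
    peptide = pep, ions = ions, counts = mf$counts,
    completeness = c(b = mf$counts$matched_b / mf$counts$total_b,
                     y = mf$counts$matched_y / mf$counts$total_y),
    spectrum = spectrum), class = "ms2_annotation")
}

#' @export
print.ms2_annotation <- function(x, ...) {
  cat(sprintf("<ms2_annotation> %s: b %d/%d (%.0f%%), y %d/%d (%.0f%%)\n",
              format(x$peptide), x$counts$matched_b, x$counts$total_b,
              100 * x$completeness["b"], x$counts$matched_y,
              x$counts$total_y, 100 * x$completeness["y"]))
  invisible(x)
}

#' @export
plot.ms2_annotation <- function(x, main = NULL, ...) {
  pk <- x$spectrum$peaks
  graphics::plot(pk$mz, pk$intensity, type = "h", col = "grey60",
                 xlab = "m/z", ylab = "intensity",
                 main = main %||% format(x$peptide), ...)
  mb <- x$ions[x$ions$matched & x$ions$series == "b", ]
  my <- x$ions[x$ions$matched & x$ions$series == "y", ]
  if (nrow(mb)) {
    graphics::segments(mb$mz_observed, 0, mb$mz_observed, mb$intensity,
                       col = "red", lwd = 2)
    graphics::text(mb$mz_observed, mb$intensity, mb$label, col = "red",
                   pos = 3, cex = 0.7)
  }
  if (nrow(my)) {
    graphics::segments(my$mz_observed, 0, my$mz_observed, my$intensity,
                       col = "blue", lwd = 2)
    graphics::text(my$mz_observed, my$intensity, my$label, col = "blue",
                   pos = 3, cex = 0.7)
  }
  invisible(x)
}
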