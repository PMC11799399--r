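#' Peptide with positioned modifications
#'
#' A peptide is an uppercase residue string plus an optional table of
#' positioned mass modifications (at most one per residue). Hydroxyproline
#' is written in bracket notation, e.g. `GVVGLP[16]GQR` is hydroxylation
#' (+15.999 Da) on the proline preceding the bracket.
#'
#' @param sequence Uppercase residue string (20 standard letters).
#' @param mods Optional data.frame with columns `position` (1-based residue
#'   index), `label`, `delta` (Da); or a list of `list(position, mod)` pairs
#'   where `mod` is a [modification()].
#' @return Object of class `peptide`.
#' @examples
#' peptide("GPR")
#' parse_peptide("GVVGLP[16]GQR")
#' @export
peptide <- function(sequence, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L) stop("peptide sequence must have length >= 1")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(mass_table()$residues))
  if (length(bad)) {
    stop(sprintf("non-standard residue '%s' at position %d in '%s'",
                 res[bad[1]], bad[1], sequence))
  }
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), label = character(),
                       delta = numeric())
  } else if (is.list(mods) && !is.data.frame(mods)) {
    mods <- do.call(rbind, lapply(mods, function(m) {
      data.frame(position = as.integer(m$position), label = m$mod$label,
                 delta = m$mod$delta)
    }))
  }
  mods <- as.data.frame(mods)
  if (nrow(mods)) {
    mods$position <- as.integer(mods$position)
    if (any(mods$position < 1L | mods$position > nchar(sequence)))
      stop("modification position outside peptide")
    if (anyDuplicated(mods$position))
      stop("at most one modification per position")
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
  }
  structure(list(sequence = sequence, mods = mods), class = "peptide")
}

#' Parse bracket-notation peptide strings
#'
#' `[16]` after a residue resolves to the registered +15.999 hydroxylation
#' when the residue is a target; otherwise, and for other integers, the
#' bracket content is matched against `registry` by rounded delta. Explicit
#' deltas like `[+15.994915]` are taken verbatim.
#'
#' @param text Peptide string, e.g. `"GVVGLP[16]GQR"`.
#' @param registry Named list of [modification()] objects.
#' @return A `peptide`.
#' @export
parse_peptide <- function(text, registry = default_modifications()) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  seq_chars <- character(0)
  mods <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- i + match("]", chars[(i + 1L):length(chars)])
      if (is.na(close)) stop("unbalanced '[' in peptide string: ", text)
      token <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      pos <- length(seq_chars)
      if (pos == 0L) stop("modification bracket before any residue in: ", text)
      residue <- seq_chars[pos]
      if (grepl("^[+-]", token)) {
        delta <- as.numeric(token)
        if (!is.finite(delta)) stop("bad modification delta: ", token)
        mods[[length(mods) + 1L]] <-
          data.frame(position = pos, label = token, delta = delta)
      } else {
        nominal <- as.numeric(token)
        if (!is.finite(nominal)) stop("bad modification token: ", token)
        hit <- NULL
        for (m in registry) {
          if (round(m$delta) == round(nominal) && residue %in% m$targets) {
            hit <- m
            break
          }
        }
        if (is.null(hit))
          stop(sprintf("no registered modification [%s] for residue %s",
                       token, residue))
        mods[[length(mods) + 1L]] <-
          data.frame(position = pos, label = hit$label, delta = hit$delta)
      }
      i <- close + 1L
    } else {
      seq_chars <- c(seq_chars, toupper(ch))
      i <- i + 1L
    }
  }
  pep_mods <- if (length(mods)) do.call(rbind, mods) else NULL
  peptide(paste(seq_chars, collapse = ""), pep_mods)
}

#' @export
format.peptide <- function(x, ...) {
  if (!nrow(x$mods)) return(x$sequence)
  chars <- strsplit(x$sequence, "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(x$mods))) {
    p <- x$mods$position[k]
    chars[p] <- sprintf("%s[%d]", chars[p], round(x$mods$delta[k]))
  }
  paste(chars, collapse = "")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s  [M+H]+ %.4f\n", format(x), mh_mz(x)))
  invisible(x)
}

# per-residue mass vector including modification deltas
.residue_mass_vector <- function(pep) {
  mt <- mass_table()
  m <- unname(mt$residues[strsplit(pep$sequence, "", fixed = TRUE)[[1]]])
  if (nrow(pep$mods)) m[pep$mods$position] <- m[pep$mods$position] + pep$mods$delta
  m
}

#' Singly protonated peptide m/z
#'
#' Sum of monoisotopic residue masses plus modification deltas, water and
#' one proton — the [M+H]+ value for the singly charged ions that dominate
#' MALDI ionization of tryptic peptides.
#'
#' @param pep A `peptide` (or string parsed with [parse_peptide()]).
#' @return m/z in Da.
#' @examples
#' mh_mz(peptide("LGGNEQVTR"))  # 973.5061
#' @export
mh_mz <- function(pep) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  mt <- mass_table()
  sum(.residue_mass_vector(pep)) + mt$water + mt$proton
}

#' Relative mass error in parts per million
#'
#' @param observed Observed m/z (Da).
#' @param reference Reference m/z (Da), must be > 0.
#' @return Signed ppm: `(observed - reference) / reference * 1e6`.
#'   Vectorised over both arguments.
#' @examples
#' ppm_error(973.5055, 973.5061)  # -0.616
#' @export
ppm_error <- function(observed, reference) {
  if (any(reference <= 0)) stop("reference m/z must be positive")
  (observed - reference) / reference * 1e6
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when followed by P, and returns all
#' peptides carrying 0 to `max_missed` internal missed cleavage sites,
#' each with its 1-based protein-relative start. Peptides containing
#' residues with no defined monoisotopic mass (B, J, O, U, X, Z) are
#' dropped with a warning; any other non-letter input is an error.
#'
#' @param protein_sequence Uppercase protein string.
#' @param max_missed Maximum internal missed cleavages (default 2, the
#'   usual search-engine setting for tryptic FFPE digests).
#' @return data.frame with columns `start`, `sequence`,
#'   `missed_cleavages`; unique on (start, sequence).
#' @examples
#' digest("AGLQFPVGRK", 0)
#' @export
digest <- function(protein_sequence, max_missed = 2L) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L,
            max_missed >= 0L)
  res <- strsplit(protein_sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n == 0L) stop("empty protein sequence")
  known <- c(names(mass_table()$residues), .ambiguous_residues)
  bad <- which(!res %in% known)
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d", res[bad[1]], bad[1]))
  }
  # cleavage after position i: K/R not followed by P
  site <- which(res %in% c("K", "R"))
  site <- site[site == n | res[pmin(site + 1L, n)] != "P"]
  bounds <- unique(c(site, n))           # segment end positions
  starts <- c(1L, head(bounds, -1L) + 1L)
  nseg <- length(bounds)
  out <- vector("list", 0L)
  for (i in seq_len(nseg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nseg) break
      out[[length(out) + 1L]] <- c(starts[i], bounds[j], m)
    }
  }
  tab <- do.call(rbind, out)
  seqs <- substring(protein_sequence, tab[, 1], tab[, 2])
  keep <- !grepl(paste0("[", paste(.ambiguous_residues, collapse = ""), "]"),
                 seqs)
  if (any(!keep)) {
    warning(sprintf("dropped %d peptide(s) containing B/J/O/U/X/Z residues",
                    sum(!keep)))
  }
  df <- data.frame(start = as.integer(tab[keep, 1]), sequence = seqs[keep],
                   missed_cleavages = as.integer(tab[keep, 3]))
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Enumerate variable-modification isoforms
#'
#' Places 0 to `max_mods` variable modifications on their target residues,
#' at most one per position, and returns all distinct isoforms including
#' the unmodified peptide.
#'
#' @param pep A `peptide`, unmodified at the targeted positions.
#' @param mods List of [modification()] objects (kind `"variable"`).
#' @param max_mods Maximum simultaneous modifications (default 2).
#' @return List of `peptide` objects; first element is the unmodified form.
#' @examples
#' length(expand_variable_mods(peptide("PPK"), default_modifications()["hydroxylation"], 2))
#' @export
expand_variable_mods <- function(pep, mods, max_mods = 2L) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  res <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
  # candidate (position, mod) slots on unmodified target residues
  slots <- list()
  for (m in mods) {
    pos <- which(res %in% m$targets)
    pos <- setdiff(pos, pep$mods$position)
    for (p in pos) slots[[length(slots) + 1L]] <- list(position = p, mod = m)
  }
  out <- list(pep)
  if (!length(slots) || max_mods < 1L) return(out)
  slot_pos <- vapply(slots, function(s) s$position, integer(1))
  ns <- length(slots)
  for (k in seq_len(min(max_mods, ns))) {
    combos <- utils::combn(ns, k, simplify = FALSE)
    for (cmb in combos) {
      if (anyDuplicated(slot_pos[cmb])) next   # one mod per position
      add <- do.call(rbind, lapply(cmb, function(i) {
        data.frame(position = slots[[i]]$position,
                   label = slots[[i]]$mod$label,
                   delta = slots[[i]]$mod$delta)
      }))
      out[[length(out) + 1L]] <- peptide(pep$sequence, rbind(pep$mods, add))
    }
  }
  out
}

#' Theoretical b/y fragment series
#'
#' Singly protonated b and y ions of a peptide: `b_i` is the sum of the
#' first i residue masses (with their modifications) plus a proton; `y_j`
#' is the sum of the last j residues plus water and a proton. A peptide of
#' length n yields n-1 ions per series.
#'
#' @param pep A `peptide` of length >= 2.
#' @return data.frame with columns `series` ("b"/"y"), `ordinal`, `mz`,
#'   `label` (e.g. "y3").
#' @examples
#' fragment_series(peptide("GPR"))
#' @export
fragment_series <- function(pep) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  n <- nchar(pep$sequence)
  if (n < 2L) stop("peptide too short for fragmentation (length 1)")
  mt <- mass_table()
  rm <- .residue_mass_vector(pep)
  b <- cumsum(rm)[1:(n - 1L)] + mt$proton
  y <- rev(cumsum(rev(rm)))[2:n] + mt$water + mt$proton
  ord <- seq_len(n - 1L)
  rbind(
    data.frame(series = "b", ordinal = ord, mz = b,
               label = paste0("b", ord)),
    data.frame(series = "y", ordinal = ord, mz = rev(y),
               label = paste0("y", ord))
  )
}

#' Match observed peaks to theoretical fragment ions
#'
#' Each theoretical ion is assigned its nearest observed peak within
#' `tol` Da (at most one peak per ion).
#'
#' @param peaks data.frame (or 2-column matrix) with `mz`, `intensity`.
#' @param theoretical data.frame from [fragment_series()].
#' @param tol Fragment match tolerance in Da (> 0; default 0.3, the usual
#'   MALDI TOF fragment tolerance).
#' @return List with `matches` (one row per matched ion: label, series,
#'   ordinal, mz_theoretical, mz_observed, intensity, delta) and `counts`
#'   (matched/total per series).
#' @export
match_fragments <- function(peaks, theoretical, tol = 0.3) {
  stopifnot(tol > 0)
  peaks <- as.data.frame(peaks)
  if (ncol(peaks) >= 2L && !all(c("mz", "intensity") %in% names(peaks)))
    names(peaks)[1:2] <- c("mz", "intensity")
  o <- order(peaks$mz)
  pmz <- peaks$mz[o]
  pint <- peaks$intensity[o]
  rows <- vector("list", nrow(theoretical))
  for (i in seq_len(nrow(theoretical))) {
    tm <- theoretical$mz[i]
    if (!length(pmz)) next
    j <- which.min(abs(pmz - tm))
    if (abs(pmz[j] - tm) <= tol) {
      rows[[i]] <- data.frame(
        label = theoretical$label[i], series = theoretical$series[i],
        ordinal = theoretical$ordinal[i], mz_theoretical = tm,
        mz_observed = pmz[j], intensity = pint[j], delta = pmz[j] - tm)
    }
  }
  matches <- do.call(rbind, rows)
  if (is.null(matches))
    matches <- data.frame(label = character(), series = character(),
                          ordinal = integer(), mz_theoretical = numeric(),
                          mz_observed = numeric(), intensity = numeric(),
                          delta = numeric())
  counts <- list(
    matched_b = sum(matches$series == "b"),
    total_b = sum(theoretical$series == "b"),
    matched_y = sum(matches$series == "y"),
    total_y = sum(theoretical$series == "y")
  )
  list(matches = matches, counts = counts)
}

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Append reversed decoy sequences
#'
#' Full sequence reversal with accession prefixed by `rev_`, the standard
#' target-decoy construction for FDR estimation.
#'
#' @param sequences Named character vector of target protein sequences.
#' @return Named character vector of targets followed by decoys.
#' @export
decoy_database <- function(sequences) {
  rev_seq <- vapply(strsplit(sequences, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), character(1))
  names(rev_seq) <- paste0("rev_", names(sequences))
  c(sequences, rev_seq)
}
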