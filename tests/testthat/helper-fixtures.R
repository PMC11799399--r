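# shared fixtures, all generated in code

# tiny dataset: explicit peaks on a small grid
tiny_dataset <- function(peaks, width = 4L, height = 4L, ...) {
  msi_dataset(peaks, width = width, height = height, ...)
}

# small two-region phantom for module tests (the full-size default phantom
# is exercised in the acceptance suite)
small_phantom <- function(seed = 1L, noise = list(), ...) {
  phantom_spec(width = 24L, height = 16L, n_per_region = 6L,
               noise = noise, seed = seed, ...)
}

noise_free <- list(sigma = 0, mz_jitter_ppm = 0, mobility_jitter = 0,
                   baseline_density = 0, bleed = 0, ms2_mz_jitter = 0,
                   ms2_rel_threshold = 0)

# random protein of given length (uniform over the 20 residues)
random_protein <- function(len, seed) {
  set.seed(seed)
  paste(sample(names(mass_table()$residues), len, TRUE), collapse = "")
}

# decoyed search database: bundled synthetic proteins + n random background
make_search_db <- function(n_background = 50L, len = 150L, seed = 99L) {
  set.seed(seed)
  aas <- names(mass_table()$residues)
  bg <- vapply(seq_len(n_background),
               function(i) paste(sample(aas, len, TRUE), collapse = ""), "")
  names(bg) <- paste0("BG", seq_len(n_background))
  fasta <- system.file("extdata", "synthetic_proteins.fasta",
                       package = "iprmtools")
  decoy_database(c(read_fasta(fasta), bg))
}

# independent fragment oracle: per-ion prefix/suffix summation
oracle_fragments <- function(sequence, mods = NULL) {
  mt <- mass_table()
  m <- unname(mt$residues[strsplit(sequence, "", fixed = TRUE)[[1]]])
  if (!is.null(mods) && nrow(mods))
    for (r in seq_len(nrow(mods)))
      m[mods$position[r]] <- m[mods$position[r]] + mods$delta[r]
  n <- length(m)
  b <- vapply(seq_len(n - 1L), function(i) sum(m[seq_len(i)]) + mt$proton,
              numeric(1))
  y <- vapply(seq_len(n - 1L),
              function(j) sum(m[seq.int(n - j + 1L, n)]) + mt$water +
                mt$proton, numeric(1))
  list(b = b, y = y)
}

# independent single-linkage oracle: explicit all-pairs adjacency +
# connected components by BFS
oracle_components <- function(mz, mobility, mz_tol, mobility_tol) {
  n <- length(mz)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    lo <- min(mz[i], mz[j]); hi <- max(mz[i], mz[j])
    mz_ok <- hi <= lo * (1 + mz_tol * 1e-6)
    mob_ok <- (is.na(mobility[i]) && is.na(mobility[j])) ||
      (!is.na(mobility[i]) && !is.na(mobility[j]) &&
         abs(mobility[i] - mobility[j]) <= mobility_tol)
    adj[i, j] <- mz_ok && mob_ok
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# exhaustive weighted-interval-scheduling oracle over bitmask subsets
oracle_schedule_value <- function(lo, hi, w, max_n) {
  n <- length(lo)
  masks <- 0:(2^n - 1)
  bits <- outer(masks, 2^(seq_len(n) - 1L),
                function(m, b) bitwAnd(m, b) > 0)
  valid <- rep(TRUE, length(masks))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (lo[j] <= hi[i] && lo[i] <= hi[j])       # touching counts as overlap
      valid <- valid & !(bits[, i] & bits[, j])
  }
  valid <- valid & rowSums(bits) <= max_n
  max((bits %*% w)[valid])
}

# two labelings agree up to renaming
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
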