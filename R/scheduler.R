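#' Collision energy annotation for a precursor mass
#'
#' Linear interpolation from 45 eV at m/z 100 to 140 eV at m/z 2000,
#' clipped to that range — the ramp used when fragmenting singly charged
#' tryptic peptides over a wide precursor mass range. Annotation only;
#' fragmentation simulation does not model energy dependence.
#'
#' @param mz Precursor m/z (Da). Vectorised.
#' @return Collision energy in eV.
#' @export
collision_energy <- function(mz) {
  ce <- 45 + (mz - 100) * (140 - 45) / (2000 - 100)
  pmin(pmax(ce, 45), 140)
}

#' Build a precursor entry around a feature
#'
#' Centres an ion mobility isolation window of half-width `half_width` on
#' the feature's 1/K0 centroid, clipped to the acquisition range, and
#' annotates the interpolated collision energy.
#'
#' @param candidate One row of a `feature_list` (needs `mz_centroid`,
#'   `mobility_centroid`, optionally `priority`).
#' @param half_width Window half-width in V·s/cm² (> 0; default 0.025,
#'   wide enough for efficient isolation while fitting ~18 disjoint
#'   windows into the 0.9 V·s/cm² mobility range).
#' @param priority Scheduling priority (defaults to `candidate$priority`,
#'   else 1).
#' @param mobility_range Acquisition range (default `c(1.2, 2.1)`).
#' @return One-row data.frame of class `precursor_list`: `id`, `mz`,
#'   `mobility_low`, `mobility_high`, `priority`, `collision_energy`.
#' @export
assign_window <- function(candidate, half_width = 0.025, priority = NULL,
                          mobility_range = c(1.2, 2.1)) {
  stopifnot(half_width > 0)
  mob <- candidate$mobility_centroid
  if (is.na(mob) || mob < mobility_range[1] || mob > mobility_range[2])
    stop(sprintf("mobility centroid %.4f outside acquisition range [%g, %g]",
                 mob, mobility_range[1], mobility_range[2]))
  pr <- priority %||% candidate$priority %||% 1
  if (is.null(pr) || is.na(pr)) pr <- 1
  structure(data.frame(
    id = as.character(candidate$id %||% NA),
    mz = candidate$mz_centroid,
    mobility_low = max(mob - half_width, mobility_range[1]),
    mobility_high = min(mob + half_width, mobility_range[2]),
    priority = pr,
    collision_energy = collision_energy(candidate$mz_centroid)),
    class = c("precursor_list", "data.frame"))
}

#' Schedule non-overlapping ion mobility windows
#'
#' Selects at most `max_n` precursor entries with pairwise disjoint 1/K0
#' windows (touching endpoints count as overlap) maximising the total
#' priority, by exact weighted-interval scheduling: entries sorted by
#' window end, dynamic programming over (entry, cardinality). Ties in
#' total priority are broken deterministically towards higher individual
#' priority, then lower m/z.
#'
#' @param candidates `precursor_list` data.frame (`mz`, `mobility_low`,
#'   `mobility_high`, `priority`).
#' @param max_n Plex limit (default 25, the practical iprm-PASEF entry
#'   limit).
#' @return Scheduled `precursor_list`, sorted by `mobility_low`.
#' @export
schedule <- function(candidates, max_n = 25L) {
  candidates <- as.data.frame(candidates)
  n <- nrow(candidates)
  if (!n) return(structure(candidates, class = c("precursor_list",
                                                 "data.frame")))
  stopifnot(all(candidates$mobility_low < candidates$mobility_high))
  # deterministic tie-break: rank by (higher priority, lower mz)
  rk <- order(-candidates$priority, candidates$mz, candidates$mobility_low)
  tie_bonus <- integer(n)
  tie_bonus[rk] <- n - seq_len(n)          # larger = more preferred
  ord <- order(candidates$mobility_high, candidates$mobility_low)
  s <- candidates$mobility_low[ord]
  e <- candidates$mobility_high[ord]
  w <- candidates$priority[ord]
  tb <- tie_bonus[ord]
  # p[i]: last interval (in end order) ending strictly before s[i]
  pprev <- vapply(seq_len(n), function(i) {
    j <- which(e < s[i])
    if (length(j)) max(j) else 0L
  }, integer(1))
  maxc <- min(max_n, n)
  # value DP + lexicographic tie score
  V <- matrix(0, nrow = n + 1L, ncol = maxc + 1L)
  Tb <- matrix(0, nrow = n + 1L, ncol = maxc + 1L)
  take <- matrix(FALSE, nrow = n + 1L, ncol = maxc + 1L)
  for (i in seq_len(n)) {
    for (c in seq_len(maxc)) {
      skip_v <- V[i, c + 1L]; skip_t <- Tb[i, c + 1L]
      inc_v <- V[pprev[i] + 1L, c] + w[i]
      inc_t <- Tb[pprev[i] + 1L, c] + tb[i]
      if (inc_v > skip_v || (inc_v == skip_v && inc_t > skip_t)) {
        V[i + 1L, c + 1L] <- inc_v
        Tb[i + 1L, c + 1L] <- inc_t
        take[i + 1L, c + 1L] <- TRUE
      } else {
        V[i + 1L, c + 1L] <- skip_v
        Tb[i + 1L, c + 1L] <- skip_t
      }
    }
  }
  sel <- integer(0)
  i <- n; c <- maxc
  while (i >= 1L && c >= 1L) {
    if (take[i + 1L, c + 1L]) {
      sel <- c(sel, i)
      i <- pprev[i]
      c <- c - 1L
    } else {
      i <- i - 1L
    }
  }
  out <- candidates[ord[sel], , drop = FALSE]
  out <- out[order(out$mobility_low), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("precursor_list", "data.frame"))
}

#' @export
print.precursor_list <- function(x, ...) {
  cat(sprintf("<precursor_list> %d entries\n", nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Export / import a precursor list as TSV
#'
#' @param precursors A `precursor_list`.
#' @param path TSV path.
#' @return `path` / a `precursor_list`.
#' @export
write_precursors <- function(precursors, path) {
  utils::write.table(as.data.frame(precursors), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_precursors
#' @export
read_precursors <- function(path) {
  df <- utils::read.delim(path, colClasses = c(id = "character"))
  structure(df, class = c("precursor_list", "data.frame"))
}
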