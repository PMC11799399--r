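#' MS1 feature discovery in (m/z, 1/K0) space
#'
#' Pools all pixel peaks of an RMS-normalized MS1 dataset and clusters
#' them by single linkage with tolerance thresholds in both coordinates:
#' two peaks are linked when they lie within `mz_tol` ppm in mass and
#' `mobility_tol` V·s/cm² in mobility, and a feature is a connected
#' component of that graph. Each feature gets intensity-weighted (m/z,
#' 1/K0) centroids, tissue coverage and intensity statistics. Components
#' failing the coverage or relative-intensity thresholds are dropped.
#' This is a deterministic, auditable replacement for proprietary
#' feature-finding tools.
#'
#' @param dataset RMS-normalized MS1 `msi_dataset`.
#' @param mz_tol Link tolerance in ppm (default 10).
#' @param mobility_tol Link tolerance in V·s/cm² (default 0.01).
#' @param min_coverage Minimum fraction of tissue pixels containing the
#'   feature (default 0.5).
#' @param min_rel_intensity Minimum feature max intensity relative to the
#'   dataset-wide maximum normalized peak intensity (default 0.01).
#' @return data.frame of class `feature_list` with columns `id`,
#'   `mz_centroid`, `mobility_centroid`, `coverage`, `mean_intensity`,
#'   `max_intensity`, `n_peaks`, sorted by m/z.
#' @export
find_features <- function(dataset, mz_tol = 10, mobility_tol = 0.01,
                          min_coverage = 0.5, min_rel_intensity = 0.01) {
  stopifnot(mz_tol > 0, mobility_tol > 0)
  p <- dataset$peaks
  if (!nrow(p)) {
    return(structure(data.frame(id = integer(), mz_centroid = numeric(),
                                mobility_centroid = numeric(),
                                coverage = numeric(),
                                mean_intensity = numeric(),
                                max_intensity = numeric(),
                                n_peaks = integer()),
                     class = c("feature_list", "data.frame")))
  }
  comp <- .tolerance_components(p$mz, p$mobility, mz_tol, mobility_tol)
  w <- p$intensity
  cw <- rowsum(w, comp)[, 1]
  mzc <- rowsum(w * p$mz, comp)[, 1] / cw
  has_mob <- !all(is.na(p$mobility))
  mobc <- if (has_mob) rowsum(w * p$mobility, comp)[, 1] / cw else
    rep(NA_real_, length(cw))
  npix_tissue <- sum(dataset$tissue_mask)
  cov <- tapply(.pixel_key(dataset, p$x, p$y), comp,
                function(k) length(unique(k))) / npix_tissue
  maxi <- tapply(w, comp, max)
  meani <- tapply(w, comp, mean)
  npk <- tabulate(comp)
  keep <- cov >= min_coverage & maxi >= min_rel_intensity * max(w)
  df <- data.frame(mz_centroid = mzc, mobility_centroid = mobc,
                   coverage = as.numeric(cov),
                   mean_intensity = as.numeric(meani),
                   max_intensity = as.numeric(maxi),
                   n_peaks = npk[sort(unique(comp))])[keep, , drop = FALSE]
  df <- df[order(df$mz_centroid), , drop = FALSE]
  df <- cbind(id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  structure(df, class = c("feature_list", "data.frame"))
}

# Connected components of the tolerance graph (single linkage): two peaks
# are linked when the higher m/z is within mz_tol ppm of the lower one and
# |dmob| <= mobility_tol (or both mobilities are absent). Exact union-find
# over tolerance-sized cells: peaks sharing a cell are mutually within
# tolerance (cell widths equal the tolerances, ppm cells on the log scale),
# so a cell is unioned wholesale; across same/adjacent cells one linked
# pair suffices to merge the components.
.tolerance_components <- function(mz, mobility, mz_tol, mobility_tol) {
  n <- length(mz)
  if (n == 0L) return(integer(0))
  rel <- mz_tol * 1e-6
  mzc <- floor(log(mz) / log1p(rel))
  na_code <- -999999
  mobc <- ifelse(is.na(mobility), na_code, floor(mobility / mobility_tol))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  key <- mzc * 1e7 + mobc
  ukeys <- sort(unique(key))
  cells <- split(seq_len(n), match(key, ukeys))
  for (g in cells) {
    if (length(g) > 1L) for (k in 2:length(g)) union2(g[[1L]], g[[k]])
  }
  # one linked cross pair merges two (already internally unioned) cells;
  # prune each side to the m/z band that can reach the other, then test
  # the cross product vectorised
  cross_link <- function(ga, gb, mob_na) {
    ga <- ga[mz[ga] >= min(mz[gb]) / (1 + rel) &
               mz[ga] <= max(mz[gb]) * (1 + rel)]
    if (!length(ga)) return(invisible())
    gb <- gb[mz[gb] >= min(mz[ga]) / (1 + rel) &
               mz[gb] <= max(mz[ga]) * (1 + rel)]
    if (!length(gb)) return(invisible())
    # chunked cross product: a genuinely linked cell pair hits in the
    # first chunk, so the full product is only evaluated for non-links
    for (chunk in split(ga, ceiling(seq_along(ga) / 32))) {
      ia <- rep(chunk, times = length(gb))
      ib <- rep(gb, each = length(chunk))
      lo <- pmin(mz[ia], mz[ib])
      hi <- pmax(mz[ia], mz[ib])
      ok <- hi <= lo * (1 + rel)
      if (!mob_na) ok <- ok & abs(mobility[ia] - mobility[ib]) <= mobility_tol
      j <- which(ok)
      if (length(j)) {
        union2(ia[j[1]], ib[j[1]])
        return(invisible())
      }
    }
    invisible()
  }
  # half of the neighbour offsets (the rest are covered symmetrically);
  # neighbour cell resolution vectorised over all cells per offset
  mob_na_vec <- (ukeys %% 1e7) == (na_code %% 1e7)
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb_idx <- match(ukeys + off[1] * 1e7 + off[2], ukeys)
    hit <- which(!is.na(nb_idx) & !(mob_na_vec & off[2] != 0))
    for (ci in hit)
      cross_link(cells[[ci]], cells[[nb_idx[ci]]], mob_na_vec[ci])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots[order(mz)])))
}

#' @export
print.feature_list <- function(x, ...) {
  cat(sprintf("<feature_list> %d features, m/z %.4f-%.4f\n", nrow(x),
              suppressWarnings(min(x$mz_centroid)),
              suppressWarnings(max(x$mz_centroid))))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Ion image of a discovered feature
#'
#' @param dataset The `msi_dataset` the feature was found in.
#' @param feature One row of a [find_features()] result (or a list with
#'   `mz_centroid`, `mobility_centroid`).
#' @param mz_tol,mobility_tol Window half-widths (ppm, V·s/cm²).
#' @return An `ion_image` at `mz_centroid` ± `mz_tol` ppm,
#'   `mobility_centroid` ± `mobility_tol`.
#' @export
feature_image <- function(dataset, feature, mz_tol = 10,
                          mobility_tol = 0.01) {
  mob <- feature$mobility_centroid
  win <- if (is.null(mob) || is.na(mob)) NULL else
    c(mob - mobility_tol, mob + mobility_tol)
  extract_ion_image(dataset, feature$mz_centroid, mz_tol,
                    mobility_window = win)
}

#' Construct a feature at user-chosen coordinates
#'
#' The manual fallback used when automated feature finding misses a peak
#' maximum in the two-dimensional (m/z, 1/K0) plot: statistics are
#' computed from the peaks inside the window around the given
#' coordinates.
#'
#' @param mz,mobility Feature coordinates; must lie inside the dataset's
#'   acquisition ranges.
#' @param dataset The `msi_dataset`.
#' @param mz_tol,mobility_tol Window half-widths (ppm, V·s/cm²).
#' @return One-row `feature_list`.
#' @export
manual_feature <- function(mz, mobility, dataset, mz_tol = 10,
                           mobility_tol = 0.01) {
  rngs <- dataset$metadata
  if (mz < rngs$mz_range[1] || mz > rngs$mz_range[2])
    stop(sprintf("m/z %.4f outside acquisition range [%g, %g]", mz,
                 rngs$mz_range[1], rngs$mz_range[2]))
  if (!is.na(mobility) &&
      (mobility < rngs$mobility_range[1] || mobility > rngs$mobility_range[2]))
    stop(sprintf("1/K0 %.4f outside acquisition range [%g, %g]", mobility,
                 rngs$mobility_range[1], rngs$mobility_range[2]))
  p <- dataset$peaks
  sel <- abs(ppm_error(p$mz, mz)) <= mz_tol
  if (!is.na(mobility))
    sel <- sel & !is.na(p$mobility) & abs(p$mobility - mobility) <= mobility_tol
  p <- p[sel, , drop = FALSE]
  cov <- if (nrow(p))
    length(unique(.pixel_key(dataset, p$x, p$y))) / sum(dataset$tissue_mask)
  else 0
  structure(data.frame(
    id = NA_integer_, mz_centroid = mz, mobility_centroid = mobility,
    coverage = cov,
    mean_intensity = if (nrow(p)) mean(p$intensity) else 0,
    max_intensity = if (nrow(p)) max(p$intensity) else 0,
    n_peaks = nrow(p)), class = c("feature_list", "data.frame"))
}

#' Export / import a feature list as TSV
#'
#' The interchange surface between feature finding, spatial statistics
#' and precursor scheduling.
#'
#' @param features A `feature_list`.
#' @param path TSV path.
#' @return `path` / a `feature_list`.
#' @export
write_features <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path)
  structure(df, class = c("feature_list", "data.frame"))
}
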