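# RNG hygiene: run `expr` under a seeded, isolated RNG stream and restore
# the caller's state afterwards.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Pixel-by-feature intensity matrix
#'
#' Builds the input for segmentation: one row per tissue pixel, one
#' column per feature, holding the windowed summed intensity of that
#' feature in that pixel.
#'
#' @param dataset An `msi_dataset`.
#' @param features A `feature_list`.
#' @param mz_tol,mobility_tol Window half-widths (ppm, V·s/cm²).
#' @return Numeric matrix with attribute `pixels` (data.frame of `x`,
#'   `y` for each row).
#' @export
feature_matrix <- function(dataset, features, mz_tol = 10,
                           mobility_tol = 0.01) {
  mask <- dataset$tissue_mask
  idx <- which(mask, arr.ind = TRUE)  # row = y+1, col = x+1
  pixels <- data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  M <- matrix(0, nrow = nrow(pixels), ncol = nrow(features))
  for (j in seq_len(nrow(features))) {
    img <- feature_image(dataset, features[j, ], mz_tol, mobility_tol)
    M[, j] <- unclass(img)[idx]
  }
  colnames(M) <- paste0("f", features$id)
  attr(M, "pixels") <- pixels
  M
}

#' Bisecting k-means segmentation under correlation distance
#'
#' Repeatedly bisects the cluster with the largest inertia using 2-means
#' until `k` clusters exist. The correlation distance
#' d(u, v) = 1 - Pearson(u, v) is handled through the identity
#' 1 - r = ||z_u - z_v||^2 / (2 (p - 1)) for row-standardised vectors, so
#' every bisection is an ordinary Euclidean 2-means on z-scored rows.
#' Deterministic for a fixed `seed`.
#'
#' @param feature_matrix Pixels-by-features intensity matrix (see
#'   [feature_matrix()]).
#' @param k Number of clusters (>= 2, <= number of rows).
#' @param seed Integer seed.
#' @return Object of class `segmentation`: `labels` (0-based, one per
#'   row), `k`, `seed`, `metric`, `inertia` (per-step total inertia, non-
#'   increasing), and the `pixels` attribute carried over when present.
#' @export
bisecting_kmeans <- function(feature_matrix, k, seed = 1L) {
  stopifnot(k >= 2L)
  n <- nrow(feature_matrix)
  if (k > n) stop("k exceeds the number of pixels")
  p <- ncol(feature_matrix)
  mu <- rowMeans(feature_matrix)
  sd_ <- apply(feature_matrix, 1, stats::sd)
  degenerate <- sd_ == 0 | !is.finite(sd_)
  z <- (feature_matrix - mu) / ifelse(degenerate, 1, sd_)
  z[degenerate, ] <- 0  # constant rows: correlation undefined, placed at origin
  z <- z / sqrt(max(p - 1, 1))

  labels <- rep(0L, n)
  sse <- function(rows) {
    if (length(rows) < 2L) return(0)
    zc <- z[rows, , drop = FALSE]
    sum(sweep(zc, 2, colMeans(zc))^2)
  }
  cluster_sse <- c(sse(seq_len(n)))
  inertia_trace <- sum(cluster_sse)
  .with_seed(seed, {
    while (length(cluster_sse) < k) {
      target <- which.max(cluster_sse)
      rows <- which(labels == target - 1L)
      zc <- z[rows, , drop = FALSE]
      ndistinct <- nrow(unique(zc))
      new_id <- length(cluster_sse)
      if (ndistinct < 2L) {
        warning("degenerate split: cluster ", target - 1L,
                " has identical pixels; splitting arbitrarily")
        half <- seq_len(ceiling(length(rows) / 2))
        labels[rows[-half]] <- new_id
      } else {
        km <- stats::kmeans(zc, centers = 2L, nstart = 5L, iter.max = 50L)
        labels[rows[km$cluster == 2L]] <- new_id
      }
      cluster_sse[target] <- sse(which(labels == target - 1L))
      cluster_sse[new_id + 1L] <- sse(which(labels == new_id))
      inertia_trace <- c(inertia_trace, sum(cluster_sse))
    }
  })
  structure(list(labels = labels, k = k, seed = seed,
                 metric = "correlation", inertia = inertia_trace,
                 pixels = attr(feature_matrix, "pixels")),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> k = %d, %d pixels, metric = %s\n", x$k,
              length(x$labels), x$metric))
  print(table(labels = x$labels))
  invisible(x)
}

#' Segmentation label map
#'
#' @param segmentation A [bisecting_kmeans()] result with pixel
#'   coordinates attached.
#' @param width,height Grid size.
#' @return Integer matrix (`NA` off tissue).
#' @export
segmentation_map <- function(segmentation, width, height) {
  m <- matrix(NA_integer_, nrow = height, ncol = width)
  px <- segmentation$pixels
  m[cbind(px$y + 1L, px$x + 1L)] <- segmentation$labels
  m
}

# Pearson r + two-sided t-test p-value between paired vectors; NA-free
# input expected. Zero variance on either side yields an undefined r.
.pearson_result <- function(a, b, feature_id = NA) {
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired on-tissue pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(data.frame(feature_id = feature_id, r = NA_real_, p = NA_real_,
                      n = n, significant = FALSE,
                      reason = "zero variance"))
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value  # exact +/-1: t statistic diverges
  data.frame(feature_id = feature_id, r = r, p = p, n = n,
             significant = is.finite(p) && p < 0.05, reason = "")
}

#' Co-localization of an ion image with a tissue region
#'
#' Pearson correlation between the ion image and the binary region
#' indicator (1 inside the region, 0 elsewhere on tissue), with a
#' two-sided p-value from the t-transform. Only correlations with
#' p < 0.05 are flagged significant. Off-tissue (`NA`) pixels are
#' excluded.
#'
#' @param image An `ion_image`.
#' @param region Logical matrix of the same dimensions (subset of the
#'   tissue).
#' @param feature_id Optional identifier carried into the result.
#' @return One-row data.frame: `feature_id`, `r`, `p`, `n`,
#'   `significant`, `reason`.
#' @export
coloc_to_region <- function(image, region, feature_id = NA) {
  m <- unclass(image)
  stopifnot(all(dim(m) == dim(region)))
  on_tissue <- !is.na(m)
  .pearson_result(m[on_tissue], as.numeric(region[on_tissue]), feature_id)
}

#' Co-localization of two ion images
#'
#' Pearson correlation between two images (e.g. a fragment MS2 image and
#' its parent MS1 image) over their common valid pixels.
#'
#' @param image,parent `ion_image`s on the same grid.
#' @param feature_id Optional identifier.
#' @return One-row data.frame as in [coloc_to_region()].
#' @export
coloc_to_feature <- function(image, parent, feature_id = NA) {
  a <- unclass(image)
  b <- unclass(parent)
  stopifnot(all(dim(a) == dim(b)))
  ok <- !is.na(a) & !is.na(b)
  .pearson_result(a[ok], b[ok], feature_id)
}

#' Rank co-localization results into precursor candidates
#'
#' Keeps statistically significant results with |r| at or above the
#' threshold (inclusive) and ranks them by |r| descending. Positive r
#' marks co-localization with the region, negative r with its
#' complement. Additional features can be forced in via `manual_ids`
#' (e.g. literature-guided picks with only moderate correlation).
#'
#' @param results data.frame of stacked [coloc_to_region()] rows.
#' @param threshold Absolute-correlation cut-off (default 0.7).
#' @param manual_ids Feature ids retained regardless of threshold.
#' @param adjust Apply Benjamini-Hochberg correction to the p-values
#'   before the significance check (off by default).
#' @return data.frame of candidates ordered by |r| descending, with a
#'   `side` column (`"region"`/`"complement"`) and `manual` flag.
#' @export
select_candidates <- function(results, threshold = 0.7, manual_ids = NULL,
                              adjust = FALSE) {
  if (!nrow(results)) return(cbind(results, side = character(0),
                                   manual = logical(0)))
  p <- if (adjust) stats::p.adjust(results$p, method = "BH") else results$p
  keep <- !is.na(results$r) & !is.na(p) & p < 0.05 &
    abs(results$r) >= threshold
  keep <- keep | (results$feature_id %in% manual_ids)
  out <- results[keep, , drop = FALSE]
  out$side <- ifelse(out$r >= 0, "region", "complement")
  out$manual <- out$feature_id %in% manual_ids &
    !(abs(out$r) >= threshold & !is.na(out$p) & out$p < 0.05)
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
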