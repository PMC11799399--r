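#' Ion-mobility-resolved MS imaging dataset
#'
#' The central container: a pixel grid of centroided peak lists, each peak
#' carrying m/z (Da), optional inverse reduced ion mobility 1/K0
#' (V·s/cm²) and intensity. MS1 survey data and multiplexed MS2 frames
#' (tagged by precursor) share the model; TIMS-off data simply has no
#' mobility column values.
#'
#' @param peaks data.frame with columns `x`, `y` (0-based pixel
#'   coordinates, row-major, origin top-left), `mz`, `intensity`, and
#'   optionally `mobility` and `precursor_id` (MS2 only).
#' @param width,height Grid size in pixels.
#' @param pixel_size Pixel edge length in micrometre (default 50, the MS1
#'   survey resolution; MS2 imaging typically uses 100).
#' @param level `"MS1"` or `"MS2"`.
#' @param tissue_mask Logical `height x width` matrix (`[y+1, x+1]`); by
#'   default every pixel with at least one peak is tissue.
#' @param mz_range,mobility_range Acquisition ranges; defaults m/z
#'   800-2000 and 1/K0 1.2-2.1 V·s/cm², the usual tryptic peptide imaging
#'   windows.
#' @return Object of class `msi_dataset`.
#' @export
msi_dataset <- function(peaks, width, height, pixel_size = 50,
                        level = c("MS1", "MS2"), tissue_mask = NULL,
                        mz_range = c(800, 2000),
                        mobility_range = c(1.2, 2.1)) {
  level <- match.arg(level)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("x", "y", "mz", "intensity") %in% names(peaks)))
  if (!"mobility" %in% names(peaks))
    peaks$mobility <- rep(NA_real_, nrow(peaks))
  if (!"precursor_id" %in% names(peaks))
    peaks$precursor_id <- rep(NA_character_, nrow(peaks))
  if (nrow(peaks)) {
    stopifnot(all(peaks$x >= 0 & peaks$x < width),
              all(peaks$y >= 0 & peaks$y < height),
              all(peaks$intensity >= 0))
    peaks <- peaks[order(peaks$y, peaks$x, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  if (is.null(tissue_mask)) {
    tissue_mask <- matrix(FALSE, nrow = height, ncol = width)
    if (nrow(peaks))
      tissue_mask[cbind(peaks$y + 1L, peaks$x + 1L)] <- TRUE
  }
  stopifnot(nrow(tissue_mask) == height, ncol(tissue_mask) == width)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, level = level, peaks = peaks,
                 tissue_mask = tissue_mask,
                 metadata = list(mz_range = mz_range,
                                 mobility_range = mobility_range,
                                 normalized = FALSE)),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf(
    "<msi_dataset> %s, %d x %d px (%g um), %d peaks in %d tissue pixels%s\n",
    x$level, x$width, x$height, x$pixel_size, nrow(x$peaks),
    sum(x$tissue_mask),
    if (isTRUE(x$metadata$normalized)) ", RMS-normalized" else ""))
  invisible(x)
}

# integer key of a pixel / spectrum within a dataset
.pixel_key <- function(d, x, y, precursor_id = NULL) {
  k <- y * d$width + x
  if (!is.null(precursor_id)) {
    pid <- as.integer(factor(precursor_id))
    pid[is.na(pid)] <- 0L
    k <- k + as.numeric(pid) * d$width * d$height
  }
  k
}

#' RMS normalization
#'
#' Scales intensities so each spectrum has root-mean-square intensity 1,
#' the normalization conventionally applied before feature finding and
#' segmentation in peptide MALDI imaging. Idempotent and scale invariant.
#'
#' For an `msi_dataset`, each pixel spectrum (per precursor for MS2 data)
#' is normalized independently; all-zero spectra are left unchanged and
#' counted in the `flagged` attribute. For a numeric vector the scaled
#' vector is returned.
#'
#' @param x An `msi_dataset` or a numeric intensity vector.
#' @return Same type as `x`.
#' @examples
#' rms_normalize(c(3, 4))  # 0.8485 1.1314
#' @export
rms_normalize <- function(x) UseMethod("rms_normalize")

#' @export
rms_normalize.numeric <- function(x) {
  r <- sqrt(mean(x^2))
  if (r == 0) {
    attr(x, "flagged") <- TRUE
    return(x)
  }
  x / r
}

#' @export
rms_normalize.msi_dataset <- function(x) {
  if (!nrow(x$peaks)) return(x)
  g <- as.integer(factor(.pixel_key(x, x$peaks$x, x$peaks$y,
                                    x$peaks$precursor_id)))
  ss <- rowsum(x$peaks$intensity^2, g)
  n <- tabulate(g, nbins = nrow(ss))
  rms <- sqrt(ss[, 1] / n)
  zero <- rms == 0
  rms[zero] <- 1
  x$peaks$intensity <- x$peaks$intensity / rms[g]
  x$metadata$normalized <- TRUE
  if (any(zero)) attr(x, "flagged_spectra") <- sum(zero)
  x
}

#' Extract an ion image
#'
#' Per-pixel summed intensity of peaks within a ppm mass window and an
#' optional inclusive 1/K0 window. Off-tissue pixels carry `NA`.
#'
#' @param dataset An `msi_dataset`.
#' @param mz Window centre m/z (Da).
#' @param tol_ppm Half-width in ppm (> 0).
#' @param mobility_window Optional `c(low, high)` in V·s/cm² with
#'   `low < high`.
#' @param precursor_id For MS2 datasets, restrict to one precursor's
#'   frames.
#' @return Object of class `ion_image`: a `height x width` matrix with
#'   attributes `window` and `pixel_size`.
#' @export
extract_ion_image <- function(dataset, mz, tol_ppm,
                              mobility_window = NULL, precursor_id = NULL) {
  stopifnot(tol_ppm > 0)
  if (!is.null(mobility_window)) {
    if (mobility_window[1] >= mobility_window[2])
      stop("empty mobility window (low >= high)")
  }
  p <- dataset$peaks
  sel <- abs(ppm_error(p$mz, mz)) <= tol_ppm
  if (!is.null(mobility_window))
    sel <- sel & !is.na(p$mobility) &
      p$mobility >= mobility_window[1] & p$mobility <= mobility_window[2]
  if (!is.null(precursor_id))
    sel <- sel & !is.na(p$precursor_id) & p$precursor_id == precursor_id
  img <- matrix(0, nrow = dataset$height, ncol = dataset$width)
  p <- p[sel, , drop = FALSE]
  if (nrow(p)) {
    key <- p$y * dataset$width + p$x
    s <- rowsum(p$intensity, key)
    ky <- as.numeric(rownames(s))
    img[cbind(ky %/% dataset$width + 1L, ky %% dataset$width + 1L)] <- s[, 1]
  }
  img[!dataset$tissue_mask] <- NA_real_
  structure(img, class = c("ion_image", "matrix"),
            window = list(mz_center = mz, mz_tol_ppm = tol_ppm,
                          mobility_low = mobility_window[1],
                          mobility_high = mobility_window[2]),
            pixel_size = dataset$pixel_size)
}

#' @export
print.ion_image <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<ion_image> %d x %d px, m/z %.4f +/- %g ppm%s\n",
              ncol(x), nrow(x), w$mz_center, w$mz_tol_ppm,
              if (!is.null(w$mobility_low))
                sprintf(", 1/K0 [%.3f, %.3f]", w$mobility_low,
                        w$mobility_high) else ""))
  invisible(x)
}

#' @export
plot.ion_image <- function(x, main = NULL, ...) {
  m <- unclass(x)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Spatial mean smoothing
#'
#' Sliding-window mean over on-tissue neighbours only; `NA` (off-tissue)
#' pixels stay `NA`. A window of 2 averages the pixel with its right,
#' lower and lower-right neighbours (edge-truncated), mirroring the 2x2
#' smoothing conventionally applied before feature finding.
#'
#' @param image An `ion_image`.
#' @param window Window edge length in pixels (>= 1); 1 is the identity.
#' @return Smoothed `ion_image`.
#' @export
smooth_image <- function(image, window = 2L) {
  stopifnot(window >= 1L)
  if (window == 1L) return(image)
  m <- unclass(image)
  off <- seq.int(-floor((window - 1) / 2), ceiling((window - 1) / 2))
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  val <- ifelse(is.na(m), 0, m)
  ok <- !is.na(m)
  for (dy in off) for (dx in off) {
    src_r <- intersect(seq_len(nr), seq_len(nr) - dy)
    src_c <- intersect(seq_len(nc), seq_len(nc) - dx)
    acc[src_r, src_c] <- acc[src_r, src_c] + val[src_r + dy, src_c + dx]
    cnt[src_r, src_c] <- cnt[src_r, src_c] + ok[src_r + dy, src_c + dx]
  }
  out <- acc / pmax(cnt, 1)
  out[is.na(m)] <- NA_real_
  attributes(out) <- attributes(image)
  out
}

# ---- imzML I/O -------------------------------------------------------------

.imzml_cv <- list(
  processed = "IMS:1000031", continuous = "IMS:1000030",
  uuid = "IMS:1000080", pos_x = "IMS:1000050", pos_y = "IMS:1000051",
  offset = "IMS:1000102", length = "IMS:1000103",
  mz_array = "MS:1000514", intensity_array = "MS:1000515",
  mobility_array = "MS:1003006")

#' Write an imzML file
#'
#' Processed-mode imzML 1.1 with 64-bit float arrays; 1/K0 values, when
#' present, are carried as an auxiliary per-peak inverse-reduced-ion-
#' mobility array. Writes `path` (XML) plus the sibling `.ibd` binary.
#' Internal 0-based pixel coordinates are converted to the format's
#' 1-based convention.
#'
#' @param dataset An `msi_dataset`.
#' @param path Output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (ibd_path == path) ibd_path <- paste0(path, ".ibd")
  uuid <- sprintf("%08x-%04x-%04x-%04x-%012x",
                  as.integer(0x1f2e3d4c), 0x1111L, 0x4abcL, 0x8123L,
                  as.integer(0x00abcdef))
  has_mob <- nrow(dataset$peaks) > 0 && !all(is.na(dataset$peaks$mobility))
  p <- dataset$peaks
  key <- .pixel_key(dataset, p$x, p$y)
  ord <- order(key, p$mz)
  p <- p[ord, , drop = FALSE]
  sp <- split(seq_len(nrow(p)), factor(key[ord], levels = unique(key[ord])))

  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(rep(0L, 16L)), con)  # uuid placeholder bytes
  offset <- 16
  specs <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    rows <- sp[[i]]
    n <- length(rows)
    arrays <- list(mz = p$mz[rows], intensity = p$intensity[rows])
    if (has_mob) arrays$mobility <- p$mobility[rows]
    offs <- numeric(length(arrays))
    for (j in seq_along(arrays)) {
      offs[j] <- offset
      writeBin(as.numeric(arrays[[j]]), con, size = 8, endian = "little")
      offset <- offset + 8 * n
    }
    specs[[i]] <- list(x = p$x[rows[1]] + 1L, y = p$y[rows[1]] + 1L,
                       n = n, offsets = offs)
  }

  cv <- .imzml_cv
  arr_defs <- list(
    list(ref = "mzArray", acc = cv$mz_array, name = "m/z array"),
    list(ref = "intensityArray", acc = cv$intensity_array,
         name = "intensity array"))
  if (has_mob)
    arr_defs[[3]] <- list(ref = "mobilityArray", acc = cv$mobility_array,
                          name = "mean inverse reduced ion mobility array")

  param_groups <- vapply(arr_defs, function(d) {
    paste0(
      sprintf('  <referenceableParamGroup id="%s">\n', d$ref),
      sprintf('   <cvParam accession="%s" name="%s" value=""/>\n', d$acc, d$name),
      '   <cvParam accession="MS:1000523" name="64-bit float" value=""/>\n',
      '   <cvParam accession="MS:1000576" name="no compression" value=""/>\n',
      '  </referenceableParamGroup>\n')
  }, character(1))

  blocks <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    bda <- vapply(seq_along(arr_defs), function(j) {
      d <- arr_defs[[j]]
      paste0(
        '      <binaryDataArray encodedLength="0">\n',
        sprintf('        <referenceableParamGroupRef ref="%s"/>\n', d$ref),
        sprintf('        <cvParam accession="%s" name="external offset" value="%.0f"/>\n',
                cv$offset, s$offsets[j]),
        sprintf('        <cvParam accession="%s" name="external array length" value="%d"/>\n',
                cv$length, s$n),
        sprintf('        <cvParam accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
                8L * s$n),
        '        <binary/>\n      </binaryDataArray>\n')
    }, character(1))
    paste0(
      sprintf('    <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
              i - 1L, i, s$n),
      '     <scanList count="1">\n      <scan>\n',
      sprintf('       <cvParam accession="%s" name="position x" value="%d"/>\n',
              cv$pos_x, s$x),
      sprintf('       <cvParam accession="%s" name="position y" value="%d"/>\n',
              cv$pos_y, s$y),
      '      </scan>\n     </scanList>\n',
      sprintf('     <binaryDataArrayList count="%d">\n', length(arr_defs)),
      paste(bda, collapse = ""),
      '     </binaryDataArrayList>\n    </spectrum>\n')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <fileDescription>\n  <fileContent>\n',
    sprintf('   <cvParam accession="%s" name="processed" value=""/>\n', cv$processed),
    sprintf('   <cvParam accession="%s" name="universally unique identifier" value="{%s}"/>\n',
            cv$uuid, uuid),
    '  </fileContent>\n </fileDescription>\n',
    sprintf(' <referenceableParamGroupList count="%d">\n',
            length(arr_defs)),
    paste(param_groups, collapse = ""),
    ' </referenceableParamGroupList>\n',
    ' <scanSettingsList count="1">\n  <scanSettings id="scan1">\n',
    sprintf('   <cvParam accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
            dataset$width),
    sprintf('   <cvParam accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
            dataset$height),
    sprintf('   <cvParam accession="IMS:1000046" name="pixel size" value="%g"/>\n',
            dataset$pixel_size),
    sprintf('   <userParam name="level" value="%s"/>\n', dataset$level),
    sprintf('   <userParam name="mz_range" value="%g %g"/>\n',
            dataset$metadata$mz_range[1], dataset$metadata$mz_range[2]),
    sprintf('   <userParam name="mobility_range" value="%g %g"/>\n',
            dataset$metadata$mobility_range[1],
            dataset$metadata$mobility_range[2]),
    '  </scanSettings>\n </scanSettingsList>\n',
    ' <instrumentConfigurationList count="1">\n',
    '  <instrumentConfiguration id="IC1"/>\n',
    ' </instrumentConfigurationList>\n',
    sprintf(' <run id="run1">\n   <spectrumList count="%d">\n', length(specs)),
    paste(blocks, collapse = ""),
    '   </spectrumList>\n </run>\n</mzML>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Read an imzML file
#'
#' Reads processed-mode imzML written by [write_imzml()] or compatible
#' tools (64-bit float external arrays). Continuous-mode files are
#' rejected: they carry profile spectra without peak picking, which this
#' data model does not represent.
#'
#' @param path Path to the `.imzML` XML; the `.ibd` binary is expected
#'   alongside.
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse imzML file '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  cv <- .imzml_cv
  fc <- xml2::xml_find_all(doc, ".//fileContent/cvParam")
  acc <- xml2::xml_attr(fc, "accession")
  if (cv$continuous %in% acc && !(cv$processed %in% acc))
    stop("continuous-mode imzML without peak picking is not supported: ",
         path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing .ibd binary next to ", path)

  num_param <- function(xp) {
    nd <- xml2::xml_find_first(doc, xp)
    as.numeric(xml2::xml_attr(nd, "value"))
  }
  width <- num_param(".//scanSettings/cvParam[@accession='IMS:1000042']")
  height <- num_param(".//scanSettings/cvParam[@accession='IMS:1000043']")
  psize <- num_param(".//scanSettings/cvParam[@accession='IMS:1000046']")
  if (is.na(psize)) psize <- 50
  level_nd <- xml2::xml_find_first(doc, ".//userParam[@name='level']")
  level <- xml2::xml_attr(level_nd, "value")
  if (is.na(level)) level <- "MS1"
  rng <- function(name, default) {
    nd <- xml2::xml_find_first(doc, sprintf(".//userParam[@name='%s']", name))
    v <- xml2::xml_attr(nd, "value")
    if (is.na(v)) return(default)
    as.numeric(strsplit(v, " ")[[1]])
  }
  mz_range <- rng("mz_range", c(800, 2000))
  mob_range <- rng("mobility_range", c(1.2, 2.1))

  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    px <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      s, sprintf(".//cvParam[@accession='%s']", cv$pos_x)), "value"))
    py <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      s, sprintf(".//cvParam[@accession='%s']", cv$pos_y)), "value"))
    arrays <- list()
    for (bda in xml2::xml_find_all(s, ".//binaryDataArray")) {
      pacc <- xml2::xml_attr(xml2::xml_find_all(bda, "cvParam"), "accession")
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "referenceableParamGroupRef"), "ref")
      if (!is.na(ref)) {
        grp <- xml2::xml_find_first(doc, sprintf(
          ".//referenceableParamGroup[@id='%s']", ref))
        pacc <- c(pacc, xml2::xml_attr(xml2::xml_find_all(grp, "cvParam"),
                                       "accession"))
      }
      off <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        bda, sprintf("cvParam[@accession='%s']", cv$offset)), "value"))
      len <- as.integer(xml2::xml_attr(xml2::xml_find_first(
        bda, sprintf("cvParam[@accession='%s']", cv$length)), "value"))
      seek(con, off)
      vals <- readBin(con, "numeric", n = len, size = 8, endian = "little")
      kind <- if (cv$mz_array %in% pacc) "mz"
      else if (cv$intensity_array %in% pacc) "intensity"
      else if (cv$mobility_array %in% pacc) "mobility"
      else next
      arrays[[kind]] <- vals
    }
    n <- length(arrays$mz)
    out[[i]] <- data.frame(
      x = rep(px - 1L, n), y = rep(py - 1L, n), mz = arrays$mz,
      mobility = if (is.null(arrays$mobility)) rep(NA_real_, n)
                 else arrays$mobility,
      intensity = arrays$intensity)
  }
  peaks <- do.call(rbind, out)
  msi_dataset(peaks, width = width, height = height, pixel_size = psize,
              level = level, mz_range = mz_range, mobility_range = mob_range)
}

# ---- MGF I/O ---------------------------------------------------------------

#' Write averaged MS2 spectra to an MGF file
#'
#' One `BEGIN IONS` block per spectrum with `PEPMASS`, `CHARGE=1+` and a
#' `TITLE` embedding the precursor id and its 1/K0 window. Spectra with
#' empty peak lists are skipped with a warning.
#'
#' @param spectra A single `ms2_spectrum` or a list of them (see
#'   [average_spectra()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (s in spectra) {
    if (!nrow(s$peaks)) {
      warning("skipping empty spectrum for precursor ",
              s$precursor$id %||% "?")
      next
    }
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=precursor_id=%s mobility_window=%.4f-%.4f n_pixels=%d",
              s$precursor$id %||% "NA",
              s$precursor$mobility_low %||% NA_real_,
              s$precursor$mobility_high %||% NA_real_, s$n_pixels),
      sprintf("PEPMASS=%.6f", s$precursor$mz),
      "CHARGE=1+",
      sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity),
      "END IONS", ""), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an MGF file
#'
#' @param path Path to a Mascot generic format file.
#' @return List of `ms2_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stopifnot(length(starts) == length(ends))
  lapply(seq_along(starts), function(i) {
    blk <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", blk, fixed = TRUE) & !grepl("^[0-9]", blk)
    kv <- strsplit(blk[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(z) paste(z[-1], collapse = "="), character(1))
    pk <- do.call(rbind, lapply(strsplit(trimws(blk[!hdr]), "[ \t]+"),
                                as.numeric))
    peaks <- if (is.null(pk)) data.frame(mz = numeric(), intensity = numeric())
    else data.frame(mz = pk[, 1], intensity = pk[, 2])
    title <- vals[match("TITLE", keys)]
    pid <- sub(".*precursor_id=([^ ]+).*", "\\1", title)
    npx <- suppressWarnings(
      as.integer(sub(".*n_pixels=([0-9]+).*", "\\1", title)))
    structure(list(
      precursor = list(id = pid,
                       mz = as.numeric(vals[match("PEPMASS", keys)])),
      peaks = peaks[order(peaks$mz), , drop = FALSE],
      n_pixels = if (is.na(npx)) 1L else npx), class = "ms2_spectrum")
  })
}
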