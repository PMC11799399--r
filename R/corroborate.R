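#' Bundled cross-platform reference tables
#'
#' Two small measured reference tables ship with the package for worked
#' examples and arithmetic checks:
#' `irt_reference()` holds MALDI-spot vs. LC-ESI-TIMS-MS/MS m/z and 1/K0
#' values of the five synthetic iRT calibration peptides;
#' `tissue_reference()` holds the MALDI-imaging vs. LC-ESI values,
#' fragment-ion counts and search scores of nine tryptic peptides
#' identified on two FFPE tissues (PDX tumor, mouse kidney). Columns
#' suffixed `_printed` carry the published rounded derived values; all
#' other columns are the measured inputs.
#'
#' In the iRT table the published 1/K0 error column is an unsigned
#' magnitude; in the tissue table deltas are signed MALDI minus LC.
#'
#' @return data.frame.
#' @export
irt_reference <- function() {
  utils::read.delim(system.file("extdata", "irt_crossplatform.tsv",
                                package = "iprmtools"))
}

#' @rdname irt_reference
#' @export
tissue_reference <- function() {
  utils::read.delim(system.file("extdata", "tissue_crossplatform.tsv",
                                package = "iprmtools"))
}

#' Cross-platform comparison of MALDI and LC-ESI identifications
#'
#' Inner-joins the two tables on the modified peptide sequence (bracket
#' notation included) and computes the signed mass and mobility deltas.
#' The default convention is MALDI minus LC for both; iRT-style inputs
#' that report the opposite mobility orientation can set
#' `mobility_orientation = "lc_minus_maldi"`. 1/K0 is charge-state
#' dependent, so mobility comparison is suppressed (`comparable` FALSE,
#' delta `NA`) when the LC charge differs from the singly charged MALDI
#' ion.
#'
#' @param maldi_table data.frame with `sequence`, `mz`, `mobility`.
#' @param lc_table data.frame with `sequence`, `mz`, `mobility`,
#'   optionally `charge`.
#' @param mobility_orientation `"maldi_minus_lc"` (default) or
#'   `"lc_minus_maldi"`.
#' @return data.frame of class `crossplatform`: one row per shared
#'   sequence with `delta_ppm`, `delta_mobility`, `lc_charge`,
#'   `comparable`; unmatched sequences are reported in the
#'   `unmatched_maldi` / `unmatched_lc` attributes.
#' @export
compare_platforms <- function(maldi_table, lc_table,
                              mobility_orientation = c("maldi_minus_lc",
                                                       "lc_minus_maldi")) {
  mobility_orientation <- match.arg(mobility_orientation)
  for (nm in list(list(maldi_table, "maldi"), list(lc_table, "lc"))) {
    dup <- unique(nm[[1]]$sequence[duplicated(nm[[1]]$sequence)])
    if (length(dup))
      stop("duplicate sequence keys in ", nm[[2]], " table: ",
           paste(dup, collapse = ", "))
  }
  shared <- intersect(maldi_table$sequence, lc_table$sequence)
  mi <- match(shared, maldi_table$sequence)
  li <- match(shared, lc_table$sequence)
  lc_charge <- if ("charge" %in% names(lc_table)) lc_table$charge[li]
  else rep(1L, length(shared))
  comparable <- !is.na(lc_charge) & lc_charge == 1L
  dmob <- maldi_table$mobility[mi] - lc_table$mobility[li]
  if (mobility_orientation == "lc_minus_maldi") dmob <- -dmob
  dmob[!comparable] <- NA_real_
  out <- data.frame(
    sequence = shared,
    mz_maldi = maldi_table$mz[mi], mz_lc = lc_table$mz[li],
    delta_ppm = ppm_error(maldi_table$mz[mi], lc_table$mz[li]),
    mobility_maldi = maldi_table$mobility[mi],
    mobility_lc = lc_table$mobility[li],
    delta_mobility = dmob, lc_charge = lc_charge,
    comparable = comparable)
  attr(out, "unmatched_maldi") <- setdiff(maldi_table$sequence, shared)
  attr(out, "unmatched_lc") <- setdiff(lc_table$sequence, shared)
  structure(out, class = c("crossplatform", "data.frame"))
}

#' Check cross-platform deltas against tolerance bounds
#'
#' @param matches A [compare_platforms()] result.
#' @param ppm_bound Bound on |delta_ppm| (> 0).
#' @param mobility_bound Bound on |delta_mobility| in V·s/cm² (> 0).
#' @return List: `per_match` (data.frame with pass flags; mobility rows
#'   that are not comparable are excluded from the mobility check),
#'   `max_abs_ppm`, `max_abs_mobility`, `pass` (vacuously TRUE for empty
#'   input).
#' @export
check_tolerances <- function(matches, ppm_bound, mobility_bound) {
  stopifnot(ppm_bound > 0, mobility_bound > 0)
  if (!nrow(matches)) {
    return(list(per_match = cbind(as.data.frame(matches),
                                  ppm_pass = logical(0),
                                  mobility_pass = logical(0)),
                max_abs_ppm = NA_real_, max_abs_mobility = NA_real_,
                pass = TRUE))
  }
  per <- as.data.frame(matches)
  per$ppm_pass <- abs(per$delta_ppm) < ppm_bound
  per$mobility_pass <- ifelse(is.na(per$delta_mobility), NA,
                              abs(per$delta_mobility) < mobility_bound)
  mob <- per$delta_mobility[!is.na(per$delta_mobility)]
  list(per_match = per,
       max_abs_ppm = max(abs(per$delta_ppm)),
       max_abs_mobility = if (length(mob)) max(abs(mob)) else NA_real_,
       pass = all(per$ppm_pass) &&
         all(per$mobility_pass[!is.na(per$mobility_pass)]))
}

#' Fragment-to-parent co-localization report
#'
#' For every matched fragment ion of an identified peptide, extracts its
#' MS2 ion image (fragment m/z ± `frag_tol` Da, restricted to the
#' precursor's mobility window and frames) and correlates it with the
#' parent's MS1 ion image — the spatial corroboration that a fragment
#' genuinely belongs to its precursor.
#'
#' @param ms2_dataset Spatially resolved MS2 `msi_dataset`.
#' @param annotation An [annotate_spectrum()] result (matched fragments).
#' @param parent_image The precursor's MS1 `ion_image` on the same grid.
#' @param entry The `precursor_list` row (for the mobility window / id).
#' @param frag_tol Fragment window half-width in Da (default 0.3).
#' @return data.frame: `label`, `mz`, `r`, `p`, `n`, `significant`,
#'   `reason` (all-zero fragment images are flagged, r undefined).
#' @export
fragment_coloc_report <- function(ms2_dataset, annotation, parent_image,
                                  entry, frag_tol = 0.3) {
  ions <- annotation$ions[annotation$ions$matched, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ions)), function(i) {
    mz <- ions$mz_observed[i]
    img <- extract_ion_image(ms2_dataset, mz, tol_ppm = frag_tol / mz * 1e6,
                             mobility_window = c(entry$mobility_low,
                                                 entry$mobility_high),
                             precursor_id = entry$id)
    res <- coloc_to_feature(img, parent_image, feature_id = ions$label[i])
    data.frame(label = ions$label[i], mz = mz, r = res$r, p = res$p,
               n = res$n, significant = res$significant,
               reason = res$reason)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = character(), mz = numeric(), r = numeric(),
                      p = numeric(), n = integer(), significant = logical(),
                      reason = character())
  out
}
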