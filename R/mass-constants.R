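#' Monoisotopic mass constants
#'
#' Masses used throughout the package: the 20 standard amino acid residue
#' masses, the proton mass added on protonation, and the mass of water that
#' terminates a peptide chain. All values are monoisotopic, in Dalton.
#'
#' @return A list with elements `residues` (named numeric vector of 20
#'   residue masses), `proton` (1.007276 Da) and `water` (18.010565 Da).
#' @examples
#' mass_table()$residues[["G"]]
#' @export
mass_table <- function() {
  list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
      V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    proton = 1.007276,
    water  = 18.010565
  )
}

# residues with no defined monoisotopic mass; peptides containing them are
# dropped during digestion
.ambiguous_residues <- c("B", "J", "O", "U", "X", "Z")

#' Define a mass modification
#'
#' @param label Short text label (e.g. `"Hydroxylation"`).
#' @param delta Mass shift in Da (finite).
#' @param targets Character vector of residue letters the modification can
#'   sit on; must be non-empty.
#' @param kind `"variable"` or `"fixed"`.
#' @return An object of class `modification`.
#' @examples
#' modification("Hydroxylation", 15.999, "P")
#' @export
modification <- function(label, delta, targets, kind = c("variable", "fixed")) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  targets <- unique(toupper(as.character(targets)))
  if (length(targets) == 0L) stop("modification targets must be non-empty")
  structure(list(label = label, delta = delta, targets = targets, kind = kind),
            class = "modification")
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf("<modification> %s %+0.6f Da on [%s] (%s)\n",
              x$label, x$delta, paste(x$targets, collapse = ""), x$kind))
  invisible(x)
}

#' Built-in modification registry
#'
#' Hydroxylation of proline is registered with the nominal +15.999 Da shift
#' used in collagen peptide notation such as `GVVGLP[16]GQR`; oxidation uses
#' the exact monoisotopic +15.994915 Da on H/W/P/M. Arbitrary user deltas
#' are accepted via [modification()].
#'
#' @return Named list of `modification` objects.
#' @export
default_modifications <- function() {
  list(
    hydroxylation = modification("Hydroxylation", 15.999, "P"),
    oxidation     = modification("Oxidation", 15.994915, c("H", "W", "P", "M"))
  )
}
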