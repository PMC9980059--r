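#' Scan a protein sequence for all placements of a degenerate motif
#'
#' Enumerates every distinct anchor placement of `pattern` on `subject`:
#' each combination of spacer lengths that changes any anchor position is
#' reported as a separate match. Characters outside the 20 standard
#' amino-acid codes never satisfy a fixed or class element but do count
#' toward spacer lengths. Coordinates are 0-based half-open, the
#' convention used in all files and reports of this package.
#'
#' @param subject a character string, `AAString`, or `AAStringSet`.
#' @param pattern a [MotifPattern-class] from [parsePattern()].
#' @param mode `"all"` (every placement) or `"first"` (leftmost only).
#' @param ... passed to methods.
#' @return A data.frame with columns `start`, `end` (0-based half-open
#'   full span over the anchors) and a list column `anchors` (integer
#'   matrices, one row per non-gap element, columns `start`, `end`).
#'   The `AAStringSet` method prepends a `sequence_id` column. Matches
#'   are sorted by full-span start, then lexicographically by anchor
#'   starts. Zero-row data.frame when there is no match.
#' @examples
#' p <- parsePattern("A[X1-2]C", name = "demo")
#' scanMotif("AGCAGGC", p)
#' @export
setGeneric("scanMotif",
           function(subject, pattern, mode = c("all", "first"), ...)
             standardGeneric("scanMotif"))

#' Molecular formula of a cyclic dinucleotide
#'
#' Computed as NMP(base1) + NMP(base2) - 2 H2O over the free-acid NMP
#' formulas; independent of the linkage donors (linkage isomers share a
#' formula).
#'
#' @param x a [CyclicDinucleotide-class].
#' @return Named integer vector of element counts over C, H, N, O, P.
#' @examples
#' formulaToString(formulaOf(parseCdnName("2'3'-cUA")))  # C19H23N7O14P2
#' @export
setGeneric("formulaOf", function(x) standardGeneric("formulaOf"))

#' Predicted assay signature of a cyclic dinucleotide
#'
#' Applies the bond rules of the radiolabel / CIP / nuclease-P1 screen:
#' the alpha-phosphate of base X sits on X's own 5' carbon; a bond whose
#' donor hydroxyl is 3' is P1-cleavable while a 2' donor bond is
#' protected; P1 cleavage exposes the cleaved phosphate as a terminal
#' 5'-phosphate which CIP removes; the label of base X survives P1+CIP
#' iff at least one alpha-phosphate of an X unit remains in an uncleaved
#' bond. Every intact cyclic product is CIP-resistant.
#'
#' @param x a canonical [CyclicDinucleotide-class].
#' @return A list with elements `labels` (bases that incorporate
#'   alpha-32P label), `cipResistant` (TRUE), `p1Retention` (named
#'   character, base -> "retained"/"lost"), `formula`, and `adductMz`
#'   (named numeric for the supported ESI adducts).
#' @examples
#' predictSignature(parseCdnName("3'3'-cUA"))$p1Retention  # both lost
#' @export
setGeneric("predictSignature", function(x) standardGeneric("predictSignature"))

#' Fit a single-site binding isotherm
#'
#' Least-squares estimate of the dissociation constant for
#' `fraction = c / (c + Kd)` under the trace-ligand approximation.
#' The search is over log10(Kd), bracketed two decades beyond the
#' measured concentration range, with a deterministic grid followed by
#' golden-section refinement, so results are reproducible.
#'
#' @param x a [BindingCurve-class] (or method-specific input).
#' @param ... passed to methods.
#' @return An [IsothermFit-class]. Degenerate curves (all fractions
#'   equal, e.g. no binding detected) return `converged = FALSE` with a
#'   diagnostic rather than an error.
#' @examples
#' cc <- 10^seq(-8, -4, length.out = 8)
#' fitIsotherm(BindingCurve("demo", cc, cc / (cc + 1e-6)))
#' @export
setGeneric("fitIsotherm", function(x, ...) standardGeneric("fitIsotherm"))
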