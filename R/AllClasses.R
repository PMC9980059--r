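#' @import methods
NULL

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CDN_BASES <- c("A", "C", "G", "U")
CDN_DONORS <- c("2'", "3'")

#' Degenerate protein motif pattern
#'
#' A parsed motif in the mini-language used for cGLR active-site curation:
#' an ordered list of elements, each a fixed residue, a residue class, or a
#' variable-length spacer (gap) with inclusive residue-count bounds.
#' Construct with [parsePattern()].
#'
#' @slot name pattern name (used in reports).
#' @slot elements list of elements; each a list with `kind`
#'   (`"fixed"`, `"class"` or `"gap"`) and kind-specific fields:
#'   `residue` for fixed, `label` + `members` for class,
#'   `min` + `max` for gap.
#' @slot classes named list of residue classes (label -> character vector
#'   of one-letter codes) available to the pattern.
#' @export
setClass("MotifPattern",
         representation(name = "character",
                        elements = "list",
                        classes = "list"))

setValidity("MotifPattern", function(object) {
  el <- object@elements
  if (length(el) == 0L) return("pattern has no elements")
  kinds <- vapply(el, `[[`, character(1), "kind")
  if (!any(kinds != "gap")) return("pattern must contain a non-gap element")
  if (any(kinds == "gap" & c(kinds[-1], "") == "gap"))
    return("consecutive gap elements (parser should have merged them)")
  for (e in el) {
    if (e$kind == "gap") {
      if (e$min > e$max) return("gap with min > max")
      if (e$min < 0L) return("gap with negative min")
    } else if (e$kind == "class") {
      if (length(e$members) == 0L) return("empty residue class")
      if (!all(e$members %in% AA_STANDARD))
        return("residue class member outside the 20 standard codes")
    } else if (e$kind == "fixed") {
      if (!e$residue %in% AA_STANDARD)
        return("fixed residue outside the 20 standard codes")
    } else return(sprintf("unknown element kind '%s'", e$kind))
  }
  TRUE
})

setMethod("show", "MotifPattern", function(object) {
  cat("MotifPattern '", object@name, "': ",
      patternToString(object), "\n", sep = "")
  cat("  ", length(object@elements), " elements (",
      sum(vapply(object@elements, function(e) e$kind != "gap", logical(1))),
      " anchors)\n", sep = "")
})

#' Canonical cyclic dinucleotide
#'
#' Two (base, ribose-donor) nucleotide units joined head-to-tail by two
#' phosphodiester bonds. `donors[i]` is the ribose hydroxyl (2' or 3')
#' that unit `i` contributes to its outgoing bond; by the synthesis
#' convention the alpha-phosphate of each base sits on that base's own 5'
#' carbon, so the bond donated by unit i contains the alpha-phosphate of
#' unit i's partner. Objects are stored in canonical unit order (unique
#' under cyclic symmetry); construct with [CDN()] or [parseCdnName()].
#'
#' @slot bases character(2), each in A/C/G/U.
#' @slot donors character(2), each `"2'"` or `"3'"`.
#' @slot name canonical rendered name, e.g. `"2'3'-cUA"`, `"3'3'-c-di-GMP"`.
#' @export
setClass("CyclicDinucleotide",
         representation(bases = "character",
                        donors = "character",
                        name = "character"))

setValidity("CyclicDinucleotide", function(object) {
  if (length(object@bases) != 2L || !all(object@bases %in% CDN_BASES))
    return("bases must be two of A/C/G/U")
  if (length(object@donors) != 2L || !all(object@donors %in% CDN_DONORS))
    return("donors must be two of 2'/3'")
  canon <- .canonicalUnits(object@bases, object@donors)
  if (!identical(canon$bases, object@bases) ||
      !identical(canon$donors, object@donors))
    return("units not in canonical order; use CDN()")
  TRUE
})

setMethod("show", "CyclicDinucleotide", function(object) {
  f <- formulaOf(object)
  m <- cdnMasses(f)
  cat(object@name, "  c[", object@bases[1], "(", object@donors[1],
      ",5')p", object@bases[2], "(", object@donors[2], ",5')p]\n", sep = "")
  cat("  ", formulaToString(f),
      sprintf("  avg %.2f g/mol, mono %.4f Da\n", m["average"],
              m["monoisotopic"]), sep = "")
})

#' Observed biochemical screen readout
#'
#' A (possibly partial) record of what the nucleotide-product assays showed
#' for one enzyme: which alpha-32P NTPs labeled the product, whether the
#' product resisted CIP phosphatase, per-base label fate after nuclease P1 +
#' CIP digestion, observed ESI m/z values, and NTP-subset substrate
#' dependencies. Absent fields are unconstrained evidence, not negative
#' evidence. Construct with [ScreenObservation()].
#'
#' @slot labels character vector of bases (subset of A/C/G/U), or
#'   `NA_character_` when not assayed.
#' @slot cipResistant logical(1), `NA` when not assayed.
#' @slot p1Retention named character, values `"retained"`/`"lost"`,
#'   names are bases; possibly empty.
#' @slot observedMz data.frame with columns `mz`, `adduct`; possibly 0-row.
#' @slot substrateDependency list of character vectors (NTP base subsets
#'   that yielded product); possibly empty.
#' @export
setClass("ScreenObservation",
         representation(labels = "character",
                        cipResistant = "logical",
                        p1Retention = "character",
                        observedMz = "data.frame",
                        substrateDependency = "list"))

setValidity("ScreenObservation", function(object) {
  lab <- object@labels
  if (!all(is.na(lab)) && !all(lab %in% CDN_BASES))
    return("labels must be bases A/C/G/U")
  ret <- object@p1Retention
  if (length(ret)) {
    if (is.null(names(ret)) || !all(names(ret) %in% CDN_BASES))
      return("p1Retention must be named by base")
    if (!all(ret %in% c("retained", "lost")))
      return("p1Retention values must be 'retained' or 'lost'")
    if (!all(is.na(lab)) && !all(names(ret) %in% lab))
      return("P1 retention reported for a base not incorporated")
  }
  if (nrow(object@observedMz) &&
      !all(c("mz", "adduct") %in% names(object@observedMz)))
    return("observedMz needs columns mz, adduct")
  TRUE
})

setMethod("show", "ScreenObservation", function(object) {
  cat("ScreenObservation\n")
  cat("  labels incorporated:",
      if (all(is.na(object@labels))) "(not assayed)"
      else paste(object@labels, collapse = ","), "\n")
  cat("  CIP resistant:", object@cipResistant, "\n")
  if (length(object@p1Retention))
    cat("  P1+CIP label fate:",
        paste(names(object@p1Retention), object@p1Retention,
              sep = "=", collapse = ", "), "\n")
  if (nrow(object@observedMz))
    cat("  observed m/z:",
        paste(sprintf("%s %s", object@observedMz$mz, object@observedMz$adduct),
              collapse = "; "), "\n")
})

#' EMSA titration curve
#'
#' Fraction of probe bound as a function of total protein concentration,
#' for a single ligand x replicate. Concentrations are molar, strictly
#' positive and strictly increasing. Fraction-bound values outside [0, 1]
#' are kept as measured but flagged. Construct with [BindingCurve()].
#'
#' @slot ligandId ligand identifier.
#' @slot replicateId replicate identifier.
#' @slot concentrations numeric, molar protein concentrations.
#' @slot fractionBound numeric, shifted/total probe signal.
#' @slot clipped logical(1), TRUE when any fraction lies outside [0, 1].
#' @export
setClass("BindingCurve",
         representation(ligandId = "character",
                        replicateId = "character",
                        concentrations = "numeric",
                        fractionBound = "numeric",
                        clipped = "logical"))

setValidity("BindingCurve", function(object) {
  cc <- object@concentrations
  if (length(cc) != length(object@fractionBound))
    return("concentrations and fractionBound differ in length")
  if (any(cc <= 0)) return("concentrations must be strictly positive")
  if (is.unsorted(cc, strictly = TRUE))
    return("concentrations must be strictly increasing")
  TRUE
})

setMethod("show", "BindingCurve", function(object) {
  cat("BindingCurve ", object@ligandId, " / ", object@replicateId, ": ",
      length(object@concentrations), " points, [",
      format(min(object@concentrations)), ", ",
      format(max(object@concentrations)), "] M",
      if (object@clipped) " (contains out-of-range fractions)", "\n",
      sep = "")
})

#' Single-site isotherm fit result
#'
#' @slot kd fitted dissociation constant (M); `NA` when not converged.
#' @slot rss residual sum of squares at the optimum.
#' @slot converged logical(1).
#' @slot nPoints number of titration points used.
#' @slot diagnostic human-readable note (non-empty when not converged).
#' @export
setClass("IsothermFit",
         representation(kd = "numeric",
                        rss = "numeric",
                        converged = "logical",
                        nPoints = "integer",
                        diagnostic = "character"))

setMethod("show", "IsothermFit", function(object) {
  if (object@converged)
    cat(sprintf("IsothermFit: Kd = %.4g M (n = %d, RSS = %.3g)\n",
                object@kd, object@nPoints, object@rss))
  else
    cat("IsothermFit: not converged -", object@diagnostic, "\n")
})
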