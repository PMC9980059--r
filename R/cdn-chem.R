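# Cyclic dinucleotide chemistry: canonical naming, molecular formula,
# average/monoisotopic masses and ESI adduct m/z arithmetic.
#
# Free-acid nucleoside-5'-monophosphate formulas; a cyclic dinucleotide
# is NMP + NMP - 2 H2O regardless of linkage (linkage isomers are
# constitutional isomers with identical formulas).
NMP_FORMULAS <- list(
  A = c(C = 10L, H = 14L, N = 5L, O = 7L, P = 1L),
  G = c(C = 10L, H = 14L, N = 5L, O = 8L, P = 1L),
  C = c(C = 9L,  H = 14L, N = 3L, O = 8L, P = 1L),
  U = c(C = 9L,  H = 13L, N = 2L, O = 9L, P = 1L))

H2O <- c(C = 0L, H = 2L, N = 0L, O = 1L, P = 0L)

.atomicConstants <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- yaml::read_yaml(system.file("extdata",
                                            "atomic_constants.yaml",
                                            package = "cGLRscreen"))
    cache
  }
})

.formulaAdd <- function(a, b, sub = FALSE) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    x <- if (e %in% names(a)) a[[e]] else 0L
    y <- if (e %in% names(b)) b[[e]] else 0L
    as.integer(if (sub) x - y else x + y)
  }, integer(1))
  if (any(out < 0L)) stop("formula subtraction yields negative counts")
  out
}

#' Render a molecular formula as a Hill-order string
#'
#' @param formula named integer vector of element counts.
#' @return e.g. `"C19H23N7O14P2"` (zero-count elements omitted).
#' @export
formulaToString <- function(formula) {
  ord <- c("C", "H", setdiff(sort(names(formula)), c("C", "H")))
  parts <- vapply(ord, function(e) {
    n <- if (e %in% names(formula)) formula[[e]] else 0L
    if (n == 0L) "" else if (n == 1L) e else paste0(e, n)
  }, character(1))
  paste(parts, collapse = "")
}

# canonical unit order under cyclic symmetry: heterodimers order bases
# descending in A<C<G<U (the community naming order: the purine/larger
# base is named first, e.g. GMP-AMP, UMP-AMP); mixed-donor homodimers
# normalize to (2',3').
.canonicalUnits <- function(bases, donors) {
  base_rank <- match(bases, CDN_BASES)
  if (bases[1] == bases[2]) {
    donors <- sort(donors)         # "2'" < "3'"
  } else if (base_rank[1] < base_rank[2]) {
    bases <- rev(bases); donors <- rev(donors)
  }
  list(bases = bases, donors = donors)
}

.cdnName <- function(bases, donors) {
  link <- paste0(sub("'", "", donors[1]), "'",
                 sub("'", "", donors[2]), "'")
  core <- if (bases[1] == bases[2]) paste0("c-di-", bases[1], "MP")
  else if (bases[1] == "G" && bases[2] == "A") "cGAMP"
  else paste0("c", bases[1], bases[2])
  paste0(link, "-", core)
}

#' Construct a canonical cyclic dinucleotide
#'
#' Units may be given in either order; the object is canonicalized under
#' cyclic symmetry (heterodimers: bases in community naming order, e.g.
#' `cGAMP` = GMP then AMP, `cUA` = UMP then AMP; homodimers: donors
#' sorted so `2'3'` and `3'2'` coincide). The linkage label gives the
#' donor of the first-named base, then of the second, so
#' `"2'3'-cGAMP"` is c[G(2',5')pA(3',5')p].
#'
#' @param base1,base2 bases in `A`, `C`, `G`, `U`.
#' @param donor1,donor2 ribose donors, `"2'"` or `"3'"` (`"2"`/`"3"`
#'   accepted).
#' @return A [CyclicDinucleotide-class].
#' @examples
#' CDN("U", "2'", "A", "3'")   # 2'3'-cUA
#' @export
CDN <- function(base1, donor1, base2, donor2) {
  norm <- function(d) if (d %in% c("2", "3")) paste0(d, "'") else d
  canon <- .canonicalUnits(c(base1, base2),
                           c(norm(donor1), norm(donor2)))
  new("CyclicDinucleotide", bases = canon$bases, donors = canon$donors,
      name = .cdnName(canon$bases, canon$donors))
}

#' Parse a cyclic dinucleotide name
#'
#' Inverse of the canonical renderer: accepts `"2'3'-cUA"`,
#' `"3'3'-c-di-GMP"`, `"2'3'-cGAMP"` and the unicode-prime spellings.
#'
#' @param name name string.
#' @return A [CyclicDinucleotide-class].
#' @export
parseCdnName <- function(name) {
  x <- gsub("′", "'", name)
  m <- regmatches(x, regexec(
    "^([23])'([23])'-(?:c-di-([ACGU])MP|(cGAMP)|c([ACGU])([ACGU]))$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse CDN name: ", name)
  donors <- paste0(m[2:3], "'")
  bases <- if (m[4] != "") c(m[4], m[4])
  else if (m[5] == "cGAMP") c("G", "A")
  else c(m[6], m[7])
  CDN(bases[1], donors[1], bases[2], donors[2])
}

#' Enumerate all canonical cyclic dinucleotides over a base set
#'
#' Every unordered pair of (base, donor) units joined cyclically:
#' each heterodimer base pair has 4 linkage isomers (2'2', 2'3', 3'2',
#' 3'3'); each homodimer has 3 (2'3' and 3'2' coincide under cyclic
#' symmetry). All four bases give 6 x 4 + 4 x 3 = 36 candidates.
#'
#' @param bases nonempty subset of `c("A","C","G","U")`.
#' @return list of [CyclicDinucleotide-class], sorted by canonical name.
#' @export
enumerateCandidates <- function(bases = CDN_BASES) {
  stopifnot(length(bases) > 0, all(bases %in% CDN_BASES))
  bases <- unique(bases)
  combos <- expand.grid(b1 = bases, b2 = bases, d1 = CDN_DONORS,
                        d2 = CDN_DONORS, stringsAsFactors = FALSE)
  cands <- lapply(seq_len(nrow(combos)), function(i)
    CDN(combos$b1[i], combos$d1[i], combos$b2[i], combos$d2[i]))
  names(cands) <- vapply(cands, function(x) x@name, character(1))
  cands <- cands[!duplicated(names(cands))]
  cands[order(names(cands))]
}

#' @rdname formulaOf
#' @export
setMethod("formulaOf", "CyclicDinucleotide", function(x) {
  f <- .formulaAdd(NMP_FORMULAS[[x@bases[1]]], NMP_FORMULAS[[x@bases[2]]])
  .formulaAdd(f, .formulaAdd(H2O, H2O), sub = TRUE)
})

#' Average and monoisotopic mass of a molecular formula
#'
#' Average mass from standard atomic weights; monoisotopic mass from
#' principal-isotope masses. Constants are pinned in the shipped
#' `atomic_constants.yaml`.
#'
#' @param formula named integer vector of element counts.
#' @return named numeric: `average` (g/mol) and `monoisotopic` (Da).
#' @examples
#' cdnMasses(formulaOf(parseCdnName("2'3'-cUA")))  # avg 635.38
#' @export
cdnMasses <- function(formula) {
  const <- .atomicConstants()
  unknown <- setdiff(names(formula)[formula > 0],
                     names(const$average_weight))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  avg <- sum(vapply(names(formula), function(e)
    formula[[e]] * const$average_weight[[e]], numeric(1)))
  mono <- sum(vapply(names(formula), function(e)
    formula[[e]] * const$monoisotopic_mass[[e]], numeric(1)))
  c(average = avg, monoisotopic = mono)
}

.normAdduct <- function(adduct) {
  key <- toupper(gsub("[][() ]", "", adduct))
  if (key %in% c("M-H", "M-H-")) return("[M-H]-")
  if (key %in% c("M-2H+NA", "M-2H+NA-")) return("[M-2H+Na]-")
  if (key %in% c("M+H", "M+H+")) return("[M+H]+")
  stop("unsupported adduct: ", adduct)
}

#' ESI adduct m/z from a monoisotopic mass
#'
#' Supported adducts: `[M-H]-` (M minus a proton), `[M-2H+Na]-`
#' (M minus two protons plus a sodium cation) and `[M+H]+`. Returns the
#' exact m/z and, as an attribute, the nominal (round-half-away-from-
#' zero integer) value matching instrument summary reporting.
#'
#' @param monoisotopicMass Da.
#' @param adduct adduct name (bracketed or bare, e.g. `"M-H"`).
#' @return numeric m/z with attribute `nominal` (integer).
#' @examples
#' adductMz(635.0778, "[M-H]-")     # ~634.07, nominal 634
#' @export
adductMz <- function(monoisotopicMass, adduct) {
  const <- .atomicConstants()
  mp <- const$particle$proton
  mNa <- const$monoisotopic_mass$Na - const$particle$electron
  mz <- switch(.normAdduct(adduct),
               "[M-H]-" = monoisotopicMass - mp,
               "[M-2H+Na]-" = monoisotopicMass - 2 * mp + mNa,
               "[M+H]+" = monoisotopicMass + mp)
  structure(mz, nominal = as.integer(sign(mz) * floor(abs(mz) + 0.5)))
}

#' Match an observed m/z against candidate cyclic dinucleotides
#'
#' Keeps every candidate whose predicted adduct m/z lies within
#' `tolerance` of the observation. Linkage isomers of one base pair
#' share a formula and therefore always co-match.
#'
#' @param observedMz observed m/z value.
#' @param adduct adduct name (see [adductMz()]).
#' @param tolerance Da, > 0.
#' @param candidates list of [CyclicDinucleotide-class]
#'   (default: all 36 over the four bases).
#' @return named list of matching candidates (possibly empty).
#' @export
matchMass <- function(observedMz, adduct, tolerance = 0.5,
                      candidates = enumerateCandidates()) {
  stopifnot(tolerance > 0)
  keep <- vapply(candidates, function(cd) {
    mono <- cdnMasses(formulaOf(cd))[["monoisotopic"]]
    abs(as.numeric(adductMz(mono, adduct)) - observedMz) <= tolerance
  }, logical(1))
  candidates[keep]
}

#' Percent theoretical yield
#'
#' Isolated amount over starting amount, in percent; used to reproduce
#' synthesis bookkeeping (e.g. 519.16 umol isolated from a 5 mmol scale
#' is 10.38%).
#'
#' @param isolated,starting amounts in the same unit (mol).
#' @return percentage.
#' @export
percentYield <- function(isolated, starting) {
  stopifnot(starting > 0, isolated >= 0)
  100 * isolated / starting
}
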