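# Deconvolution of nucleotide second-messenger identity from the
# radiolabel / CIP / nuclease-P1 / mass screen.

#' @rdname predictSignature
#' @export
setMethod("predictSignature", "CyclicDinucleotide", function(x) {
  b <- x@bases; d <- x@donors
  # bond donated by unit i carries the alpha-phosphate of unit (3 - i);
  # a 2'-donor bond is P1-protected, a 3'-donor bond is cleaved and its
  # phosphate then removed by CIP.
  alpha_protected <- c(d[2] == "2'",   # unit 1's alpha-phosphate
                       d[1] == "2'")   # unit 2's alpha-phosphate
  labels <- sort(unique(b))
  retention <- vapply(labels, function(base) {
    if (any(alpha_protected[b == base])) "retained" else "lost"
  }, character(1))
  f <- formulaOf(x)
  mono <- cdnMasses(f)[["monoisotopic"]]
  list(labels = labels,
       cipResistant = TRUE,
       p1Retention = retention,
       formula = f,
       adductMz = c("[M-H]-" = as.numeric(adductMz(mono, "[M-H]-")),
                    "[M-2H+Na]-" = as.numeric(adductMz(mono,
                                                       "[M-2H+Na]-"))))
})

#' Construct a screen observation
#'
#' Any subset of the assay fields may be supplied; absent fields are
#' treated as unconstrained evidence by [inferProduct()].
#'
#' @param labels bases whose alpha-32P NTP labeled the product, or
#'   `NULL` when the labeling panel was not run.
#' @param cipResistant logical or `NA`.
#' @param p1Retention named character (base -> `"retained"`/`"lost"`)
#'   for the nuclease P1 + CIP double digest, or `NULL`.
#' @param observedMz data.frame with columns `mz`, `adduct`, or `NULL`.
#' @param substrateDependency list of character vectors: NTP base
#'   subsets that yielded product, or `NULL`.
#' @return A [ScreenObservation-class]. Reporting P1 retention for a
#'   base outside `labels` is an inconsistent observation and errors.
#' @examples
#' ScreenObservation(labels = c("A", "U"), cipResistant = TRUE,
#'                   p1Retention = c(A = "lost", U = "lost"))
#' @export
ScreenObservation <- function(labels = NULL, cipResistant = NA,
                              p1Retention = NULL, observedMz = NULL,
                              substrateDependency = NULL) {
  new("ScreenObservation",
      labels = if (is.null(labels)) NA_character_ else sort(unique(labels)),
      cipResistant = as.logical(cipResistant),
      p1Retention = if (is.null(p1Retention)) character(0)
                    else p1Retention,
      observedMz = if (is.null(observedMz))
        data.frame(mz = numeric(0), adduct = character(0))
      else observedMz,
      substrateDependency = if (is.null(substrateDependency)) list()
                            else substrateDependency)
}

# default mass tolerance: 0.5 Da for nominal (integer) observations,
# 0.02 Da for decimal observations.
.massTol <- function(mz, tol) {
  if (!is.null(tol)) return(tol)
  if (abs(mz - round(mz)) < .Machine$double.eps^0.5) 0.5 else 0.02
}

.sigConsistent <- function(sig, obs, tol = NULL) {
  if (!all(is.na(obs@labels)) &&
      !setequal(sig$labels, obs@labels)) return(FALSE)
  if (!is.na(obs@cipResistant) &&
      !identical(sig$cipResistant, obs@cipResistant)) return(FALSE)
  if (length(obs@p1Retention)) {
    for (base in names(obs@p1Retention)) {
      if (!base %in% names(sig$p1Retention)) return(FALSE)
      if (sig$p1Retention[[base]] != obs@p1Retention[[base]]) return(FALSE)
    }
  }
  if (nrow(obs@observedMz)) {
    for (i in seq_len(nrow(obs@observedMz))) {
      mz <- obs@observedMz$mz[i]
      pred <- as.numeric(adductMz(
        cdnMasses(sig$formula)[["monoisotopic"]],
        obs@observedMz$adduct[i]))
      if (abs(pred - mz) > .massTol(mz, tol)) return(FALSE)
    }
  }
  if (length(obs@substrateDependency)) {
    for (s in obs@substrateDependency)
      if (!all(sig$labels %in% s)) return(FALSE)
  }
  TRUE
}

#' Infer the cyclic dinucleotide product consistent with a screen
#' observation
#'
#' Filters candidates to those whose [predictSignature()] matches every
#' field provided in the observation; absent fields do not constrain.
#' An empty result is never silent: the return value carries a
#' `diagnostic` attribute naming the closest candidates (most observation
#' fields satisfied), and a message is emitted.
#'
#' @param obs a [ScreenObservation-class].
#' @param candidates list of [CyclicDinucleotide-class]; default all 36
#'   over the four bases.
#' @param tol mass tolerance in Da; `NULL` (default) selects 0.5 for
#'   integer-valued observed m/z and 0.02 otherwise.
#' @return Named list of consistent candidates.
#' @examples
#' obs <- ScreenObservation(labels = c("A", "U"),
#'                          p1Retention = c(A = "retained", U = "lost"))
#' names(inferProduct(obs))   # "2'3'-cUA"
#' @export
inferProduct <- function(obs, candidates = enumerateCandidates(),
                         tol = NULL) {
  stopifnot(is(obs, "ScreenObservation"), length(candidates) > 0)
  validObject(obs)
  sigs <- lapply(candidates, predictSignature)
  keep <- vapply(sigs, .sigConsistent, logical(1), obs = obs, tol = tol)
  out <- candidates[keep]
  if (length(out) == 0L) {
    nfield <- vapply(sigs, function(sig) {
      score <- 0L
      if (!all(is.na(obs@labels)) && setequal(sig$labels, obs@labels))
        score <- score + 1L
      if (!is.na(obs@cipResistant) &&
          identical(sig$cipResistant, obs@cipResistant))
        score <- score + 1L
      if (length(obs@p1Retention) &&
          all(names(obs@p1Retention) %in% names(sig$p1Retention)) &&
          all(sig$p1Retention[names(obs@p1Retention)] == obs@p1Retention))
        score <- score + 1L
      score
    }, integer(1))
    closest <- names(candidates)[nfield == max(nfield)]
    diag <- paste0("no candidate consistent with all fields; closest: ",
                   paste(utils::head(closest, 5), collapse = ", "))
    message(diag)
    attr(out, "diagnostic") <- diag
  }
  out
}

#' Which candidates can a given assay panel distinguish?
#'
#' Partitions candidates into groups with identical predicted
#' signatures when restricted to the chosen assays; groups of size > 1
#' are unresolvable by that panel. Under the full panel the only
#' degeneracy among the 36 four-base candidates is 2'2' vs 2'3'
#' homodimers, whose per-base retained/lost readout coincides.
#'
#' @param candidates list of [CyclicDinucleotide-class].
#' @param assays nonempty subset of
#'   `c("labels", "cip", "p1", "mass")`.
#' @return list of character vectors (candidate names), one per
#'   signature-equivalence class.
#' @export
distinguishabilityReport <- function(candidates = enumerateCandidates(),
                                     assays = c("labels", "cip", "p1",
                                                "mass")) {
  assays <- match.arg(assays, several.ok = TRUE)
  stopifnot(length(candidates) > 0)
  keys <- vapply(candidates, function(cd) {
    sig <- predictSignature(cd)
    parts <- character(0)
    if ("labels" %in% assays)
      parts <- c(parts, paste(sig$labels, collapse = ""))
    if ("cip" %in% assays)
      parts <- c(parts, as.character(sig$cipResistant))
    if ("p1" %in% assays)
      parts <- c(parts, paste(names(sig$p1Retention), sig$p1Retention,
                              sep = "=", collapse = ","))
    if ("mass" %in% assays)
      parts <- c(parts, formulaToString(sig$formula))
    paste(parts, collapse = "|")
  }, character(1))
  unname(split(names(candidates), keys))
}
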