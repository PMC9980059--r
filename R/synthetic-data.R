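# Seeded synthetic-data generators. Each generator is a pure function of
# its arguments: it seeds a private RNG stream and restores the caller's
# RNG state on exit, so the same configuration yields byte-identical
# output regardless of surrounding code.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

.randomResidues <- function(n, composition = NULL) {
  if (is.null(composition))
    sample(AA_STANDARD, n, replace = TRUE)
  else
    sample(names(composition), n, replace = TRUE, prob = composition)
}

# draw one concrete instance of a pattern: residues for anchors, lengths
# for spacers; returns the instance string and 0-based anchor offsets
# within it.
.sampleInstance <- function(pattern, composition = NULL) {
  chars <- character(0)
  anchor_off <- integer(0)
  for (e in pattern@elements) {
    if (e$kind == "gap") {
      g <- if (e$max > e$min) sample(e$min:e$max, 1L) else e$min
      if (g > 0L) chars <- c(chars, .randomResidues(g, composition))
    } else {
      anchor_off <- c(anchor_off, length(chars))
      chars <- c(chars,
                 if (e$kind == "fixed") e$residue
                 else sample(e$members, 1L))
    }
  }
  list(text = paste(chars, collapse = ""), anchors = anchor_off)
}

#' Generate a labeled synthetic proteome for motif-scanner testing
#'
#' Positives embed exactly one concrete instance of the pattern (spacer
#' lengths drawn uniformly within bounds) at a recorded offset inside
#' random background; negatives are random sequences rejection-sampled
#' until provably pattern-free. The truth table records the planted
#' anchor spans (0-based half-open), giving exact
#' sensitivity/specificity ground truth.
#'
#' @param nPos,nNeg numbers of positive and decoy sequences (>= 0).
#' @param pattern a [MotifPattern-class].
#' @param lengthRange integer(2), sequence length bounds; must
#'   accommodate the longest pattern instance.
#' @param seed integer seed.
#' @param composition optional named residue-frequency vector for the
#'   background (default uniform over the 20 standard residues).
#' @return list with `sequences` (named `AAStringSet`) and `truth`
#'   (data.frame `sequence_id`, `label` ("pos"/"neg"), `start`, `end`,
#'   `anchor_spans` — semicolon-joined `start-end` pairs, NA for
#'   negatives).
#' @export
genMotifProteome <- function(nPos, nNeg, pattern,
                             lengthRange = c(250L, 450L), seed = 1L,
                             composition = NULL) {
  stopifnot(nPos >= 0, nNeg >= 0, length(lengthRange) == 2L)
  max_instance <- sum(vapply(pattern@elements, function(e)
    if (e$kind == "gap") e$max else 1L, integer(1)))
  min_instance <- sum(vapply(pattern@elements, function(e)
    if (e$kind == "gap") e$min else 1L, integer(1)))
  if (min_instance > lengthRange[2])
    stop("pattern unsatisfiable within lengthRange")
  .withSeed(seed, {
    seqs <- character(0); ids <- character(0)
    truth <- list()
    for (i in seq_len(nPos)) {
      repeat {
        inst <- .sampleInstance(pattern, composition)
        m <- nchar(inst$text)
        if (m <= lengthRange[2]) break
      }
      L <- sample(max(lengthRange[1], nchar(inst$text)):lengthRange[2], 1L)
      off <- sample(0:(L - m), 1L)
      seq <- paste0(
        paste(.randomResidues(off, composition), collapse = ""),
        inst$text,
        paste(.randomResidues(L - off - m, composition), collapse = ""))
      id <- sprintf("POS%04d", i)
      ids <- c(ids, id); seqs <- c(seqs, seq)
      a <- inst$anchors + off
      truth[[length(truth) + 1L]] <- data.frame(
        sequence_id = id, label = "pos",
        start = a[1L], end = a[length(a)] + 1L,
        anchor_spans = paste(sprintf("%d-%d", a, a + 1L),
                             collapse = ";"),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nNeg)) {
      tries <- 0L
      repeat {
        L <- sample(lengthRange[1]:lengthRange[2], 1L)
        seq <- paste(.randomResidues(L, composition), collapse = "")
        if (nrow(scanMotif(seq, pattern, mode = "first")) == 0L) break
        tries <- tries + 1L
        if (tries > 1000L) stop("cannot sample a pattern-free decoy")
      }
      id <- sprintf("NEG%04d", i)
      ids <- c(ids, id); seqs <- c(seqs, seq)
      truth[[length(truth) + 1L]] <- data.frame(
        sequence_id = id, label = "neg", start = NA_integer_,
        end = NA_integer_, anchor_spans = NA_character_,
        stringsAsFactors = FALSE)
    }
    sset <- Biostrings::AAStringSet(seqs)
    names(sset) <- ids
    list(sequences = sset, truth = do.call(rbind, truth))
  })
}

#' Generate a screen observation from a known product
#'
#' Restricts the predicted signature of `cdn` to the requested fields —
#' the forward model of the assay panel, used to test inference
#' round-trips.
#'
#' @param cdn a [CyclicDinucleotide-class].
#' @param fields subset of `c("labels", "cip", "p1", "mass")`.
#' @param seed integer seed (used only when `massJitterSd > 0`).
#' @param massJitterSd Gaussian jitter (Da) added to the observed m/z.
#' @return A [ScreenObservation-class].
#' @export
genScreenObservation <- function(cdn,
                                 fields = c("labels", "cip", "p1",
                                            "mass"),
                                 seed = 1L, massJitterSd = 0) {
  if (length(fields))    # empty = fully unconstrained observation
    fields <- match.arg(fields, several.ok = TRUE)
  sig <- predictSignature(cdn)
  mzdf <- NULL
  if ("mass" %in% fields) {
    mz <- sig$adductMz[["[M-H]-"]]
    if (massJitterSd > 0)
      mz <- .withSeed(seed, mz + stats::rnorm(1, 0, massJitterSd))
    mzdf <- data.frame(mz = mz, adduct = "[M-H]-")
  }
  ScreenObservation(
    labels = if ("labels" %in% fields) sig$labels else NULL,
    cipResistant = if ("cip" %in% fields) sig$cipResistant else NA,
    p1Retention = if ("p1" %in% fields) sig$p1Retention else NULL,
    observedMz = mzdf)
}

#' Generate a noisy EMSA titration from a known Kd
#'
#' `fraction = c / (c + Kd) + N(0, noiseSd)`, truncated to [0, 1].
#' Whether any draw fell outside [0, 1] before truncation is reported
#' in the `truncated` attribute of the returned curve.
#'
#' @param kd true dissociation constant (M), > 0.
#' @param concentrations strictly increasing molar concentrations.
#' @param noiseSd Gaussian noise standard deviation, >= 0.
#' @param seed integer seed.
#' @param ligandId,replicateId identifiers for the curve.
#' @return A [BindingCurve-class] with attribute `truncated` (logical:
#'   any value fell outside [0, 1] before truncation).
#' @export
genBindingCurve <- function(kd, concentrations, noiseSd = 0, seed = 1L,
                            ligandId = "synthetic", replicateId = "1") {
  stopifnot(kd > 0, noiseSd >= 0)
  fb <- fractionBound(concentrations, kd)
  if (noiseSd > 0)
    fb <- .withSeed(seed, fb + stats::rnorm(length(fb), 0, noiseSd))
  truncated <- any(fb < 0 | fb > 1)
  fb <- pmin(pmax(fb, 0), 1)
  curve <- BindingCurve(ligandId, concentrations, fb, replicateId)
  attr(curve, "truncated") <- truncated
  curve
}

#' Generate an annotation table with known census truth
#'
#' Draws a copy-number pair per species from a given distribution and an
#' architecture per cGLR record from a mixture, then records the exact
#' realized counts and percentages as ground truth for the census
#' summaries.
#'
#' @param nSpecies number of species in the roster.
#' @param copyNumberDist data.frame with columns `n_cGLR`, `n_STING`,
#'   `prob` (probabilities summing to 1).
#' @param architectureMixture named numeric of architecture
#'   probabilities for cGLR records (summing to 1).
#' @param seed integer seed.
#' @return list with `records` (data.frame `protein_id`, `species`,
#'   `phylum`, `family`, `architecture`), `roster` (character), and
#'   `truth` (list: `per_species` counts and `architecture_percentage`
#'   of the realized draw).
#' @export
genCensusTable <- function(nSpecies, copyNumberDist,
                           architectureMixture = c(cGLR = 1), seed = 1L) {
  stopifnot(all(c("n_cGLR", "n_STING", "prob") %in%
                  names(copyNumberDist)),
            abs(sum(copyNumberDist$prob) - 1) < 1e-8,
            abs(sum(architectureMixture) - 1) < 1e-8)
  .withSeed(seed, {
    roster <- sprintf("species_%03d", seq_len(nSpecies))
    rows <- sample(nrow(copyNumberDist), nSpecies, replace = TRUE,
                   prob = copyNumberDist$prob)
    records <- list()
    for (i in seq_len(nSpecies)) {
      ncg <- copyNumberDist$n_cGLR[rows[i]]
      nst <- copyNumberDist$n_STING[rows[i]]
      if (ncg > 0) {
        arch <- sample(names(architectureMixture), ncg, replace = TRUE,
                       prob = architectureMixture)
        records[[length(records) + 1L]] <- data.frame(
          protein_id = sprintf("%s_cGLR%d", roster[i], seq_len(ncg)),
          species = roster[i], phylum = "synthetic", family = "cGLR",
          architecture = arch, stringsAsFactors = FALSE)
      }
      if (nst > 0)
        records[[length(records) + 1L]] <- data.frame(
          protein_id = sprintf("%s_STING%d", roster[i], seq_len(nst)),
          species = roster[i], phylum = "synthetic", family = "STING",
          architecture = "TM+CBD", stringsAsFactors = FALSE)
    }
    records <- if (length(records)) do.call(rbind, records)
    else data.frame(protein_id = character(0), species = character(0),
                    phylum = character(0), family = character(0),
                    architecture = character(0))
    per_species <- data.frame(
      species = roster,
      n_cGLR = copyNumberDist$n_cGLR[rows],
      n_STING = copyNumberDist$n_STING[rows],
      stringsAsFactors = FALSE)
    cg <- records$architecture[records$family == "cGLR"]
    arch_pct <- if (length(cg))
      100 * table(cg) / length(cg) else table(character(0))
    list(records = records, roster = roster,
         truth = list(per_species = per_species,
                      architecture_percentage = arch_pct))
  })
}
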