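#' Default residue classes for the motif mini-language
#'
#' The hydrophobic class `h` used throughout cGLR active-site curation.
#' The membership (A, C, F, I, L, M, V, W, Y) is the standard
#' Kyte-Doolittle-positive set; override by passing your own named list
#' of character vectors to [parsePattern()].
#'
#' @return Named list of character vectors.
#' @export
defaultResidueClasses <- function() {
  list(h = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"))
}

#' Parse a degenerate motif string
#'
#' Tokens, read left to right (whitespace ignored):
#' \itemize{
#'   \item a bare uppercase letter: fixed residue (unless declared as a
#'     class label in `classes`);
#'   \item `[ABC]` or `[A/B]`: inline residue class;
#'   \item a declared class letter, e.g. `h`: named residue class;
#'   \item `[Xm-n]` or `Xm-n`: spacer of m..n arbitrary residues
#'     (inclusive bounds, counted strictly between the flanking anchors).
#' }
#' Adjacent spacers are merged by summing their bounds. The result
#' round-trips through [patternToString()].
#'
#' @param text motif string, e.g. `"h[QT]GS[X8-20][DE]h[DE]h[X50-90]h[DE]h"`.
#' @param classes named list mapping class labels to residue sets.
#' @param name pattern name carried into match reports.
#' @return A [MotifPattern-class].
#' @examples
#' parsePattern("G[SG]", name = "activation_loop")
#' @export
parsePattern <- function(text, classes = defaultResidueClasses(),
                         name = "pattern") {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("–", "-", text)       # accept en-dash in spacer bounds
  txt <- gsub("\\s+", "", txt)
  chars <- strsplit(txt, "")[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  push <- function(e) elements[[length(elements) + 1L]] <<- e
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated '[' in pattern: ", text)
      content <- if (j == i + 1L) "" else
        paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (content == "") stop("empty residue class '[]' in pattern")
      gap <- regmatches(content, regexec("^X([0-9]+)-([0-9]+)$", content))[[1]]
      if (length(gap) == 3L) {
        push(list(kind = "gap",
                  min = as.integer(gap[2]), max = as.integer(gap[3])))
      } else {
        members <- setdiff(strsplit(content, "")[[1]], "/")
        if (length(members) == 0L)
          stop("empty residue class '[", content, "]'")
        if (!all(members %in% AA_STANDARD))
          stop("unknown residue in class '[", content, "]'")
        members <- sort(unique(members))   # canonical member order
        push(list(kind = "class", label = paste(members, collapse = ""),
                  members = members))
      }
      i <- j + 1L
    } else if (ch == "X" && i < n && grepl("[0-9]", chars[i + 1L])) {
      rest <- paste(chars[i:n], collapse = "")
      gap <- regmatches(rest, regexec("^X([0-9]+)-([0-9]+)", rest))[[1]]
      if (length(gap) != 3L) stop("malformed spacer at '", rest, "'")
      push(list(kind = "gap",
                min = as.integer(gap[2]), max = as.integer(gap[3])))
      i <- i + nchar(gap[1])
    } else if (ch %in% names(classes)) {
      members <- unique(classes[[ch]])
      if (length(members) == 0L) stop("class '", ch, "' is empty")
      push(list(kind = "class", label = ch, members = members))
      i <- i + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      if (!ch %in% AA_STANDARD)
        stop("unknown token '", ch, "' in pattern: ", text)
      push(list(kind = "fixed", residue = ch))
      i <- i + 1L
    } else {
      stop("unknown token '", ch, "' in pattern: ", text)
    }
  }
  # merge adjacent gaps by summing bounds
  merged <- list()
  for (e in elements) {
    k <- length(merged)
    if (e$kind == "gap" && k > 0L && merged[[k]]$kind == "gap") {
      merged[[k]]$min <- merged[[k]]$min + e$min
      merged[[k]]$max <- merged[[k]]$max + e$max
    } else merged[[length(merged) + 1L]] <- e
  }
  for (e in merged)
    if (e$kind == "gap" && e$min > e$max)
      stop("spacer with min > max: X", e$min, "-", e$max)
  new("MotifPattern", name = name, elements = merged, classes = classes)
}

#' Canonical text rendering of a motif pattern
#'
#' Inverse of [parsePattern()]: named classes render as their label,
#' inline classes as `[...]`, spacers as `[Xm-n]`.
#'
#' @param pattern a [MotifPattern-class].
#' @return A single string; `parsePattern(patternToString(p), p@classes)`
#'   reproduces `p`'s elements.
#' @export
patternToString <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  paste(vapply(pattern@elements, function(e) {
    switch(e$kind,
           fixed = e$residue,
           gap = sprintf("[X%d-%d]", e$min, e$max),
           class = {
             lab <- e$label
             if (lab %in% names(pattern@classes) &&
                 setequal(pattern@classes[[lab]], e$members)) lab
             else paste0("[", paste(sort(e$members), collapse = ""), "]")
           })
  }, character(1)), collapse = "")
}

# anchors/gap-bounds view of a pattern: anchors are the non-gap elements,
# gaps[i] bounds the residue count between anchor i and anchor i+1.
.patternLayout <- function(pattern) {
  el <- pattern@elements
  kinds <- vapply(el, `[[`, character(1), "kind")
  anchor_idx <- which(kinds != "gap")
  anchors <- lapply(el[anchor_idx], function(e)
    if (e$kind == "fixed") e$residue else e$members)
  k <- length(anchor_idx)
  gmin <- integer(max(k - 1L, 0L)); gmax <- integer(max(k - 1L, 0L))
  if (k > 1L) for (i in seq_len(k - 1L)) {
    if (anchor_idx[i + 1L] - anchor_idx[i] > 1L) {
      between <- el[[anchor_idx[i] + 1L]]   # at most one gap (merged)
      gmin[i] <- between$min; gmax[i] <- between$max
    }
  }
  lead <- if (anchor_idx[1L] > 1L) el[[1L]] else NULL
  trail <- if (anchor_idx[k] < length(el)) el[[length(el)]] else NULL
  list(anchors = anchors, gmin = gmin, gmax = gmax,
       lead = lead, trail = trail)
}

.scanOne <- function(seqchars, pattern) {
  lay <- .patternLayout(pattern)
  k <- length(lay$anchors)
  n <- length(seqchars)
  # ok[[i]][p] : does position p satisfy anchor i
  ok <- lapply(lay$anchors, function(allowed) seqchars %in% allowed)
  placements <- list()
  lead_min <- if (is.null(lay$lead)) 0L else lay$lead$min
  trail_min <- if (is.null(lay$trail)) 0L else lay$trail$min
  dfs <- function(i, positions) {
    if (i > k) {
      if (n - positions[k] >= trail_min)
        placements[[length(placements) + 1L]] <<- positions
      return(invisible())
    }
    if (i == 1L) {
      for (p in seq_len(n)) {
        if (ok[[1L]][p] && p - 1L >= lead_min) dfs(2L, p)
      }
    } else {
      lo <- positions[i - 1L] + 1L + lay$gmin[i - 1L]
      hi <- positions[i - 1L] + 1L + lay$gmax[i - 1L]
      hi <- min(hi, n)
      if (lo <= hi) for (p in lo:hi) {
        if (ok[[i]][p]) dfs(i + 1L, c(positions, p))
      }
    }
    invisible()
  }
  if (n >= k && k > 0L) dfs(1L, integer(0))
  if (length(placements) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      anchors = I(list())))
  # order: full-span start, then lexicographic anchor starts
  key <- vapply(placements, function(p)
    paste(sprintf("%09d", p), collapse = ""), character(1))
  placements <- placements[order(key)]
  anchors <- lapply(placements, function(p) {
    m <- cbind(start = p - 1L, end = p)   # 0-based half-open, width 1
    m
  })
  data.frame(start = vapply(placements, function(p) p[1L] - 1L, integer(1)),
             end = vapply(placements, function(p) p[length(p)], integer(1)),
             anchors = I(anchors))
}

#' @rdname scanMotif
#' @export
setMethod("scanMotif", "character", function(subject, pattern,
                                             mode = c("all", "first"), ...) {
  mode <- match.arg(mode)
  stopifnot(is(pattern, "MotifPattern"), length(subject) == 1L,
            nchar(subject) > 0L)
  res <- .scanOne(strsplit(subject, "")[[1]], pattern)
  if (mode == "first" && nrow(res) > 0L) res <- res[1L, , drop = FALSE]
  res
})

#' @rdname scanMotif
#' @export
setMethod("scanMotif", "AAString", function(subject, pattern,
                                            mode = c("all", "first"), ...) {
  scanMotif(as.character(subject), pattern, mode = mode)
})

#' @rdname scanMotif
#' @export
setMethod("scanMotif", "AAStringSet", function(subject, pattern,
                                               mode = c("all", "first"),
                                               ...) {
  mode <- match.arg(mode)
  ids <- names(subject)
  if (is.null(ids)) ids <- as.character(seq_along(subject))
  out <- lapply(seq_along(subject), function(i) {
    m <- scanMotif(as.character(subject[[i]]), pattern, mode = mode)
    if (nrow(m)) cbind(sequence_id = ids[i], m,
                       stringsAsFactors = FALSE)
    else cbind(sequence_id = character(0), m)
  })
  do.call(rbind, out)
})

#' Curate candidate cGLR records by the three-criterion rule
#'
#' A record is retained iff (1) its sequence contains at least one
#' active-site motif match plus a G[S/G] activation-loop match and an
#' acidic catalytic-triad match, (2) the externally supplied
#' NTase-core/helix-bundle homology flag is TRUE, and (3) the externally
#' supplied predicted-structural-homology flag is TRUE. Criteria (2) and
#' (3) come from out-of-scope alignment and structure tools and are
#' consumed as booleans, never computed here. Exclusions list every
#' failed criterion.
#'
#' @param records data.frame with columns `sequence_id`, `species`,
#'   `sequence`, `ntase_helix_bundle_homology`, `structural_homology`.
#'   Missing (NA) flags are an error naming the record: there is no
#'   silent default.
#' @param patterns named list of [MotifPattern-class] with entries
#'   `active_site`, `activation_loop`, `catalytic_triad` (see
#'   [readPatternConfig()]); defaults to the shipped configuration.
#' @param motifCriteria `"all"` requires all three motif patterns;
#'   `"active_site_only"` relaxes the loop/triad to the single
#'   active-site criterion (they are contained in it for most spacer
#'   lengths).
#' @return data.frame with columns `sequence_id`, `species`, `decision`
#'   (`"retained"`/`"excluded"`), `reasons` (semicolon-joined, empty when
#'   retained) and list column `matches` (active-site matches per record).
#' @export
curateRecords <- function(records,
                          patterns = readPatternConfig(),
                          motifCriteria = c("all", "active_site_only")) {
  motifCriteria <- match.arg(motifCriteria)
  need <- c("sequence_id", "species", "sequence",
            "ntase_helix_bundle_homology", "structural_homology")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records table lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(c("active_site", "activation_loop", "catalytic_triad")
                %in% names(patterns)))
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    for (fl in c("ntase_helix_bundle_homology", "structural_homology"))
      if (is.na(r[[fl]]))
        stop("record '", r$sequence_id, "' is missing external flag '",
             fl, "'")
    m_act <- scanMotif(r$sequence, patterns$active_site)
    reasons <- character(0)
    if (nrow(m_act) == 0L) reasons <- c(reasons, "active-site motif absent")
    if (motifCriteria == "all") {
      if (nrow(scanMotif(r$sequence, patterns$activation_loop,
                         mode = "first")) == 0L)
        reasons <- c(reasons, "activation loop absent")
      if (nrow(scanMotif(r$sequence, patterns$catalytic_triad,
                         mode = "first")) == 0L)
        reasons <- c(reasons, "catalytic triad absent")
    }
    if (!isTRUE(as.logical(r$ntase_helix_bundle_homology)))
      reasons <- c(reasons, "no NTase-core/helix-bundle homology")
    if (!isTRUE(as.logical(r$structural_homology)))
      reasons <- c(reasons, "no predicted structural homology")
    data.frame(sequence_id = r$sequence_id, species = r$species,
               decision = if (length(reasons)) "excluded" else "retained",
               reasons = paste(reasons, collapse = "; "),
               matches = I(list(m_act)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# global alignment identity and mutual coverage between two sequences.
# identity = exact matches / alignment columns; unit match, zero mismatch,
# affine gaps (open 5, extend 1). Coverage of a global alignment is the
# fraction of the longer sequence covered by the shorter: min(L)/max(L).
.alnIdentity <- function(s1, s2, gapOpening = 5, gapExtension = 1) {
  letters <- unique(c(strsplit(s1, "")[[1]], strsplit(s2, "")[[1]]))
  sub <- diag(1, length(letters))
  dimnames(sub) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(
    s1, s2, type = "global", substitutionMatrix = sub,
    gapOpening = gapOpening, gapExtension = gapExtension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(pa)
  matches <- sum(pa == sa & pa != "-")
  c(identity = matches / cols,
    coverage = min(nchar(s1), nchar(s2)) / max(nchar(s1), nchar(s2)))
}

#' Greedy centroid redundancy removal
#'
#' Deterministic re-implementation of the redundancy-removal step used
#' before tree construction: sequences are visited in order of
#' decreasing length (ties broken by ascending id); each joins the first
#' existing cluster whose representative it matches at or above both
#' thresholds, otherwise it founds a new cluster. Identity is exact
#' matches over alignment columns of a global alignment with unit match
#' score, zero mismatch and affine gap penalties (open 5, extend 1);
#' mutual coverage is min length / max length.
#'
#' @param sequences named character vector (names = ids) or
#'   `AAStringSet`.
#' @param minIdentity,minCoverage thresholds in (0, 1]; the curation
#'   defaults are 0.95 and 1.
#' @return data.frame with columns `cluster_id`, `representative_id`,
#'   `member_id`; zero rows for empty input.
#' @export
dedupeCluster <- function(sequences, minIdentity = 0.95, minCoverage = 1.0) {
  stopifnot(minIdentity > 0, minIdentity <= 1,
            minCoverage > 0, minCoverage <= 1)
  if (is(sequences, "XStringSet")) {
    ids <- names(sequences)
    seqs <- as.character(sequences)
  } else {
    ids <- names(sequences)
    seqs <- unname(sequences)
  }
  if (length(seqs) == 0L)
    return(data.frame(cluster_id = integer(0),
                      representative_id = character(0),
                      member_id = character(0)))
  if (is.null(ids)) stop("sequences must be named by id")
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  rep_ids <- character(0); rep_seqs <- character(0)
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (j in seq_along(rep_seqs)) {
      st <- .alnIdentity(seqs[i], rep_seqs[j])
      if (st["identity"] >= minIdentity && st["coverage"] >= minCoverage) {
        assignment[i] <- j; placed <- TRUE; break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, ids[i]); rep_seqs <- c(rep_seqs, seqs[i])
      assignment[i] <- length(rep_ids)
    }
  }
  data.frame(cluster_id = assignment,
             representative_id = rep_ids[assignment],
             member_id = ids,
             stringsAsFactors = FALSE)[order(assignment), ]
}
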