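# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation: exhaustive
# enumeration of spacer-length combinations with positional character
# checks (vs the scanner's anchor DFS), a dense pH grid search (vs
# bisection), and multiset-based dedup of cyclic arrangements (vs
# canonical naming).

# ---- motif scanning oracle ------------------------------------------

# allowed residue set per non-gap element, and spacer bounds between
# consecutive anchors, read off the parsed pattern object
.oracleLayout <- function(pattern) {
  el <- pattern@elements
  kinds <- vapply(el, `[[`, character(1), "kind")
  idx <- which(kinds != "gap")
  allowed <- lapply(el[idx], function(e)
    if (e$kind == "fixed") e$residue else e$members)
  k <- length(idx)
  gaps <- vector("list", max(k - 1, 0))
  if (k > 1) for (i in seq_len(k - 1)) {
    gaps[[i]] <- if (idx[i + 1] - idx[i] > 1)
      el[[idx[i] + 1]]$min:el[[idx[i] + 1]]$max else 0L
  }
  list(allowed = allowed, gaps = gaps)
}

# every anchor placement, by brute force over all spacer-length
# combinations and all start positions; returns a sorted matrix of
# 0-based anchor start positions (one row per placement)
oracleScan <- function(sequence, pattern) {
  lay <- .oracleLayout(pattern)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  k <- length(lay$allowed)
  combos <- if (k > 1) expand.grid(lay$gaps) else
    data.frame(row.names = 1)
  hits <- list()
  for (ci in seq_len(nrow(combos))) {
    gl <- if (k > 1) as.integer(combos[ci, ]) else integer(0)
    offsets <- cumsum(c(0L, gl + 1L))     # anchor offsets within combo
    width <- offsets[k] + 1L
    for (s in seq_len(n - width + 1L)) {
      pos <- s + offsets                  # 1-based anchor positions
      if (all(mapply(function(p, a) chars[p] %in% a, pos,
                     lay$allowed)))
        hits[[length(hits) + 1L]] <- pos - 1L
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = k))
  m <- unique(do.call(rbind, hits))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# anchor-start matrix from scanMotif output, for comparison
anchorStarts <- function(matches) {
  if (nrow(matches) == 0L)
    return(matrix(integer(0), ncol = 0))
  do.call(rbind, lapply(matches$anchors, function(a) a[, "start"]))
}

# random (pattern, sequence) pair with bounded spacer-combination count,
# over a reduced alphabet so matches actually occur
randomScanCase <- function() {
  alphabet <- c("A", "C", "D", "G", "S")
  k <- sample(2:4, 1)
  mk_anchor <- function() {
    if (runif(1) < 0.5) sample(alphabet, 1)
    else paste0("[", paste(sample(alphabet, sample(2:3, 1)),
                           collapse = ""), "]")
  }
  parts <- mk_anchor()
  for (i in seq_len(k - 1)) {
    if (runif(1) < 0.7) {
      lo <- sample(0:2, 1); hi <- lo + sample(0:2, 1)
      parts <- c(parts, sprintf("[X%d-%d]", lo, hi))
    }
    parts <- c(parts, mk_anchor())
  }
  seqlen <- sample(60:120, 1)
  list(pattern = parsePattern(paste(parts, collapse = "")),
       sequence = paste(sample(alphabet, seqlen, replace = TRUE),
                        collapse = ""))
}

# ---- isoelectric point oracle ---------------------------------------

# dense grid search for the zero-charge pH
gridPI <- function(sequence, table = readPkaTable(), step = 0.01) {
  grid <- seq(0, 14, by = step)
  grid[which.min(abs(netCharge(sequence, grid, table)))]
}

randomProtein <- function(len = sample(30:120, 1)) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# ---- cyclic dinucleotide oracles ------------------------------------

# distinct cyclic dimers as unordered multisets of (base, donor) units
bruteCdnCount <- function(bases) {
  combos <- expand.grid(b1 = bases, b2 = bases, d1 = c("2'", "3'"),
                        d2 = c("2'", "3'"), stringsAsFactors = FALSE)
  keys <- apply(combos, 1, function(r) {
    units <- sort(c(paste0(r[["b1"]], r[["d1"]]),
                    paste0(r[["b2"]], r[["d2"]])))
    paste(units, collapse = "|")
  })
  length(unique(keys))
}

# free-acid NMP composition sums, written out independently
oracleCdnFormula <- function(base1, base2) {
  nmp <- list(A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
              G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
              C = c(C = 9, H = 14, N = 3, O = 8, P = 1),
              U = c(C = 9, H = 13, N = 2, O = 9, P = 1))
  f <- nmp[[base1]] + nmp[[base2]]
  f["H"] <- f["H"] - 4     # minus 2 H2O
  f["O"] <- f["O"] - 2
  f
}
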