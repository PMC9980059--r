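test_that("the active-site motif string parses into the expected element structure", {
  p <- parsePattern("h[QT]GS[X8-20][DE]h[DE]h[X50-90]h[DE]h",
                    name = "active_site")
  kinds <- vapply(p@elements, `[[`, character(1), "kind")
  expect_length(kinds, 13L)
  expect_identical(kinds,
                   c("class", "class", "fixed", "fixed", "gap", "class",
                     "class", "class", "class", "gap", "class", "class",
                     "class"))
  expect_identical(p@elements[[3]]$residue, "G")
  expect_setequal(p@elements[[2]]$members, c("Q", "T"))
  expect_identical(p@elements[[5]][c("min", "max")],
                   list(min = 8L, max = 20L))
  # unicode en-dash spacer notation and whitespace are accepted
  p2 <- parsePattern("h[QT]GS X8–20 [DE]h[DE]h X50–90 h[DE]h")
  expect_identical(patternToString(p2), patternToString(p))
})

test_that("two-token patterns, slash classes and gap merging parse correctly", {
  p <- parsePattern("G[SG]")
  expect_length(p@elements, 2L)
  expect_identical(p@elements[[1]]$kind, "fixed")
  expect_setequal(p@elements[[2]]$members, c("S", "G"))
  # [E/D] slash notation
  p2 <- parsePattern("[E/D]h[E/D]")
  expect_setequal(p2@elements[[1]]$members, c("E", "D"))
  # adjacent spacers merge by summing bounds
  p3 <- parsePattern("A[X1-2][X3-4]C")
  expect_length(p3@elements, 3L)
  expect_identical(p3@elements[[2]][c("min", "max")],
                   list(min = 4L, max = 6L))
})

test_that("malformed patterns are rejected", {
  expect_error(parsePattern("[X3-2]"), "min > max")
  expect_error(parsePattern("A[]C"), "empty")
  expect_error(parsePattern("a"), "unknown token")
  expect_error(parsePattern("AXC"), "unknown token")  # bare X is not a residue
  expect_error(parsePattern("[X1-2][X2-3]"), "non-gap")
})

test_that("patterns round-trip through their canonical text rendering", {
  for (txt in c("h[QT]GS[X8-20][DE]h[DE]h[X50-90]h[DE]h", "G[SG]",
                "[ED]h[ED][X50-90][ED]", "A[X0-3]h")) {
    p <- parsePattern(txt)
    p2 <- parsePattern(patternToString(p))
    expect_identical(p2@elements, p@elements, label = txt)
  }
})

test_that("scanner reports every distinct anchor placement with 0-based half-open spans", {
  m <- scanMotif("AGSGSA", parsePattern("GS"))
  expect_identical(m$start, c(1L, 3L))
  expect_identical(m$end, c(3L, 5L))
  m2 <- scanMotif("AGCAGGC", parsePattern("A[X1-2]C"))
  expect_identical(m2$start, c(0L, 3L))
  expect_identical(m2$end, c(3L, 7L))
  expect_identical(m2$anchors[[2]][, "start"], c(3L, 6L))
  # mode = "first" keeps only the leftmost placement
  expect_identical(nrow(scanMotif("AGSGSA", parsePattern("GS"),
                                  mode = "first")), 1L)
  # no match is an empty result, not an error
  expect_identical(nrow(scanMotif("AAAA", parsePattern("GS"))), 0L)
})

test_that("non-standard residues never satisfy anchors but do fill spacers", {
  p <- parsePattern("A[X1-1]C")
  expect_identical(scanMotif("AXC", p)$start, 0L)
  expect_identical(scanMotif("AZC", p)$start, 0L)
  # non-standard letters cannot satisfy fixed or class anchors
  expect_identical(nrow(scanMotif("XXX", parsePattern("h"))), 0L)
  expect_identical(nrow(scanMotif("XX", parsePattern("C"))), 0L)
})

test_that("scanner agrees with the exhaustive spacer-enumeration oracle", {
  set.seed(101)
  for (i in 1:40) {
    case <- randomScanCase()
    got <- anchorStarts(scanMotif(case$sequence, case$pattern))
    want <- oracleScan(case$sequence, case$pattern)
    if (nrow(want) == 0L) {
      expect_identical(nrow(got), 0L, label = patternToString(case$pattern))
    } else {
      expect_equal(unname(got), unname(want),
                   label = patternToString(case$pattern))
    }
  }
})

test_that("scanning is shift-equivariant under a non-matching prefix", {
  set.seed(7)
  p <- parsePattern("G[SG][X2-4][DE]")
  s <- paste(sample(c("A", "G", "S", "D", "E"), 90, replace = TRUE),
             collapse = "")
  base <- scanMotif(s, p)
  for (k in c(1L, 5L, 17L)) {
    shifted <- scanMotif(paste0(strrep("P", k), s), p)  # P never matches G
    expect_identical(shifted$start, base$start + k)
    expect_identical(shifted$end, base$end + k)
  }
})

test_that("curation retains records passing all criteria and names every failed one", {
  pats <- readPatternConfig()
  # controlled instance: no acidic residues outside the planted motif, so
  # criterion failures are attributable
  set.seed(11)
  backbone <- function(n) paste(sample(c("G", "S", "P"), n, replace = TRUE),
                                collapse = "")
  inst <- paste0("L", "Q", "G", "S", backbone(10), "D", "L", "E", "V",
                 backbone(60), "M", "D", "F")
  seqfull <- paste0(backbone(20), inst, backbone(20))
  rec <- data.frame(sequence_id = "S1", species = "sp", sequence = seqfull,
                    ntase_helix_bundle_homology = TRUE,
                    structural_homology = TRUE, stringsAsFactors = FALSE)
  out <- curateRecords(rec, pats)
  expect_identical(out$decision, "retained")
  expect_identical(out$reasons, "")
  expect_gte(nrow(out$matches[[1]]), 1L)

  # mutate the first catalytic acidic residue (D -> A): active site and
  # triad both collapse
  mut <- rec
  mut$sequence <- sub("DLE", "ALE", mut$sequence)
  out2 <- curateRecords(mut, pats)
  expect_identical(out2$decision, "excluded")
  expect_match(out2$reasons, "catalytic triad absent")
  expect_match(out2$reasons, "active-site motif absent")

  # false external flags are reported alongside motif failures
  rec$ntase_helix_bundle_homology <- FALSE
  rec$structural_homology <- FALSE
  out3 <- curateRecords(rec, pats)
  expect_identical(out3$decision, "excluded")
  expect_match(out3$reasons, "NTase-core/helix-bundle")
  expect_match(out3$reasons, "structural homology")

  # a missing flag is an explicit error naming the record
  rec$structural_homology <- NA
  expect_error(curateRecords(rec, pats), "S1")
})

test_that("curation decisions on a generated batch equal the generator truth", {
  pats <- readPatternConfig()
  prot <- genMotifProteome(30, 30, pats$active_site, seed = 2024)
  seqs <- as.character(prot$sequences)
  flags <- rep(TRUE, length(seqs))
  # half of the positives get a false structure flag: excluded by truth
  flagged_off <- seq(1, 30, by = 2)
  flags[flagged_off] <- FALSE
  recs <- data.frame(sequence_id = names(seqs),
                     species = "syn", sequence = unname(seqs),
                     ntase_helix_bundle_homology = TRUE,
                     structural_homology = flags,
                     stringsAsFactors = FALSE)
  out <- curateRecords(recs, pats, motifCriteria = "active_site_only")
  truth <- ifelse(prot$truth$label == "pos" & flags, "retained",
                  "excluded")
  expect_identical(out$decision, truth)
  # same input, shuffled order: decisions are a pure per-record function
  perm <- sample(nrow(recs))
  out2 <- curateRecords(recs[perm, ], pats,
                        motifCriteria = "active_site_only")
  expect_identical(out2$decision, truth[perm])
})

test_that("greedy centroid clustering honours identity and coverage thresholds", {
  # identical pair collapses
  cl <- dedupeCluster(c(a = "MKVLA", b = "MKVLA"))
  expect_identical(length(unique(cl$cluster_id)), 1L)
  # 10 substitutions in 100 positions: identity 0.90, below 0.95
  set.seed(3)
  s1 <- randomProtein(100)
  chars <- strsplit(s1, "")[[1]]
  idx <- sample(100, 10)
  chars[idx] <- vapply(chars[idx], function(a)
    sample(setdiff(c("A", "G", "V", "L"), a), 1), character(1))
  s2 <- paste(chars, collapse = "")
  cl2 <- dedupeCluster(c(x = s1, y = s2), minIdentity = 0.95)
  expect_identical(length(unique(cl2$cluster_id)), 2L)
  # the same pair clusters together once the threshold drops below 0.90
  cl3 <- dedupeCluster(c(x = s1, y = s2), minIdentity = 0.89)
  expect_identical(length(unique(cl3$cluster_id)), 1L)
  # empty input
  expect_identical(nrow(dedupeCluster(character(0))), 0L)
})

test_that("mutation clouds cluster by construction and exact thresholds give duplicate groups", {
  set.seed(17)
  mutate <- function(s, k) {
    chars <- strsplit(s, "")[[1]]
    idx <- sample(length(chars), k)
    chars[idx] <- vapply(chars[idx], function(a)
      sample(setdiff(AA <- c("A", "C", "D", "E", "F", "G"), a), 1),
      character(1))
    paste(chars, collapse = "")
  }
  centers <- replicate(3, randomProtein(200))
  seqs <- unlist(lapply(centers, function(ctr)
    c(ctr, replicate(3, mutate(ctr, 2)))))        # <=2% divergence
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  cl <- dedupeCluster(seqs, minIdentity = 0.95, minCoverage = 1.0)
  expect_identical(length(unique(cl$cluster_id)), 3L)
  # members of one cloud share a cluster
  truth <- rep(1:3, each = 4)
  grouping <- cl$cluster_id[match(names(seqs), cl$member_id)]
  expect_identical(length(unique(paste(truth, grouping))), 3L)

  # at thresholds 1.0/1.0 the partition is exactly the duplicate groups
  dup <- c(u = "MKV", v = "MKV", w = "MKVA", z = "MKQ")
  cl4 <- dedupeCluster(dup, minIdentity = 1.0, minCoverage = 1.0)
  g <- cl4$cluster_id[match(names(dup), cl4$member_id)]
  expect_identical(g[1], g[2])
  expect_identical(length(unique(g)), 3L)
})
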