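test_that("predicted P1+CIP label fates follow the bond rules", {
  # canonical 3'-5'/3'-5' linkage: both bonds cleaved, both labels lost
  sig33 <- predictSignature(parseCdnName("3'3'-cUA"))
  expect_setequal(sig33$labels, c("A", "U"))
  expect_true(sig33$cipResistant)
  expect_identical(sig33$p1Retention[["A"]], "lost")
  expect_identical(sig33$p1Retention[["U"]], "lost")
  # 2'2' homodimer: no P1-cleavable bond, label retained
  sig22 <- predictSignature(parseCdnName("2'2'-c-di-AMP"))
  expect_identical(sig22$p1Retention[["A"]], "retained")
  # mixed linkage c[U(2',5')pA(3',5')p]: the adenosine alpha-phosphate
  # sits in the protected U-2'->A-5' bond, so A is retained and U lost
  sig23 <- predictSignature(parseCdnName("2'3'-cUA"))
  expect_identical(sig23$p1Retention[["A"]], "retained")
  expect_identical(sig23$p1Retention[["U"]], "lost")
})

test_that("linkage class determines the retention pattern across all candidates", {
  for (cd in enumerateCandidates()) {
    sig <- predictSignature(cd)
    ret <- sig$p1Retention
    if (all(cd@donors == "3'")) {
      expect_true(all(ret == "lost"), label = cd@name)
    } else if (all(cd@donors == "2'")) {
      expect_true(all(ret == "retained"), label = cd@name)
    } else if (cd@bases[1] != cd@bases[2]) {
      # mixed-linkage heterodimer: exactly one of the two labels survives
      expect_identical(sum(ret == "retained"), 1L, label = cd@name)
    }
    expect_setequal(sig$labels, unique(cd@bases))
    expect_setequal(names(ret), sig$labels)
    expect_true(sig$cipResistant)
  }
})

test_that("inference inverts full observations to the known products", {
  obs33 <- ScreenObservation(labels = c("A", "U"), cipResistant = TRUE,
                             p1Retention = c(A = "lost", U = "lost"),
                             observedMz = data.frame(mz = 634,
                                                     adduct = "[M-H]-"))
  expect_identical(names(inferProduct(obs33)), "3'3'-cUA")
  obs23 <- ScreenObservation(labels = c("A", "U"),
                             p1Retention = c(A = "retained", U = "lost"))
  expect_identical(names(inferProduct(obs23)), "2'3'-cUA")
  # an empty observation leaves the whole candidate space
  expect_length(inferProduct(ScreenObservation()), 36L)
})

test_that("inconsistent and unsatisfiable observations are surfaced", {
  expect_error(ScreenObservation(labels = "A",
                                 p1Retention = c(U = "lost")),
               "not incorporated")
  # intact cyclic products always resist CIP: no candidate fits
  impossible <- ScreenObservation(labels = "A", cipResistant = FALSE)
  expect_message(res <- inferProduct(impossible), "closest")
  expect_length(res, 0L)
  expect_match(attr(res, "diagnostic"), "no candidate")
})

test_that("adding evidence never enlarges the consistent set", {
  fields <- c("labels", "cip", "p1", "mass")
  for (nm in c("2'3'-cUA", "3'3'-c-di-GMP", "2'3'-cGAMP", "2'2'-cUC")) {
    cd <- parseCdnName(nm)
    subsets <- unlist(lapply(1:4, function(k)
      combn(fields, k, simplify = FALSE)), recursive = FALSE)
    for (sub in subsets) {
      small <- inferProduct(genScreenObservation(cd, fields = sub))
      full <- inferProduct(genScreenObservation(cd, fields = fields))
      expect_true(all(names(full) %in% names(small)),
                  label = paste(nm, paste(sub, collapse = "+")))
      # and the true product is always in the consistent set
      expect_true(nm %in% names(small),
                  label = paste(nm, paste(sub, collapse = "+")))
    }
  }
})

test_that("round-trip identifiability is consistent with the distinguishability report", {
  cands <- enumerateCandidates()
  groups <- distinguishabilityReport(cands)
  for (cd in cands) {
    got <- names(inferProduct(genScreenObservation(cd), candidates = cands))
    expect_true(cd@name %in% got, label = cd@name)
    grp <- groups[[which(vapply(groups, function(g) cd@name %in% g,
                                logical(1)))]]
    # the consistent set is exactly this candidate's signature class
    expect_setequal(got, grp)
  }
  # full panel resolves every heterodimer linkage isomer
  het <- Filter(function(cd) cd@bases[1] != cd@bases[2], cands)
  for (cd in het)
    expect_identical(names(inferProduct(genScreenObservation(cd),
                                        candidates = cands)),
                     cd@name)
  # the only residual ambiguity is 2'2' vs 2'3' homodimers
  degen <- Filter(function(g) length(g) > 1, groups)
  expect_length(degen, 4L)
  for (g in degen) {
    expect_length(g, 2L)
    expect_match(g, "c-di-", all = TRUE)
  }
})

test_that("assay panels partition candidates as expected", {
  cands <- enumerateCandidates()
  by_mass <- distinguishabilityReport(cands, "mass")
  expect_length(by_mass, 10L)     # one class per molecular formula
  by_labels <- distinguishabilityReport(cands, "labels")
  expect_length(by_labels, 10L)   # one class per base set
  for (g in by_labels) {
    sets <- lapply(g, function(nm) unique(parseCdnName(nm)@bases))
    expect_length(unique(lapply(sets, sort)), 1L)
  }
})

test_that("substrate-dependency evidence constrains the base composition", {
  # product formed only when both ATP and UTP are present
  obs <- ScreenObservation(substrateDependency = list(c("A", "U")))
  got <- names(inferProduct(obs))
  comp <- lapply(got, function(nm) unique(parseCdnName(nm)@bases))
  expect_true(all(vapply(comp, function(b) all(b %in% c("A", "U")),
                         logical(1))))
})
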