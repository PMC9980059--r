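# Henderson-Hasselbalch net charge and isoelectric point.
# The ionizable-group model is composition-only: side-chain counts plus
# exactly one free N-terminus and one free C-terminus; every cysteine is
# treated as a free thiol (no disulfides or modifications).

#' Load a pKa table
#'
#' Reads a YAML pKa table (see `inst/extdata/pka_emboss.yaml` for the
#' layout). With no argument, returns the shipped default ("EMBOSS" set).
#' The cited pI implementations differ by <= ~0.3 pH units in their pKa
#' constants; reported pI values are therefore table-dependent and the
#' table in use is named in the returned object.
#'
#' @param path YAML file path; default: shipped EMBOSS table.
#' @return list with `name`, `n_terminus`, `c_terminus`, `positive`
#'   (named numeric: H, K, R) and `negative` (named numeric: D, E, C, Y).
#' @export
readPkaTable <- function(path = system.file("extdata", "pka_emboss.yaml",
                                            package = "cGLRscreen")) {
  tab <- yaml::read_yaml(path)
  tab$positive <- unlist(tab$positive)
  tab$negative <- unlist(tab$negative)
  stopifnot(all(c(tab$positive, tab$negative,
                  tab$n_terminus, tab$c_terminus) > 0),
            all(c(tab$positive, tab$negative,
                  tab$n_terminus, tab$c_terminus) < 14))
  tab
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch summation: each positive group contributes
#' `1 / (1 + 10^(pH - pKa))` elementary charges, each negative group
#' `-1 / (1 + 10^(pKa - pH))`. Group counts come from residue
#' composition plus one N- and one C-terminus.
#'
#' @param sequence amino-acid string (non-ionizable and non-standard
#'   characters contribute nothing).
#' @param pH pH value(s); vectorized.
#' @param table pKa table from [readPkaTable()].
#' @return Net charge in elementary charges (same length as `pH`).
#' @examples
#' netCharge("G", 0)    # ~ +1: protonated N-terminus
#' netCharge("G", 14)   # ~ -1
#' @export
netCharge <- function(sequence, pH, table = readPkaTable()) {
  stopifnot(nchar(sequence) > 0L)
  chars <- strsplit(sequence, "")[[1]]
  comp <- vapply(AA_STANDARD, function(a) sum(chars == a), numeric(1))
  pos_pka <- c(table$n_terminus, table$positive)
  pos_n <- c(1, comp[names(table$positive)])
  neg_pka <- c(table$c_terminus, table$negative)
  neg_n <- c(1, comp[names(table$negative)])
  vapply(pH, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pka))) -
      sum(neg_n / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] at which [netCharge()] crosses zero, by
#' bisection to the requested tolerance. The charge is strictly
#' decreasing in pH and the free termini guarantee a sign change inside
#' the bracket, so the root is unique and the procedure deterministic.
#'
#' @inheritParams netCharge
#' @param tol absolute pH tolerance (default 1e-3).
#' @return pI in pH units.
#' @examples
#' round(isoelectricPoint("KKKKKKKKKK"), 1)   # strongly basic
#' @export
isoelectricPoint <- function(sequence, table = readPkaTable(), tol = 1e-3) {
  stopifnot(tol > 0)
  lo <- 0; hi <- 14
  f_lo <- netCharge(sequence, lo, table)
  f_hi <- netCharge(sequence, hi, table)
  if (f_lo <= 0) return(lo)    # cannot occur with a free N-terminus
  if (f_hi >= 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (netCharge(sequence, mid, table) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify a cGLR by isoelectric point
#'
#' Nucleic-acid-sensing cGLRs carry a high predicted pI (> 8.5 by the
#' screening convention), consistent with a positively charged ligand
#' binding surface; strongly acidic enzymes (pI < `acidicThreshold`) are
#' candidates for non-nucleic-acid ligands. Comparisons are strict, so a
#' pI exactly at a threshold falls in the intermediate class.
#'
#' @param pI isoelectric point(s); vectorized.
#' @param basicThreshold default 8.5.
#' @param acidicThreshold default 7.0; must be below `basicThreshold`.
#' @return character vector in
#'   `{"nucleic-acid-sensor-like", "intermediate", "acidic"}`.
#' @export
classifyByPI <- function(pI, basicThreshold = 8.5, acidicThreshold = 7.0) {
  stopifnot(acidicThreshold < basicThreshold)
  ifelse(pI > basicThreshold, "nucleic-acid-sensor-like",
         ifelse(pI < acidicThreshold, "acidic", "intermediate"))
}

#' pI table for a set of sequences
#'
#' Convenience wrapper: computes pI and class label for every sequence
#' in a FASTA/`AAStringSet`, the per-protein summary exported alongside
#' curation results.
#'
#' @param sequences `AAStringSet` or named character vector.
#' @inheritParams isoelectricPoint
#' @inheritParams classifyByPI
#' @return data.frame with `sequence_id`, `pI` (2 decimals), `class_label`.
#' @export
piTable <- function(sequences, table = readPkaTable(),
                    basicThreshold = 8.5, acidicThreshold = 7.0) {
  if (is(sequences, "XStringSet")) {
    ids <- names(sequences); seqs <- as.character(sequences)
  } else {
    ids <- names(sequences); seqs <- unname(sequences)
  }
  pis <- vapply(seqs, isoelectricPoint, numeric(1), table = table)
  data.frame(sequence_id = ids, pI = round(pis, 2),
             class_label = classifyByPI(pis, basicThreshold,
                                        acidicThreshold),
             row.names = NULL, stringsAsFactors = FALSE)
}
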