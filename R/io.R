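# File interfaces. All coordinates written to or read from disk are
# 0-based half-open.

#' Read a protein FASTA with annotated description lines
#'
#' Description lines of the form `id species=Homo sapiens phylum=Chordata`
#' are split into an id (first whitespace-delimited token) and key=value
#' annotations whose values may contain spaces.
#'
#' @param path FASTA file (wrapped or single-line).
#' @return list with `sequences` (`AAStringSet` named by id) and
#'   `annotations` (data.frame `sequence_id`, plus one column per key
#'   seen, NA where absent).
#' @export
readProteinFasta <- function(path) {
  sset <- Biostrings::readAAStringSet(path)
  desc <- names(sset)
  ids <- sub("\\s.*$", "", desc)
  names(sset) <- ids
  ann <- lapply(desc, function(d) {
    rest <- sub("^\\S+\\s*", "", d)
    if (rest == "") return(list())
    starts <- gregexpr("\\b[[:alnum:]_]+=", rest)[[1]]
    if (starts[1] == -1L) return(list())
    lens <- attr(starts, "match.length")
    keys <- substring(rest, starts, starts + lens - 2L)
    vstart <- starts + lens
    vend <- c(starts[-1] - 1L, nchar(rest))
    vals <- trimws(substring(rest, vstart, vend))
    stats::setNames(as.list(vals), keys)
  })
  keys <- unique(unlist(lapply(ann, names)))
  df <- data.frame(sequence_id = ids, stringsAsFactors = FALSE)
  for (k in keys)
    df[[k]] <- vapply(ann, function(a)
      if (k %in% names(a)) a[[k]] else NA_character_, character(1))
  list(sequences = sset, annotations = df)
}

#' Read the external curation flags table
#'
#' TSV with columns `sequence_id`, `ntase_helix_bundle_homology`,
#' `structural_homology` (logical); these criteria are computed by
#' out-of-scope alignment/structure tools and consumed here as booleans.
#'
#' @param path TSV path.
#' @return data.frame with logical flag columns.
#' @export
readFlagsTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "ntase_helix_bundle_homology",
            "structural_homology")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("flags table lacks column(s): ", paste(miss, collapse = ", "))
  for (k in need[-1]) df[[k]] <- as.logical(df[[k]])
  df
}

#' Load motif pattern configuration
#'
#' Reads a YAML file declaring residue classes and pattern strings (see
#' the shipped `inst/extdata/patterns.yaml` for the defaults used in
#' cGLR curation) and parses every pattern.
#'
#' @param path YAML path; default: shipped configuration.
#' @return named list of [MotifPattern-class].
#' @export
readPatternConfig <- function(path = system.file("extdata",
                                                 "patterns.yaml",
                                                 package = "cGLRscreen")) {
  cfg <- yaml::read_yaml(path)
  classes <- lapply(cfg$classes, unlist)
  out <- lapply(names(cfg$patterns), function(nm)
    parsePattern(cfg$patterns[[nm]], classes = classes, name = nm))
  stats::setNames(out, names(cfg$patterns))
}

.anchorString <- function(anchors)
  paste(sprintf("%d-%d", anchors[, "start"], anchors[, "end"]),
        collapse = ";")

#' Write motif matches as TSV
#'
#' Columns: `sequence_id`, `pattern_name`, `full_start`, `full_end`,
#' `anchor_spans` (semicolon-joined `start-end` pairs), 0-based
#' half-open.
#'
#' @param matches output of the `AAStringSet` method of [scanMotif()].
#' @param patternName pattern name column value.
#' @param path output TSV path.
#' @export
writeMatchesTsv <- function(matches, patternName, path) {
  df <- data.frame(
    sequence_id = matches$sequence_id,
    pattern_name = patternName,
    full_start = matches$start,
    full_end = matches$end,
    anchor_spans = vapply(matches$anchors, .anchorString, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Write curation decisions as TSV
#'
#' @param curation output of [curateRecords()].
#' @param path output TSV path.
#' @export
writeCurationTsv <- function(curation, path) {
  df <- curation[, c("sequence_id", "decision", "reasons")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Write redundancy-removal clusters as TSV
#'
#' @param clusters output of [dedupeCluster()].
#' @param path output TSV path.
#' @export
writeClustersTsv <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(clusters)
}
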