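# Gene-family census summaries: per-species cGLR/STING copy numbers and
# domain-architecture prevalence with the sub-threshold "Other" fold.

#' Per-species cGLR/STING copy-number table
#'
#' Counts cGLR and STING records per species over a complete species
#' roster (roster species with no records appear with zero counts), and
#' tabulates the frequency of each (n_cGLR, n_STING) pair across the
#' roster — the data behind a copy-number bubble plot.
#'
#' @param records data.frame with columns `species` and `family`
#'   (values `"cGLR"` or `"STING"`); an optional logical column
#'   `mab21_like` marks Mab21-like proteins.
#' @param speciesRoster character vector of all species under study;
#'   must contain every species present in `records`.
#' @param excludeMab21 drop records flagged `mab21_like` before counting
#'   (the census of enzymes with putative immune function).
#' @return list with `per_species` (data.frame `species`, `n_cGLR`,
#'   `n_STING`) and `frequency` (data.frame `n_cGLR`, `n_STING`,
#'   `n_species`; frequencies sum to the roster size).
#' @export
copyNumberTable <- function(records, speciesRoster,
                            excludeMab21 = FALSE) {
  stopifnot(all(c("species", "family") %in% names(records)))
  outside <- setdiff(unique(records$species), speciesRoster)
  if (length(outside))
    stop("record species outside roster: ",
         paste(utils::head(outside, 5), collapse = ", "))
  if (excludeMab21 && "mab21_like" %in% names(records))
    records <- records[!isTRUE_vec(records$mab21_like), , drop = FALSE]
  count <- function(fam) {
    tab <- table(factor(records$species[records$family == fam],
                        levels = speciesRoster))
    as.integer(tab)
  }
  per_species <- data.frame(species = speciesRoster,
                            n_cGLR = count("cGLR"),
                            n_STING = count("STING"),
                            stringsAsFactors = FALSE)
  freq <- as.data.frame(table(n_cGLR = per_species$n_cGLR,
                              n_STING = per_species$n_STING),
                        stringsAsFactors = FALSE)
  freq <- freq[freq$Freq > 0, ]
  freq <- data.frame(n_cGLR = as.integer(freq$n_cGLR),
                     n_STING = as.integer(freq$n_STING),
                     n_species = freq$Freq)
  list(per_species = per_species,
       frequency = freq[order(freq$n_cGLR, freq$n_STING), ])
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Domain-architecture prevalence with an "Other" fold
#'
#' Shares of each domain architecture within one gene family, with
#' every architecture whose share falls strictly below the threshold
#' folded into a single `"Other"` class (0.5% by the screening
#' convention). Percentages are exact; round for display.
#'
#' @param records data.frame with columns `family` and `architecture`
#'   (plus-joined domain labels, e.g. `"ANK+cGLR"`).
#' @param otherThreshold fraction in (0, 1); strict comparison.
#' @param family family to summarize (default `"cGLR"`).
#' @return data.frame with `architecture`, `count`, `percentage`,
#'   retained classes sorted by decreasing share, `"Other"` last.
#'   Percentages sum to 100.
#' @export
architecturePrevalence <- function(records, otherThreshold = 0.005,
                                   family = "cGLR") {
  stopifnot(all(c("family", "architecture") %in% names(records)),
            otherThreshold > 0, otherThreshold < 1)
  arch <- records$architecture[records$family == family]
  if (length(arch) == 0L)
    stop("no records for family '", family, "'")
  counts <- sort(table(arch), decreasing = TRUE)
  share <- as.numeric(counts) / length(arch)
  fold <- share < otherThreshold
  out <- data.frame(architecture = names(counts)[!fold],
                    count = as.integer(counts[!fold]),
                    percentage = 100 * share[!fold],
                    stringsAsFactors = FALSE)
  if (any(fold))
    out <- rbind(out, data.frame(architecture = "Other",
                                 count = sum(counts[fold]),
                                 percentage = 100 * sum(share[fold])))
  rownames(out) <- NULL
  out
}
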