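# Single-site binding isotherm analysis of EMSA titrations.

#' Single-site binding isotherm
#'
#' Fraction of probe bound at total protein concentration `c` under the
#' trace-ligand approximation: `c / (c + Kd)`. Strictly increasing in
#' concentration, strictly decreasing in Kd.
#'
#' @param concentration molar concentration(s), >= 0; vectorized.
#' @param kd dissociation constant (M), > 0.
#' @return fraction bound in [0, 1).
#' @examples
#' fractionBound(1e-6, 1e-6)   # 0.5 at the midpoint
#' @export
fractionBound <- function(concentration, kd) {
  if (kd <= 0) stop("kd must be > 0")
  stopifnot(all(concentration >= 0))
  concentration / (concentration + kd)
}

#' Construct an EMSA titration curve
#'
#' @param ligandId ligand identifier.
#' @param concentrations molar protein concentrations, strictly positive
#'   and strictly increasing.
#' @param fractionBound measured shifted/total signal; values outside
#'   [0, 1] are retained but flagged.
#' @param replicateId replicate identifier.
#' @return A [BindingCurve-class].
#' @export
BindingCurve <- function(ligandId, concentrations, fractionBound,
                         replicateId = "1") {
  new("BindingCurve", ligandId = as.character(ligandId),
      replicateId = as.character(replicateId),
      concentrations = as.numeric(concentrations),
      fractionBound = as.numeric(fractionBound),
      clipped = any(fractionBound < 0 | fractionBound > 1))
}

#' @rdname fitIsotherm
#' @param gridPoints number of points of the initial log10(Kd) grid.
#' @export
setMethod("fitIsotherm", "BindingCurve", function(x, gridPoints = 601L,
                                                  ...) {
  cc <- x@concentrations
  fb <- x@fractionBound
  n <- length(cc)
  if (n < 3L) stop("need at least 3 titration points")
  if (diff(range(fb)) < .Machine$double.eps^0.5) {
    diag <- if (mean(fb) < 0.05) "no binding detected"
    else if (mean(fb) > 0.95) "saturated at all concentrations"
    else "flat titration response"
    return(new("IsothermFit", kd = NA_real_, rss = NA_real_,
               converged = FALSE, nPoints = n, diagnostic = diag))
  }
  rss <- function(logkd) sum((fb - cc / (cc + 10^logkd))^2)
  lo <- log10(min(cc)) - 2    # bracket: min conc / 100 .. max conc * 100
  hi <- log10(max(cc)) + 2
  grid <- seq(lo, hi, length.out = gridPoints)
  vals <- vapply(grid, rss, numeric(1))
  i <- which.min(vals)
  bracket <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, gridPoints)])
  opt <- stats::optimize(rss, interval = bracket, tol = 1e-12)
  new("IsothermFit", kd = 10^opt$minimum, rss = opt$objective,
      converged = TRUE, nPoints = n, diagnostic = "")
})

#' Fit every ligand x replicate series in an EMSA table
#'
#' @param table data.frame with columns `ligand_id`, `replicate_id`,
#'   `concentration_M`, `fraction_bound`.
#' @param pooled also fit each ligand with replicates pooled.
#' @return data.frame with one row per fit: `ligand_id`, `replicate_id`
#'   (`"pooled"` for pooled fits), `kd_M`, `rss`, `converged`,
#'   `n_points`, `diagnostic`.
#' @export
fitEmsaTable <- function(table, pooled = TRUE) {
  need <- c("ligand_id", "replicate_id", "concentration_M",
            "fraction_bound")
  stopifnot(all(need %in% names(table)))
  fitOne <- function(df, rep_label) {
    df <- df[order(df$concentration_M), ]
    # pooled data may repeat concentrations; average duplicates so the
    # curve stays strictly increasing
    agg <- stats::aggregate(fraction_bound ~ concentration_M, df, mean)
    fit <- fitIsotherm(BindingCurve(df$ligand_id[1], agg$concentration_M,
                                    agg$fraction_bound, rep_label))
    data.frame(ligand_id = df$ligand_id[1], replicate_id = rep_label,
               kd_M = fit@kd, rss = fit@rss, converged = fit@converged,
               n_points = fit@nPoints, diagnostic = fit@diagnostic,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (lig in unique(table$ligand_id)) {
    sub <- table[table$ligand_id == lig, ]
    for (rep in unique(sub$replicate_id))
      out[[length(out) + 1L]] <-
        fitOne(sub[sub$replicate_id == rep, ], as.character(rep))
    if (pooled && length(unique(sub$replicate_id)) > 1L)
      out[[length(out) + 1L]] <- fitOne(sub, "pooled")
  }
  do.call(rbind, out)
}
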