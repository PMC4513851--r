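#' Functional-category composition from peak areas
#'
#' For each run, every quantified protein's top-3 peak area is summed
#' within its functional category and expressed as a percentage of the
#' run's total area; the per-category mean over runs is then taken.
#' Proteins absent from the category map fall into "other".  Runs with
#' zero total area are excluded with a warning.
#'
#' @param runQuants list of \linkS4class{RunQuant}s (typically the
#'   adjusted bait runs surviving control subtraction).
#' @param categoryMap named character vector, protein id to category.
#' @return a \linkS4class{CompositionSummary}.
#' @examples
#' cfg <- pullQuantConfig()
#' psms <- data.frame(spectrum_id = c("s1", "s2", "s3", "s4"),
#'   run_id = "B1", fraction_id = "F1",
#'   peptide_seq = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK"),
#'   protein_ids = c("P1", "P1", "P2", "P2"), rank = 1L, score = 10,
#'   mass_error_ppm = 0, intensity = c(46, 46, 54, 54),
#'   is_decoy = FALSE, stringsAsFactors = FALSE)
#' prot <- data.frame(protein_id = c("P1", "P2"), description = "",
#'   sequence = c("AAAAAAKCCCCCCK", "DDDDDDKEEEEEEK"),
#'   mw_da = c(1e4, 1e4), is_decoy = FALSE, category = "")
#' rq <- quantifyRun(psms, prot, c("P1", "P2"), cfg)
#' compositionPercentages(list(rq), c(P1 = "A", P2 = "B"))
#' @export
compositionPercentages <- function(runQuants, categoryMap = NULL) {
  stopifnot(length(runQuants) >= 1L)
  perRunList <- list()
  for (q in runQuants) {
    tab <- quantTable(q)
    if (nrow(tab) == 0L || sum(tab$top3_area) <= 0) {
      warning("run '", runId(q),
              "' has zero total peak area; excluded from composition")
      next
    }
    cats <- if (is.null(categoryMap)) rep(NA_character_, nrow(tab)) else
      unname(categoryMap[tab$protein_id])
    cats[is.na(cats)] <- "other"
    tot <- tapply(tab$top3_area, cats, sum)
    perRunList[[runId(q)]] <- 100 * tot / sum(tab$top3_area)
  }
  if (!length(perRunList))
    stop("no run with nonzero total peak area")
  allCats <- sort(unique(unlist(lapply(perRunList, names))))
  mat <- matrix(0, nrow = length(perRunList), ncol = length(allCats),
                dimnames = list(names(perRunList), allCats))
  for (r in names(perRunList))
    mat[r, names(perRunList[[r]])] <- perRunList[[r]]
  perRun <- as.data.frame(mat)
  new("CompositionSummary", perRun = perRun,
      meanPercent = colMeans(mat), nRuns = nrow(mat))
}
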