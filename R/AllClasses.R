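## Central S4 containers. Tabular payloads are plain data.frames held in
## slots; validity methods enforce the pipeline's arithmetic invariants.

#' GroundTruth: the known composition behind a synthetic pull-down
#'
#' Describes a simulated AP-MS scenario: one bait protein, complex members
#' at fixed stoichiometry relative to the bait, and background contaminants
#' shared between bait and control runs.  Everything downstream of the
#' generator can be checked against this object.
#'
#' @slot baitId protein id of the bait; its stoichiometry is exactly 1.
#' @slot stoichiometry named numeric, true abundance of each complex member
#'   relative to the bait (bait included, value 1).
#' @slot contaminants named numeric, relative abundance of each background
#'   protein; contaminants are present in bait and control runs alike.
#' @slot controlLevel multiplier applied to contaminant abundance in
#'   control runs (1 = identical background in bait and control).
#' @slot nBaitRuns,nControlRuns number of replicate bait / mock-bait runs.
#' @slot seed master seed; all per-run seeds derive from it.
#' @slot noiseCv coefficient of variation of the per-protein, per-run
#'   multiplicative abundance noise (log-normal, mean 1).
#' @slot depth expected PSMs per detectable peptide per unit abundance.
#' @slot proteome data.frame of protein records (see
#'   \code{\link{readFasta}} for columns), including reversed decoys.
#' @slot simParams list of detection-model constants (score means and SD
#'   for correct and incorrect PSMs, intensity scale, injected-noise PSM
#'   rate, etc.); see \code{\link{simulateRun}}.
#'
#' @seealso \code{\link{generateProteome}}, \code{\link{eif3GroundTruth}},
#'   \code{\link{simulateExperimentSet}}
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    baitId        = "character",
    stoichiometry = "numeric",
    contaminants  = "numeric",
    controlLevel  = "numeric",
    nBaitRuns     = "integer",
    nControlRuns  = "integer",
    seed          = "integer",
    noiseCv       = "numeric",
    depth         = "numeric",
    proteome      = "data.frame",
    simParams     = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  s <- object@stoichiometry
  if (!(object@baitId %in% names(s)))
    msg <- c(msg, "bait must appear in 'stoichiometry'")
  else if (s[[object@baitId]] != 1)
    msg <- c(msg, "bait stoichiometry must be exactly 1")
  if (any(s <= 0)) msg <- c(msg, "all stoichiometries must be > 0")
  if (length(object@contaminants) && any(object@contaminants <= 0))
    msg <- c(msg, "all contaminant abundances must be > 0")
  ids <- object@proteome$protein_id
  miss <- setdiff(c(names(s), names(object@contaminants)), ids)
  if (length(miss))
    msg <- c(msg, paste0("ids missing from proteome: ",
                         paste(miss, collapse = ", ")))
  if (object@nBaitRuns < 1L) msg <- c(msg, "nBaitRuns must be >= 1")
  if (object@nControlRuns < 0L) msg <- c(msg, "nControlRuns must be >= 0")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (length(msg)) msg else TRUE
})

#' RunQuant: per-run protein-level quantification
#'
#' One row per protein that passed the per-run evidence filters, carrying
#' the unique-peptide count U, the spectral count S, the top-3 peak area,
#' and the protein abundance factor PAF = (count / MW in Da) x pafScale.
#' After control subtraction an additional column \code{paf_adj} holds the
#' background-corrected PAF (clamped at zero).
#'
#' @slot runId run identifier.
#' @slot role "bait" or "control".
#' @slot quant data.frame with columns \code{protein_id}, \code{mw_da},
#'   \code{U}, \code{S}, \code{top3_area}, \code{paf} (and \code{paf_adj}
#'   after \code{\link{subtractControl}}).
#' @slot basis count basis of the PAF: "unique" (distinct peptides) or
#'   "spectral" (PSM count).
#' @slot pafScale scale factor of the PAF (default 1e4).
#'
#' @seealso \code{\link{quantifyRun}}
#' @exportClass RunQuant
setClass("RunQuant",
  representation(
    runId    = "character",
    role     = "character",
    quant    = "data.frame",
    basis    = "character",
    pafScale = "numeric"
  )
)

setValidity("RunQuant", function(object) {
  msg <- character()
  q <- object@quant
  need <- c("protein_id", "mw_da", "U", "S", "top3_area", "paf")
  if (!all(need %in% names(q)))
    return(paste0("quant must have columns: ", paste(need, collapse = ", ")))
  if (!object@role %in% c("bait", "control"))
    msg <- c(msg, "role must be 'bait' or 'control'")
  if (!object@basis %in% c("unique", "spectral"))
    msg <- c(msg, "basis must be 'unique' or 'spectral'")
  if (nrow(q)) {
    if (any(q$U < 0) || any(q$S < 0) || any(q$top3_area < 0))
      msg <- c(msg, "U, S and top3_area must be >= 0")
    if (any(q$U > 0 & q$S < q$U))
      msg <- c(msg, "S must be >= U for detected proteins")
    cnt <- if (object@basis == "unique") q$U else q$S
    expect <- cnt / q$mw_da * object@pafScale
    if (any(abs(q$paf - expect) > 1e-9 * pmax(1, expect)))
      msg <- c(msg, "paf must equal (count / mw_da) * pafScale")
    if (anyDuplicated(q$protein_id))
      msg <- c(msg, "duplicate protein_id in quant")
  }
  if (length(msg)) msg else TRUE
})

#' AbundanceTable: cross-replicate stoichiometry report
#'
#' The final report of a pull-down series: per protein, the mean and
#' sample standard deviation of the bait-normalized relative PAF across
#' bait runs, the mean top-3 area, the number of runs in which the
#' protein was detected, and its functional category.  The bait row is
#' exactly (1, 0) by construction.
#'
#' @slot table data.frame with columns \code{protein_id},
#'   \code{description}, \code{category}, \code{mw_kda},
#'   \code{mean_rel_paf}, \code{sd_rel_paf}, \code{mean_area},
#'   \code{n_runs_detected}.
#' @slot baitId bait protein id.
#' @slot nBaitRuns,nControlRuns run counts the report is based on.
#' @slot params list of pipeline parameters used (for the run log).
#'
#' @seealso \code{\link{aggregateReplicates}}
#' @exportClass AbundanceTable
setClass("AbundanceTable",
  representation(
    baitId       = "character",
    nBaitRuns    = "integer",
    nControlRuns = "integer",
    table        = "data.frame",
    params       = "list"
  )
)

setValidity("AbundanceTable", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("protein_id", "description", "category", "mw_kda",
            "mean_rel_paf", "sd_rel_paf", "mean_area", "n_runs_detected")
  if (!all(need %in% names(tab)))
    return(paste0("table must have columns: ", paste(need, collapse = ", ")))
  if (nrow(tab)) {
    if (any(tab$mean_rel_paf < 0) || any(tab$sd_rel_paf < 0) ||
        any(tab$mean_area < 0))
      msg <- c(msg, "means and SDs must be >= 0")
    b <- tab[tab$protein_id == object@baitId, ]
    if (nrow(b) == 1L &&
        (b$mean_rel_paf != 1 || b$sd_rel_paf != 0))
      msg <- c(msg, "bait row must be exactly mean 1, SD 0")
  }
  if (length(msg)) msg else TRUE
})

#' FilterReport: audit trail of the PSM confidence filters
#'
#' Counts are conserved: \code{input} equals \code{retained} plus the sum
#' of the per-criterion removals, each PSM being attributed to the first
#' criterion it fails (rank, then mass accuracy, then FDR, then decoy).
#'
#' @slot runId run the report describes.
#' @slot counts named numeric with elements \code{input},
#'   \code{removed_rank}, \code{removed_mass}, \code{removed_fdr},
#'   \code{removed_decoy}, \code{retained}.
#' @slot proteinsDropped ids failing the minimum-peptide rule (filled in
#'   by \code{\link{filterProteins}}).
#' @slot decoyFraction fraction of decoy PSMs among the input.
#'
#' @seealso \code{\link{filterPsms}}
#' @exportClass FilterReport
setClass("FilterReport",
  representation(
    runId           = "character",
    counts          = "numeric",
    proteinsDropped = "character",
    decoyFraction   = "numeric"
  )
)

setValidity("FilterReport", function(object) {
  cn <- c("input", "removed_rank", "removed_mass", "removed_fdr",
          "removed_decoy", "retained")
  if (!all(cn %in% names(object@counts)))
    return(paste0("counts must be named: ", paste(cn, collapse = ", ")))
  k <- object@counts
  if (k[["input"]] != k[["retained"]] + k[["removed_rank"]] +
      k[["removed_mass"]] + k[["removed_fdr"]] + k[["removed_decoy"]])
    return("counts are not conserved (input != retained + removals)")
  TRUE
})

#' CompositionSummary: functional-category composition of a pull-down
#'
#' Per-run percentages of total top-3 peak area falling in each
#' functional category, and their mean across runs.  Each run's
#' percentages sum to 100.
#'
#' @slot perRun data.frame, one row per run (rownames = run ids), one
#'   column per category, values in percent.
#' @slot meanPercent named numeric, per-category mean percent across runs.
#' @slot nRuns number of runs contributing.
#'
#' @seealso \code{\link{compositionPercentages}}
#' @exportClass CompositionSummary
setClass("CompositionSummary",
  representation(
    perRun      = "data.frame",
    meanPercent = "numeric",
    nRuns       = "integer"
  )
)

setValidity("CompositionSummary", function(object) {
  p <- object@perRun
  if (nrow(p)) {
    if (any(as.matrix(p) < 0)) return("percentages must be >= 0")
    if (any(abs(rowSums(p) - 100) > 1e-6))
      return("per-run percentages must sum to 100")
  }
  if (object@nRuns != nrow(p)) return("nRuns must equal nrow(perRun)")
  TRUE
})

## show methods ------------------------------------------------------------

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth synthetic pull-down scenario\n")
  cat("  bait:", object@baitId, "\n")
  cat("  complex members:", length(object@stoichiometry),
      "(stoichiometry", paste0(range(object@stoichiometry), collapse = "-"),
      ")\n")
  cat("  contaminants:", length(object@contaminants), "\n")
  cat("  runs:", object@nBaitRuns, "bait +", object@nControlRuns,
      "control; depth", object@depth, "; noise CV", object@noiseCv,
      "; seed", object@seed, "\n")
  cat("  proteome:", nrow(object@proteome), "records (incl. decoys)\n")
})

setMethod("show", "RunQuant", function(object) {
  cat(sprintf("RunQuant '%s' (%s run): %d proteins, PAF basis '%s'\n",
              object@runId, object@role, nrow(object@quant), object@basis))
  if (nrow(object@quant)) {
    print(utils::head(object@quant, 5L), row.names = FALSE)
    if (nrow(object@quant) > 5L)
      cat("  ...", nrow(object@quant) - 5L, "more rows\n")
  }
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf(
    "AbundanceTable: bait '%s', %d bait + %d control runs, %d proteins\n",
    object@baitId, object@nBaitRuns, object@nControlRuns,
    nrow(object@table)))
  if (nrow(object@table)) {
    tab <- object@table[order(-object@table$mean_rel_paf), ]
    print(utils::head(tab, 8L), row.names = FALSE)
    if (nrow(tab) > 8L) cat("  ...", nrow(tab) - 8L, "more rows\n")
  }
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport for run '%s'\n", object@runId))
  print(object@counts)
  cat(sprintf("  decoy fraction of input: %.4f; proteins dropped: %d\n",
              object@decoyFraction, length(object@proteinsDropped)))
})

setMethod("show", "CompositionSummary", function(object) {
  cat(sprintf("CompositionSummary over %d runs\n", object@nRuns))
  print(round(sort(object@meanPercent, decreasing = TRUE), 2))
})
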