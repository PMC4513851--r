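#' Protein abundance factor
#'
#' PAF = (peptide count / molecular weight in Da) x scale.  With the
#' default unique-peptide basis the count is the number of distinct
#' peptide sequences identifying the protein; mass-normalizing makes the
#' index comparable across proteins of different size.
#'
#' @param count unique-peptide or spectral count (>= 0).
#' @param mwDa molecular weight in Daltons (> 0).
#' @param pafScale scale factor (default 1e4).
#' @return numeric PAF (vectorized).
#' @examples
#' pafScore(20, 1e5)  # 2
#' @export
pafScore <- function(count, mwDa, pafScale = 1e4) {
  if (any(mwDa <= 0)) stop("'mwDa' must be > 0")
  if (any(count < 0)) stop("'count' must be >= 0")
  count / mwDa * pafScale
}

#' Top-N peak area
#'
#' The mean of the \code{n} largest per-peptide intensities of a protein
#' within a run (default \code{n = 3}); with fewer than \code{n} peptides
#' the mean of all available, and 0 for none.
#'
#' @param peptideIntensities numeric vector, one intensity per distinct
#'   peptide (the maximum PSM intensity of that peptide in the run).
#' @param n how many top peptides to average (default 3).
#' @return numeric scalar.
#' @examples
#' top3Area(c(9, 7, 5, 1))  # 7
#' top3Area(c(8, 2))        # 5
#' @export
top3Area <- function(peptideIntensities, n = 3L) {
  if (!length(peptideIntensities)) return(0)
  mean(sort(peptideIntensities, decreasing = TRUE)[
    seq_len(min(n, length(peptideIntensities)))])
}

#' Per-run protein quantification
#'
#' Computes, for every protein that passed the minimum-peptide rule, the
#' unique-peptide count U, the spectral count S, the top-N peak area and
#' the PAF, from the retained PSMs of one run (fractions pooled).  A
#' peptide shared between proteins contributes to every mapped protein.
#'
#' @param psms retained PSMs of one run.
#' @param proteomeDf proteome data.frame (from \code{\link{readFasta}} or
#'   \code{\link{proteome}}); every quantified protein must be present.
#' @param passingProteins ids that passed \code{\link{filterProteins}}.
#' @param config parameter list from \code{\link{pullQuantConfig}}
#'   (uses \code{paf_basis}, \code{paf_scale}, \code{top_n_area}).
#' @param runId run identifier; defaults to the PSMs' run_id.
#' @param role "bait" or "control".
#' @return a \linkS4class{RunQuant}.
#' @export
quantifyRun <- function(psms, proteomeDf, passingProteins,
                        config = pullQuantConfig(),
                        runId = if (nrow(psms)) psms$run_id[1L] else "<none>",
                        role = "bait") {
  empty <- data.frame(protein_id = character(), mw_da = numeric(),
                      U = integer(), S = integer(), top3_area = numeric(),
                      paf = numeric(), stringsAsFactors = FALSE)
  if (nrow(psms) == 0L || length(passingProteins) == 0L)
    return(new("RunQuant", runId = as.character(runId), role = role,
               quant = empty, basis = config$paf_basis,
               pafScale = config$paf_scale))
  long <- expandProteinIds(psms)
  long <- long[long$protein_id %in% passingProteins, , drop = FALSE]
  missing <- setdiff(unique(long$protein_id), proteomeDf$protein_id)
  if (length(missing))
    stop("protein(s) in PSMs but absent from proteome: ",
         paste(missing, collapse = ", "))
  if (nrow(long) == 0L)
    return(new("RunQuant", runId = as.character(runId), role = role,
               quant = empty, basis = config$paf_basis,
               pafScale = config$paf_scale))
  sp <- split(long, long$protein_id)
  ids <- names(sp)
  U <- vapply(sp, function(d) length(unique(d$peptide_seq)), integer(1L))
  S <- vapply(sp, nrow, integer(1L))
  area <- vapply(sp, function(d) {
    perPep <- tapply(d$intensity, d$peptide_seq, max)
    top3Area(as.numeric(perPep), n = config$top_n_area)
  }, numeric(1L))
  mw <- proteomeDf$mw_da[match(ids, proteomeDf$protein_id)]
  cnt <- if (config$paf_basis == "unique") U else S
  quant <- data.frame(
    protein_id = ids, mw_da = mw, U = unname(U), S = unname(S),
    top3_area = unname(area),
    paf = pafScore(unname(cnt), mw, config$paf_scale),
    stringsAsFactors = FALSE)
  rownames(quant) <- NULL
  new("RunQuant", runId = as.character(runId), role = role, quant = quant,
      basis = config$paf_basis, pafScale = config$paf_scale)
}

#' Subtract mock-bait control background
#'
#' For every protein, the mean PAF over the control runs (a protein
#' absent from a control run contributes 0 to that mean) is subtracted
#' from its PAF in each bait run, clamping at zero.  Proteins whose
#' adjusted PAF is zero in every bait run are removed.  With no control
#' runs this is the identity (an extra \code{paf_adj} column equal to
#' \code{paf}).
#'
#' @param baitQuants list of bait-run \linkS4class{RunQuant}s.
#' @param controlQuants list of control-run \linkS4class{RunQuant}s
#'   (possibly empty).
#' @return list of adjusted bait \linkS4class{RunQuant}s whose quant
#'   tables carry a \code{paf_adj} column; fully-cancelled proteins are
#'   dropped from every run.
#' @export
subtractControl <- function(baitQuants, controlQuants = list()) {
  stopifnot(length(baitQuants) >= 1L)
  nCtl <- length(controlQuants)
  ctlMean <- numeric()
  if (nCtl > 0L) {
    ctlAll <- do.call(rbind, lapply(controlQuants, function(q)
      quantTable(q)[, c("protein_id", "paf")]))
    ctlSum <- tapply(ctlAll$paf, ctlAll$protein_id, sum)
    ctlMean <- as.numeric(ctlSum) / nCtl   # absent run contributes 0
    names(ctlMean) <- names(ctlSum)
  }
  adjusted <- lapply(baitQuants, function(q) {
    tab <- quantTable(q)
    bg <- ctlMean[tab$protein_id]
    bg[is.na(bg)] <- 0
    tab$paf_adj <- pmax(0, tab$paf - bg)
    methods::initialize(q, quant = tab)
  })
  ## drop proteins cancelled in every bait run
  allTabs <- do.call(rbind, lapply(adjusted, function(q)
    quantTable(q)[, c("protein_id", "paf_adj")]))
  keepIds <- unique(allTabs$protein_id[allTabs$paf_adj > 0])
  lapply(adjusted, function(q) {
    tab <- quantTable(q)
    methods::initialize(q,
      quant = tab[tab$protein_id %in% keepIds, , drop = FALSE])
  })
}

#' Bait-normalized relative PAF for one run
#'
#' Divides every protein's control-adjusted PAF by the bait's in the same
#' run; the bait maps to exactly 1.  A bait run in which the bait itself
#' is undetected or fully cancelled is invalid (a pull-down without its
#' bait), and is a hard error naming the run.
#'
#' @param runQuant an adjusted bait \linkS4class{RunQuant} (with
#'   \code{paf_adj}; a plain \code{paf} column is used when no
#'   subtraction was applied).
#' @param baitId bait protein id.
#' @return data.frame with \code{run_id}, \code{protein_id},
#'   \code{rel_paf}, \code{top3_area}.
#' @export
relativeToBait <- function(runQuant, baitId) {
  tab <- quantTable(runQuant)
  pafCol <- if ("paf_adj" %in% names(tab)) "paf_adj" else "paf"
  i <- match(baitId, tab$protein_id)
  if (is.na(i) || tab[[pafCol]][i] <= 0)
    stop("bait '", baitId, "' absent or zero in bait run '",
         runId(runQuant), "'")
  rel <- tab[[pafCol]] / tab[[pafCol]][i]
  rel[i] <- 1
  data.frame(run_id = runId(runQuant), protein_id = tab$protein_id,
             rel_paf = rel, top3_area = tab$top3_area,
             stringsAsFactors = FALSE)
}

#' Aggregate replicate runs into an abundance table
#'
#' Per protein, the mean and sample standard deviation (n - 1
#' denominator; 0 for a single run) of the relative PAF across all bait
#' runs, and the mean top-3 area.  By default a run in which the protein
#' was undetected contributes 0 to both means (\code{missing_as_zero});
#' with \code{missing_as_zero = FALSE} means are taken over detected runs
#' only.  Output values are kept at full precision; rounding to the
#' 2-decimal report format happens only on write
#' (\code{\link{buildReport}}).
#'
#' @param relTables list of per-run data.frames from
#'   \code{\link{relativeToBait}}.
#' @param proteomeDf proteome data.frame (for descriptions and MW).
#' @param baitId bait protein id.
#' @param categoryMap named character vector mapping protein ids to
#'   functional categories; unmapped ids become "other".
#' @param nControlRuns recorded in the result's metadata.
#' @param config parameter list (uses \code{missing_as_zero}).
#' @return an \linkS4class{AbundanceTable}.
#' @export
aggregateReplicates <- function(relTables, proteomeDf, baitId,
                                categoryMap = NULL, nControlRuns = 0L,
                                config = pullQuantConfig()) {
  stopifnot(length(relTables) >= 1L)
  nRuns <- length(relTables)
  all <- do.call(rbind, relTables)
  ids <- sort(unique(all$protein_id))
  relMat <- matrix(NA_real_, nrow = length(ids), ncol = nRuns,
                   dimnames = list(ids, NULL))
  areaMat <- relMat
  for (j in seq_len(nRuns)) {
    t <- relTables[[j]]
    relMat[t$protein_id, j] <- t$rel_paf
    areaMat[t$protein_id, j] <- t$top3_area
  }
  if (config$missing_as_zero) {
    relMat[is.na(relMat)] <- 0
    areaMat[is.na(areaMat)] <- 0
  }
  rowStat <- function(m, f) apply(m, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    f(x)
  })
  meanRel <- rowStat(relMat, mean)
  sdRel <- rowStat(relMat, function(x) if (length(x) > 1L) stats::sd(x) else 0)
  meanArea <- rowStat(areaMat, mean)
  nDet <- apply(relMat, 1L, function(x) sum(!is.na(x) & x > 0))
  ## the bait is 1 in every run by construction; pin it exactly
  if (baitId %in% ids) {
    meanRel[baitId] <- 1; sdRel[baitId] <- 0
  }
  m <- match(ids, proteomeDf$protein_id)
  cats <- if (is.null(categoryMap)) rep(NA_character_, length(ids)) else
    unname(categoryMap[ids])
  cats[is.na(cats)] <- "other"
  tab <- data.frame(
    protein_id = ids,
    description = ifelse(is.na(m), "", proteomeDf$description[m]),
    category = cats,
    mw_kda = ifelse(is.na(m), NA_real_, proteomeDf$mw_da[m] / 1000),
    mean_rel_paf = unname(meanRel),
    sd_rel_paf = unname(sdRel),
    mean_area = unname(meanArea),
    n_runs_detected = unname(as.integer(nDet)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("AbundanceTable", baitId = baitId, nBaitRuns = as.integer(nRuns),
      nControlRuns = as.integer(nControlRuns), table = tab,
      params = config)
}
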