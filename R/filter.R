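#' Target-decoy q-values for PSMs
#'
#' For every candidate score threshold \eqn{t} (each observed score), the
#' FDR is estimated as the number of decoy PSMs scoring at least \eqn{t}
#' divided by the number of target PSMs scoring at least \eqn{t} (at
#' least 1).  The q-value of a PSM is the smallest such estimate over all
#' thresholds that would still accept it (all \eqn{t \le} its score),
#' which makes q monotone non-increasing in score.  Decoy PSMs receive
#' q-values too but are never retained downstream.
#'
#' With no decoys present all q-values are 0; with no targets the decoy
#' q-values are computed against an empty target list (denominator
#' clamped at 1).
#'
#' @param psms PSM data.frame with \code{score} and \code{is_decoy}.
#' @return the same data.frame with a \code{q_value} column
#'   (overwritten if present).
#' @examples
#' psms <- data.frame(score = c(10, 9, 8, 7, 8.5),
#'                    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE))
#' computeQvalues(psms)$q_value
#' @export
computeQvalues <- function(psms) {
  stopifnot(all(c("score", "is_decoy") %in% names(psms)))
  n <- nrow(psms)
  if (n == 0L) { psms$q_value <- numeric(); return(psms) }
  ord <- order(psms$score, decreasing = TRUE)
  dec <- psms$is_decoy[ord]
  ## FDR at threshold = each sorted score: counts of decoys / targets at
  ## or above it. Ties share the threshold of the last tied element.
  cumDec <- cumsum(dec)
  cumTar <- cumsum(!dec)
  s <- psms$score[ord]
  ends <- which(c(s[-1L] != s[-n], TRUE))      # last index of each tie group
  lastTie <- rep(ends, times = diff(c(0L, ends)))
  fdr <- cumDec[lastTie] / pmax(1, cumTar[lastTie])
  ## q = min FDR over this and any lower threshold
  q <- rev(cummin(rev(fdr)))
  psms$q_value <- q[order(ord)]
  psms
}

#' PSM-level confidence filtering
#'
#' Retains PSMs that are top-ranked (\code{rank == 1}), mass-accurate
#' (\code{|mass_error_ppm| <= ppmTolerance}), pass the target-decoy FDR
#' threshold (\code{q_value <= fdrThreshold}) and are not decoys.  The
#' retained set is the intersection of the four criteria; for the audit
#' report each removed PSM is attributed to the first criterion it fails,
#' in the order rank, mass accuracy, FDR, decoy.
#'
#' @param psms PSM data.frame with q-values (see
#'   \code{\link{computeQvalues}}).
#' @param fdrThreshold q-value cutoff (default 0.01).
#' @param ppmTolerance maximum absolute mass error in ppm (default 10).
#' @param runId label for the report.
#' @return list with \code{psms} (retained rows) and \code{report}
#'   (a \linkS4class{FilterReport}).
#' @export
filterPsms <- function(psms, fdrThreshold = 0.01, ppmTolerance = 10,
                       runId = if (nrow(psms)) psms$run_id[1L] else "<none>") {
  if (!"q_value" %in% names(psms))
    stop("q-values not computed; call computeQvalues() first")
  okRank <- psms$rank == 1L
  okMass <- abs(psms$mass_error_ppm) <= ppmTolerance
  okFdr <- psms$q_value <= fdrThreshold
  okDecoy <- !psms$is_decoy
  keep <- okRank & okMass & okFdr & okDecoy
  firstFail <- ifelse(!okRank, "rank",
               ifelse(!okMass, "mass",
               ifelse(!okFdr, "fdr",
               ifelse(!okDecoy, "decoy", "none"))))
  counts <- c(
    input = nrow(psms),
    removed_rank = sum(firstFail == "rank"),
    removed_mass = sum(firstFail == "mass"),
    removed_fdr = sum(firstFail == "fdr"),
    removed_decoy = sum(firstFail == "decoy"),
    retained = sum(keep)
  )
  report <- new("FilterReport", runId = as.character(runId),
                counts = counts, proteinsDropped = character(),
                decoyFraction = if (nrow(psms))
                  mean(psms$is_decoy) else 0)
  list(psms = psms[keep, , drop = FALSE], report = report)
}

#' Protein-level minimum-peptide filter
#'
#' A protein passes when it is supported by at least \code{minPeptides}
#' distinct peptide sequences among the retained PSMs of the run,
#' counting across gel-segment fractions (evidence is pooled per run, not
#' per fraction).  Shared peptides count toward every mapped protein.
#'
#' @param psms retained PSMs of one run (post \code{\link{filterPsms}}).
#' @param minPeptides minimum distinct peptides (default 2).
#' @return character vector of passing protein ids.
#' @export
filterProteins <- function(psms, minPeptides = 2L) {
  if (nrow(psms) == 0L) return(character())
  long <- expandProteinIds(psms)
  u <- tapply(long$peptide_seq, long$protein_id,
              function(x) length(unique(x)))
  names(u)[u >= minPeptides]
}
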