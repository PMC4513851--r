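#' Published Leishmania eIF3 pull-down scenario
#'
#' Reference stoichiometries and molecular weights of the
#' \emph{Leishmania} eIF3 complex (bait: the tagged e subunit) and of the
#' translation factors that co-purify with it, as estimated by
#' bait-normalized PAF in replicate SBP-tag pull-downs.  These values
#' parameterize the default synthetic scenario used for parameter-recovery
#' testing.
#'
#' @param includeAssociated also return the associated initiation and
#'   elongation factors (default FALSE: the 12 complex subunits only).
#' @return data.frame with columns \code{protein_id} (short analog id),
#'   \code{protein} (subunit name), \code{stoichiometry} (relative PAF,
#'   bait = 1), \code{mw_kda}, \code{category}, \code{is_bait}.
#' @examples
#' leishEIF3Complex()
#' @export
leishEIF3Complex <- function(includeAssociated = FALSE) {
  sub <- data.frame(
    protein_id = c("IF3A", "IF3B", "IF3C", "IF3D", "IF3E", "IF3F",
                   "IF3G", "IF3H", "IF3I", "IF3J", "IF3K", "IF3L"),
    protein = paste0("LeishIF3", c("a", "b", "c", "d", "e", "f",
                                   "g", "h", "i", "j", "k", "l")),
    stoichiometry = c(0.65, 0.59, 0.47, 0.42, 1.00, 0.68,
                      0.48, 0.78, 0.34, 0.13, 0.67, 0.58),
    mw_kda = c(87.6, 80.7, 82.0, 60.6, 46.3, 36.7,
               28.8, 37.9, 45.4, 23.5, 26.3, 62.7),
    category = "eIF3 subunits",
    is_bait = FALSE,
    stringsAsFactors = FALSE
  )
  sub$is_bait[sub$protein_id == "IF3E"] <- TRUE
  if (!includeAssociated) return(sub)
  assoc <- data.frame(
    protein_id = c("IF1", "IF2A", "IF2B", "IF2G", "IF5", "IF1A",
                   "EF1B", "EF2", "EF1G", "EF1A"),
    protein = c("LeishIF1", "LeishIF2alpha", "LeishIF2beta",
                "LeishIF2gamma", "LeishIF5", "LeishIF1A",
                "EF1B", "EF2", "EF1gamma", "EF1alpha"),
    stoichiometry = c(0.51, 0.25, 0.17, 0.11, 0.19, 0.34,
                      0.32, 0.25, 0.12, 0.15),
    mw_kda = c(12.3, 46.6, 38.0, 52.5, 42.9, 18.6,
               25.6, 94.1, 46.2, 49.1),
    category = c(rep("initiation factors", 6L),
                 rep("elongation factors", 4L)),
    is_bait = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(sub, assoc)
}

CONTAMINANT_CATEGORIES <- c("ribosomal proteins", "chaperones",
                            "metabolic enzymes", "cytoskeleton",
                            "ubiquitination")

#' Ground truth for the eIF3 pull-down recovery scenario
#'
#' Builds a complete \linkS4class{GroundTruth} whose complex members carry
#' the stoichiometries and molecular weights of
#' \code{\link{leishEIF3Complex}}, plus \code{nContaminants} shared
#' background proteins present at equal expected abundance in bait and
#' control runs.  Protein sequences are synthesized to the published
#' masses; contaminant abundances are drawn log-normally around 0.5
#' (relative to the bait) with masses uniform in 20-120 kDa.
#'
#' @param seed master seed (drives the proteome synthesis and every run).
#' @param includeAssociated include the associated initiation/elongation
#'   factors in the complex (default FALSE).
#' @param nContaminants number of shared background proteins (default 20).
#' @param nBaitRuns,nControlRuns replicate counts (defaults 4 and 1).
#' @param depth,noiseCv,controlLevel,simParams passed to
#'   \code{\link{groundTruth}}.
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' gt <- eif3GroundTruth(seed = 1)
#' stoichiometry(gt)
#' @export
eif3GroundTruth <- function(seed = 1L, includeAssociated = FALSE,
                            nContaminants = 20L, nBaitRuns = 4L,
                            nControlRuns = 1L, depth = 0.7,
                            noiseCv = 0.1, controlLevel = 1,
                            simParams = list()) {
  cx <- leishEIF3Complex(includeAssociated = includeAssociated)
  withSeed(deriveSeed(seed, 0L), function() {
    nc <- as.integer(nContaminants)
    contIds <- if (nc) sprintf("CONT_%02d", seq_len(nc)) else character()
    contMw <- if (nc) stats::runif(nc, 20, 120) * 1000 else numeric()
    contAb <- if (nc) stats::rlnorm(nc, log(0.5), 0.5) else numeric()
    ids <- c(cx$protein_id, contIds)
    desc <- c(paste("synthetic analog of", cx$protein),
              if (nc) paste("synthetic contaminant", seq_len(nc)))
    cats <- c(cx$category,
              if (nc) rep_len(CONTAMINANT_CATEGORIES, nc))
    masses <- c(cx$mw_kda * 1000, contMw)
    proteomeDf <- buildProteome(ids, desc, masses, cats)
    groundTruth(
      proteome = proteomeDf,
      baitId = cx$protein_id[cx$is_bait],
      stoichiometry = stats::setNames(cx$stoichiometry, cx$protein_id),
      contaminants = stats::setNames(contAb, contIds),
      nBaitRuns = nBaitRuns, nControlRuns = nControlRuns,
      depth = depth, noiseCv = noiseCv, controlLevel = controlLevel,
      seed = seed, simParams = simParams)
  })
}
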