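#' Run the full AP-MS quantification pipeline
#'
#' Executes, for every run in the manifest: q-value computation, PSM
#' confidence filtering and the minimum-peptide rule; then quantifies
#' each run, subtracts the mock-bait control background, normalizes each
#' bait run to the bait protein, aggregates replicates into an
#' \linkS4class{AbundanceTable} and computes the functional-category
#' composition.  The first failing stage aborts with its name.
#'
#' @param manifest list as returned by \code{\link{readRunManifest}} (or
#'   the \code{manifest} element of \code{\link{simulateExperimentSet}}).
#' @param proteomeDf proteome data.frame from \code{\link{readFasta}}.
#' @param config parameter list from \code{\link{pullQuantConfig}} /
#'   \code{\link{loadConfig}}.
#' @param categoryMap named character vector (see
#'   \code{\link{readCategoryMap}}); NULL for all-"other".
#' @param outputDir if non-NULL, \code{\link{buildReport}} writes the
#'   result files there.
#' @param verbose log per-stage counts to the console.
#' @return list with \code{abundance} (\linkS4class{AbundanceTable}),
#'   \code{composition} (\linkS4class{CompositionSummary}),
#'   \code{filterReports} (list of \linkS4class{FilterReport}),
#'   \code{runQuants} (adjusted bait \linkS4class{RunQuant}s) and
#'   \code{files} (paths written, if any).
#' @examples
#' gt <- eif3GroundTruth(seed = 2, nContaminants = 3)
#' sim <- simulateExperimentSet(gt, tempfile())
#' res <- runPipeline(sim$manifest, proteome(gt), verbose = FALSE)
#' abundance(res$abundance)[1:3, ]
#' @export
runPipeline <- function(manifest, proteomeDf, config = pullQuantConfig(),
                        categoryMap = NULL, outputDir = NULL,
                        verbose = TRUE) {
  stage <- "manifest"
  res <- tryCatch({
    runs <- manifest$runs
    baitId <- manifest$bait_protein_id
    if (!baitId %in% proteomeDf$protein_id)
      stop("bait '", baitId, "' not present in proteome")
    say <- function(...) if (verbose) message(...)

    stage <- "filter"
    quants <- list(); reports <- list()
    for (i in seq_len(nrow(runs))) {
      psms <- readPsmTable(runs$psm_table[i],
                           decoyPrefix = config$decoy_prefix)
      psms <- computeQvalues(psms)
      f <- filterPsms(psms, fdrThreshold = config$fdr_threshold,
                      ppmTolerance = config$ppm_tolerance,
                      runId = runs$run_id[i])
      passing <- filterProteins(f$psms, minPeptides = config$min_peptides)
      dropped <- setdiff(
        unique(expandProteinIds(f$psms)$protein_id), passing)
      f$report@proteinsDropped <- dropped
      reports[[runs$run_id[i]]] <- f$report
      say(sprintf("[filter] run %s: %d -> %d PSMs, %d proteins pass",
                  runs$run_id[i], filterCounts(f$report)[["input"]],
                  filterCounts(f$report)[["retained"]], length(passing)))
      stage <- "quantify"
      quants[[runs$run_id[i]]] <- quantifyRun(
        f$psms, proteomeDf, passing, config,
        runId = runs$run_id[i], role = runs$role[i])
      stage <- "filter"
    }

    stage <- "subtract"
    baitQ <- quants[runs$run_id[runs$role == "bait"]]
    ctlQ <- quants[runs$run_id[runs$role == "control"]]
    adj <- subtractControl(baitQ, ctlQ)
    say(sprintf("[subtract] %d control run(s); %d proteins survive",
                length(ctlQ),
                length(unique(unlist(lapply(adj, function(q)
                  quantTable(q)$protein_id))))))

    anyRows <- any(vapply(adj, function(q) nrow(quantTable(q)) > 0L,
                          logical(1L)))
    if (anyRows) {
      stage <- "normalize"
      relTables <- lapply(adj, relativeToBait, baitId = baitId)

      stage <- "aggregate"
      ab <- aggregateReplicates(relTables, proteomeDf, baitId,
                                categoryMap = categoryMap,
                                nControlRuns = length(ctlQ),
                                config = config)
    } else {
      warning("no protein passed the filters in any bait run; ",
              "abundance table is empty")
      ab <- new("AbundanceTable", baitId = baitId,
                nBaitRuns = length(baitQ), nControlRuns = length(ctlQ),
                table = data.frame(
                  protein_id = character(), description = character(),
                  category = character(), mw_kda = numeric(),
                  mean_rel_paf = numeric(), sd_rel_paf = numeric(),
                  mean_area = numeric(), n_runs_detected = integer(),
                  stringsAsFactors = FALSE),
                params = config)
    }
    say(sprintf("[aggregate] %d proteins in abundance table",
                nrow(abundance(ab))))

    stage <- "composition"
    comp <- if (any(vapply(adj, function(q) nrow(quantTable(q)) > 0,
                           logical(1L))))
      compositionPercentages(adj, categoryMap) else NULL

    stage <- "report"
    files <- if (!is.null(outputDir))
      buildReport(ab, comp, reports, outputDir) else character()

    list(abundance = ab, composition = comp, filterReports = reports,
         runQuants = adj, files = files)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' Write the pipeline's report files
#'
#' Writes four deterministic text artifacts under \code{dir}:
#' \code{abundance.tsv} (the Table-1-style report, relative PAF and SD
#' rounded to 2 decimals, MW in kDa to 1 decimal),
#' \code{composition.tsv} (per-run and mean category percentages),
#' \code{filter_report.tsv} (per-run PSM filter counts) and
#' \code{run_log.json} (one JSON object with parameters and table sizes).
#' Identical inputs produce byte-identical files.
#'
#' @param abundanceTable an \linkS4class{AbundanceTable}.
#' @param composition a \linkS4class{CompositionSummary} or NULL.
#' @param filterReports list of \linkS4class{FilterReport}s.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
buildReport <- function(abundanceTable, composition, filterReports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             composition = file.path(dir, "composition.tsv"),
             filter = file.path(dir, "filter_report.tsv"),
             log = file.path(dir, "run_log.json"))

  tab <- abundance(abundanceTable)
  out <- data.frame(
    protein = tab$protein_id,
    description = tab$description,
    mean_area = signif(tab$mean_area, 4),
    rel_paf_mean = sprintf("%.2f", tab$mean_rel_paf),
    rel_paf_sd = sprintf("%.2f", tab$sd_rel_paf),
    mw_kda = sprintf("%.1f", tab$mw_kda),
    n_runs_detected = tab$n_runs_detected,
    category = tab$category,
    stringsAsFactors = FALSE)
  out <- out[order(-tab$mean_rel_paf, tab$protein_id), , drop = FALSE]
  utils::write.table(out, paths[["abundance"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(composition)) {
    pr <- perRunPercent(composition)
    compOut <- rbind(pr, mean = meanPercent(composition)[names(pr)])
    compOut <- data.frame(run = rownames(compOut),
                          round(compOut, 4), check.names = FALSE,
                          stringsAsFactors = FALSE)
  } else {
    compOut <- data.frame(run = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(compOut, paths[["composition"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fr <- do.call(rbind, lapply(filterReports, function(r) {
    data.frame(run_id = r@runId, t(filterCounts(r)),
               decoy_fraction = round(r@decoyFraction, 6),
               proteins_dropped = length(r@proteinsDropped),
               stringsAsFactors = FALSE)
  }))
  if (is.null(fr))
    fr <- data.frame(run_id = character(), stringsAsFactors = FALSE)
  utils::write.table(fr, paths[["filter"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  log <- list(
    bait = baitId(abundanceTable),
    n_bait_runs = abundanceTable@nBaitRuns,
    n_control_runs = abundanceTable@nControlRuns,
    parameters = abundanceTable@params,
    n_proteins = nrow(tab),
    categories = if (!is.null(composition))
      names(meanPercent(composition)) else character())
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA),
             paths[["log"]])
  paths
}
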