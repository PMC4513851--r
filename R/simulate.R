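## Synthetic AP-MS experiment generator.
##
## Detection model (deliberately minimal):
##   abundance a  = stoichiometry x log-normal run noise (complex members,
##                  bait runs only) or contaminant level x noise (always);
##   PSM counts   ~ Poisson(depth * a) per detectable tryptic peptide;
##   intensities  ~ log-normal around a * intensity_scale;
##   PSM scores   ~ Normal(mu_target, sd) for correct matches,
##                  Normal(mu_decoy, sd) for injected noise matches,
##                  which are split between target and decoy proteins so
##                  the target-decoy FDR filter has work to do;
##   mass errors  ~ Normal(0, 3) ppm for correct matches; a configured
##                  fraction of noise matches gets Uniform(-20, 20) ppm.

defaultSimParams <- function() {
  list(
    peptide_length_range = c(7, 30),  # detectable tryptic peptide window
    missed_cleavages = 2L,            # partial digestion: overlapping peptides
    score_mean_target = 10,
    score_mean_decoy = 4,
    score_sd = 1.5,
    intensity_scale = 1e8,            # area units, matches LTQ-Orbitrap scale
    intensity_sdlog = 0.5,
    psm_intensity_jitter = 0.1,
    noise_psm_rate = 0.3,             # noise PSMs per true PSM
    bad_mass_fraction = 0.5,          # noise PSMs with wild mass error
    rank2_rate = 0.05,                # true PSMs acquiring a rank-2 sibling
    noise_intensity_frac = 0.05,
    n_fractions = 3L                  # gel segments per run
  )
}

## Build one protein as a concatenation of fully detectable tryptic
## fragments: interior residues uniform over the 17 non-K/R/P letters
## (P allowed except at a fragment start, where it would suppress the
## upstream cleavage), each fragment terminated by K or R.  Fragment
## lengths are uniform on [7, 9], so every fragment falls inside the
## default detectable window and the number of detectable peptides grows
## proportionally with protein mass -- the regime in which unique-peptide
## counts are informative about abundance.
synthesizeSequence <- function(targetMassDa) {
  interior <- setdiff(names(AA_AVERAGE_MASS), c("K", "R"))
  first <- setdiff(interior, "P")
  frags <- character()
  mass <- WATER_MASS
  while (mass < targetMassDa - 900) {
    len <- sample(7:9, 1L)
    f <- paste0(paste(c(sample(first, 1L),
                        sample(interior, len - 2L, replace = TRUE)),
                      collapse = ""),
                sample(c("K", "R"), 1L))
    frags <- c(frags, f)
    mass <- mass + proteinMw(f) - WATER_MASS
  }
  if (mass < targetMassDa - 60) {
    len <- max(7L, min(9L, round((targetMassDa - mass) / 115)))
    f <- paste0(paste(c(sample(first, 1L),
                        sample(interior, len - 2L, replace = TRUE)),
                      collapse = ""),
                sample(c("K", "R"), 1L))
    frags <- c(frags, f)
  }
  paste(frags, collapse = "")
}

reverseSequence <- function(sequence) {
  vapply(sequence, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1L), USE.NAMES = FALSE)
}

## Assemble the full proteome data.frame (targets + reversed decoys) from
## id / description / target-mass vectors, enforcing the detectable-
## peptide guarantee with bounded retries.
buildProteome <- function(ids, descriptions, targetMassDa, categories,
                          minDetectable = 4L, decoyPrefix = "DECOY_",
                          lengthRange = c(7, 30), maxRetries = 20L) {
  seqs <- character(length(ids))
  for (i in seq_along(ids)) {
    ok <- FALSE
    for (try in seq_len(maxRetries)) {
      s <- synthesizeSequence(targetMassDa[i])
      npep <- length(unique(trypticDigest(s, 0L, lengthRange)))
      if (npep >= minDetectable) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not synthesize '", ids[i], "' with >= ", minDetectable,
           " detectable tryptic peptides (target mass ", targetMassDa[i],
           " Da too small?)")
    seqs[i] <- s
  }
  targets <- data.frame(
    protein_id = ids, description = descriptions, sequence = seqs,
    mw_da = proteinMwVec(seqs), is_decoy = FALSE,
    category = categories, stringsAsFactors = FALSE
  )
  decoys <- data.frame(
    protein_id = paste0(decoyPrefix, ids),
    description = paste("decoy of", ids),
    sequence = reverseSequence(seqs),
    mw_da = targets$mw_da, is_decoy = TRUE,
    category = "", stringsAsFactors = FALSE
  )
  rbind(targets, decoys)
}

#' Generate a random proteome with ground-truth scaffolding
#'
#' Synthesizes \code{nComplex} complex-member proteins (the first one is
#' the bait) and \code{nContaminants} background proteins, each built
#' from detectable tryptic fragments so that every protein is guaranteed
#' at least \code{minDetectable} distinct peptides in the 7-30 residue
#' window, plus one reversed-sequence decoy per target.  Deterministic
#' under \code{seed}.
#'
#' @param nComplex number of complex members including the bait (>= 1).
#' @param nContaminants number of shared background proteins.
#' @param lengthRange length-2 vector, protein lengths drawn uniformly in
#'   this range (residues, within [50, 2000]).
#' @param seed integer seed.
#' @param minDetectable guaranteed minimum of detectable tryptic peptides
#'   per protein (default min_peptides + 2 = 4).
#' @param decoyPrefix decoy id prefix.
#' @return list with \code{proteome} (data.frame, targets then decoys),
#'   \code{baitId}, \code{memberIds} (bait included),
#'   \code{contaminantIds}.
#' @examples
#' p <- generateProteome(3, 2, c(100, 300), seed = 7)
#' table(p$proteome$is_decoy)
#' @export
generateProteome <- function(nComplex, nContaminants,
                             lengthRange = c(150, 800), seed = 1L,
                             minDetectable = 4L, decoyPrefix = "DECOY_") {
  stopifnot(nComplex >= 1L, nContaminants >= 0L)
  if (lengthRange[1L] < 50 || lengthRange[2L] > 2000 ||
      lengthRange[1L] > lengthRange[2L])
    stop("'lengthRange' must be increasing and within [50, 2000] residues")
  withSeed(seed, function() {
    nm <- as.integer(nComplex); nc <- as.integer(nContaminants)
    ids <- c(sprintf("CPLX_%02d", seq_len(nm)),
             if (nc) sprintf("CONT_%02d", seq_len(nc)))
    lens <- sample(lengthRange[1L]:lengthRange[2L], nm + nc, replace = TRUE)
    desc <- c(paste("synthetic complex member", seq_len(nm)),
              if (nc) paste("synthetic contaminant", seq_len(nc)))
    cats <- c(rep("complex subunits", nm), rep("other", nc))
    proteome <- buildProteome(ids, desc, lens * 115, cats,
                              minDetectable = minDetectable,
                              decoyPrefix = decoyPrefix)
    list(proteome = proteome,
         baitId = ids[1L],
         memberIds = ids[seq_len(nm)],
         contaminantIds = if (nc) ids[nm + seq_len(nc)] else character())
  })
}

#' Construct a GroundTruth scenario
#'
#' @param proteome proteome data.frame (targets + decoys), e.g. from
#'   \code{\link{generateProteome}}.
#' @param baitId bait protein id; its stoichiometry must be 1.
#' @param stoichiometry named numeric of true member abundances relative
#'   to the bait (bait included at 1).
#' @param contaminants named numeric of background abundances (same scale
#'   as the bait).
#' @param nBaitRuns,nControlRuns replicate counts (defaults 4 and 1,
#'   mirroring a typical pull-down series with one mock-bait control).
#' @param depth expected PSMs per detectable peptide per unit abundance;
#'   the default keeps counts in the informative, non-saturated regime
#'   (see the package vignette).
#' @param noiseCv per-protein per-run abundance noise CV (default 0.1).
#' @param controlLevel contaminant abundance multiplier in control runs
#'   (default 1: same background in bait and control).
#' @param seed master seed for the whole experiment set.
#' @param simParams detection-model constants; see
#'   \code{pullQuant:::defaultSimParams} for the fields and defaults.
#' @return a \linkS4class{GroundTruth}.
#' @export
groundTruth <- function(proteome, baitId, stoichiometry,
                        contaminants = numeric(),
                        nBaitRuns = 4L, nControlRuns = 1L,
                        depth = 0.7, noiseCv = 0.1, controlLevel = 1,
                        seed = 1L, simParams = list()) {
  sp <- utils::modifyList(defaultSimParams(), simParams)
  new("GroundTruth",
      baitId = baitId,
      stoichiometry = stoichiometry,
      contaminants = contaminants,
      controlLevel = controlLevel,
      nBaitRuns = as.integer(nBaitRuns),
      nControlRuns = as.integer(nControlRuns),
      seed = as.integer(seed),
      noiseCv = as.numeric(noiseCv),
      depth = as.numeric(depth),
      proteome = proteome,
      simParams = sp)
}

#' Simulate one LC-MS/MS run of a pull-down
#'
#' Draws a complete PSM table for one bait or control run under the
#' generator's detection model.  In control runs the complex members
#' (bait included) are absent; contaminants are present in both roles at
#' equal expected abundance (times \code{controlLevel} in controls).
#' Injected noise PSMs map to random target and decoy proteins with a
#' low score channel, exercising the FDR filter downstream.  Peptides
#' are spread over gel-segment fractions by length.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param role "bait" or "control".
#' @param runId run identifier.
#' @param seed run-level seed (derive from the master seed for
#'   reproducible sets; \code{\link{simulateExperimentSet}} does this).
#' @return list with \code{run_id}, \code{role}, \code{psms} (PSM
#'   data.frame as in \code{\link{readPsmTable}}), \code{abundance}
#'   (named numeric, the true per-protein abundance used) and
#'   \code{n_true} (rows 1..n_true of \code{psms} are correct matches;
#'   the rest are injected noise).
#' @export
simulateRun <- function(gt, role = c("bait", "control"), runId,
                        seed = gt@seed) {
  role <- match.arg(role)
  sp <- gt@simParams
  prot <- gt@proteome
  targets <- prot[!prot$is_decoy, ]
  digests <- lapply(prot$sequence, function(s)
    unique(trypticDigest(s, sp$missed_cleavages, sp$peptide_length_range)))
  names(digests) <- prot$protein_id
  withSeed(seed, function() {
    ab <- stats::setNames(numeric(nrow(targets)), targets$protein_id)
    if (role == "bait")
      ab[names(gt@stoichiometry)] <- gt@stoichiometry
    if (length(gt@contaminants)) {
      lvl <- if (role == "control") gt@controlLevel else 1
      ab[names(gt@contaminants)] <- gt@contaminants * lvl
    }
    if (gt@noiseCv > 0) {
      sdl <- sqrt(log(1 + gt@noiseCv^2))
      ab <- ab * stats::rlnorm(length(ab), -sdl^2 / 2, sdl)
    }
    parts <- list()
    for (i in seq_len(nrow(targets))) {
      id <- targets$protein_id[i]
      a <- ab[[id]]
      if (a <= 0) next
      peps <- digests[[id]]
      if (!length(peps)) next
      k <- stats::rpois(length(peps), gt@depth * a)
      det <- which(k > 0)
      if (!length(det)) next
      base <- stats::rlnorm(length(det),
                            log(a * sp$intensity_scale), sp$intensity_sdlog)
      kk <- k[det]
      m <- sum(kk)
      parts[[length(parts) + 1L]] <- data.frame(
        pep = rep(peps[det], kk),
        pid = id,
        score = stats::rnorm(m, sp$score_mean_target, sp$score_sd),
        inten = rep(base, kk) * stats::rlnorm(m, 0, sp$psm_intensity_jitter),
        ppm = stats::rnorm(m, 0, 3),
        dec = FALSE, stringsAsFactors = FALSE)
    }
    true <- if (length(parts)) do.call(rbind, parts) else NULL
    nTrue <- if (is.null(true)) 0L else nrow(true)
    ## injected noise matches: random protein (target or decoy), random
    ## peptide of its digest, low score channel.  In control runs no PSM
    ## may map to a complex member: noise lands on contaminants and
    ## decoys only.
    nNoise <- stats::rpois(1L, sp$noise_psm_rate * max(nTrue, 1L))
    noise <- NULL
    cand <- seq_len(nrow(prot))
    if (role == "control")
      cand <- cand[!(prot$protein_id %in% names(gt@stoichiometry))]
    if (nNoise > 0 && length(cand)) {
      rows <- sample(cand, nNoise, replace = TRUE)
      npep <- vapply(rows, function(r) {
        peps <- digests[[r]]
        if (length(peps)) sample(peps, 1L) else NA_character_
      }, character(1L))
      keep <- !is.na(npep)
      rows <- rows[keep]; npep <- npep[keep]
      nk <- length(rows)
      if (nk) {
        bad <- stats::runif(nk) < sp$bad_mass_fraction
        noise <- data.frame(
          pep = npep,
          pid = prot$protein_id[rows],
          score = stats::rnorm(nk, sp$score_mean_decoy, sp$score_sd),
          inten = stats::rlnorm(
            nk, log(sp$intensity_scale * sp$noise_intensity_frac),
            sp$intensity_sdlog),
          ppm = ifelse(bad, stats::runif(nk, -20, 20),
                       stats::rnorm(nk, 0, 3)),
          dec = prot$is_decoy[rows], stringsAsFactors = FALSE)
      }
    }
    allp <- rbind(true, noise)
    n <- if (is.null(allp)) 0L else nrow(allp)
    pep <- allp$pep; pid <- allp$pid; score <- allp$score
    inten <- allp$inten; ppm <- allp$ppm; dec <- allp$dec
    if (n == 0L) {
      psms <- data.frame(
        spectrum_id = character(), run_id = character(),
        fraction_id = character(), peptide_seq = character(),
        protein_ids = character(), rank = integer(), score = numeric(),
        mass_error_ppm = numeric(), intensity = numeric(),
        is_decoy = logical(), stringsAsFactors = FALSE)
      return(list(run_id = runId, role = role, psms = psms, n_true = 0L,
                  abundance = ab))
    }
    ## gel-segment fractions assigned by peptide length (size separation)
    br <- stats::quantile(nchar(pep), probs = seq(0, 1,
                                                  length.out = sp$n_fractions + 1L))
    br[1L] <- -Inf; br[length(br)] <- Inf
    frac <- paste0("F", as.integer(cut(nchar(pep), breaks = unique(br),
                                       labels = FALSE)))
    specIdx <- seq_len(n)
    psms <- data.frame(
      spectrum_id = sprintf("%s.%06d", runId, specIdx),
      run_id = runId, fraction_id = frac, peptide_seq = pep,
      protein_ids = pid, rank = 1L, score = score,
      mass_error_ppm = ppm, intensity = inten, is_decoy = dec,
      stringsAsFactors = FALSE)
    ## rank-2 siblings for a fraction of true spectra (removed by the
    ## top-rank filter downstream)
    isTrue <- which(!psms$is_decoy & seq_len(n) <= nTrue)
    nR2 <- round(sp$rank2_rate * length(isTrue))
    if (nR2 > 0) {
      pick <- sample(isTrue, nR2)
      r2 <- psms[pick, , drop = FALSE]
      r2$rank <- 2L
      alt <- sample(cand, nR2, replace = TRUE)
      for (j in seq_len(nR2)) {
        peps <- digests[[alt[j]]]
        if (!length(peps)) next
        r2$peptide_seq[j] <- sample(peps, 1L)
        r2$protein_ids[j] <- prot$protein_id[alt[j]]
        r2$is_decoy[j] <- prot$is_decoy[alt[j]]
      }
      r2$score <- stats::rnorm(nR2, sp$score_mean_decoy, sp$score_sd)
      r2$intensity <- r2$intensity * 0.2
      psms <- rbind(psms, r2)
    }
    rownames(psms) <- NULL
    list(run_id = runId, role = role, psms = psms, abundance = ab, n_true = nTrue)
  })
}

#' Simulate and write a complete experiment set
#'
#' Draws all bait and control runs of a \linkS4class{GroundTruth}
#' scenario, writes the proteome FASTA, one PSM table per run, a
#' category map and a run manifest under \code{dir}, and returns the
#' manifest.  Per-run seeds derive deterministically from the master
#' seed, so the same ground truth always yields byte-identical files.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param dir output directory (created if needed).
#' @return list with \code{manifest} (as from
#'   \code{\link{readRunManifest}}), \code{manifest_path},
#'   \code{proteome_path}, \code{category_path} and \code{runs} (the
#'   in-memory simulated runs).
#' @examples
#' gt <- eif3GroundTruth(seed = 3, nContaminants = 2)
#' out <- simulateExperimentSet(gt, tempfile())
#' out$manifest$runs
#' @export
simulateExperimentSet <- function(gt, dir) {
  stopifnot(is(gt, "GroundTruth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- c(sprintf("B%d", seq_len(gt@nBaitRuns)),
           if (gt@nControlRuns > 0) sprintf("C%d", seq_len(gt@nControlRuns)))
  roles <- c(rep("bait", gt@nBaitRuns), rep("control", gt@nControlRuns))
  runs <- vector("list", length(ids))
  paths <- character(length(ids))
  for (i in seq_along(ids)) {
    runs[[i]] <- simulateRun(gt, roles[i], ids[i],
                             seed = deriveSeed(gt@seed, i))
    paths[i] <- file.path(dir, paste0("psm_", ids[i], ".tsv"))
    writePsmTable(runs[[i]]$psms, paths[i])
  }
  fastaPath <- file.path(dir, "proteome.fasta")
  writeFasta(gt@proteome, fastaPath)
  catPath <- file.path(dir, "categories.tsv")
  tg <- gt@proteome[!gt@proteome$is_decoy & nzchar(gt@proteome$category), ]
  writeCategoryMap(stats::setNames(tg$category, tg$protein_id), catPath)
  manifestPath <- file.path(dir, "manifest.tsv")
  runsDf <- data.frame(run_id = ids, role = roles, psm_table = paths,
                       stringsAsFactors = FALSE)
  writeRunManifest(runsDf, gt@baitId, manifestPath)
  list(manifest = list(runs = runsDf, bait_protein_id = gt@baitId),
       manifest_path = manifestPath, proteome_path = fastaPath,
       category_path = catPath, runs = runs)
}
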