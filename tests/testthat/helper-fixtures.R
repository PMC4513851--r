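# In-code fixtures shared across test files.

# Minimal PSM data.frame with sensible defaults; override any column.
makePsms <- function(n = 1L, ...) {
  base <- data.frame(
    spectrum_id = sprintf("s%03d", seq_len(n)),
    run_id = "R1",
    fraction_id = "F1",
    peptide_seq = sprintf("AAAAAA%s", LETTERS[(seq_len(n) - 1L) %% 26 + 1L]),
    protein_ids = "P1",
    rank = 1L,
    score = 10,
    mass_error_ppm = 0,
    intensity = 1e6,
    is_decoy = FALSE,
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

# Tiny proteome: ids and sequences given as named character vector.
makeProteome <- function(seqs, decoyPrefix = "DECOY_") {
  data.frame(
    protein_id = names(seqs),
    description = paste("test protein", names(seqs)),
    sequence = unname(seqs),
    mw_da = vapply(unname(seqs), proteinMw, numeric(1)),
    is_decoy = startsWith(names(seqs), decoyPrefix),
    category = "",
    stringsAsFactors = FALSE
  )
}

# Independent O(n^2) threshold-enumeration q-value oracle: for every PSM,
# try every observed score as a threshold t <= its own score and take the
# minimum decoy/target ratio among PSMs scoring >= t.
oracleQvalues <- function(scores, isDecoy) {
  n <- length(scores)
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (t in scores[scores <= scores[i]]) {
      nd <- sum(isDecoy & scores >= t)
      nt <- sum(!isDecoy & scores >= t)
      best <- min(best, nd / max(1, nt))
    }
    q[i] <- best
  }
  q
}

# Brute-force recount of per-run quantification by nested loops.
oracleQuant <- function(psms, proteomeDf, passing, cfg = pullQuantConfig()) {
  rows <- list()
  for (pid in sort(passing)) {
    peps <- character(); nS <- 0L; pepMax <- list()
    for (i in seq_len(nrow(psms))) {
      ids <- strsplit(psms$protein_ids[i], ";", fixed = TRUE)[[1]]
      if (!pid %in% ids) next
      nS <- nS + 1L
      p <- psms$peptide_seq[i]
      peps <- union(peps, p)
      pepMax[[p]] <- max(c(pepMax[[p]], psms$intensity[i]))
    }
    if (!length(peps)) next
    ints <- sort(unlist(pepMax), decreasing = TRUE)
    area <- mean(ints[seq_len(min(cfg$top_n_area, length(ints)))])
    mw <- proteomeDf$mw_da[proteomeDf$protein_id == pid]
    cnt <- if (cfg$paf_basis == "unique") length(peps) else nS
    rows[[pid]] <- data.frame(
      protein_id = pid, U = length(peps), S = nS, top3_area = area,
      paf = cnt / mw * cfg$paf_scale, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
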