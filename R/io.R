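## On-disk formats: FASTA proteomes (via Biostrings), PSM tables (TSV),
## category maps (TSV), run manifests (TSV with a bait comment line).
## Readers validate and fail loudly with line numbers; they never coerce
## malformed rows silently.

PSM_COLUMNS <- c("spectrum_id", "run_id", "fraction_id", "peptide_seq",
                 "protein_ids", "rank", "score", "mass_error_ppm",
                 "intensity", "is_decoy")

#' Read a proteome FASTA file
#'
#' Parses a FASTA file into one protein record per entry.  The protein id
#' is the first whitespace-delimited token of the header, the rest is the
#' description.  Molecular mass is computed from the sequence with
#' \code{\link{proteinMw}}; entries whose id starts with
#' \code{decoyPrefix} are flagged as decoys.
#'
#' @param path FASTA file.
#' @param decoyPrefix id prefix marking decoy entries (default "DECOY_").
#' @return data.frame with columns \code{protein_id}, \code{description},
#'   \code{sequence}, \code{mw_da}, \code{is_decoy}, \code{category}
#'   (empty string; fill from \code{\link{readCategoryMap}}), input order
#'   preserved.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 subunit a", "GGAV"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, decoyPrefix = "DECOY_") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(data.frame(protein_id = character(), description = character(),
                      sequence = character(), mw_da = numeric(),
                      is_decoy = logical(), category = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA: line ", nonblank[1L],
         " is not a header ('>' expected)")
  ## locate illegal residues up front so errors can name the line
  seqLines <- setdiff(nonblank, which(startsWith(trimws(lines), ">")))
  bad <- seqLines[!grepl("^[ACDEFGHIKLMNPQRSTVWY]*$",
                         trimws(lines[seqLines]))]
  if (length(bad))
    stop("illegal residue in FASTA at line ", bad[1L], ": '",
         trimws(lines[bad[1L]]), "'")
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(aas)
  if (any(!nzchar(seqs)))
    stop("empty sequence for entry '", ids[which(!nzchar(seqs))[1L]], "'")
  data.frame(
    protein_id = ids, description = desc, sequence = unname(seqs),
    mw_da = proteinMwVec(seqs),
    is_decoy = startsWith(ids, decoyPrefix),
    category = "", stringsAsFactors = FALSE
  )
}

#' Write a proteome FASTA file
#'
#' Inverse of \code{\link{readFasta}}: \code{readFasta(writeFasta(x, f))}
#' reproduces ids, descriptions and sequences exactly.
#'
#' @param records data.frame with at least \code{protein_id} and
#'   \code{sequence} (optionally \code{description}).
#' @param path output file.
#' @param width sequence line width (cosmetic).
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(records, path, width = 80L) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "sequence") %in% names(records)))
  if (nrow(records) && !all(checkSequence(records$sequence)))
    stop("invalid amino-acid sequence in records")
  hdr <- records$protein_id
  if ("description" %in% names(records)) {
    has <- nzchar(records$description)
    hdr[has] <- paste(records$protein_id[has], records$description[has])
  }
  aas <- Biostrings::AAStringSet(stats::setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(aas, path, width = width)
  invisible(path)
}

#' Read a PSM table
#'
#' Reads the tab-separated peptide-spectrum-match format used throughout
#' the pipeline.  Required columns: \code{spectrum_id}, \code{run_id},
#' \code{fraction_id}, \code{peptide_seq}, \code{protein_ids}
#' (";"-separated), \code{rank}, \code{score}, \code{mass_error_ppm},
#' \code{intensity}, \code{is_decoy}; an optional \code{q_value} column
#' is preserved.  Rows violating the PSM invariants (rank >= 1,
#' intensity >= 0, decoy flag consistent with the mapped proteins,
#' duplicate (spectrum_id, rank) within a run+fraction) are an error, not
#' a warning.
#'
#' @param path TSV file.
#' @param decoyPrefix protein-id prefix marking decoys, used to verify the
#'   \code{is_decoy} flag.
#' @return data.frame, one row per PSM, \code{protein_ids} kept as the
#'   ";"-joined string.
#' @export
readPsmTable <- function(path, decoyPrefix = "DECOY_") {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  missing <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing))
    stop("PSM table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  psms <- raw[, c(PSM_COLUMNS, intersect("q_value", names(raw)))]
  numify <- function(col, integer = FALSE) {
    v <- suppressWarnings(as.numeric(psms[[col]]))
    bad <- which(is.na(v) & !(psms[[col]] %in% c("NA", "")))
    bad <- c(bad, which(is.na(v) & col %in% c("rank", "score", "intensity",
                                              "mass_error_ppm")))
    bad <- sort(unique(bad))
    if (length(bad))
      stop("non-numeric '", col, "' in ", path, " at line ", bad[1L] + 1L,
           ": '", psms[[col]][bad[1L]], "'")
    if (integer) as.integer(v) else v
  }
  psms$rank <- numify("rank", integer = TRUE)
  psms$score <- numify("score")
  psms$mass_error_ppm <- numify("mass_error_ppm")
  psms$intensity <- numify("intensity")
  if ("q_value" %in% names(psms)) psms$q_value <- numify("q_value")
  psms$is_decoy <- toupper(psms$is_decoy) %in% c("TRUE", "T", "1")
  validatePsms(psms, decoyPrefix = decoyPrefix, path = path)
  psms
}

## Enforces the PeptideMatch invariants; `path` only decorates messages.
validatePsms <- function(psms, decoyPrefix = "DECOY_", path = "<psms>") {
  line <- function(i) i + 1L  # header offset
  if (any(psms$rank < 1L)) {
    i <- which(psms$rank < 1L)[1L]
    stop("PSM with rank < 1 in ", path, " at line ", line(i))
  }
  if (any(psms$intensity < 0)) {
    i <- which(psms$intensity < 0)[1L]
    stop("negative intensity in ", path, " at line ", line(i))
  }
  if (any(!nzchar(psms$protein_ids))) {
    i <- which(!nzchar(psms$protein_ids))[1L]
    stop("empty protein_ids in ", path, " at line ", line(i))
  }
  if ("q_value" %in% names(psms) &&
      any(!is.na(psms$q_value) &
          (psms$q_value < 0 | psms$q_value > 1)))
    stop("q_value outside [0, 1] in ", path)
  idl <- strsplit(psms$protein_ids, ";", fixed = TRUE)
  allDecoy <- vapply(idl, function(x) all(startsWith(x, decoyPrefix)),
                     logical(1L))
  if (any(psms$is_decoy != allDecoy)) {
    i <- which(psms$is_decoy != allDecoy)[1L]
    stop("is_decoy flag inconsistent with mapped proteins in ", path,
         " at line ", line(i))
  }
  key <- paste(psms$run_id, psms$fraction_id, psms$spectrum_id, psms$rank,
               sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate (spectrum_id, rank) within run+fraction in ", path,
         " at line ", line(i))
  }
  invisible(psms)
}

#' Write a PSM table
#'
#' @param psms PSM data.frame (see \code{\link{readPsmTable}}).
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @rdname readPsmTable
#' @export
writePsmTable <- function(psms, path) {
  cols <- c(PSM_COLUMNS, intersect("q_value", names(psms)))
  stopifnot(all(PSM_COLUMNS %in% names(psms)))
  out <- psms[, cols]
  out$is_decoy <- ifelse(out$is_decoy, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein-to-category map
#'
#' Two-column TSV without header: protein id, functional category.
#' Duplicate rows are tolerated when consistent and an error when they
#' conflict.  Ids absent from the map default to category "other"
#' downstream.
#'
#' @param path TSV file.
#' @return named character vector, names = protein ids.
#' @export
readCategoryMap <- function(path) {
  if (!file.exists(path)) stop("category map not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  if (!nrow(raw))
    return(stats::setNames(character(), character()))
  if (ncol(raw) != 2L)
    stop("category map must have exactly 2 tab-separated columns, found ",
         ncol(raw))
  ids <- raw[[1L]]; cats <- raw[[2L]]
  for (id in unique(ids[duplicated(ids)])) {
    u <- unique(cats[ids == id])
    if (length(u) > 1L)
      stop("conflicting categories for '", id, "': ",
           paste(u, collapse = " vs "))
  }
  keep <- !duplicated(ids)
  stats::setNames(cats[keep], ids[keep])
}

#' Write a protein-to-category map
#' @param map named character vector (names = protein ids).
#' @rdname readCategoryMap
#' @export
writeCategoryMap <- function(map, path) {
  utils::write.table(
    data.frame(names(map), unname(map), stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write run manifests
#'
#' A run manifest lists every LC-MS/MS run of a pull-down series with its
#' role ("bait" or "control") and the path of its PSM table, and names
#' the bait protein.  On disk it is a TSV with header
#' \code{run_id, role, psm_table} preceded by a comment line
#' \code{# bait_protein_id: <id>}.
#'
#' @param path manifest file.
#' @return \code{readRunManifest}: list with elements \code{runs} (a
#'   data.frame \code{run_id}, \code{role}, \code{psm_table}) and
#'   \code{bait_protein_id}.
#' @export
readRunManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path, warn = FALSE)
  bl <- grep("^#\\s*bait_protein_id\\s*:", lines, value = TRUE)
  if (!length(bl))
    stop("manifest ", path, " lacks the '# bait_protein_id: <id>' line")
  bait <- trimws(sub("^#\\s*bait_protein_id\\s*:", "", bl[1L]))
  if (!nzchar(bait)) stop("empty bait_protein_id in manifest ", path)
  body <- lines[!startsWith(lines, "#")]
  runs <- utils::read.delim(text = paste(body, collapse = "\n"),
                            sep = "\t", colClasses = "character",
                            stringsAsFactors = FALSE)
  need <- c("run_id", "role", "psm_table")
  missing <- setdiff(need, names(runs))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  badRole <- setdiff(unique(runs$role), c("bait", "control"))
  if (length(badRole))
    stop("manifest contains unknown role(s): ",
         paste(badRole, collapse = ", "))
  if (!any(runs$role == "bait"))
    stop("manifest must contain at least one bait run")
  if (anyDuplicated(runs$run_id))
    stop("duplicate run_id in manifest")
  list(runs = runs[, need], bait_protein_id = bait)
}

#' @param runs data.frame with columns \code{run_id}, \code{role},
#'   \code{psm_table}.
#' @param baitProteinId id of the bait protein.
#' @rdname readRunManifest
#' @export
writeRunManifest <- function(runs, baitProteinId, path) {
  stopifnot(all(c("run_id", "role", "psm_table") %in% names(runs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# bait_protein_id: ", baitProteinId), con)
  utils::write.table(runs[, c("run_id", "role", "psm_table")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ";"-joined protein_ids -> long format (one row per PSM x protein)
expandProteinIds <- function(psms) {
  idl <- strsplit(psms$protein_ids, ";", fixed = TRUE)
  n <- lengths(idl)
  out <- psms[rep(seq_len(nrow(psms)), n), , drop = FALSE]
  out$protein_id <- unlist(idl, use.names = FALSE)
  rownames(out) <- NULL
  out
}
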