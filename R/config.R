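#' Pipeline parameter set
#'
#' Builds the validated parameter list used throughout the pipeline.
#' \code{loadConfig} reads the same parameters from a plain
#' \code{key = value} text file (one pair per line, \code{#} comments
#' allowed); absent keys take their defaults, unknown keys are an error.
#'
#' @param fdr_threshold PSM q-value cutoff of the target-decoy filter
#'   (default 0.01, i.e. 1\% FDR).
#' @param min_peptides minimum number of distinct peptide sequences that
#'   must support a protein within a run (default 2).
#' @param ppm_tolerance maximum absolute PSM mass error in ppm
#'   (default 10).
#' @param decoy_prefix protein-id prefix marking decoy entries
#'   (default "DECOY_").
#' @param top_n_area number of most intense peptides averaged into the
#'   peak-area score (default 3).
#' @param paf_scale scale factor of the protein abundance factor
#'   (default 1e4).
#' @param paf_basis count entering the PAF: "unique" distinct peptides
#'   (default) or "spectral" PSM count.
#' @param missing_as_zero if TRUE (default) a protein undetected in a
#'   bait run contributes a relative PAF of 0 to the cross-run mean;
#'   if FALSE the mean is taken over detected runs only.
#' @return named list of validated parameters.
#' @examples
#' cfg <- pullQuantConfig(fdr_threshold = 0.05)
#' cfg$fdr_threshold
#' @export
pullQuantConfig <- function(fdr_threshold = 0.01,
                            min_peptides = 2L,
                            ppm_tolerance = 10,
                            decoy_prefix = "DECOY_",
                            top_n_area = 3L,
                            paf_scale = 1e4,
                            paf_basis = c("unique", "spectral"),
                            missing_as_zero = TRUE) {
  paf_basis <- match.arg(paf_basis)
  cfg <- list(
    fdr_threshold = as.numeric(fdr_threshold),
    min_peptides = as.integer(min_peptides),
    ppm_tolerance = as.numeric(ppm_tolerance),
    decoy_prefix = as.character(decoy_prefix),
    top_n_area = as.integer(top_n_area),
    paf_scale = as.numeric(paf_scale),
    paf_basis = paf_basis,
    missing_as_zero = isTRUE(missing_as_zero)
  )
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  with(cfg, {
    if (is.na(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1)
      stop("'fdr_threshold' must be in (0, 1]")
    if (is.na(min_peptides) || min_peptides < 1L)
      stop("'min_peptides' must be >= 1")
    if (is.na(ppm_tolerance) || ppm_tolerance <= 0)
      stop("'ppm_tolerance' must be > 0")
    if (!nzchar(decoy_prefix))
      stop("'decoy_prefix' must be non-empty")
    if (is.na(top_n_area) || top_n_area < 1L)
      stop("'top_n_area' must be >= 1")
    if (is.na(paf_scale) || paf_scale <= 0)
      stop("'paf_scale' must be > 0")
  })
  invisible(cfg)
}

#' @param path for \code{loadConfig}, path to a key = value text file.
#' @rdname pullQuantConfig
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- pullQuantConfig()
  logical_keys <- "missing_as_zero"
  char_keys <- c("decoy_prefix", "paf_basis")
  int_keys <- c("min_peptides", "top_n_area")
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key=value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults))
      stop("unknown config key: '", key, "'")
    vals[[key]] <-
      if (key %in% char_keys) val
      else if (key %in% logical_keys) as.logical(val)
      else if (key %in% int_keys) {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v) || v != round(v))
          stop("config key '", key, "' must be an integer, got '", val, "'")
        as.integer(v)
      } else {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v))
          stop("config key '", key, "' must be numeric, got '", val, "'")
        v
      }
  }
  do.call(pullQuantConfig, utils::modifyList(defaults, vals))
}
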