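## Average (chemical) residue masses, Da. Sum over residues + one water
## gives the average molecular mass of the intact chain.
AA_AVERAGE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.01528

#' Average molecular mass of a protein
#'
#' Sums standard average residue masses over the sequence and adds one
#' water (18.015 Da).  This is the molecular weight used as the PAF
#' denominator and reported (in kDa) in abundance tables.
#'
#' @param sequence amino-acid string, uppercase, 20-letter alphabet.
#' @return molecular mass in Daltons.
#' @examples
#' proteinMw("GG")   # 132.12 Da
#' @export
proteinMw <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("'sequence' must be a single non-empty amino-acid string")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- AA_AVERAGE_MASS[res]
  if (anyNA(m))
    stop("illegal residue(s) in sequence: ",
         paste(unique(res[is.na(m)]), collapse = ", "))
  sum(m) + WATER_MASS
}

## Vectorized over sequences; used by the generator and FASTA reader.
proteinMwVec <- function(sequences) {
  vapply(sequences, proteinMw, numeric(1L), USE.NAMES = FALSE)
}

checkSequence <- function(sequence) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
}
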