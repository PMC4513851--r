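#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine (K) or arginine (R),
#' except when the next residue is proline (the Keil rule).  With
#' \code{missedCleavages = m}, every concatenation of up to \code{m + 1}
#' adjacent fragments is also produced.  Peptides outside
#' \code{lengthRange} are dropped after missed-cleavage expansion.
#'
#' @param sequence amino-acid string.
#' @param missedCleavages integer in 0..2, number of missed cleavage
#'   sites allowed.
#' @param lengthRange numeric length-2 vector, inclusive peptide-length
#'   window (default c(7, 30), the typical detectable range of a tryptic
#'   LC-MS/MS peptide).
#' @return character vector of peptides in N- to C-terminal order
#'   (fully-cleaved fragments first at each start position); possibly
#'   empty.
#' @examples
#' trypticDigest("MKAYRPLKGFR", 0, c(1, 30))  # "MK" "AYRPLK" "GFR"
#' trypticDigest("AAAA", 0, c(1, 30))         # no cleavage site
#' @export
trypticDigest <- function(sequence, missedCleavages = 0L,
                          lengthRange = c(7, 30)) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (!missedCleavages %in% 0:2)
    stop("'missedCleavages' must be 0, 1 or 2")
  if (length(lengthRange) != 2L || lengthRange[1L] > lengthRange[2L])
    stop("'lengthRange' must be an increasing length-2 vector")
  if (nchar(sequence) == 0L) return(character())
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  ## cleavage after position i: K/R at i, not followed by P
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut == n | res[pmin(cut + 1L, n)] != "P"]
  bounds <- c(0L, cut[cut < n], n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nfrag <- length(starts)
  out <- character()
  for (i in seq_len(nfrag)) {
    for (m in 0:missedCleavages) {
      j <- i + m
      if (j > nfrag) break
      out <- c(out, substr(sequence, starts[i], ends[j]))
    }
  }
  len <- nchar(out)
  out[len >= lengthRange[1L] & len <= lengthRange[2L]]
}
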