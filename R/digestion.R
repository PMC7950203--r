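#' In-silico tryptic digestion options
#'
#' Trypsin cleaves after Lys (K) and Arg (R). With `proline_rule = TRUE` a
#' K/R immediately followed by Pro is not cleaved (Keil rule). The defaults
#' (no missed cleavages, minimum length 6, proline rule off) define the set of
#' distinct observable peptides used as the RPSM denominator; search-engine
#' emulation typically uses `max_missed = 2`.
#'
#' @param max_missed Maximum number of missed cleavage sites, 0-5.
#' @param proline_rule Suppress cleavage before proline?
#' @param min_length Minimum peptide length in residues.
#' @param max_length Maximum peptide length (`Inf` for unlimited).
#' @return A list of class `"digest_options"`.
#' @export
digest_options <- function(max_missed = 0L, proline_rule = FALSE,
                           min_length = 6L, max_length = Inf) {
  if (max_missed < 0 || max_missed > 5) stop("max_missed must be in 0..5")
  if (min_length < 1) stop("min_length must be >= 1")
  if (max_length < min_length) stop("max_length must be >= min_length")
  structure(list(max_missed = as.integer(max_missed),
                 proline_rule = isTRUE(proline_rule),
                 min_length = as.integer(min_length),
                 max_length = max_length),
            class = "digest_options")
}

# Cleavage boundaries of a sequence: 0, every position after which trypsin
# cuts, and the final position. Segments between consecutive boundaries are
# the zero-missed-cleavage peptides.
tryptic_boundaries <- function(chars, proline_rule) {
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n]
  if (proline_rule && length(sites) > 0L)
    sites <- sites[chars[sites + 1L] != "P"]
  c(0L, sites, n)
}

#' Digest a protein sequence with trypsin in silico
#'
#' Returns every fully tryptic peptide (both ends at a cleavage site or a
#' sequence terminus) with at most `opts$max_missed` internal missed cleavage
#' sites and length within `[min_length, max_length]`, sorted by start
#' position then length.
#'
#' @param sequence Amino-acid string over the standard 20-letter alphabet.
#' @param opts Options from [digest_options()].
#' @return data.frame with columns `peptide`, `start` (1-based), `missed`.
#' @export
digest <- function(sequence, opts = digest_options()) {
  validate_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  b <- tryptic_boundaries(chars, opts$proline_rule)
  n_seg <- length(b) - 1L
  pep <- character(0); start <- integer(0); missed <- integer(0)
  for (i in seq_len(n_seg)) {
    for (j in 0:min(opts$max_missed, n_seg - i)) {
      from <- b[i] + 1L
      to <- b[i + 1L + j]
      len <- to - from + 1L
      if (len >= opts$min_length && len <= opts$max_length) {
        pep <- c(pep, substr(sequence, from, to))
        start <- c(start, from)
        missed <- c(missed, j)
      }
    }
  }
  ord <- order(start, nchar(pep))
  data.frame(peptide = pep[ord], start = start[ord], missed = missed[ord],
             stringsAsFactors = FALSE)
}

#' Count predicted tryptic peptides
#'
#' The length of the [digest()] output; with the default options this is the
#' RPSM denominator (distinct fully tryptic peptides, no missed cleavages,
#' at least 6 residues).
#'
#' @inheritParams digest
#' @return Non-negative integer count.
#' @export
count_predicted_peptides <- function(sequence, opts = digest_options()) {
  nrow(digest(sequence, opts))
}
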