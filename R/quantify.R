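#' RPSM: spectra normalized to predicted peptides
#'
#' `RPSM = 100 * PSM / n_predicted`, where `n_predicted` is the number of
#' predicted tryptic peptides of the protein. Proteins yielding no predicted
#' peptides must be excluded upstream; dividing by zero is an error, never a
#' silent `Inf`.
#'
#' @param psm Non-negative spectral count(s).
#' @param n_predicted Positive predicted-peptide count(s).
#' @return Numeric RPSM value(s).
#' @export
compute_rpsm <- function(psm, n_predicted) {
  if (any(psm < 0)) stop("PSM counts must be non-negative")
  if (any(n_predicted < 1))
    stop("protein yields no predicted peptides")
  100 * psm / n_predicted
}

#' Aggregate replicate spectral counts into RPSM records
#'
#' One record per protein in the table: per-replicate RPSM values, their
#' arithmetic mean, the accumulated (summed) PSM, and whether the protein was
#' detected in every replicate.
#'
#' @param table A `"psm_table"`.
#' @param denominators Named integer vector: protein id -> predicted-peptide
#'   count. Must cover every id in the table.
#' @return data.frame with columns `id`, `n_predicted`, `accumulated_psm`,
#'   `mean_rpsm`, `in_all_replicates`, and one `rpsm_<rep>` column per
#'   replicate.
#' @export
aggregate_replicates <- function(table, denominators) {
  stopifnot(inherits(table, "psm_table"))
  ids <- rownames(table$counts)
  missing <- ids[!(ids %in% names(denominators))]
  if (length(missing) > 0L)
    stop("missing predicted-peptide denominator for protein: ", missing[1])
  den <- denominators[ids]
  rpsm <- sweep(100 * table$counts, 1, den, "/")
  colnames(rpsm) <- paste0("rpsm_", colnames(table$counts))
  out <- data.frame(id = ids,
                    n_predicted = as.integer(den),
                    accumulated_psm = as.integer(rowSums(table$counts)),
                    mean_rpsm = rowMeans(rpsm),
                    in_all_replicates = apply(table$counts > 0, 1, all),
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(rpsm, row.names = NULL))
}

#' Replicate dispersion of RPSM values
#'
#' Range over mean (`(max - min) / mean`), the reproducibility measure used
#' to screen low-count proteins.
#'
#' @param rpsm Numeric vector of per-replicate RPSM values.
#' @return Dispersion fraction, `NA` for an all-zero protein.
#' @export
rpsm_dispersion <- function(rpsm) {
  m <- mean(rpsm)
  if (m == 0) return(NA_real_)
  (max(rpsm) - min(rpsm)) / m
}

#' Summarize identified proteins per replicon
#'
#' Counts the members of `ids` on each replicon of the proteome and reports
#' each count as a percentage (one decimal, round-half-away-from-zero) of
#' either the column total or an explicitly supplied denominator. An explicit
#' denominator reproduces published tables whose per-replicon counts do not
#' sum to the printed total.
#'
#' @param ids Character vector of protein ids (must all be in the proteome).
#' @param proteome data.frame from [read_proteome()].
#' @param denominator `"column_total"` (default) or a positive number.
#' @param replicon_levels Optional replicon ordering for the output.
#' @return data.frame with columns `replicon`, `count`, `percent` (numeric,
#'   1 decimal), `percent_label` (e.g. `"(81.6%)"`).
#' @export
replicon_summary <- function(ids, proteome, denominator = "column_total",
                             replicon_levels = NULL) {
  unknown <- setdiff(ids, proteome$id)
  if (length(unknown) > 0L)
    stop("id not present in proteome: ", unknown[1])
  repl <- proteome$replicon[match(ids, proteome$id)]
  if (is.null(replicon_levels)) replicon_levels <- unique(proteome$replicon)
  counts <- table(factor(repl, levels = replicon_levels))
  den <- if (identical(denominator, "column_total")) sum(counts) else {
    if (!is.numeric(denominator) || denominator <= 0)
      stop("denominator must be 'column_total' or a positive number")
    denominator
  }
  pct <- round_half_away(100 * as.integer(counts) / den, 1L)
  data.frame(replicon = replicon_levels,
             count = as.integer(counts),
             percent = pct,
             percent_label = sprintf("(%s%%)", format_percent(100 * as.integer(counts) / den)),
             stringsAsFactors = FALSE)
}

#' Percent reduction of a treatment mean relative to a reference
#'
#' `100 * (reference - treatment) / reference`, reported rounded to the
#' nearest whole percent (half away from zero), the convention for symbiotic
#' performance comparisons such as shoot nitrogen accumulation.
#'
#' @param mean_reference Positive reference mean.
#' @param mean_treatment Treatment mean.
#' @param raw If `TRUE`, return the unrounded percentage.
#' @return Percentage value.
#' @export
percent_reduction <- function(mean_reference, mean_treatment, raw = FALSE) {
  if (any(mean_reference <= 0)) stop("mean_reference must be > 0")
  p <- 100 * (mean_reference - mean_treatment) / mean_reference
  if (raw) p else round_half_away(p, 0L)
}
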