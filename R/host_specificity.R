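#' Call host-specific proteins from replicate presence/absence
#'
#' A protein is specific to host A when it is detected (PSM > 0) in every A
#' replicate, its spectra accumulated over the A replicates reach
#' `min_accumulated`, and it is absent (PSM = 0, including "not listed") from
#' every B replicate; symmetrically for B. The two call sets are disjoint by
#' construction.
#'
#' @param table_a,table_b `"psm_table"` objects for the two hosts (replicate
#'   numbers may differ between hosts).
#' @param min_accumulated Accumulated-spectra floor applied to the detecting
#'   host (default 10).
#' @return List with elements `a` and `b`, each a data.frame of calls with
#'   columns `id`, `host`, `accumulated_psm`, `n_replicates_present`.
#' @export
call_host_specific <- function(table_a, table_b, min_accumulated = 10L) {
  stopifnot(inherits(table_a, "psm_table"), inherits(table_b, "psm_table"))
  ids <- union(rownames(table_a$counts), rownames(table_b$counts))
  get_counts <- function(tab, id) {
    if (id %in% rownames(tab$counts)) tab$counts[id, ] else
      rep(0L, tab$n_replicates)
  }
  call_one_side <- function(tab_det, tab_other, host) {
    keep <- vapply(ids, function(id) {
      det <- get_counts(tab_det, id)
      oth <- get_counts(tab_other, id)
      all(det > 0L) && sum(det) >= min_accumulated && all(oth == 0L)
    }, logical(1))
    called <- ids[keep]
    acc <- vapply(called, function(id) sum(get_counts(tab_det, id)), numeric(1))
    data.frame(id = called, host = rep(host, length(called)),
               accumulated_psm = as.integer(acc),
               n_replicates_present = rep(tab_det$n_replicates, length(called)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(a = call_one_side(table_a, table_b, table_a$host),
       b = call_one_side(table_b, table_a, table_b$host))
}

#' Classify an iTRAQ pea/lentil ratio
#'
#' A ratio at or above `threshold` is pea-overrepresented, at or below
#' `1/threshold` lentil-overrepresented, anything in between not significant.
#' Both boundaries are inclusive, so published tables listing ratios of
#' exactly 2.00 and 0.50 among the over-represented sets are reproduced.
#'
#' @param ratio Positive pea/lentil ratio(s).
#' @param threshold Significance threshold, must exceed 1 (default 2).
#' @return Character vector over `{"pea_over", "lentil_over",
#'   "not_significant"}`.
#' @export
classify_itraq <- function(ratio, threshold = 2.0) {
  if (threshold <= 1) stop("itraq threshold must be > 1")
  if (any(ratio <= 0)) stop("iTRAQ ratios must be positive")
  ifelse(ratio >= threshold, "pea_over",
         ifelse(ratio <= 1 / threshold, "lentil_over", "not_significant"))
}

#' Reconcile presence/absence calls with iTRAQ classification
#'
#' Joins the two differential approaches per protein. A protein absent from
#' the iTRAQ table is "not_measurable" (spectral absence in one host usually
#' precludes a ratio). The two methods agree when they point at the same host
#' or when one of them is silent.
#'
#' @param calls Result of [call_host_specific()].
#' @param itraq data.frame with columns `id` and `ratio`.
#' @param host_a,host_b Which host label of `calls` corresponds to the ratio
#'   numerator (pea) and denominator (lentil).
#' @param threshold iTRAQ significance threshold.
#' @return data.frame with columns `id`, `presence_call`, `itraq_label`,
#'   `agreement`.
#' @export
reconcile_calls <- function(calls, itraq, host_a = "pea", host_b = "lentil",
                            threshold = 2.0) {
  ids <- unique(c(calls$a$id, calls$b$id, itraq$id))
  presence <- rep("none", length(ids))
  presence[ids %in% calls$a$id] <- host_a
  presence[ids %in% calls$b$id] <- host_b
  idx <- match(ids, itraq$id)
  label <- rep("not_measurable", length(ids))
  has_ratio <- !is.na(idx)
  label[has_ratio] <- classify_itraq(itraq$ratio[idx[has_ratio]], threshold)
  itraq_host <- ifelse(label == "pea_over", host_a,
                       ifelse(label == "lentil_over", host_b, NA_character_))
  agreement <- presence == "none" | is.na(itraq_host) | presence == itraq_host
  data.frame(id = ids, presence_call = presence, itraq_label = label,
             agreement = agreement, stringsAsFactors = FALSE)
}
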