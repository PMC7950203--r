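#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rnorm runif setNames
#' @importFrom utils read.delim write.table count.fields
NULL

# Standard 20-letter amino-acid alphabet; ambiguity codes are rejected at parse
# time so every downstream stage can assume a clean sequence.
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Analysis configuration
#'
#' Bundles the tunable cut-offs of the pipeline: the accumulated-spectra floor
#' for host-specific calls, the iTRAQ significance threshold, in-silico
#' digestion options, isoelectric-point bin boundaries, and the
#' identity/coverage cut-offs of the NCR contig matching step.
#'
#' @param min_accumulated_spectra Minimum summed spectra across the detecting
#'   host's replicates for a host-specific call (default 10).
#' @param itraq_threshold Fold-change threshold on the pea/lentil ratio; a
#'   ratio `>= itraq_threshold` is pea-overrepresented and `<= 1/threshold`
#'   lentil-overrepresented, boundaries inclusive. Must exceed 1.
#' @param digest Digestion options from [digest_options()], used for the RPSM
#'   denominator.
#' @param pi_bins Two strictly increasing pH boundaries separating anionic /
#'   neutral / cationic mature peptides (default `c(6.5, 7.5)`).
#' @param min_identity,min_coverage Percent cut-offs (strict `>`) for
#'   candidate-to-ORF matches.
#' @param seed Integer seed for any randomized stage.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(min_accumulated_spectra = 10L,
                            itraq_threshold = 2.0,
                            digest = digest_options(),
                            pi_bins = c(6.5, 7.5),
                            min_identity = 90,
                            min_coverage = 50,
                            seed = 1L) {
  if (min_accumulated_spectra < 0) stop("min_accumulated_spectra must be >= 0")
  if (itraq_threshold <= 1) stop("itraq_threshold must be > 1")
  if (length(pi_bins) != 2L || diff(pi_bins) <= 0)
    stop("pi_bins must be two strictly increasing boundaries")
  if (min_identity < 0 || min_identity > 100 || min_coverage < 0 || min_coverage > 100)
    stop("identity/coverage cut-offs must lie in [0, 100]")
  structure(list(min_accumulated_spectra = as.integer(min_accumulated_spectra),
                 itraq_threshold = itraq_threshold,
                 digest = digest,
                 pi_bins = pi_bins,
                 min_identity = min_identity,
                 min_coverage = min_coverage,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

nod_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Round half away from zero
#'
#' Fixed-decimal rounding in which a residual of exactly 5 in the next digit
#' moves away from zero, matching the convention used for all reported
#' percentages (e.g. `100 * 901/1104` renders as `81.6`).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a percentage to one decimal
#'
#' @param x Percentage value(s) on the 0-100 scale.
#' @return Character vector such as `"81.6"`.
#' @export
format_percent <- function(x) {
  sprintf("%.1f", round_half_away(x, 1L))
}

validate_sequence <- function(seq, id = "<sequence>") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0L)
    stop(sprintf("invalid amino-acid character '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], id))
  invisible(TRUE)
}

#' Read a proteome FASTA with replicon annotation
#'
#' Replicons are read from a `replicon=<label>` token in the FASTA header or,
#' if absent, from a two-column tab-separated file (`id`, `replicon`). When a
#' replicon vocabulary is supplied, labels outside it map to `"unassigned"`.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param replicon_map Optional TSV path mapping protein id to replicon.
#' @param replicon_levels Optional character vector of admissible labels.
#' @return A data.frame with columns `id`, `replicon`, `sequence`, input order
#'   preserved.
#' @export
read_proteome <- function(path, replicon_map = NULL, replicon_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    return(data.frame(id = character(), replicon = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate protein id in proteome: ", dup[1])
  repl <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("replicon=\\S+", h))
    if (length(m) == 1L) sub("^replicon=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(replicon_map)) {
    map <- read.delim(replicon_map, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("id", "replicon"))
    idx <- match(ids, map$id)
    repl[is.na(repl)] <- map$replicon[idx[is.na(repl)]]
  }
  repl[is.na(repl)] <- "unassigned"
  if (!is.null(replicon_levels))
    repl[!(repl %in% replicon_levels)] <- "unassigned"
  seqs <- as.character(aa)
  for (i in seq_along(seqs)) validate_sequence(seqs[i], ids[i])
  data.frame(id = ids, replicon = repl, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a proteome as FASTA
#'
#' Headers carry the replicon as a `replicon=<label>` token so that
#' [read_proteome()] round-trips the annotation.
#'
#' @param proteome data.frame as returned by [read_proteome()].
#' @param path Output file.
#' @export
write_proteome <- function(proteome, path) {
  lines <- character(0)
  if (nrow(proteome) > 0L)
    lines <- as.vector(rbind(sprintf(">%s replicon=%s", proteome$id, proteome$replicon),
                             proteome$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a PSM table
#'
#' @param counts Integer matrix of spectra counts, rows named by protein id,
#'   one column per replicate.
#' @param host Host label.
#' @return Object of class `"psm_table"`.
#' @export
psm_table <- function(counts, host) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have protein ids as rownames")
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0))
    stop("PSM counts must be non-negative integers")
  structure(list(host = host, counts = counts,
                 n_replicates = ncol(counts)),
            class = "psm_table")
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("PSM table for host '%s': %d proteins x %d replicates\n",
              x$host, nrow(x$counts), x$n_replicates))
  invisible(x)
}

#' Read a per-replicate PSM count table
#'
#' Expects a tab-separated file whose header is
#' `protein_id<TAB>rep1<TAB>...<TAB>repN` and whose cells are non-negative
#' integers. Proteins absent from the table are treated downstream as zero in
#' every replicate.
#'
#' @param path TSV file.
#' @param host Host label attached to the table.
#' @return Object of class `"psm_table"`.
#' @export
read_psm_table <- function(path, host) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) stop("empty PSM table (no header): ", path)
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged PSM table '%s': row %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  n_rep <- ncol(df) - 1L
  if (n_rep < 1L) stop("PSM table must have at least one replicate column")
  if (nrow(df) == 0L) {
    counts <- matrix(integer(0), nrow = 0, ncol = n_rep,
                     dimnames = list(character(0), colnames(df)[-1]))
    return(psm_table(counts, host))
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid PSM count '%s' at row %d, column %d of %s",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2] + 1L, path))
  counts <- matrix(as.integer(num), nrow = nrow(num),
                   dimnames = list(df[[1]], colnames(df)[-1]))
  psm_table(counts, host)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]; write-then-read reproduces counts exactly.
#'
#' @param table A `"psm_table"`.
#' @param path Output TSV file.
#' @export
write_psm_table <- function(table, path) {
  df <- data.frame(protein_id = rownames(table$counts),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- setNames(df, c("protein_id", colnames(table$counts)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables to a directory
#'
#' Each element of `tables` (a named list of data.frames) is written as
#' `<name>.tsv` with a deterministic column order; reruns on identical inputs
#' produce byte-identical files.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
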