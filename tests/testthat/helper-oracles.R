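# Independent oracles used by the property-style tests. Each is written as a
# direct transcription of the definition, favoring exhaustive enumeration
# over efficiency, so it shares no code path with the implementation.

# Brute-force tryptic digestion: enumerate every substring, keep those whose
# boundaries sit on cleavage sites or termini and whose internal cleavage
# count does not exceed the allowance.
brute_digest <- function(sequence, max_missed = 0, proline_rule = FALSE,
                         min_length = 1, max_length = Inf) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  if (proline_rule && length(cuts) > 0) cuts <- cuts[chars[cuts + 1] != "P"]
  bounds <- c(0, cuts, n)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!((i - 1) %in% bounds) || !(j %in% bounds)) next
      internal <- sum(cuts >= i & cuts < j)
      len <- j - i + 1
      if (internal > max_missed || len < min_length || len > max_length) next
      out <- rbind(out, data.frame(peptide = substr(sequence, i, j),
                                   start = i, missed = internal,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(peptide = character(), start = integer(),
                      missed = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$start, nchar(out$peptide)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_aa <- function(len) {
  paste0(sample(c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y"),
                len, replace = TRUE), collapse = "")
}

# Brute-force host-specific filter over explicit count matrices, written with
# per-protein set logic rather than the package's vectorized rule.
brute_host_specific <- function(counts_a, counts_b, min_accumulated = 10) {
  ids <- sort(union(rownames(counts_a), rownames(counts_b)))
  row_of <- function(m, id) {
    if (id %in% rownames(m)) as.integer(m[id, ]) else
      integer(ncol(m)) # all zero
  }
  a_specific <- character(0); b_specific <- character(0)
  for (id in ids) {
    a <- row_of(counts_a, id); b <- row_of(counts_b, id)
    present_all_a <- min(a) > 0
    present_all_b <- min(b) > 0
    if (present_all_a && sum(a) >= min_accumulated && max(b) == 0)
      a_specific <- c(a_specific, id)
    if (present_all_b && sum(b) >= min_accumulated && max(a) == 0)
      b_specific <- c(b_specific, id)
  }
  list(a = a_specific, b = b_specific)
}

# Fine-grid scan for the isoelectric point: evaluate the net charge on a pH
# grid and return the grid point where the charge changes sign.
grid_pi <- function(peptide, step = 1e-4) {
  tab <- data.frame(
    group = c("Nterm", "K", "R", "H", "Cterm", "D", "E", "C", "Y"),
    pka = c(8.6, 10.8, 12.5, 6.5, 3.6, 3.9, 4.1, 8.5, 10.1),
    type = c(rep("basic", 4), rep("acidic", 5)),
    stringsAsFactors = FALSE)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  counts <- c(Nterm = 1, Cterm = 1,
              sapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(chars == a)))
  ph <- seq(0, 14, by = step)
  q <- numeric(length(ph))
  for (i in seq_len(nrow(tab))) {
    n <- counts[[tab$group[i]]]
    if (n == 0) next
    q <- q + if (tab$type[i] == "basic") n / (1 + 10^(ph - tab$pka[i]))
             else -n / (1 + 10^(tab$pka[i] - ph))
  }
  ph[which.min(abs(q))]
}

# Path-length (patristic) distances from a known tree, used to build additive
# matrices whose generating tree neighbor joining must recover.
tree_path_distances <- function(newick) {
  tr <- ape::read.tree(text = newick)
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}
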