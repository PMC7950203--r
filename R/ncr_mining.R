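as_aligned_matrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  seqs <- as.character(alignment)
  if (length(seqs) < 2L) stop("alignment must contain at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Derive conserved 3-residue tags from a reference alignment
#'
#' Scans every gap-free window of three consecutive alignment columns; a
#' window in which each column's majority residue reaches `min_conservation`
#' contributes its majority triple as a tag. Tags are the short, conserved
#' motifs that can be searched for in de novo peptide lists where full-length
#' identification is impossible.
#'
#' @param alignment Aligned FASTA path, `AAStringSet`, or character vector of
#'   equal-length sequences (gaps as `-` or `.`).
#' @param min_conservation Minimum per-column majority fraction (default 0.8).
#' @return Object of class `"tag_set"`: list with `tags` (character) and
#'   `windows` (data.frame of tag, alignment start column, minimum column
#'   conservation).
#' @export
build_tag_set <- function(alignment, min_conservation = 0.8) {
  m <- as_aligned_matrix(alignment)
  n_col <- ncol(m); n_seq <- nrow(m)
  gap <- m == "-" | m == "."
  tags <- character(0); starts <- integer(0); cons <- numeric(0)
  for (i in seq_len(max(0L, n_col - 2L))) {
    cols <- i:(i + 2L)
    if (any(gap[, cols])) next
    maj <- character(3); frac <- numeric(3)
    for (k in 1:3) {
      tab <- table(m[, cols[k]])
      maj[k] <- names(tab)[which.max(tab)]
      frac[k] <- max(tab) / n_seq
    }
    if (all(frac >= min_conservation)) {
      tags <- c(tags, paste0(maj, collapse = ""))
      starts <- c(starts, i)
      cons <- c(cons, min(frac))
    }
  }
  keep <- !duplicated(tags)
  structure(list(tags = tags[keep],
                 windows = data.frame(tag = tags[keep], start = starts[keep],
                                      conservation = cons[keep],
                                      stringsAsFactors = FALSE)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("Tag set: %d conserved 3-residue tags (%s)\n",
              length(x$tags), paste(x$tags, collapse = ", ")))
  invisible(x)
}

collapse_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Search peptides for conserved tags
#'
#' A peptide is retained when it contains at least one tag as an exact
#' substring. Ile and Leu are treated as equivalent: de novo sequencing
#' cannot distinguish the isobaric pair.
#'
#' @param peptides Character vector of peptide sequences.
#' @param tags A `"tag_set"` or character vector of 3-residue tags.
#' @return data.frame of matches with columns `peptide`, `tag`, `start`
#'   (one row per occurrence); peptides with no match are absent.
#' @export
tag_search <- function(peptides, tags) {
  if (inherits(tags, "tag_set")) tags <- tags$tags
  if (length(tags) == 0L) stop("tag set is empty")
  pep_il <- collapse_il(peptides)
  tag_il <- collapse_il(tags)
  out <- list()
  for (i in seq_along(peptides)) {
    for (k in seq_along(tags)) {
      hits <- gregexpr(tag_il[k], pep_il[i], fixed = TRUE)[[1]]
      if (hits[1] != -1L)
        out[[length(out) + 1L]] <- data.frame(peptide = peptides[i],
                                              tag = tags[k],
                                              start = as.integer(hits),
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide = character(), tag = character(),
                      start = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Six-frame translation of transcript contigs into ORFs
#'
#' ORFs are maximal stop-free stretches in each of the six reading frames; a
#' start codon is not required, since mined peptide fragments may be internal
#' to a longer coding region. Ambiguous codons translate to `X`.
#'
#' @param contigs FASTA path, `DNAStringSet`, or named character vector.
#' @param min_orf_length Minimum ORF length in residues (default 30).
#' @return data.frame with columns `contig`, `frame` (-3..3, no 0), `orf`
#'   (peptide), `nt_start`, `nt_end` (1-based inclusive, forward strand).
#' @export
translate_contigs <- function(contigs, min_orf_length = 30L) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- Biostrings::readDNAStringSet(contigs)
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  ids <- names(contigs)
  if (is.null(ids)) ids <- paste0("contig_", seq_along(contigs))
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  widths <- Biostrings::width(contigs)
  empty_ctg <- widths == 0L
  if (any(empty_ctg))
    warning("empty contig skipped: ", paste(ids[empty_ctg], collapse = ", "))
  keep <- widths >= 3L
  contigs <- contigs[keep]; ids <- ids[keep]; widths <- widths[keep]
  res <- list()
  if (length(contigs) > 0L) {
    revs <- Biostrings::reverseComplement(contigs)
    for (f in 1:3) {
      for (strand in c(1L, -1L)) {
        s <- if (strand == 1L) contigs else revs
        n_codon <- (widths - f + 1L) %/% 3L
        ok <- n_codon >= 1L
        if (!any(ok)) next
        sub <- Biostrings::subseq(s[ok], f, f + 3L * n_codon[ok] - 1L)
        aa <- as.character(suppressWarnings(
          Biostrings::translate(sub, if.fuzzy.codon = "X")))
        for (k in seq_along(aa)) {
          ci <- which(ok)[k]
          L <- widths[ci]
          parts <- strsplit(aa[k], "*", fixed = TRUE)[[1]]
          pos <- 1L
          for (p in parts) {
            plen <- nchar(p)
            if (plen >= min_orf_length) {
              nt_a <- f + 3L * (pos - 1L)
              nt_b <- f + 3L * (pos + plen - 1L) - 1L
              if (strand == 1L) {
                nt_start <- nt_a; nt_end <- nt_b
              } else {
                nt_start <- L - nt_b + 1L; nt_end <- L - nt_a + 1L
              }
              res[[length(res) + 1L]] <- data.frame(
                contig = ids[ci], frame = strand * f, orf = p,
                nt_start = nt_start, nt_end = nt_end,
                stringsAsFactors = FALSE)
            }
            pos <- pos + plen + 1L
          }
        }
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(contig = character(), frame = integer(),
                      orf = character(), nt_start = integer(),
                      nt_end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$contig, out$frame, out$nt_start), , drop = FALSE]
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

alignment_identity <- function(pat, sub) {
  a <- strsplit(pat, "", fixed = TRUE)[[1]]
  b <- strsplit(sub, "", fixed = TRUE)[[1]]
  a[a == "I"] <- "L"; b[b == "I"] <- "L"
  ident <- sum(a == b & a != "-")
  100 * ident / length(a)
}

#' Match candidate peptides against translated contig ORFs
#'
#' Each candidate is locally aligned (Smith-Waterman, BLOSUM62, gap open 11 /
#' extend 1) against every ORF; the best-scoring ORF is kept, with ties
#' broken by lexicographic contig id, then frame, then position. A candidate
#' is retained when identity (identical alignment columns over all alignment
#' columns, Ile = Leu) strictly exceeds `min_identity` and coverage (aligned
#' candidate residues over candidate length) strictly exceeds `min_coverage`.
#'
#' @param candidates Character vector of candidate peptide sequences.
#' @param orfs data.frame from [translate_contigs()].
#' @param min_identity,min_coverage Percent cut-offs, strict inequalities
#'   (defaults 90 and 50).
#' @return data.frame of retained candidates with columns `peptide`,
#'   `contig`, `frame`, `nt_start`, `score`, `identity`, `coverage`.
#' @export
match_candidates <- function(candidates, orfs, min_identity = 90,
                             min_coverage = 50) {
  empty <- data.frame(peptide = character(), contig = character(),
                      frame = integer(), nt_start = integer(),
                      score = numeric(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (length(candidates) == 0L || nrow(orfs) == 0L) return(empty)
  mat <- blosum62()
  ord <- order(orfs$contig, orfs$frame, orfs$nt_start)
  orfs <- orfs[ord, , drop = FALSE]
  candidates <- unique(candidates)
  self_score <- function(pep) {
    ch <- strsplit(pep, "", fixed = TRUE)[[1]]
    sum(mat[cbind(ch, ch)])
  }
  pat_set <- Biostrings::AAStringSet(candidates)
  # an exact substring hit attains the maximum possible local score (the
  # self-match), so the first such ORF in sorted order is the best match
  best_oi <- rep(NA_integer_, length(candidates))
  best_score <- rep(-Inf, length(candidates))
  exact <- rep(FALSE, length(candidates))
  for (ci in seq_along(candidates)) {
    hit <- which(vapply(orfs$orf, grepl, logical(1), pattern = candidates[ci],
                        fixed = TRUE, USE.NAMES = FALSE))
    if (length(hit) > 0L) {
      best_oi[ci] <- hit[1]
      best_score[ci] <- self_score(candidates[ci])
      exact[ci] <- TRUE
    }
  }
  open_cand <- which(!exact)
  if (length(open_cand) > 0L) {
    for (oi in seq_len(nrow(orfs))) {
      sc <- Biostrings::pairwiseAlignment(
        pat_set[open_cand], Biostrings::AAString(orfs$orf[oi]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
      better <- sc > best_score[open_cand]
      best_oi[open_cand][better] <- oi
      best_score[open_cand][better] <- sc[better]
    }
  }
  res <- list()
  for (ci in seq_along(candidates)) {
    if (is.na(best_oi[ci])) next
    pep <- candidates[ci]; oi <- best_oi[ci]
    if (exact[ci]) {
      identity <- 100; coverage <- 100
    } else {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pep), Biostrings::AAString(orfs$orf[oi]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 11, gapExtension = 1)
      pat <- as.character(Biostrings::alignedPattern(aln))
      sub <- as.character(Biostrings::alignedSubject(aln))
      identity <- alignment_identity(pat, sub)
      coverage <- 100 * sum(strsplit(pat, "", fixed = TRUE)[[1]] != "-") /
        nchar(pep)
    }
    if (identity > min_identity && coverage > min_coverage)
      res[[length(res) + 1L]] <- data.frame(
        peptide = pep, contig = orfs$contig[oi], frame = orfs$frame[oi],
        nt_start = orfs$nt_start[oi], score = best_score[ci],
        identity = identity, coverage = coverage, stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty)
  do.call(rbind, res)
}

#' Mature peptide after signal-peptide cleavage
#'
#' @param precursor Full precursor sequence.
#' @param cleavage_position 1-based residue after which the signal peptide
#'   ends; the mature peptide is the suffix that follows it.
#' @return Mature peptide string.
#' @export
predict_mature <- function(precursor, cleavage_position) {
  n <- nchar(precursor)
  if (cleavage_position < 1L || cleavage_position >= n)
    stop(sprintf("cleavage position %d out of range for precursor of length %d",
                 cleavage_position, n))
  substr(precursor, cleavage_position + 1L, n)
}

#' Heuristic signal-peptide cleavage guess
#'
#' Fallback used only when no externally predicted cleavage table is
#' available: the most C-terminal position within the first `max_signal`
#' residues whose (-3, -1) residues relative to the cleavage site are both
#' small (A, G, S, C, T, V), following the classic von Heijne pattern.
#'
#' @param precursor Precursor sequence.
#' @param max_signal Longest signal peptide considered (default 40).
#' @return Cleavage position, or `NA` when the pattern is absent.
#' @export
guess_cleavage <- function(precursor, max_signal = 40L) {
  small <- c("A", "G", "S", "C", "T", "V")
  chars <- strsplit(precursor, "", fixed = TRUE)[[1]]
  upto <- min(max_signal, length(chars) - 1L)
  cand <- which(seq_along(chars) <= upto & seq_along(chars) >= 3L)
  ok <- cand[chars[cand] %in% small & chars[cand - 2L] %in% small]
  if (length(ok) == 0L) return(NA_integer_)
  max(ok)
}

#' Default pKa table for isoelectric-point computation
#'
#' EMBOSS-style dissociation constants for the peptide termini and the seven
#' ionizable side chains, shipped as an editable tab-separated data file.
#'
#' @param path Optional alternative table (columns `group`, `pka`, `type`
#'   with type `basic` or `acidic`).
#' @return data.frame with columns `group`, `pka`, `type`.
#' @export
pka_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pka_default.tsv", package = "nodulomics")
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("group", "pka", "type") %in% colnames(tab)))
  tab
}

peptide_net_charge <- function(pH, counts, pka) {
  q <- 0
  for (i in seq_len(nrow(pka))) {
    n <- counts[[pka$group[i]]]
    if (is.null(n) || n == 0) next
    q <- q + if (pka$type[i] == "basic") n / (1 + 10^(pH - pka$pka[i]))
             else -n / (1 + 10^(pka$pka[i] - pH))
  }
  q
}

ionizable_counts <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  counts <- as.list(table(chars)[c("K", "R", "H", "D", "E", "C", "Y")])
  names(counts) <- c("K", "R", "H", "D", "E", "C", "Y")
  counts <- lapply(counts, function(x) if (is.na(x)) 0L else as.integer(x))
  counts$Nterm <- 1L
  counts$Cterm <- 1L
  counts
}

#' Isoelectric point of a peptide
#'
#' The pH at which the Henderson-Hasselbalch net charge over the N-terminus,
#' C-terminus and ionizable side chains (K, R, H, D, E, C, Y) is zero. The
#' net charge is strictly decreasing in pH, so the root is unique; it is
#' found by bisection on \[0, 14\] to `|Q| < 1e-6`.
#'
#' @param peptide Peptide sequence(s).
#' @param pka pKa table from [pka_table()].
#' @return Numeric pI value(s).
#' @export
compute_pi <- function(peptide, pka = pka_table()) {
  one <- function(p) {
    if (nchar(p) == 0L) stop("empty peptide")
    counts <- ionizable_counts(p)
    lo <- 0; hi <- 14
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      q <- peptide_net_charge(mid, counts, pka)
      if (abs(q) < 1e-6) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
    mid
  }
  vapply(peptide, one, numeric(1), USE.NAMES = FALSE)
}

#' Charge class of a mature peptide from its pI
#'
#' Bins: anionic below the first boundary, neutral between the boundaries
#' (inclusive on both sides), cationic above the second (defaults 6.5 and
#' 7.5). Cationic mature peptides are the ones most likely to interact with
#' bacterial membranes. Values outside the typical 4-10 range are still
#' classified, with a warning.
#'
#' @param pi Numeric pI value(s).
#' @param bins Two increasing boundaries (default `c(6.5, 7.5)`).
#' @return Character vector over `{"anionic", "neutral", "cationic"}`.
#' @export
classify_charge <- function(pi, bins = c(6.5, 7.5)) {
  stopifnot(length(bins) == 2L, bins[1] < bins[2])
  if (any(pi < 4 | pi > 10))
    warning("pI value outside the typical 4-10 range")
  ifelse(pi < bins[1], "anionic", ifelse(pi > bins[2], "cationic", "neutral"))
}

#' Charge-class distribution of a peptide set
#'
#' @param classes Character vector of charge classes (from
#'   [classify_charge()]).
#' @return Named numeric vector of whole-number percentages (anionic,
#'   neutral, cationic); sums to 100 +/- 1 from rounding.
#' @export
charge_distribution <- function(classes) {
  if (length(classes) == 0L) stop("empty peptide set")
  lev <- c("anionic", "neutral", "cationic")
  counts <- table(factor(classes, levels = lev))
  setNames(round_half_away(100 * as.integer(counts) / length(classes), 0L), lev)
}
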