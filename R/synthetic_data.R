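# Residues used for untuned filler positions: no ionizable side chains, no
# K/R (which would add cleavage sites), no I (reserved against I/L ambiguity).
NEUTRAL_AA <- c("A", "S", "T", "N", "Q", "G", "V", "F", "W", "P")
HYDROPHOBIC_AA <- c("L", "A", "V", "F", "M", "W", "T", "S")

# Conserved 3-residue tags carried by the synthetic reference alignment and
# embedded in every synthetic mature NCR region. None contains K/R (which
# would move tryptic boundaries) or I (I/L ambiguity).
SYNTH_TAGS <- c("CPT", "TDC", "NGQ")

#' Specification for the synthetic-data generators
#'
#' Collects every knob of the seeded generators. Defaults emulate the study
#' conditions: six replicons with genome-share proportions, three replicates
#' per host, over-dispersed negative-binomial spectral counts, planted
#' host-specific proteins with a comfortable accumulated-spectra margin,
#' log-normal iTRAQ ratios with a handful of planted shifts, and a pea-like
#' NCR complement (52 peptides, 44% cationic).
#'
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @param n_proteins Proteome size.
#' @param replicon_props Named proportions summing to 1.
#' @param n_replicates Replicates per host.
#' @param psm_mean_range Range of per-protein negative-binomial means.
#' @param psm_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param detect_fraction Fraction of proteins detected in both hosts.
#' @param n_specific_per_host Planted host-specific proteins per host.
#' @param planted_margin Minimum accumulated spectra of a planted protein.
#' @param n_distractors_per_host Near-miss distractors per host (half present
#'   in all-but-one replicate, half with accumulated spectra 5-9).
#' @param itraq_sigma Log-scale standard deviation of null iTRAQ ratios.
#' @param planted_itraq Ratios assigned to planted differential proteins.
#' @param n_itraq Number of proteins carrying an iTRAQ ratio.
#' @param ncr List of NCR-corpus knobs: `n` peptides, `class_mix` (named
#'   anionic/neutral/cationic fractions), `signal_len` range, `cys_motifs`
#'   (4 and/or 6), `n_decoy_contigs`, `n_decoy_peptides`.
#' @return List of class `"generator_spec"`.
#' @export
generator_spec <- function(seed = 1L,
                           n_proteins = 400L,
                           replicon_props = c(Chromosome = 0.627, pRlvA = 0.17,
                                              pRlvB = 0.08, pRlvC = 0.05,
                                              pRlvD = 0.033, pRlvE = 0.04),
                           n_replicates = 3L,
                           psm_mean_range = c(5, 50),
                           psm_dispersion = 0.3,
                           detect_fraction = 0.6,
                           n_specific_per_host = 8L,
                           planted_margin = 12L,
                           n_distractors_per_host = 4L,
                           itraq_sigma = 0.25,
                           planted_itraq = c(2.5, 3.2, 0.4),
                           n_itraq = 150L,
                           ncr = list(n = 52L,
                                      class_mix = c(anionic = 0.46,
                                                    neutral = 0.10,
                                                    cationic = 0.44),
                                      signal_len = c(20L, 30L),
                                      cys_motifs = c(4L, 6L),
                                      n_decoy_contigs = 20L,
                                      n_decoy_peptides = 40L)) {
  if (abs(sum(replicon_props) - 1) > 1e-6)
    stop("replicon proportions must sum to 1")
  if (planted_margin < 10) stop("planted margin must be >= 10")
  if (abs(sum(ncr$class_mix) - 1) > 1e-6)
    stop("NCR class mix must sum to 1")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 replicon_props = replicon_props,
                 n_replicates = as.integer(n_replicates),
                 psm_mean_range = psm_mean_range,
                 psm_dispersion = psm_dispersion,
                 detect_fraction = detect_fraction,
                 n_specific_per_host = as.integer(n_specific_per_host),
                 planted_margin = as.integer(planted_margin),
                 n_distractors_per_host = as.integer(n_distractors_per_host),
                 itraq_sigma = itraq_sigma, planted_itraq = planted_itraq,
                 n_itraq = as.integer(n_itraq), ncr = ncr),
            class = "generator_spec")
}

#' Generate a replicon-structured synthetic proteome
#'
#' Random sequences of 80-600 residues, each guaranteed at least three
#' internal tryptic sites, with replicons drawn from the configured
#' proportions.
#'
#' @param spec A [generator_spec()].
#' @return data.frame with columns `id`, `replicon`, `sequence` (same layout
#'   as [read_proteome()]).
#' @export
generate_proteome <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_proteins
  if (n == 0L)
    return(data.frame(id = character(), replicon = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  lens <- sample(80:600, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    chars <- sample(AA_ALPHABET, L, replace = TRUE)
    internal <- 5:(L - 5L)
    ntryp <- sum(chars[internal] %in% c("K", "R"))
    if (ntryp < 3L) {
      pos <- sample(internal, 3L)
      chars[pos] <- sample(c("K", "R"), 3L, replace = TRUE)
    }
    paste0(chars, collapse = "")
  }, character(1))
  data.frame(id = sprintf("SYN_%04d", seq_len(n)),
             replicon = sample(names(spec$replicon_props), n, replace = TRUE,
                               prob = spec$replicon_props),
             sequence = seqs, stringsAsFactors = FALSE)
}

# distribute a total over k replicates, each >= 1
split_total <- function(total, k) {
  base <- rep(1L, k)
  extra <- total - k
  if (extra > 0L) {
    add <- table(factor(sample.int(k, extra, replace = TRUE), levels = 1:k))
    base <- base + as.integer(add)
  }
  base
}

#' Generate replicate PSM tables with planted host-specific proteins
#'
#' Shared proteins receive correlated negative-binomial counts in both hosts
#' (and are guaranteed at least one detected replicate per host, so they can
#' never satisfy the absence criterion). Planted host-specific proteins are
#' present in every replicate of their host with accumulated spectra at or
#' above the configured margin and exactly zero in the other host. Near-miss
#' distractors violate exactly one criterion each: presence in all but one
#' replicate, or accumulated spectra of 5-9.
#'
#' @param proteome data.frame from [generate_proteome()].
#' @param spec A [generator_spec()].
#' @return List with `table_a` (host "pea"), `table_b` (host "lentil"), and
#'   `truth` (data.frame `id`, `role`).
#' @export
generate_psm_tables <- function(proteome, spec) {
  set.seed(spec$seed + 1L)
  ids <- proteome$id
  n <- length(ids)
  n_special <- 2L * spec$n_specific_per_host + 2L * spec$n_distractors_per_host
  if (n_special > n)
    stop("planted + distractor proteins exceed proteome size")
  shuffled <- sample(ids)
  take <- function(k) {
    out <- shuffled[seq_len(k)]
    shuffled <<- shuffled[-seq_len(k)]
    out
  }
  planted_a <- take(spec$n_specific_per_host)
  planted_b <- take(spec$n_specific_per_host)
  n_dist_pres <- spec$n_distractors_per_host %/% 2L
  n_dist_low <- spec$n_distractors_per_host - n_dist_pres
  dist_pres_a <- take(n_dist_pres); dist_low_a <- take(n_dist_low)
  dist_pres_b <- take(n_dist_pres); dist_low_b <- take(n_dist_low)
  n_shared <- max(0L, round(spec$detect_fraction * n) - n_special)
  shared <- take(min(n_shared, length(shuffled)))
  k <- spec$n_replicates
  counts_a <- list(); counts_b <- list()
  size <- 1 / spec$psm_dispersion
  for (id in shared) {
    mu <- runif(1, spec$psm_mean_range[1], spec$psm_mean_range[2])
    a <- rnbinom(k, mu = mu, size = size)
    b <- rnbinom(k, mu = mu, size = size)
    if (all(a == 0L)) a[sample.int(k, 1)] <- 1L
    if (all(b == 0L)) b[sample.int(k, 1)] <- 1L
    counts_a[[id]] <- a; counts_b[[id]] <- b
  }
  plant <- function(margin) {
    total <- margin + sample(0:8, 1)
    split_total(total, k)
  }
  for (id in planted_a) { counts_a[[id]] <- plant(spec$planted_margin) }
  for (id in planted_b) { counts_b[[id]] <- plant(spec$planted_margin) }
  for (id in dist_pres_a) {
    x <- plant(spec$planted_margin); x[sample.int(k, 1)] <- 0L
    counts_a[[id]] <- x
  }
  for (id in dist_pres_b) {
    x <- plant(spec$planted_margin); x[sample.int(k, 1)] <- 0L
    counts_b[[id]] <- x
  }
  for (id in dist_low_a) counts_a[[id]] <- split_total(sample(5:9, 1), k)
  for (id in dist_low_b) counts_b[[id]] <- split_total(sample(5:9, 1), k)
  to_table <- function(counts, host) {
    if (length(counts) == 0L)
      return(psm_table(matrix(integer(0), 0, k,
                              dimnames = list(character(0),
                                              paste0("rep", 1:k))), host))
    m <- do.call(rbind, counts)
    dimnames(m) <- list(names(counts), paste0("rep", 1:k))
    m <- m[order(rownames(m)), , drop = FALSE]
    psm_table(m, host)
  }
  role <- setNames(rep("undetected", n), ids)
  role[shared] <- "shared"
  role[planted_a] <- "planted_a"; role[planted_b] <- "planted_b"
  role[dist_pres_a] <- "distractor_presence_a"
  role[dist_pres_b] <- "distractor_presence_b"
  role[dist_low_a] <- "distractor_low_a"
  role[dist_low_b] <- "distractor_low_b"
  list(table_a = to_table(counts_a, "pea"),
       table_b = to_table(counts_b, "lentil"),
       truth = data.frame(id = ids, role = unname(role[ids]),
                          stringsAsFactors = FALSE))
}

#' Generate an iTRAQ ratio table with planted shifts
#'
#' Null proteins receive `exp(N(0, sigma))` ratios; the planted proteins
#' receive the configured ratios exactly.
#'
#' @param proteome data.frame from [generate_proteome()].
#' @param spec A [generator_spec()].
#' @return List with `itraq` (data.frame `id`, `ratio`) and `truth`
#'   (data.frame `id`, `planted`, `planted_ratio`).
#' @export
generate_itraq <- function(proteome, spec) {
  set.seed(spec$seed + 2L)
  n <- min(spec$n_itraq, nrow(proteome))
  ids <- sample(proteome$id, n)
  n_plant <- min(length(spec$planted_itraq), n)
  ratio <- exp(rnorm(n, 0, spec$itraq_sigma))
  planted <- rep(FALSE, n)
  if (n_plant > 0L) {
    ratio[seq_len(n_plant)] <- spec$planted_itraq[seq_len(n_plant)]
    planted[seq_len(n_plant)] <- TRUE
  }
  ord <- order(ids)
  list(itraq = data.frame(id = ids[ord], ratio = ratio[ord],
                          stringsAsFactors = FALSE),
       truth = data.frame(id = ids[ord], planted = planted[ord],
                          planted_ratio = ifelse(planted[ord], ratio[ord], NA),
                          stringsAsFactors = FALSE))
}

# Synthetic reference alignment: 10 gap-free sequences in which exactly three
# 3-column windows (the planted tags) are fully conserved; every other window
# crosses a 50/50 variable column, so an 0.8 conservation cut-off recovers
# exactly the planted tags. Two isolated conserved cysteine columns mimic the
# defensin-like cysteine scaffold without creating extra conserved windows.
synth_reference_alignment <- function(n_seq = 10L) {
  layout <- c(strsplit(SYNTH_TAGS[1], "")[[1]], "V", "V",
              strsplit(SYNTH_TAGS[2], "")[[1]], "V", "V",
              strsplit(SYNTH_TAGS[3], "")[[1]], "V",
              "C", "V", "V", "C", "V", "V", "V")
  m <- matrix("", n_seq, length(layout))
  for (j in seq_along(layout)) {
    if (layout[j] == "V") {
      pair <- sample(NEUTRAL_AA, 2L)
      m[, j] <- pair[1L + (seq_len(n_seq) %% 2L)]
    } else m[, j] <- layout[j]
  }
  setNames(apply(m, 1, paste0, collapse = ""),
           sprintf("ref%02d", seq_len(n_seq)))
}

# Tunable-slot composition proposals per target charge class.
propose_charges <- function(class, n_slots) {
  # the mature scaffold always carries one fixed Lys (the tryptic boundary
  # after the tag segment), so proposals are relative to a +1 baseline
  nk <- switch(class, cationic = sample(2:4, 1), anionic = sample(0:1, 1),
               neutral = sample(0:1, 1))
  comp <- switch(class,
    cationic = c(rep("K", nk), rep("R", sample(1:2, 1))),
    anionic = c(rep("K", nk),
                sample(c("D", "E"), nk + sample(2:4, 1), replace = TRUE)),
    neutral = c(rep("K", nk),
                sample(c("D", "E"), nk + 1L, replace = TRUE),
                rep("H", sample(2:3, 1))))
  if (length(comp) > n_slots) comp <- comp[seq_len(n_slots)]
  slots <- c(comp, sample(NEUTRAL_AA, n_slots - length(comp), replace = TRUE))
  sample(slots)
}

build_mature <- function(class, cys_motif, tag, pka, bins = c(6.5, 7.5),
                         max_tries = 500L) {
  filler <- function(k) paste0(sample(NEUTRAL_AA, k, replace = TRUE),
                               collapse = "")
  for (try in seq_len(max_tries)) {
    n_slots <- if (cys_motif == 6L) 12L else 9L
    slots <- propose_charges(class, n_slots)
    b3 <- paste0(slots[1:5], collapse = "")
    b5 <- paste0(slots[6:9], collapse = "")
    body <- paste0(filler(2), "C", filler(2), "C", b3, "C", filler(2), "C", b5)
    if (cys_motif == 6L)
      body <- paste0(body, "C", filler(2), "C",
                     paste0(slots[10:12], collapse = ""))
    mature <- paste0(tag, filler(4), "K", body)
    pi <- compute_pi(mature, pka)
    # keep pI inside the realistic 4-10 window as well as in the target bin
    if (pi >= 4 && pi <= 10 && classify_charge(pi, bins) == class)
      return(list(mature = mature, pi = pi))
  }
  stop(sprintf("could not achieve pI class '%s' within %d tries",
               class, max_tries))
}

reverse_translate <- function(aa_seq) {
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(a) {
    opts <- names(gc)[gc == a]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(codons, collapse = "")
}

# class counts by largest remainder so the realized mix is within rounding
# of the target for any n
class_counts <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  base
}

#' Generate a synthetic NCR corpus
#'
#' Produces every input of the NCR mining stage: a reference alignment whose
#' conserved windows define three tags, precursor sequences (hydrophobic
#' signal peptide plus cysteine-rich mature region embedding one tag), the
#' cleavage-position table, transcript contigs embedding the coding sequences
#' (half on the reverse strand) among random decoys, and a de novo peptide
#' list of tryptic mature fragments plus tag-free decoy peptides. Mature
#' charge classes follow the configured mix exactly (largest-remainder
#' counts); the pI of each peptide is tuned by accept/reject over the
#' charged-residue composition.
#'
#' @param spec A [generator_spec()].
#' @return List with `reference_alignment` (named character), `tags`,
#'   `ncr` (truth data.frame), `cleavage` (id, position), `contigs` (named
#'   character), `denovo` (peptide, source, role, has_tag).
#' @export
generate_ncr_corpus <- function(spec) {
  set.seed(spec$seed + 3L)
  nc <- spec$ncr
  pka <- pka_table()
  ref <- synth_reference_alignment()
  n <- nc$n
  lev <- c("anionic", "neutral", "cationic")
  counts <- class_counts(n, nc$class_mix[lev])
  classes <- rep(lev, counts)
  ids <- sprintf("NCR_%03d", seq_len(n))
  precursor <- character(n); mature <- character(n); pi <- numeric(n)
  cleav <- integer(n); cys <- integer(n); tag_used <- character(n)
  for (i in seq_len(n)) {
    cys_motif <- nc$cys_motifs[sample.int(length(nc$cys_motifs), 1)]
    tag <- SYNTH_TAGS[sample.int(length(SYNTH_TAGS), 1)]
    m <- build_mature(classes[i], cys_motif, tag, pka)
    sl <- sample(nc$signal_len[1]:nc$signal_len[2], 1)
    signal <- paste0(c("M", sample(HYDROPHOBIC_AA, sl - 1L, replace = TRUE)),
                     collapse = "")
    precursor[i] <- paste0(signal, m$mature)
    mature[i] <- m$mature
    pi[i] <- m$pi
    cleav[i] <- sl
    cys[i] <- lengths(regmatches(m$mature, gregexpr("C", m$mature)))
    tag_used[i] <- tag
  }
  # contigs: coding sequences with random UTR-like flanks, half reversed
  contigs <- character(0)
  rand_nt <- function(k) paste0(sample(c("A", "C", "G", "T"), k, TRUE),
                                collapse = "")
  for (i in seq_len(n)) {
    cds <- paste0(reverse_translate(precursor[i]), "TAA")
    ctg <- paste0(rand_nt(sample(30:90, 1)), cds, rand_nt(sample(30:90, 1)))
    if (i %% 2L == 0L) ctg <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ctg)))
    contigs[sprintf("ctg_%03d", i)] <- ctg
  }
  for (j in seq_len(nc$n_decoy_contigs))
    contigs[sprintf("decoy_ctg_%03d", j)] <- rand_nt(sample(200:600, 1))
  # de novo list: tryptic fragments of the mature regions (up to one missed
  # cleavage) plus tag-free decoy peptides
  dig_opts <- digest_options(max_missed = 1L, min_length = 6L)
  denovo <- list()
  tag_il <- collapse_il(SYNTH_TAGS)
  has_tag <- function(p) any(vapply(tag_il, function(t)
    grepl(t, collapse_il(p), fixed = TRUE), logical(1)))
  for (i in seq_len(n)) {
    frags <- unique(digest(mature[i], dig_opts)$peptide)
    denovo[[i]] <- data.frame(peptide = frags, source = ids[i],
                              role = "planted",
                              has_tag = vapply(frags, has_tag, logical(1)),
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  decoys <- character(0)
  while (length(decoys) < nc$n_decoy_peptides) {
    p <- paste0(sample(AA_ALPHABET, sample(8:15, 1), TRUE), collapse = "")
    if (!has_tag(p)) decoys <- c(decoys, p)
  }
  denovo[[n + 1L]] <- data.frame(peptide = decoys, source = "decoy",
                                 role = "decoy", has_tag = FALSE,
                                 stringsAsFactors = FALSE)
  list(reference_alignment = ref,
       tags = SYNTH_TAGS,
       ncr = data.frame(id = ids, class_target = classes, cys_count = cys,
                        signal_len = cleav, tag = tag_used, pi = pi,
                        precursor = precursor, mature = mature,
                        stringsAsFactors = FALSE),
       cleavage = data.frame(id = ids, position = cleav,
                             stringsAsFactors = FALSE),
       contigs = contigs,
       denovo = do.call(rbind, denovo))
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  lines <- character(0)
  if (length(seqs) > 0L)
    lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}
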