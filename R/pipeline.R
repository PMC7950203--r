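#' Preset generator specifications
#'
#' `"pea-like"` emulates the pea bacteroid study arm (52 NCR peptides, 44%
#' cationic), `"lentil-like"` the lentil arm (65 peptides, 51% cationic), and
#' `"minimal"` is a small smoke-test configuration.
#'
#' @param preset One of `"pea-like"`, `"lentil-like"`, `"minimal"`.
#' @param seed Integer seed.
#' @return A [generator_spec()].
#' @export
preset_spec <- function(preset = c("pea-like", "lentil-like", "minimal"),
                        seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "pea-like" = generator_spec(seed = seed),
    "lentil-like" = generator_spec(
      seed = seed,
      ncr = list(n = 65L,
                 class_mix = c(anionic = 0.41, neutral = 0.08,
                               cationic = 0.51),
                 signal_len = c(20L, 30L), cys_motifs = c(4L, 6L),
                 n_decoy_contigs = 20L, n_decoy_peptides = 40L)),
    "minimal" = generator_spec(
      seed = seed, n_proteins = 20L, n_specific_per_host = 2L,
      n_distractors_per_host = 2L, n_itraq = 10L,
      ncr = list(n = 2L,
                 class_mix = c(anionic = 0.5, neutral = 0, cationic = 0.5),
                 signal_len = c(20L, 25L), cys_motifs = 4L,
                 n_decoy_contigs = 3L, n_decoy_peptides = 6L)))
}

#' Run the full synthetic pipeline
#'
#' Orchestrates generation, digestion, RPSM quantification, host-specific
#' calling, iTRAQ classification, NCR mining and the neighbor-joining tree,
#' writing every input and result table under `out_dir`. With a fixed seed
#' and configuration the output manifest (file checksums) is reproducible.
#'
#' @param out_dir Output directory.
#' @param preset Preset name for [preset_spec()], ignored when `spec` given.
#' @param config An [analysis_config()].
#' @param spec Optional explicit [generator_spec()].
#' @return Object of class `"pipeline_run"`: list with `config`, `spec`,
#'   `stages` (character log), `results` (list of data.frames) and
#'   `manifest` (data.frame `file`, `md5`).
#' @export
run_pipeline <- function(out_dir, preset = "pea-like",
                         config = analysis_config(), spec = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(spec)) spec <- preset_spec(preset, seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  stages <- character(0)
  log_stage <- function(s) {
    stages <<- c(stages, s); nod_log("pipeline", s)
  }

  log_stage("simulate: proteome")
  proteome <- generate_proteome(spec)
  write_proteome(proteome, file.path(in_dir, "proteome.fasta"))

  log_stage("digest: predicted tryptic peptides")
  denominators <- setNames(
    vapply(proteome$sequence, count_predicted_peptides, numeric(1),
           opts = config$digest, USE.NAMES = FALSE),
    proteome$id)
  no_pep <- names(denominators)[denominators == 0]
  if (length(no_pep) > 0L) {
    nod_log("digest", length(no_pep), " proteins yield no predicted peptides; excluded")
    proteome <- proteome[!(proteome$id %in% no_pep), , drop = FALSE]
    denominators <- denominators[proteome$id]
  }
  digest_tab <- data.frame(id = proteome$id,
                           n_peptides = as.integer(denominators),
                           stringsAsFactors = FALSE)

  log_stage("simulate: PSM tables")
  psm <- generate_psm_tables(proteome, spec)
  write_psm_table(psm$table_a, file.path(in_dir, "psm_pea.tsv"))
  write_psm_table(psm$table_b, file.path(in_dir, "psm_lentil.tsv"))

  log_stage("quantify: RPSM per host")
  quant_a <- aggregate_replicates(psm$table_a, denominators)
  quant_b <- aggregate_replicates(psm$table_b, denominators)

  log_stage("summarize: replicon distribution")
  levels <- names(spec$replicon_props)
  sum_a <- replicon_summary(rownames(psm$table_a$counts), proteome,
                            replicon_levels = levels)
  sum_b <- replicon_summary(rownames(psm$table_b$counts), proteome,
                            replicon_levels = levels)

  log_stage("compare: host-specific calls")
  calls <- call_host_specific(psm$table_a, psm$table_b,
                              config$min_accumulated_spectra)
  host_specific <- rbind(calls$a, calls$b)

  log_stage("compare: iTRAQ classification")
  itraq <- generate_itraq(proteome, spec)
  itraq_tab <- itraq$itraq
  write.table(itraq_tab, file.path(in_dir, "itraq.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  itraq_tab$label <- classify_itraq(itraq_tab$ratio, config$itraq_threshold)
  reconciled <- reconcile_calls(calls, itraq$itraq,
                                host_a = psm$table_a$host,
                                host_b = psm$table_b$host,
                                threshold = config$itraq_threshold)

  log_stage("mine-ncr: corpus, tags, search, matching")
  corpus <- generate_ncr_corpus(spec)
  write_fasta(corpus$reference_alignment,
              file.path(in_dir, "ncr_reference_alignment.fasta"))
  write_fasta(corpus$contigs, file.path(in_dir, "contigs.fasta"))
  writeLines(corpus$denovo$peptide, file.path(in_dir, "denovo_peptides.txt"))
  write.table(corpus$cleavage, file.path(in_dir, "cleavage_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tags <- build_tag_set(corpus$reference_alignment)
  hits <- tag_search(corpus$denovo$peptide, tags)
  orfs <- translate_contigs(corpus$contigs)
  matched <- match_candidates(unique(hits$peptide), orfs,
                              config$min_identity, config$min_coverage)

  log_stage("mine-ncr: mature peptides, pI, charge classes")
  matures <- mapply(predict_mature, corpus$ncr$precursor,
                    corpus$cleavage$position, USE.NAMES = FALSE)
  pis <- compute_pi(matures)
  cls <- classify_charge(pis, config$pi_bins)
  ncr_classes <- data.frame(id = corpus$ncr$id, mature = matures, pi = pis,
                            charge_class = cls, stringsAsFactors = FALSE)
  dist <- charge_distribution(cls)
  dist_tab <- data.frame(charge_class = names(dist),
                         percent = as.numeric(dist),
                         stringsAsFactors = FALSE)

  results <- list(digest = digest_tab,
                  quant_pea = quant_a, quant_lentil = quant_b,
                  replicon_summary_pea = sum_a,
                  replicon_summary_lentil = sum_b,
                  host_specific = host_specific,
                  itraq_classified = itraq_tab,
                  reconciled = reconciled,
                  ncr_candidates = matched,
                  ncr_classes = ncr_classes,
                  charge_distribution = dist_tab)
  write_report(results, out_dir)

  if (nrow(ncr_classes) >= 3L) {
    log_stage("ncr-tree: neighbor joining of mature peptides")
    width <- max(nchar(matures))
    aligned <- vapply(matures, function(m)
      paste0(m, strrep("-", width - nchar(m))), character(1),
      USE.NAMES = FALSE)
    names(aligned) <- corpus$ncr$id
    tree <- neighbor_joining(p_distance(aligned))
    writeLines(write_newick(tree), file.path(out_dir, "ncr_tree.nwk"))
  } else {
    log_stage("ncr-tree: skipped (< 3 mature peptides)")
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  structure(list(config = config, spec = spec, stages = stages,
                 results = results, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", length(x$stages), "stages,",
      nrow(x$manifest), "output files\n")
  invisible(x)
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "nodulomics")
  if (p == "") stop("missing fixture: ", name)
  p
}

#' Replicon summary computed from published per-replicon counts
#'
#' Expands a count table into a pseudo-proteome and delegates to
#' [replicon_summary()], so published column counts can be pushed through
#' the same code path as real identifications.
#'
#' @param counts Named integer vector: replicon -> identified-protein count.
#' @param denominator `"column_total"` or an explicit total.
#' @return See [replicon_summary()].
#' @export
replicon_summary_from_counts <- function(counts, denominator = "column_total") {
  ids <- unlist(lapply(names(counts), function(r)
    sprintf("%s_%05d", r, seq_len(counts[[r]]))), use.names = FALSE)
  proteome <- data.frame(
    id = ids,
    replicon = rep(names(counts), times = as.integer(counts)),
    sequence = "M", stringsAsFactors = FALSE)
  replicon_summary(ids, proteome, denominator = denominator,
                   replicon_levels = names(counts))
}

#' Validate recomputed statistics against the shipped reference tables
#'
#' Recomputes, from the reference summary tables shipped with the package
#' (per-replicon protein counts, the 36 iTRAQ pea/lentil ratios, and the
#' symbiotic-performance means for the Rlv UPM791 pea/lentil comparison),
#' every desk-scale quantity of the analysis: per-replicon percentages,
#' host-specific totals, iTRAQ classification counts, and the percent
#' reduction in nitrogen accumulation, and reports each against its printed
#' value.
#'
#' @return data.frame with columns `check`, `expected`, `computed`, `pass`.
#' @export
validate_reference_tables <- function() {
  t1 <- read.delim(fixture_path("upm791_replicon_counts.tsv"),
                   comment.char = "#", stringsAsFactors = FALSE)
  checks <- list()
  add <- function(check, expected, computed) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, expected = expected, computed = computed,
      pass = isTRUE(all.equal(expected, computed)), stringsAsFactors = FALSE)
  }
  cols <- c(genome = "genome", vegetative = "vegetative", pea = "pea",
            lentil = "lentil")
  for (nm in names(cols)) {
    counts <- setNames(t1[[cols[nm]]], t1$replicon)
    den <- if (nm == "genome") 7318 else "column_total"
    s <- replicon_summary_from_counts(counts, denominator = den)
    printed <- t1[[paste0(cols[nm], "_pct")]]
    for (i in seq_len(nrow(s)))
      add(sprintf("%s %s percent", nm, s$replicon[i]), printed[i],
          s$percent[i])
  }
  add("pea host-specific total", 28, sum(t1$pea_specific))
  add("lentil host-specific total", 25, sum(t1$lentil_specific))
  t4 <- read.delim(fixture_path("upm791_itraq_ratios.tsv"),
                   comment.char = "#", stringsAsFactors = FALSE)
  lab <- classify_itraq(t4$ratio)
  add("iTRAQ pea-overrepresented count", 28, sum(lab == "pea_over"))
  add("iTRAQ lentil-overrepresented count", 8, sum(lab == "lentil_over"))
  t5 <- read.delim(fixture_path("upm791_symbiosis_means.tsv"),
                   comment.char = "#", stringsAsFactors = FALSE)
  nfix <- function(strain, host)
    t5$n_fixed[t5$strain == strain & t5$host == host]
  sdw <- function(strain, host)
    t5$shoot_dw[t5$strain == strain & t5$host == host]
  add("pea N-fixed reduction (gntR mutant)", 28,
      percent_reduction(nfix("UPM791", "pea"), nfix("UPM1418", "pea")))
  add("pea shoot-dry-weight reduction (gntR mutant)", 28,
      percent_reduction(sdw("UPM791", "pea"), sdw("UPM1418", "pea")))
  do.call(rbind, checks)
}
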