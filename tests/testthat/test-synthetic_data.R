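small_spec <- function(seed = 1) {
  generator_spec(seed = seed, n_proteins = 60L, n_specific_per_host = 4L,
                 n_distractors_per_host = 4L, n_itraq = 30L,
                 ncr = list(n = 6L,
                            class_mix = c(anionic = 0.5, neutral = 0,
                                          cationic = 0.5),
                            signal_len = c(20L, 25L), cys_motifs = c(4L, 6L),
                            n_decoy_contigs = 4L, n_decoy_peptides = 8L))
}

test_that("generators are deterministic for a fixed seed", {
  s <- small_spec(seed = 42)
  p1 <- generate_proteome(s); p2 <- generate_proteome(s)
  expect_identical(p1, p2)
  t1 <- generate_psm_tables(p1, s); t2 <- generate_psm_tables(p2, s)
  expect_identical(t1, t2)
  i1 <- generate_itraq(p1, s); i2 <- generate_itraq(p1, s)
  expect_identical(i1, i2)
  c1 <- generate_ncr_corpus(s); c2 <- generate_ncr_corpus(s)
  expect_identical(c1, c2)
  # and a different seed changes the output
  expect_false(identical(p1, generate_proteome(small_spec(seed = 43))))
})

test_that("proteome generation respects size, replicons and tryptic sites", {
  spec <- generator_spec(seed = 5, n_proteins = 1000L)
  prot <- generate_proteome(spec)
  expect_equal(nrow(prot), 1000L)
  expect_false(anyDuplicated(prot$id) > 0)
  # replicon counts within 3 sigma of the multinomial expectation
  counts <- table(factor(prot$replicon, levels = names(spec$replicon_props)))
  for (r in names(spec$replicon_props)) {
    p <- spec$replicon_props[[r]]
    expect_lt(abs(counts[[r]] - 1000 * p), 3 * sqrt(1000 * p * (1 - p)) + 1)
  }
  lens <- nchar(prot$sequence)
  expect_true(all(lens >= 80 & lens <= 600))
  # every protein offers at least 3 internal tryptic sites
  n_sites <- vapply(prot$sequence, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(ch[-length(ch)] %in% c("K", "R"))
  }, numeric(1))
  expect_true(all(n_sites >= 3))

  empty <- generate_proteome(generator_spec(seed = 1, n_proteins = 0L))
  expect_equal(nrow(empty), 0L)
})

test_that("planted host-specific proteins are recovered exactly; distractors never", {
  spec <- generator_spec(seed = 8)
  prot <- generate_proteome(spec)
  psm <- generate_psm_tables(prot, spec)
  calls <- call_host_specific(psm$table_a, psm$table_b, 10)
  planted_a <- psm$truth$id[psm$truth$role == "planted_a"]
  planted_b <- psm$truth$id[psm$truth$role == "planted_b"]
  expect_setequal(calls$a$id, planted_a)   # recall 1, false positives 0
  expect_setequal(calls$b$id, planted_b)
  expect_true(all(calls$a$accumulated_psm >= spec$planted_margin))
  distract <- psm$truth$id[grepl("distractor", psm$truth$role)]
  expect_false(any(distract %in% c(calls$a$id, calls$b$id)))

  none <- generator_spec(seed = 8, n_specific_per_host = 0L,
                         n_distractors_per_host = 0L)
  psm0 <- generate_psm_tables(generate_proteome(none), none)
  calls0 <- call_host_specific(psm0$table_a, psm0$table_b, 10)
  expect_equal(nrow(calls0$a) + nrow(calls0$b), 0L)
})

test_that("planted iTRAQ ratios classify as planted; null FDR follows the normal tail", {
  spec <- generator_spec(seed = 3, planted_itraq = c(2.5, 3.2, 0.4))
  out <- generate_itraq(generate_proteome(spec), spec)
  planted <- merge(out$itraq, out$truth[out$truth$planted, ], by = "id")
  lab <- classify_itraq(planted$ratio)
  expect_setequal(lab[planted$ratio >= 2], "pea_over")
  expect_setequal(lab[planted$ratio <= 0.5], "lentil_over")

  # tight null noise: P(|N(0, 0.1)| >= ln 2) is ~2e-12, so no false calls
  null_spec <- generator_spec(seed = 3, n_proteins = 1000L, n_itraq = 1000L,
                              itraq_sigma = 0.1, planted_itraq = numeric(0))
  nulls <- generate_itraq(generate_proteome(null_spec), null_spec)
  expect_equal(sum(classify_itraq(nulls$itraq$ratio) != "not_significant"), 0L)
})

test_that("NCR corpus guarantees tags in planted fragments and none in decoys", {
  corpus <- generate_ncr_corpus(small_spec(seed = 21))
  tags <- build_tag_set(corpus$reference_alignment)
  expect_setequal(tags$tags, corpus$tags)
  # every NCR mature region carries its tag; cysteine scaffold present
  expect_true(all(mapply(grepl, corpus$ncr$tag, corpus$ncr$mature,
                         MoreArgs = list(fixed = TRUE))))
  expect_true(all(corpus$ncr$cys_count >= 4))
  # mature = precursor suffix after the signal
  expect_identical(mapply(predict_mature, corpus$ncr$precursor,
                          corpus$cleavage$position, USE.NAMES = FALSE),
                   corpus$ncr$mature)
  # planted tagged fragments all hit; decoys never do
  hits <- tag_search(corpus$denovo$peptide, tags)
  tagged <- corpus$denovo$peptide[corpus$denovo$has_tag]
  decoys <- corpus$denovo$peptide[corpus$denovo$role == "decoy"]
  expect_true(all(tagged %in% hits$peptide))
  expect_false(any(decoys %in% hits$peptide))
  # recorded pI values classify to the targeted class
  expect_identical(unname(classify_charge(corpus$ncr$pi)),
                   corpus$ncr$class_target)
})

test_that("generated files parse through the io layer unchanged", {
  s <- small_spec(seed = 9)
  prot <- generate_proteome(s)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_proteome(prot, fa)
  expect_identical(read_proteome(fa), prot)
  psm <- generate_psm_tables(prot, s)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psm$table_a, tsv)
  expect_identical(read_psm_table(tsv, "pea")$counts, psm$table_a$counts)
  corpus <- generate_ncr_corpus(s)
  cfa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(corpus$contigs, cfa)
  back <- Biostrings::readDNAStringSet(cfa)
  expect_identical(as.character(back), corpus$contigs)
})
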