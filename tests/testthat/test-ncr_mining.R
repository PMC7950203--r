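test_that("tag derivation finds conserved windows and majority residues", {
  full <- rep("CPTDC", 4)
  ts <- build_tag_set(full)
  expect_setequal(ts$tags, c("CPT", "PTD", "TDC"))

  # one 90%-conserved column: windows through it use the majority residue
  aln <- c(rep("ACTGG", 9), "ASTGG")
  ts2 <- build_tag_set(aln, min_conservation = 0.8)
  expect_setequal(ts2$tags, c("ACT", "CTG", "TGG"))

  # a fully variable column inside every window kills all tags
  var <- vapply(1:6, function(i)
    paste0(c("A", "C")[1 + i %% 2], "P", c("G", "W")[1 + i %% 2], "T"),
    character(1))
  ts3 <- build_tag_set(var, min_conservation = 0.8)
  expect_length(ts3$tags, 0L)

  # gapped windows are skipped
  gapped <- c("CP-DC", "CP-DC", "CPTDC", "CPTDC")
  expect_false(any(grepl("-", build_tag_set(gapped)$tags)))

  expect_error(build_tag_set(c("CPTD", "CPTDC")), "ragged")
})

test_that("tag search retains exactly peptides containing a tag (I = L)", {
  ts <- build_tag_set(rep("ACPTG", 3))
  hits <- tag_search(c("LCPTDCK", "AAAAAK"), "CPT")
  expect_equal(unique(hits$peptide), "LCPTDCK")
  expect_equal(hits$start[1], 2L)
  expect_equal(unique(tag_search("CPT", "CPT")$peptide), "CPT")
  expect_equal(nrow(tag_search("NCPTN", "CPT")), 1L)
  # isobaric equivalence in both directions
  expect_equal(nrow(tag_search("ACITA", "CLT")), 1L)
  expect_equal(nrow(tag_search("ACLTA", "CIT")), 1L)
  expect_error(tag_search("AAA", character(0)), "empty")
  # removing tags never adds retained peptides
  peps <- c("LCPTDCK", "TTDCA", "AAAAAK", "CPT")
  full_set <- unique(tag_search(peps, c("CPT", "TDC"))$peptide)
  reduced <- unique(tag_search(peps, "CPT")$peptide)
  expect_true(all(reduced %in% full_set))
})

test_that("six-frame translation finds ORFs on both strands with coordinates", {
  orfs <- translate_contigs(c(c1 = "ATGGCCTAA"), min_orf_length = 1)
  fwd1 <- orfs[orfs$frame == 1, ]
  expect_equal(fwd1$orf, "MA")
  expect_equal(c(fwd1$nt_start, fwd1$nt_end), c(1L, 6L))

  # a peptide embedded reverse-complement is recovered in a negative frame
  pep <- "MKWNPTDHE"
  cds <- paste0(c("ATG", "AAA", "TGG", "AAT", "CCG", "ACC", "GAT", "CAC",
                  "GAA"), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    paste0("GGG", cds, "CCC"))))
  orfs2 <- translate_contigs(c(r1 = rc), min_orf_length = 3)
  expect_true(any(grepl(pep, orfs2$orf[orfs2$frame < 0], fixed = TRUE)))

  # degenerate inputs
  expect_equal(nrow(translate_contigs(c(tiny = "AT"), 1)), 0L)
  expect_warning(translate_contigs(c(none = "", c2 = "ATGGCCTAA")), "empty")
  # ambiguous codons become X
  orfs3 <- translate_contigs(c(n1 = "ATGNNNGCC"), min_orf_length = 1)
  expect_true(any(grepl("X", orfs3$orf[orfs3$frame == 1])))
})

test_that("candidate matching enforces strict identity and coverage cut-offs", {
  orfs <- data.frame(contig = "c1", frame = 1L,
                     orf = "AAAAWCDEFGHKMNAAAA", nt_start = 1L,
                     nt_end = 54L, stringsAsFactors = FALSE)
  # exact substring: 100/100, retained
  hit <- match_candidates("WCDEFGHKMN", orfs)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 100)

  # one substitution in a 10-mer: identity 90, not > 90, dropped
  miss <- match_candidates("WCDEFAHKMN", orfs)
  expect_equal(nrow(miss), 0L)
  kept <- match_candidates("WCDEFAHKMN", orfs, min_identity = 80)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$identity, 90)

  # half the candidate aligns perfectly, the rest is unalignable:
  # coverage 50 fails the strict > 50 rule
  half <- match_candidates("WCDEFGPPPPPP",
                           data.frame(contig = "c1", frame = 1L,
                                      orf = "AAAAWCDEFGAAAA",
                                      nt_start = 1L, nt_end = 42L,
                                      stringsAsFactors = FALSE))
  expect_equal(nrow(half), 0L)

  # identity treats I and L as identical
  il <- match_candidates("WCDEFGHKMI",
                         data.frame(contig = "c1", frame = 1L,
                                    orf = "AAAAWCDEFGHKMLAAAA",
                                    nt_start = 1L, nt_end = 54L,
                                    stringsAsFactors = FALSE),
                         min_identity = 95, min_coverage = 50)
  expect_equal(nrow(il), 1L)
  expect_equal(il$identity, 100)

  # score ties resolve to the lexicographically smallest contig
  two <- rbind(orfs, transform(orfs, contig = "a0"))
  tie <- match_candidates("WCDEFGHKMN", two)
  expect_equal(tie$contig, "a0")

  expect_equal(nrow(match_candidates(character(0), orfs)), 0L)
  expect_equal(nrow(match_candidates("WCDEFGHKMN", orfs[0, ])), 0L)
})

test_that("mature-peptide extraction validates the cleavage position", {
  expect_equal(predict_mature("MKLLACPTDC", 5), "CPTDC")
  expect_equal(predict_mature("MKLLA", 4), "A")
  expect_error(predict_mature("MKLLA", 0), "out of range")
  expect_error(predict_mature("MKLLA", 5), "out of range")
})

test_that("signal cleavage heuristic finds the small-residue pattern", {
  # A-X-A ending at position 20 within the hydrophobic stretch
  precursor <- paste0("MKLLLLLLLLLLLLLLLAFA", "DDKKRWWE")
  expect_equal(guess_cleavage(precursor), 20L)
  expect_true(is.na(guess_cleavage("MKKKKKKKKK")))
})

test_that("pI bisection matches the fine-grid oracle and exact symmetry case", {
  # no ionizable side chains: pI is exactly the terminal pKa midpoint
  expect_equal(compute_pi("GGGG"), (8.6 + 3.6) / 2, tolerance = 1e-4)
  expect_gt(compute_pi("KKKK"), compute_pi("DDDD"))
  set.seed(13)
  for (i in 1:15) {
    pep <- random_aa(sample(5:30, 1))
    expect_equal(compute_pi(pep), grid_pi(pep), tolerance = 1e-3, info = pep)
  }
  expect_error(compute_pi(""), "empty")
})

test_that("charge classification partitions the pI axis with inclusive neutral bounds", {
  expect_equal(classify_charge(4.5), "anionic")
  expect_equal(classify_charge(7.0), "neutral")
  expect_equal(classify_charge(8.5), "cationic")
  expect_equal(classify_charge(6.5), "neutral")
  expect_equal(classify_charge(7.5), "neutral")
  expect_warning(out <- classify_charge(3.2), "outside")
  expect_equal(out, "anionic")
  # total function: every value maps to exactly one class
  grid <- seq(4, 10, by = 0.01)
  cls <- classify_charge(grid)
  expect_true(all(cls %in% c("anionic", "neutral", "cationic")))
  expect_equal(length(cls), length(grid))
})

test_that("charge distributions are whole-number percentages summing to ~100", {
  expect_equal(unname(charge_distribution(c("anionic", "anionic",
                                            "cationic", "cationic"))),
               c(50, 0, 50))
  expect_equal(unname(charge_distribution(rep("neutral", 5))), c(0, 100, 0))
  d <- charge_distribution(c(rep("cationic", 44), rep("anionic", 46),
                             rep("neutral", 10)))
  expect_equal(unname(d["cationic"]), 44)
  set.seed(4)
  cls <- sample(c("anionic", "neutral", "cationic"), 37, replace = TRUE)
  expect_lt(abs(sum(charge_distribution(cls)) - 100), 1.5)
  expect_error(charge_distribution(character(0)), "empty")
})
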