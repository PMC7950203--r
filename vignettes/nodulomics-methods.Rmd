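---
title: "Methods: bacteroid proteome quantification and NCR peptide mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bacteroid proteome quantification and NCR peptide mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulomics)
```

## Scope and model

`nodulomics` implements the downstream computational analysis of a
label-free + isobaric-label proteomic comparison of *Rhizobium
leguminosarum* bv *viciae* bacteroids induced in two legume hosts (pea and
lentil), together with the mining of the plant-encoded nodule-specific
cysteine-rich (NCR) peptides delivered to those bacteroids. Raw spectra,
database search and de novo sequencing are upstream of this package; its
inputs are peptide-spectrum-match (PSM) count tables, iTRAQ ratio tables, de
novo peptide lists and transcript contigs.

### Spectral-count abundance (RPSM)

Protein abundance is estimated by spectral counting normalized to protein
"observability":

$$\mathrm{RPSM} = 100 \times \frac{\mathrm{PSM}}{N_\mathrm{pred}}$$

where $N_\mathrm{pred}$ is the number of predicted tryptic peptides of the
protein. Trypsin is modeled as cleaving after Lys/Arg; the optional Keil
rule suppresses cleavage before Pro (off by default, since the upstream
search in this workflow did not use it). The denominator convention is the
set of distinct fully tryptic peptides with **zero missed cleavages and at
least six residues**, the most common "observable peptides" convention for
digestion simulators. The tool that produced the original denominators does
not document its settings, so the convention is exposed in
`digest_options()` and any alternative (e.g. the search-emulation setting of
up to two missed cleavages) can be reproduced. As a consequence, absolute
RPSM values depend on this choice and published per-protein RPSM values are
not treated as numeric targets; all of the package's own comparisons are
internally consistent under a single convention. Proteins that yield no
predicted peptide under the active convention are excluded before division,
never divided by zero. The initial Met is not stripped.

Replicate aggregation reports per-replicate RPSM values, their arithmetic
mean, the accumulated PSM (sum over replicates), and a replicate dispersion
defined as range over mean — the reproducibility measure used to motivate
the accumulated-spectra floor below.

### Host-specific protein calls

A protein is called specific to one host when three conditions hold
jointly: detected (PSM > 0) in *every* replicate of that host; accumulated
spectra over those replicates of at least 10; and zero PSMs in *every*
replicate of the other host, where "not listed in the table" counts as
zero. Absence is literal: a single spectrum in one other-host replicate
disqualifies. The floor and the presence rule are a conjunction, so their
order of application cannot change the result. Both knobs live in
`analysis_config()`.

### iTRAQ ratio classification

A pea/lentil ratio $r$ is pea-overrepresented when $r \ge 2$,
lentil-overrepresented when $r \le 0.5$, otherwise not significant. The
boundaries are **inclusive**: the published tables list proteins at exactly
2.00 and 0.50 among the over-represented sets, which forces this reading.
The threshold must exceed 1, keeping the rule symmetric on the log scale.

### Replicon summaries and percentage formatting

Identified proteins are counted per replicon (chromosome and the five
plasmids pRlvA–pRlvE in the UPM791 reference; the vocabulary is
configurable) and reported as percentages of either the column total or an
explicitly supplied denominator. The explicit denominator exists because
the published genome column's per-replicon counts sum to 7571 while every
printed percentage is consistent with the printed total of 7318; the
package reproduces the printed numbers without silently repairing the
table. All percentages use round-half-away-from-zero to one decimal.
Recomputation shows that three printed identified-column cells (vegetative
Chromosome and pRlvC, lentil pRlvB) differ by exactly one unit in the last
printed digit from their own printed counts under any standard rounding
rule; `validate_reference_tables()` reports them honestly as discordant
rather than special-casing them.

### NCR peptide mining

De novo peptide lists cannot be searched against a proteome that does not
exist, so mining proceeds by conserved **3-residue sequence tags**: every
gap-free window of three consecutive columns of a reference NCR alignment
whose per-column majority residue reaches 80% (configurable; the source
procedure says only "conserved") contributes its majority triple. Tag
matching and all identity computations treat Ile and Leu as equivalent —
de novo sequencing cannot distinguish the isobaric pair.

Tag-positive peptides are then matched against six-frame translations of
nodule transcript contigs. ORFs are maximal stop-free stretches (stop to
stop, no start-codon requirement, since a mined fragment may be internal to
a longer coding region) of at least 30 residues. Matching is Smith–Waterman
local alignment with BLOSUM62 and gap open 11 / extend 1; a candidate is
retained when identity (identical columns over alignment columns, I = L)
strictly exceeds 90% and coverage (aligned candidate residues over
candidate length) strictly exceeds 50% — strict inequalities exactly as the
published cut-offs are phrased. Score ties across ORFs resolve to the
lexicographically smallest contig id, then frame, then position, making
output deterministic. The original genome-level validation used nucleotide
BLAST; this package matches at protein level because its candidates are
peptides, not reads.

Signal-peptide cleavage positions are an input (they come from a dedicated
predictor); a crude fallback pattern heuristic (`guess_cleavage()`) exists
but is off by default. The mature peptide is the precursor suffix after the
cleavage position.

### Isoelectric points and charge classes

The pI of a mature peptide is the root of the Henderson–Hasselbalch net
charge over the two termini and the seven ionizable side chains. The charge
is strictly decreasing in pH, so the root is unique; it is bracketed on
[0, 14] and found by bisection to $|Q| < 10^{-6}$ (at most 200 iterations).
The pKa table ships as an editable text file (EMBOSS-style values: N-term
8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1)
because the web tool used originally does not publish its table; tests pin
the implementation to an independent fine-grid oracle and to the exact
two-group symmetry case (a Gly tetramer's pI is the terminal-pKa midpoint,
6.1). Charge classes follow the published bins — anionic below 6.5, neutral
6.5–7.5 (both boundaries assigned to neutral), cationic above 7.5; values
outside 4–10 are still classified, with a warning.

### Neighbor-joining tree

Mature peptides are compared by p-distance (mismatches over compared
columns) with pairwise gap deletion; the original tree software's distance
model and gap treatment are not documented, and p-distance with pairwise
deletion is the simplest peptide default, so it was chosen and is stated in
output. Tree construction is classic Saitou–Nei neighbor joining on the
Q-criterion with the standard limb-length formulas; negative limbs are
clamped to zero and Q-ties resolve to the lexicographically smallest label
pair, so the output is fully deterministic. The tree is returned unrooted
(trifurcating root) as an `ape` `phylo` object; `write_newick()` serializes
with six significant digits and children ordered by smallest descendant
label, so topologically identical trees serialize identically. Alignment
construction is an input: the package does not implement progressive
multiple alignment (the pipeline pads its equal-scaffold synthetic matures
with trailing gaps, which is adequate only because those sequences share a
common template).

## Synthetic data: what it emulates, and what it does not

The generators replace the raw MS and RNA-seq inputs so the full pipeline
runs and is validated offline.

* **Proteome**: random sequences of 80–600 residues, at least three
  internal tryptic sites each, replicons drawn from the genome-share
  proportions of the six UPM791 replicons (0.627/0.17/0.08/0.05/0.033/0.04).
* **PSM tables**: three replicates per host; shared proteins get
  negative-binomial counts (per-protein mean uniform on 5–50, dispersion
  0.3 — over-dispersed spectral counts; no count distributions are
  published, so these are field-plausible choices fixed once). Planted
  host-specific proteins are present in every replicate of their host with
  accumulated spectra ≥ 12 (a margin above the floor of 10) and exactly
  zero in the other host; shared proteins are guaranteed one nonzero
  replicate per host so they can never be called. Near-miss distractors
  violate exactly one criterion (present in all but one replicate, or
  accumulated 5–9). Recovery by the filter is therefore exact by
  construction, and tests assert recall 1 with zero false positives.
* **iTRAQ**: null ratios are log-normal, $\exp(N(0, 0.25))$; planted
  proteins receive fixed ratios (2.5, 3.2, 0.4 by default). The null
  false-significant fraction has the closed form
  $2\Phi(-\ln 2 / \sigma)$, which the tests check at $n = 1000$.
* **NCR corpus**: precursors are a hydrophobic signal peptide (20–30
  residues) plus a mature region carrying one of three reference tags, a
  fixed early tryptic boundary (so the first tryptic fragment always
  contains the tag), and a 4- or 6-cysteine scaffold. Charge classes follow
  the configured mix by largest-remainder counts (pea-like preset: 52
  peptides, 44% cationic; lentil-like: 65, 51%), achieved by accept/reject
  over the charged-residue composition with the pI kept inside 4–10. The
  reference alignment is constructed so that exactly the three planted tags
  are 80%-conserved windows. Contigs embed back-translated coding sequences
  (half reverse-complemented) among random decoys; the de novo list is the
  tryptic fragments of the mature regions (up to one missed cleavage, ≥ 6
  residues) plus decoy peptides filtered to contain no tag.

These constructions are deliberate idealizations: real de novo lists
contain sequencing errors, real decoys can share tags with true NCRs, real
transcripts have UTR/intron structure (the corpus is cDNA-like, matching
poly(A)-selected RNA-seq), and real NCR families are not generated from a
common scaffold. Passing the end-to-end recovery tests therefore shows the
pipeline's logic is sound under its stated assumptions — not that its
sensitivity/specificity on real nodule data is 100%/100%.

## Numerical choices and degenerate inputs

* Percentages: round half away from zero; one decimal for tables, whole
  percent for charge distributions and performance reductions.
* Digestion of a sequence without K/R yields the whole chain (one peptide,
  subject to the length filter).
* Empty FASTA parses to an empty proteome; a header-only PSM table to an
  empty count matrix; duplicate ids and non-amino-acid characters are hard
  errors naming the offender.
* Bisection tolerance $10^{-6}$ on net charge corresponds to well under
  $10^{-3}$ pH units for peptides with any ionizable content.
* Neighbor joining requires at least 3 taxa; a pair of aligned sequences
  with no comparable columns is an error rather than a silent 0.

## Problem sizes

The shipped tests run the digestion oracle on 200 random sequences of up to
60 residues, the host-specificity oracle on tables of up to 200 proteins,
the null-iTRAQ tail check at 1000 proteins, and the end-to-end NCR recovery
on the full pea-like preset (400 proteins, 52 NCRs, 72 contigs); the whole
suite completes in well under a minute on a single core. These sizes were
chosen as the smallest that exercise every code path and the separation
guarantees; the generators scale to larger corpora by changing
`generator_spec()` fields only.

## Known limitations

* Published per-protein RPSM values cannot be reproduced bit-exactly
  without the original digestion-simulator settings; only the definition
  and its internal consistency are guaranteed.
* The 52/65 NCR identification totals and the published 44%/51% cationic
  split depend on supplementary sequence data and are emulated, not
  reproduced; the presets target those percentages by construction.
* Signal-peptide prediction, multiple alignment, genome-level BLAST and
  the greenhouse statistics (ANOVA/LSD) are out of scope; their outputs are
  package inputs.
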