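# nodulomics

Downstream analysis of rhizobial **bacteroid proteomes** and of the plant
**NCR (nodule-specific cysteine-rich) peptides** that shape them.

Legumes of the IRLC clade (pea, lentil, vetch…) house nitrogen-fixing
*Rhizobium* bacteroids inside nodule cells and control them with
defensin-like NCR peptides. Comparing the proteome the same strain
(*R. leguminosarum* bv *viciae* UPM791) expresses in two hosts reveals
host-specific bacterial programs — and the two hosts deliver different NCR
repertoires. This package implements the computational layer of that
comparison for anyone working from PSM count tables, iTRAQ ratios, de novo
peptide lists and nodule transcript contigs:

* **RPSM quantification** — spectral counts normalized to protein
  observability, `RPSM = 100 * PSM / n_predicted_tryptic_peptides`, with a
  configurable in-silico tryptic digestion supplying the denominator;
* **host-specific protein calls** — present in every replicate of one host
  (accumulated spectra ≥ 10), absent from every replicate of the other;
* **iTRAQ ratio classification** — pea/lentil ratio ≥ 2 or ≤ 0.5,
  boundaries inclusive, plus reconciliation of the two approaches;
* **replicon summaries** — chromosome vs plasmid origin of identified
  proteins, with publication-style percentage formatting;
* **NCR mining** — conserved 3-residue tags from a reference alignment,
  tag search over de novo peptides (I = L), six-frame contig translation,
  Smith–Waterman matching with >90% identity / >50% coverage cut-offs,
  mature-peptide isoelectric points (bisection on the Henderson–Hasselbalch
  net charge) and anionic/neutral/cationic binning;
* **neighbor-joining trees** of mature peptides with deterministic Newick
  output;
* a seeded **synthetic-data generator** that emulates every input
  (replicon-structured proteomes, replicate PSM tables with planted
  host-specific proteins, log-normal iTRAQ ratios, NCR genes embedded in
  contigs) so the whole pipeline runs and is testable offline.

## Worked example

Classify published-style iTRAQ ratios and summarize identified proteins per
replicon:

```r
library(nodulomics)

classify_itraq(c(2.62, 2.00, 1.45, 0.50, 0.17))
#> [1] "pea_over"        "pea_over"        "not_significant" "lentil_over"
#> [5] "lentil_over"

pea <- c(Chromosome = 901, pRlvA = 50, pRlvB = 50, pRlvC = 68,
         pRlvD = 3, pRlvE = 32)
replicon_summary_from_counts(pea)
#>     replicon count percent percent_label
#> 1 Chromosome   901    81.6       (81.6%)
#> 2      pRlvA    50     4.5        (4.5%)
#> 3      pRlvB    50     4.5        (4.5%)
#> 4      pRlvC    68     6.2        (6.2%)
#> 5      pRlvD     3     0.3        (0.3%)
#> 6      pRlvE    32     2.9        (2.9%)
```

The ratios at exactly 2.00 and 0.50 are counted as over-represented
(inclusive boundaries), and 81.6% of the 1104 proteins identified in pea
bacteroids are chromosome-encoded. A mature NCR peptide's charge class from
its isoelectric point:

```r
pi <- compute_pi("CPTDDKSSCGGKHHC")
round(pi, 2)
#> [1] 7.35
classify_charge(pi)
#> [1] "neutral"
```

And the symbiotic-performance arithmetic — nitrogen accumulation of pea
plants drops from a mean of 21.96 to 15.74 mg/plant when the GntR-type
regulator RLV_1934A is knocked out:

```r
percent_reduction(21.96, 15.74)
#> [1] 28
```

A full synthetic run (`run_pipeline(tempdir(), preset = "pea-like")`)
generates all inputs, quantifies both hosts, calls host-specific proteins,
classifies iTRAQ ratios, mines the planted NCR peptides and writes every
result table plus a Newick tree, with a checksum manifest that is identical
across reruns at the same seed.

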