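Package: nodulomics
Title: Bacteroid Proteome Quantification and NCR Peptide Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of rhizobial bacteroid proteomes from
    spectral-count data. Computes RPSM abundance values (peptide spectrum
    matches normalized to the number of predicted tryptic peptides), calls
    host-specific proteins from replicate presence/absence with an
    accumulated-spectra floor, classifies iTRAQ pea/lentil ratios against a
    symmetric significance threshold, and summarizes protein origin per
    replicon. Mines nodule-specific cysteine-rich (NCR) peptides from de novo
    peptide lists and nodule transcript contigs via conserved three-residue
    sequence tags, local alignment with identity/coverage cut-offs,
    isoelectric-point computation of processed mature peptides, charge-class
    binning, and neighbor-joining trees of mature peptides. A seeded synthetic
    data generator emulates replicon-structured proteomes, replicate PSM
    tables with planted host-specific proteins, log-scale iTRAQ ratios, and
    NCR genes embedded in transcript contigs, so the full pipeline runs and is
    validated without raw mass-spectrometry inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
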