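Package: segmap
Title: Selective-Genotyping Dissection of Higher-Order Epistasis in Yeast Backcrosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and mapping toolkit for dissecting multi-locus
    (five-plus gene) synthetic interactions underlying yeast colony
    morphology in BY x 3S-style backcrosses. Provides a meiosis and
    backcross simulator under clause-based epistatic phenotype models
    with per-clause penetrance, low-coverage read-count simulation,
    two-state hidden Markov model genotype inference with
    contamination/diploidy/aneuploidy QC, allele-frequency scans over
    phenotype-selected segregants with a fixation threshold and
    breakpoint-bounded interval delimitation, pooled-control artifact
    screening, conditional mapping of loci that complement a non-causal
    allele, and an exact enumeration engine for expected phenotype
    frequencies of arbitrary cross designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
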