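#!/usr/bin/env Rscript

# Demonstrates the QC screen: a small backcross cohort is sequenced at ~4x,
# one segregant is made disomic for chrIV and another is contaminated 50/50
# with an unrelated genotype; the flagged individuals are excluded exactly as
# real contaminated/diploid/aneuploid segregants would be.
#
# Usage: Rscript analysis/04_qc_artifacts.R [seed]

suppressPackageStartupMessages(library(segmap))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

genome <- build_default_genome()
loci <- default_causal_loci()
model <- default_phenotype_model()
panel <- make_snp_panel(genome, 5000, derive_seed(seed, "panel"))
seg <- make_parent_strain(genome, reference_rough_genotype(), loci,
                          background = "B")
by <- founder_strain(genome, "A", loci)

d <- cross_design(seg, by, 24, selection = "rough", name = "qc")
coh <- simulate_backcross_cohort(d, model, genome,
                                 seed = derive_seed(seed, "cohort"),
                                 track = "loci",
                                 extra_positions = panel[, c("chrom", "pos")])
rc <- simulate_reads(coh, panel, 4, 0.005, seed = derive_seed(seed, "reads"))
rc <- inject_artifacts(rc, genome,
                       aneuploid = list(id = coh$ids[1], chrom = "chrIV",
                                        copy_factor = 2),
                       contaminated = list(id = coh$ids[2], fraction = 0.5),
                       seed = derive_seed(seed, "artifacts"))
calls <- infer_genotypes(rc, panel)

write.table(calls$qc, "results/qc_artifact_demo.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(calls$coverage, "results/coverage_artifact_demo.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("QC flags over %d segregants (1 disomic chrIV, 1 contaminated 50%%):\n",
            length(coh$ids)))
print(calls$qc[!calls$qc$pass, c("id", "contaminated_or_diploid", "aneuploid")])
cov1 <- calls$coverage[calls$coverage$id == coh$ids[1], ]
cat(sprintf("chrIV coverage ratio of the disomic segregant: %.2f (others ~1)\n",
            cov1$ratio[cov1$chrom == "chrIV"]))
cat(sprintf("segregants passing QC: %d/%d\n", sum(calls$qc$pass),
            length(coh$ids)))
cat("outputs: results/qc_artifact_demo.tsv, results/coverage_artifact_demo.tsv\n")
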