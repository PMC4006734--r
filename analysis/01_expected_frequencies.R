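#!/usr/bin/env Rscript

# Exact expected phenotype frequencies for the backcross designs under the
# clause-based rough-morphology model, by exhaustive enumeration over the
# segregating loci (with the chrXV linkage handled through the Haldane map).
#
# Usage: Rscript analysis/01_expected_frequencies.R [seed]

suppressPackageStartupMessages(library(segmap))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

genome <- build_default_genome()
loci <- default_causal_loci()
seg <- make_parent_strain(genome, reference_rough_genotype(), loci,
                          background = "B", id = "rough_segregant")
by <- founder_strain(genome, "A", loci)
s3 <- founder_strain(genome, "B", loci)

rows <- list()
for (pi_alt in c(0, 0.1, 0.2, 0.5, 1)) {
  model <- default_phenotype_model(pi_alt = pi_alt)
  d_by <- cross_design(seg, by, 100, name = "by")
  d_s3 <- cross_design(seg, s3, 100, name = "s3")
  p_by <- expected_phenotype_frequency(d_by, model, genome)
  p_s3 <- expected_phenotype_frequency(d_s3, model, genome)
  minor <- expected_allele_given_phenotype(d_s3, model, genome, "END3", "B")
  rows[[length(rows) + 1]] <- data.frame(
    pi_alt = pi_alt,
    rough_freq_by_backcross = p_by,
    rough_freq_s3_backcross = p_s3,
    end3_3s_fraction_of_rough = minor,
    expected_minor_of_88 = 88 * minor)
}
tab <- do.call(rbind, rows)
write.table(tab, "results/expected_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Expected rough-colony frequencies by enumeration\n")
cat(sprintf("  backcross to BY: %.4f (12.5%% observed in the original study)\n",
            tab$rough_freq_by_backcross[tab$pi_alt == 0.2]))
cat(sprintf("  backcross to 3S: %.4f at pi_alt = 0.2 (max %.4f at pi_alt = 1;\n",
            tab$rough_freq_s3_backcross[tab$pi_alt == 0.2],
            tab$rough_freq_s3_backcross[tab$pi_alt == 1]))
cat("   the 21.2% observed in the original study exceeds every enumeration of\n")
cat("   this architecture and is treated as unmodeled excess)\n")
cat(sprintf("  expected END3-3S rough among 88: %.2f\n",
            tab$expected_minor_of_88[tab$pi_alt == 0.2]))
cat("written: results/expected_frequencies.tsv\n")
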