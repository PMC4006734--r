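#!/usr/bin/env Rscript

# Conditional mapping of the alternate rough-morphology architecture: the
# rough 3S-backcross cohort is partitioned at END3, the END3-3S minority is
# screened for regions where all members share BY alleles, candidates are
# pruned with additional progeny and tested for fixation in a
# second-generation backcross.
#
# Usage: Rscript analysis/03_conditional_mapping.R [seed]

suppressPackageStartupMessages(library(segmap))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

res <- run_mapping_study(seed = seed)
co <- res$conditional

cat(sprintf("seed %d\n", seed))
cat(sprintf("END3-3S rough individuals among %d: %d (expected %.2f)\n",
            res$summary$n_rough_3s, res$summary$minor_class_size,
            res$summary$expected_minor_class))

if (is.null(co$tested)) {
  cat("no candidate regions (empty minor class); nothing to report\n")
} else {
  tested <- as.data.frame(co$tested)
  write.table(tested, "results/conditional_regions.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  bedish <- data.frame(chrom = tested$chrom,
                       start = as.integer(tested$start) - 1L,
                       end = as.integer(tested$end),
                       name = paste0(tested$chrom, "_", tested$status))
  write.table(bedish, "results/conditional_regions.bed", sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  cat(sprintf("regions shared by the minor class (previously unidentified): %d\n",
              nrow(tested)))
  for (i in seq_len(nrow(tested))) {
    cat(sprintf("  %-8s %9d-%-9d -> %s\n", tested$chrom[i], tested$start[i],
                tested$end[i], tested$status[i]))
  }
  cat(sprintf("confirmed complementation loci: %s\n",
              if (length(res$summary$confirmed_chroms))
                paste(res$summary$confirmed_chroms, collapse = ", ")
              else "none"))
  cat("outputs: results/conditional_regions.{tsv,bed}\n")
}
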