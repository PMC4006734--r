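# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately written without reusing the package's forward-backward,
# enumeration or scan code paths.

# Small genomes for fast simulation tests.
tiny_genome <- function(n_chrom = 2, len = 1e6, rate = 3.8e-6) {
  genome_map(data.frame(name = paste0("c", seq_len(n_chrom)), length = len),
             recomb_rate = rate)
}

scaled_setup <- function(scale = 0.25) {
  list(genome = build_default_genome(scale),
       loci = default_causal_loci(scale),
       model = default_phenotype_model(scale = scale),
       markers = sga_markers(scale))
}

# The reference rough segregant as a specified-genotype strain (optionally
# carrying the selection-cassette haplotype).
spec_segregant <- function(genome, scale = 1, with_marker = FALSE) {
  loci <- default_causal_loci(scale)
  al <- reference_rough_genotype()
  if (with_marker) {
    mk <- sga_markers(scale)
    loci <- rbind(loci, data.frame(locus = mk$name, chrom = mk$chrom,
                                   pos = mk$pos, stringsAsFactors = FALSE))
    al <- c(al, stats::setNames(mk$allele, mk$name))
  }
  make_parent_strain(genome, al, loci, background = "B")
}

# Brute-force posterior by exhaustive enumeration over all 2^k state paths.
# states coded 1 (A) / 2 (B); emissions given as log-likelihood matrices.
brute_force_posteriors <- function(lA, lB, r) {
  k <- length(lA)
  paths <- as.matrix(expand.grid(rep(list(1:2), k)))
  logw <- numeric(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    st <- paths[p, ]
    w <- log(0.5) + (if (st[1] == 1) lA[1] else lB[1])
    if (k > 1) {
      for (t in 2:k) {
        w <- w + log(if (st[t] != st[t - 1]) r[t - 1] else 1 - r[t - 1])
        w <- w + (if (st[t] == 1) lA[t] else lB[t])
      }
    }
    logw[p] <- w
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  vapply(seq_len(k), function(t) sum(w[paths[, t] == 1]), numeric(1))
}

# Brute-force interval intersection: scan candidate positions and keep those
# covered by every interval.
brute_force_intersection <- function(intervals, positions) {
  covered <- vapply(positions, function(p) {
    all(vapply(intervals, function(iv) p >= iv$start && p <= iv$end,
               logical(1)))
  }, logical(1))
  positions[covered]
}

# Closed-form rough probability for the reference segregant x 3S founder
# backcross, derived by hand. Clause 1 needs the segregating END3-BY,
# MSS11-BY, IRA2-mut: (1/2)^3. Clause 2 needs END3-3S, MSS11-BY, ChrVII-BY
# ((1/2)^3) and co-transmission of IRA2-mut with ChrXV-BY on chrXV
# (probability (1/2)(1 - r), r = Haldane fraction between the two loci):
# total 1/8 + pi_alt (1 - r)/16.
closed_form_s3_rough <- function(pi_alt, genome, loci = default_causal_loci()) {
  d <- abs(loci$pos[loci$locus == "ChrXV"] - loci$pos[loci$locus == "IRA2"])
  r <- 0.5 * (1 - exp(-2 * genome$recomb_rate * d))
  1 / 8 + pi_alt * (1 - r) / 16
}

# Origin labels of a segments-track segregant at every panel site.
origin_at_vec <- function(seg, panel) {
  out <- character(nrow(panel))
  for (ch in unique(panel$chrom)) {
    i <- panel$chrom == ch
    out[i] <- origin_at(seg, ch, panel$pos[i])
  }
  out
}

# Truth-level genotype_calls for a loci-track cohort tracked at panel sites.
truth_calls <- function(cohort, panel) {
  as_genotype_calls(cohort_origin_matrix(cohort, panel), panel,
                    ids = cohort$ids)
}

# The conditional-mapping pipeline at truth-genotype level and reduced scale:
# partition the rough 3S-backcross cohort at END3, scan the END3-3S minority
# for shared BY-allele regions (excluding the five known loci +- 50 kb),
# prune with six extra minor-class progeny, and test candidates for fixation
# among 39 rough vs 12 smooth second-generation backcross progeny typed on a
# 1-kb grid. Returns whether exactly the chrVII/chrXV complementation loci
# were confirmed (with each confirmed span within 30 kb of a true position).
run_conditional_truth <- function(seed, scale = 0.25, n_rough = 88) {
  genome <- build_default_genome(scale)
  loci <- default_causal_loci(scale)
  model <- default_phenotype_model(scale = scale)
  panel <- make_snp_panel(genome, 1500, seed = derive_seed(seed, "panel"))
  seg <- make_parent_strain(genome, reference_rough_genotype(), loci,
                            background = "B")
  s3 <- founder_strain(genome, "B", loci)
  d <- cross_design(seg, s3, n_rough, selection = "rough", name = "c")
  coh <- simulate_backcross_cohort(d, model, genome,
                                   seed = derive_seed(seed, "cohort"),
                                   track = "loci",
                                   extra_positions = panel[, c("chrom", "pos")])
  calls <- truth_calls(coh, panel)
  end3 <- loci[loci$locus == "END3", ]
  part <- partition_by_focal_genotype(calls, end3$chrom, end3$pos)
  if (length(part$B) == 0) return(list(ok = FALSE, why = "empty minor class"))
  prim <- loci[loci$locus %in% c("TRR1", "FLO8", "IRA2", "MSS11", "END3"), ]
  known <- data.frame(chrom = prim$chrom, start = pmax(1, prim$pos - 50000),
                      end = prim$pos + 50000)
  cands <- shared_allele_scan(calls, part$B, allele = "A", min_run = 5,
                              exclude = known)
  if (nrow(cands) == 0) return(list(ok = FALSE, why = "no candidates"))
  sub_pos <- unique(do.call(rbind, lapply(seq_len(nrow(cands)), function(i) {
    data.frame(chrom = cands$chrom[i],
               pos = round(seq(cands$start[i], cands$end[i], by = 1000)))
  })))
  ord <- order(match(sub_pos$chrom, genome$chromosomes$name), sub_pos$pos)
  sub_pos <- sub_pos[ord, , drop = FALSE]
  extras <- NULL
  es <- derive_seed(seed, "extras")
  while (is.null(extras) || nrow(extras) < 6) {
    more <- simulate_backcross_cohort(
      cross_design(seg, s3, 60, selection = "rough", name = "x"),
      model, genome, seed = es, track = "loci", extra_positions = sub_pos)
    es <- es + 1L
    pick <- more$alleles[, "END3"] == "B"
    if (any(pick)) extras <- rbind(extras, more$origins[pick, , drop = FALSE])
  }
  extras <- extras[1:6, , drop = FALSE]
  rownames(extras) <- paste0("e", 1:6)
  cands <- refine_candidates(cands, as_genotype_calls(extras, sub_pos))
  mi <- match(part$B[1], coh$ids)
  p2g <- segregant_from_origins("m", coh$origins[mi, ], coh$positions,
                                genome, coh$alleles[mi, ], loci)
  c2r <- simulate_backcross_cohort(
    cross_design(p2g, s3, 39, selection = "rough", name = "r"),
    model, genome, seed = derive_seed(seed, "g2r"),
    track = "loci", extra_positions = sub_pos)
  c2s <- simulate_backcross_cohort(
    cross_design(p2g, s3, 12, selection = "smooth", name = "s"),
    model, genome, seed = derive_seed(seed, "g2s"),
    track = "loci", extra_positions = sub_pos)
  tested <- second_generation_test(
    cands,
    as_genotype_calls(c2r$origins, sub_pos, ids = c2r$ids),
    as_genotype_calls(c2s$origins, sub_pos, ids = c2s$ids))
  conf <- tested[tested$status == "confirmed", , drop = FALSE]
  tv <- loci[loci$locus %in% c("ChrVII", "ChrXV"), ]
  chrom_ok <- identical(sort(unique(conf$chrom)), sort(unique(tv$chrom)))
  near_ok <- nrow(conf) > 0 && all(vapply(seq_len(nrow(conf)), function(i) {
    any(tv$chrom == conf$chrom[i] & tv$pos >= conf$start[i] - 30000 &
          tv$pos <= conf$end[i] + 30000)
  }, logical(1)))
  list(ok = chrom_ok && near_ok, confirmed = conf)
}
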