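# Shared fixture: a rough-selected 3S-backcross cohort at reduced scale with
# truth-level calls, the setting of the conditional (END3-3S) analysis.
cond_fixture <- function(seed, n = 88, scale = 0.25, pi_alt = 0.2) {
  s <- scaled_setup(scale)
  s$model <- default_phenotype_model(pi_alt = pi_alt, scale = scale)
  panel <- make_snp_panel(s$genome, 1500, seed = seed)
  seg <- spec_segregant(s$genome, scale = scale)
  s3 <- founder_strain(s$genome, "B", s$loci)
  d <- cross_design(seg, s3, n, selection = "rough", name = "cf")
  coh <- simulate_backcross_cohort(d, s$model, s$genome, seed = seed + 1,
                                   track = "loci",
                                   extra_positions = panel[, c("chrom", "pos")])
  list(setup = s, panel = panel, seg = seg, s3 = s3, cohort = coh,
       calls = truth_calls(coh, panel))
}

test_that("partition splits by focal genotype with flanking agreement", {
  fx <- cond_fixture(201)
  end3 <- fx$setup$loci[fx$setup$loci$locus == "END3", ]
  part <- partition_by_focal_genotype(fx$calls, end3$chrom, end3$pos)
  expect_equal(length(part$A) + length(part$B) + length(part$missing),
               length(fx$cohort$ids))
  truth_b <- fx$cohort$ids[fx$cohort$alleles[, "END3"] == "B"]
  # with truth-level calls the B class matches the truth minor class exactly,
  # up to individuals set aside by flanking disagreement
  expect_true(all(setdiff(truth_b, part$missing) %in% part$B))
  expect_true(all(part$B %in% truth_b))

  # a cohort uniform at the focus yields one non-empty class
  mss11 <- fx$setup$loci[fx$setup$loci$locus == "MSS11", ]
  part2 <- partition_by_focal_genotype(fx$calls, mss11$chrom, mss11$pos)
  expect_equal(length(part2$B), 0L)  # MSS11-BY is required for rough
  expect_gt(length(part2$A), 0L)
})

test_that("minor-class size matches the enumeration expectation", {
  sizes <- integer(0)
  expected <- NULL
  for (seed in c(211, 221, 231)) {
    fx <- cond_fixture(seed)
    if (is.null(expected)) {
      d <- cross_design(fx$seg, fx$s3, 88, selection = "rough")
      expected <- 88 * expected_allele_given_phenotype(
        d, fx$setup$model, fx$setup$genome, "END3", "B")
    }
    sizes <- c(sizes, sum(fx$cohort$alleles[, "END3"] == "B"))
  }
  se <- sqrt(expected * (1 - expected / 88))
  expect_lt(abs(mean(sizes) - expected), 3 * se / sqrt(length(sizes)))
})

test_that("shared-allele scan finds the complementation regions and honors exclusions", {
  fx <- cond_fixture(241)
  minors <- fx$cohort$ids[fx$cohort$alleles[, "END3"] == "B"]
  skip_if(length(minors) < 2)  # never triggered in practice at these seeds
  regions <- shared_allele_scan(fx$calls, minors, allele = "A", min_run = 5)
  tv <- fx$setup$loci[fx$setup$loci$locus %in% c("ChrVII", "ChrXV"), ]
  for (i in seq_len(nrow(tv))) {
    expect_true(any(regions$chrom == tv$chrom[i] &
                      regions$start <= tv$pos[i] &
                      regions$end >= tv$pos[i]))
  }
  # excluding an interval removes the region covering it
  excl <- list(interval(tv$chrom[1], tv$pos[1] - 50000, tv$pos[1] + 50000))
  regions2 <- shared_allele_scan(fx$calls, minors, allele = "A", min_run = 5,
                                 exclude = excl)
  expect_false(any(regions2$chrom == tv$chrom[1] &
                     regions2$start <= tv$pos[1] &
                     regions2$end >= tv$pos[1]))

  # a one-member subcohort shares its entire A complement: regions cover all
  # its called-A runs
  one <- shared_allele_scan(fx$calls, minors[1], allele = "A", min_run = 5)
  g1 <- fx$calls$calls[match(minors[1], fx$calls$ids), ]
  expect_gt(nrow(one), 0L)
  for (i in seq_len(nrow(one))) {
    inside <- fx$calls$chrom == one$chrom[i] &
      fx$calls$pos >= one$start[i] & fx$calls$pos <= one$end[i]
    expect_true(all(g1[inside] == 1L, na.rm = TRUE))
  }
})

test_that("chance-shared regions dwindle as the subcohort grows", {
  fx <- cond_fixture(251)
  # use arbitrary (not phenotype-partitioned) members so sharing is pure chance
  counts <- vapply(c(2, 4, 6, 8), function(k) {
    nrow(shared_allele_scan(fx$calls, fx$cohort$ids[seq_len(k)],
                            allele = "B", min_run = 5))
  }, numeric(1))
  expect_gte(counts[1], counts[4])
  expect_gt(counts[1], 0)
})

test_that("refinement refutes chance regions but never model-consistent ones", {
  fx <- cond_fixture(261)
  minors <- fx$cohort$ids[fx$cohort$alleles[, "END3"] == "B"]
  skip_if(length(minors) < 2)
  regions <- shared_allele_scan(fx$calls, minors, allele = "A", min_run = 5)
  n0 <- nrow(regions)

  # extras consistent with the model: rough END3-3S progeny
  extra_pool <- simulate_backcross_cohort(
    cross_design(fx$seg, fx$s3, 150, selection = "rough", name = "xp"),
    fx$setup$model, fx$setup$genome, seed = 262, track = "loci",
    extra_positions = fx$panel[, c("chrom", "pos")])
  ex_ids <- extra_pool$ids[extra_pool$alleles[, "END3"] == "B"]
  skip_if(length(ex_ids) < 2)
  ex_calls <- truth_calls(extra_pool, fx$panel)
  refined <- refine_candidates(regions, ex_calls, subset = ex_ids)
  expect_lte(sum(refined$status == "candidate"), n0)
  tv <- fx$setup$loci[fx$setup$loci$locus %in% c("ChrVII", "ChrXV"), ]
  for (i in seq_len(nrow(tv))) {
    covering <- refined$chrom == tv$chrom[i] &
      refined$start <= tv$pos[i] & refined$end >= tv$pos[i]
    expect_true(all(refined$status[covering] == "candidate"))
  }

  # an extra individual carrying the shared allele everywhere changes nothing
  all_a <- as_genotype_calls(matrix(1L, 1, nrow(fx$panel)), fx$panel,
                             ids = "allA")
  same <- refine_candidates(regions, all_a)
  expect_equal(same$status, regions$status)
  expect_equal(same$start, regions$start)
})

test_that("second-generation fixation test confirms causal regions and refutes markers", {
  fx <- cond_fixture(271)
  tv <- fx$setup$loci[fx$setup$loci$locus %in% c("ChrVII", "ChrXV"), ]
  regions <- data.frame(
    chrom = c(tv$chrom, "chrII"),
    start = c(tv$pos - 20000, 200000), end = c(tv$pos + 20000, 260000),
    n_snps = 10L, allele = "A", status = "candidate",
    stringsAsFactors = FALSE)
  class(regions) <- c("candidate_regions", "data.frame")

  # a minor-class rough segregant crossed back to 3S
  minors <- fx$cohort$ids[fx$cohort$alleles[, "END3"] == "B"]
  skip_if(length(minors) < 1)
  mi <- match(minors[1], fx$cohort$ids)
  p2g <- segregant_from_origins("m1", fx$cohort$origins[mi, ],
                                fx$cohort$positions, fx$setup$genome,
                                fx$cohort$alleles[mi, ], fx$setup$loci)
  typing <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    data.frame(chrom = regions$chrom[i],
               pos = seq(regions$start[i], regions$end[i], by = 500))
  }))
  d2r <- cross_design(p2g, fx$s3, 39, selection = "rough", name = "g2r")
  d2s <- cross_design(p2g, fx$s3, 12, selection = "smooth", name = "g2s")
  coh2r <- simulate_backcross_cohort(d2r, fx$setup$model, fx$setup$genome,
                                     seed = 272, track = "loci",
                                     extra_positions = typing)
  coh2s <- simulate_backcross_cohort(d2s, fx$setup$model, fx$setup$genome,
                                     seed = 273, track = "loci",
                                     extra_positions = typing)
  c2r <- as_genotype_calls(coh2r$origins, typing, ids = coh2r$ids)
  c2s <- as_genotype_calls(coh2s$origins, typing, ids = coh2s$ids)
  tested <- second_generation_test(regions, c2r, c2s)
  expect_equal(tested$status[1:2], c("confirmed", "confirmed"))
  expect_equal(tested$status[3], "refuted")  # unlinked chance region

  # a candidate fixed in rough AND smooth (marker-like) is refuted
  both_fixed <- regions[3, ]
  c_all <- as_genotype_calls(matrix(1L, 10, nrow(typing)), typing,
                             ids = sprintf("x%d", 1:10))
  out <- second_generation_test(both_fixed, c_all, c_all)
  expect_equal(out$status, "refuted")

  # empty candidate set passes through
  empty <- regions[0, ]
  expect_equal(nrow(second_generation_test(empty, c2r, c2s)), 0L)
  expect_error(second_generation_test(regions, as_genotype_calls(
    matrix(integer(0), 0, nrow(typing)), typing, ids = character(0)), c2s),
    class = "segmap_error_bad_subset")
})

test_that("full-cohort shared scan is consistent with the fixation scan", {
  fx <- cond_fixture(281)
  # regions shared by the entire rough cohort must cover the fixed loci found
  # by the frequency scan
  tr <- allele_frequency_scan(fx$calls, backcross_parent = "B")
  fixed <- detect_loci(tr)
  fixed <- fixed[fixed$is_fixed, , drop = FALSE]
  shared <- shared_allele_scan(fx$calls, fx$cohort$ids, allele = "A",
                               min_run = 3)
  for (i in seq_len(nrow(fixed))) {
    expect_true(any(shared$chrom == fixed$chrom[i] &
                      shared$start <= fixed$peak_pos[i] &
                      shared$end >= fixed$peak_pos[i]))
  }
})
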