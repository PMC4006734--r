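make_track <- function(freq, allele = "B", chrom = "c1",
                       pos = seq_along(freq) * 1000, n = 92) {
  out <- data.frame(chrom = chrom, pos = pos, freq = freq,
                    n = rep(n, length(freq)), stringsAsFactors = FALSE)
  attr(out, "allele") <- allele
  class(out) <- c("freq_track", "data.frame")
  out
}

test_that("allele-frequency scans respect denominators and subsets", {
  panel <- data.frame(chrom = "c1", pos = c(1000, 2000, 3000),
                      allele_A = "A", allele_B = "C")
  class(panel) <- c("snp_panel", "data.frame")
  mat <- rbind(c(2L, 2L, NA), c(2L, 1L, NA), c(2L, 2L, 1L), c(2L, 1L, 2L))
  calls <- as_genotype_calls(mat, panel, ids = paste0("s", 1:4))
  tr <- allele_frequency_scan(calls, backcross_parent = "A")
  expect_equal(tr$freq, c(1, 0.5, 0.5))
  expect_equal(tr$n, c(4L, 4L, 2L))

  # complementary subsets average (n-weighted) to the full-cohort frequency
  t1 <- allele_frequency_scan(calls, "A", subset = c("s1", "s2"))
  t2 <- allele_frequency_scan(calls, "A", subset = c("s3", "s4"))
  recomb <- ifelse(tr$n > 0,
                   (ifelse(is.na(t1$freq), 0, t1$freq * t1$n) +
                      ifelse(is.na(t2$freq), 0, t2$freq * t2$n)) / tr$n,
                   NA_real_)
  expect_equal(recomb, tr$freq)
  expect_error(allele_frequency_scan(calls, "A", subset = character(0)),
               class = "segmap_error_bad_subset")
})

test_that("locus detection applies the 95% rule with run filtering and merging", {
  # flat Mendelian track: nothing reported
  expect_equal(nrow(detect_loci(make_track(rep(0.5, 200)))), 0L)

  # boundary behavior: 0.94 is below "95% or higher", 0.95 is at it
  tr <- make_track(c(rep(0.5, 20), rep(0.94, 10), rep(0.5, 20)))
  expect_equal(nrow(detect_loci(tr, threshold = 0.95, min_run = 3)), 0L)
  tr95 <- make_track(c(rep(0.5, 20), rep(0.95, 10), rep(0.5, 20)))
  out <- detect_loci(tr95, threshold = 0.95, min_run = 3)
  expect_equal(nrow(out), 1L)
  expect_equal(out$peak_pos, 21000)  # leftmost maximal site
  expect_false(out$is_fixed)

  # runs separated by a short sub-threshold gap merge into one locus
  f <- c(rep(0.5, 10), rep(0.97, 4), 0.90, rep(1.0, 4), rep(0.5, 10))
  merged <- detect_loci(make_track(f), threshold = 0.95, min_run = 3)
  expect_equal(nrow(merged), 1L)
  expect_true(merged$is_fixed)
  expect_equal(merged$peak_pos, 16000)  # leftmost of the 1.0 sites
  expect_equal(merged$n_snps, 8L)

  # a long gap keeps loci separate, intervals disjoint and sorted
  f2 <- c(rep(1, 5), rep(0.5, 10), rep(1, 5), rep(0.5, 5))
  two <- detect_loci(make_track(f2), threshold = 0.95, min_run = 3)
  expect_equal(nrow(two), 2L)
  expect_true(two$end[1] < two$start[2])
})

test_that("delimitation intersects carrier breakpoint intervals and contains the truth", {
  s <- scaled_setup(0.25)
  genome <- s$genome
  panel <- make_snp_panel(genome, 1500, seed = 71)
  seg <- spec_segregant(genome, scale = 0.25)
  by <- founder_strain(genome, "A", s$loci)
  d <- cross_design(seg, by, 60, selection = "rough", name = "dl")
  coh <- simulate_backcross_cohort(d, s$model, genome, seed = 72,
                                   track = "loci",
                                   extra_positions = panel[, c("chrom", "pos")])
  calls <- truth_calls(coh, panel)
  tr <- allele_frequency_scan(calls, backcross_parent = "A")
  loci_det <- detect_loci(tr)
  expect_gte(nrow(loci_det), 3L)
  truthpos <- s$loci[s$loci$locus %in% c("TRR1", "FLO8", "IRA2"), ]
  for (i in seq_len(nrow(loci_det))) {
    iv <- delimit_locus(loci_det[i, ], calls, genome)
    expect_equal(iv$chrom, loci_det$chrom[i])
    hit <- truthpos[truthpos$chrom == iv$chrom, ]
    if (nrow(hit) == 1L) {
      expect_true(hit$pos >= iv$start && hit$pos <= iv$end)
    }
    # delimited interval contains the peak
    expect_true(loci_det$peak_pos[i] >= iv$start &&
                  loci_det$peak_pos[i] <= iv$end)
  }

  # interval shrinks (weakly) as the carrier set grows
  l1 <- loci_det[1, ]
  iv_small <- delimit_locus(l1, calls, genome, subset = coh$ids[1:15])
  iv_big <- delimit_locus(l1, calls, genome, subset = coh$ids)
  expect_gte(iv_big$start, iv_small$start)
  expect_lte(iv_big$end, iv_small$end)

  # single carrier with no breakpoint on the chromosome: whole chromosome
  one <- matrix(1L, 1, nrow(panel))
  calls1 <- as_genotype_calls(one, panel, ids = "solo")
  lsolo <- l1
  lsolo$allele <- "A"
  iv1 <- delimit_locus(lsolo, calls1, genome)
  expect_equal(iv1$start, 1)
  expect_equal(iv1$end, chrom_length <- genome$chromosomes$length[
    match(l1$chrom, genome$chromosomes$name)])
})

test_that("smoothing is a centered moving average with missing edges", {
  tr <- make_track(rep(0.7, 200))
  sm <- smooth_track(tr, window = 50)
  inner <- !is.na(sm$freq)
  expect_true(all(abs(sm$freq[inner] - 0.7) < 1e-12))
  expect_true(any(is.na(sm$freq)))  # incomplete edge windows

  imp <- make_track(c(rep(0, 100), 1, rep(0, 100)))
  smi <- smooth_track(imp, window = 50)
  nz <- which(!is.na(smi$freq) & smi$freq > 0)
  expect_equal(length(nz), 50L)
  expect_true(all(abs(smi$freq[nz] - 1 / 50) < 1e-12))

  set.seed(81)
  rnd <- make_track(runif(5000))
  smr <- smooth_track(rnd, window = 50)
  ratio <- var(smr$freq, na.rm = TRUE) / var(rnd$freq)
  expect_lt(abs(ratio - 1 / 50), 0.3 / 50)
  expect_error(smooth_track(tr, window = 0),
               class = "segmap_error_bad_params")
})

test_that("control screening separates selected markers from causal loci", {
  s <- scaled_setup(0.25)
  panel <- make_snp_panel(s$genome, 1200, seed = 91)
  seg <- spec_segregant(s$genome, scale = 0.25, with_marker = TRUE)
  ext_loci <- seg$loci
  s3 <- founder_strain(s$genome, "B", ext_loci)
  d <- cross_design(seg, s3, 88, selection = "rough", markers = s$markers,
                    name = "scr")
  coh <- simulate_backcross_cohort(d, s$model, s$genome, seed = 92,
                                   track = "loci",
                                   extra_positions = panel[, c("chrom", "pos")])
  calls <- truth_calls(coh, panel)
  tr <- allele_frequency_scan(calls, backcross_parent = "B")
  loci_det <- detect_loci(tr)
  ctl <- simulate_pooled_control(d, s$model, s$genome, panel,
                                 lambda_pool = 200, n_pool = 600, seed = 93)
  screened <- screen_against_control(loci_det, ctl)
  mk_rows <- screened$chrom == s$markers$chrom &
    screened$start <= s$markers$pos + 30000 &
    screened$end >= s$markers$pos - 30000
  expect_true(any(mk_rows))          # the marker locus was detected
  expect_true(all(screened$artifact[mk_rows]))   # and flagged as artifact
  causal <- screened$chrom %in% c("chrXIII", "chrXIV") & !mk_rows
  expect_true(all(!screened$artifact[causal]))   # causal loci are not

  empty <- detect_loci(make_track(rep(0.5, 50)))
  expect_equal(nrow(screen_against_control(empty, ctl)), 0L)
  bad <- screened[1, ]
  bad$chrom <- "chrZZ"
  expect_error(screen_against_control(bad, ctl),
               class = "segmap_error_missing_control")
})

test_that("introgression strains intersect to a sub-interval containing the truth", {
  s <- scaled_setup(0.25)
  genome <- s$genome
  seg <- spec_segregant(genome, scale = 0.25)
  s3 <- founder_strain(genome, "B", s$loci)
  ira2 <- s$loci[s$loci$locus == "IRA2", ]
  prior <- interval(ira2$chrom, max(1, ira2$pos - 60000), ira2$pos + 60000)

  # identical single-segment strains: intersection is that segment (cut to prior)
  fake <- lapply(1:3, function(i) {
    st <- make_parent_strain(genome, stats::setNames(rep("B", 7), s$loci$locus),
                             s$loci, background = "A", id = paste0("f", i))
    st
  })
  ivf <- fine_map_introgressions(fake, prior, donor_allele = "B", genome)
  expect_equal(c(ivf$start, ivf$end), c(prior$start, prior$end))

  # eight round-6 strains recurrently backcrossed to BY with rough selection:
  # the retained donor (3S-origin) segment over IRA2 carries the mut allele
  set.seed(101)
  by <- founder_strain(genome, "A", s$loci)
  strains_by <- lapply(1:8, function(i) {
    d <- cross_design(seg, by, 1, selection = "rough", rounds = 6,
                      name = paste0("introB", i))
    coh <- simulate_backcross_cohort(d, s$model, genome, track = "segments")
    coh$segregants[[1]]
  })
  ivB <- fine_map_introgressions(strains_by, prior, donor_allele = "B", genome)
  expect_gte(ivB$start, prior$start)
  expect_lte(ivB$end, prior$end)
  expect_true(ira2$pos >= ivB$start && ira2$pos <= ivB$end)

  # adding a strain never widens the interval
  ivB7 <- fine_map_introgressions(strains_by[1:7], donor_allele = "B",
                                  prior = prior, genome = genome)
  expect_gte(ivB$start, ivB7$start)
  expect_lte(ivB$end, ivB7$end)
})
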