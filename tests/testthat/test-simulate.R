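test_that("meiosis of identical parents returns the parent regardless of crossovers", {
  g <- tiny_genome(2)
  loci <- data.frame(locus = "L1", chrom = "c1", pos = 5e5)
  p <- founder_strain(g, "A", loci)
  off <- simulate_meiosis(p, p, g, seed = 1)
  pts <- c(1, 12345, 5e5, 999999)
  for (ch in c("c1", "c2")) {
    expect_equal(origin_at(off, ch, pts), origin_at(p, ch, pts))
  }
  expect_equal(off$alleles, p$alleles)
})

test_that("crossover counts are Poisson with mean = map length", {
  g <- tiny_genome(1, len = 1e6, rate = 3.8e-6)  # 3.8 Morgans
  loci <- data.frame(locus = "L1", chrom = "c1", pos = 5e5)
  p1 <- founder_strain(g, "A", loci)
  p2 <- founder_strain(g, "B", loci)
  set.seed(11)
  nx <- vapply(1:10000, function(i) {
    length(simulate_meiosis(p1, p2, g)$crossovers$c1)
  }, numeric(1))
  se <- sqrt(3.8 / 10000)
  expect_lt(abs(mean(nx) - 3.8), 3 * se)
})

test_that("Mendelian segregation: marginal origin probability is 1/2", {
  g <- tiny_genome(1, len = 1e6)
  loci <- data.frame(locus = "L1", chrom = "c1", pos = 237000)
  p1 <- founder_strain(g, "A", loci)
  p2 <- founder_strain(g, "B", loci)
  d <- cross_design(p1, p2, 10000, name = "f1")
  model <- phenotype_model(list(list(requires = c(L1 = "A"), penetrance = 0)),
                           loci)
  coh <- simulate_backcross_cohort(d, model, g, seed = 3, track = "loci",
                                   extra_positions = data.frame(
                                     chrom = "c1", pos = c(100, 612000)))
  se <- 3 * sqrt(0.25 / 10000)
  expect_lt(abs(mean(coh$alleles[, "L1"] == "A") - 0.5), se)
  expect_lt(abs(mean(coh$origins[, 1] == 1) - 0.5), se)
  expect_lt(abs(mean(coh$origins[, 2] == 1) - 0.5), se)
})

test_that("tetrads segregate exactly 2:2 at every site", {
  s <- scaled_setup(0.2)
  p1 <- founder_strain(s$genome, "A", s$loci)
  p2 <- founder_strain(s$genome, "B", s$loci, ira2_mut = TRUE)
  panel <- make_snp_panel(s$genome, 400, seed = 5)
  set.seed(9)
  pooled <- 0
  n_tet <- 200
  for (i in seq_len(n_tet)) {
    tet <- simulate_tetrad(p1, p2, s$genome)
    O <- vapply(tet, function(sp) match(origin_at_vec(sp, panel), c("A", "B")),
                integer(nrow(panel)))
    expect_true(all(rowSums(O == 1L) == 2L))
    pooled <- pooled + rowSums(O == 1L)
    # mut transmitted to exactly the two spores with 3S origin at IRA2
    muts <- vapply(tet, function(sp) sp$alleles[["IRA2"]] == "mut", logical(1))
    expect_equal(sum(muts), 2L)
  }
  # pooled allele frequency across tetrads is exactly 1/2
  expect_true(all(pooled == 2L * n_tet))

  tet_same <- simulate_tetrad(p1, p1, s$genome, seed = 2)
  for (sp in tet_same) expect_equal(sp$alleles, p1$alleles)
})

test_that("phenotype assignment follows clause order and penetrance", {
  model <- default_phenotype_model()
  g1 <- c(END3 = "A", FLO8 = "B", IRA2 = "mut", MSS11 = "A", TRR1 = "B",
          ChrVII = "B", ChrXV = "B")
  set.seed(1)
  expect_equal(assign_phenotype(g1, model), "rough")  # penetrance 1 clause

  all_b <- c(END3 = "B", FLO8 = "B", IRA2 = "B", MSS11 = "B", TRR1 = "B",
             ChrVII = "B", ChrXV = "B")
  expect_equal(assign_phenotype(all_b, model), "smooth")  # pure 3S founder

  alt <- c(END3 = "B", FLO8 = "B", IRA2 = "mut", MSS11 = "A", TRR1 = "B",
           ChrVII = "A", ChrXV = "A")
  m1 <- default_phenotype_model(pi_alt = 1)
  expect_equal(assign_phenotype(alt, m1), "rough")
  m0 <- default_phenotype_model(pi_alt = 0)
  expect_equal(assign_phenotype(alt, m0), "smooth")
  # alternate clause fires with probability ~ pi_alt
  set.seed(4)
  lab <- replicate(2000, assign_phenotype(alt, model))
  expect_lt(abs(mean(lab == "rough") - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))

  mb <- default_phenotype_model(bumpy = TRUE)
  bump <- c(END3 = "A", FLO8 = "B", IRA2 = "mut", MSS11 = "A", TRR1 = "A",
            ChrVII = "B", ChrXV = "B")
  expect_equal(assign_phenotype(bump, mb), "bumpy")

  expect_error(assign_phenotype(c(END3 = "A"), model),
               class = "segmap_error_missing_locus")
})

test_that("phenotype-selected cohorts honor the contract and record attempts", {
  g <- build_default_genome()
  seg <- spec_segregant(g)
  by <- founder_strain(g, "A")
  model <- default_phenotype_model()
  d <- cross_design(seg, by, 92, selection = "rough", name = "bc")
  coh <- simulate_backcross_cohort(d, model, g, seed = 10, track = "loci")
  expect_equal(length(coh$ids), 92L)
  expect_true(all(coh$phenotype == "rough"))
  expect_gte(coh$attempts, 92L)

  # impossible selection classes are refused by enumeration, not by looping
  d_b <- cross_design(founder_strain(g, "B"), founder_strain(g, "B"), 5,
                      selection = "rough")
  expect_error(simulate_backcross_cohort(d_b, model, g),
               class = "segmap_error_impossible_selection")
})

test_that("unselected cohorts reproduce the enumeration frequency (both tracks)", {
  g <- build_default_genome()
  seg <- spec_segregant(g)
  by <- founder_strain(g, "A")
  model <- default_phenotype_model()
  d <- cross_design(seg, by, 4000, name = "f")
  p_exp <- expected_phenotype_frequency(d, model, g)
  expect_equal(p_exp, 0.125)

  coh_l <- simulate_backcross_cohort(d, model, g, seed = 21, track = "loci")
  f_l <- mean(coh_l$phenotype == "rough")
  se <- sqrt(p_exp * (1 - p_exp) / 4000)
  expect_lt(abs(f_l - p_exp), 3 * se)

  d2 <- cross_design(seg, by, 800, name = "f2")
  coh_s <- simulate_backcross_cohort(d2, model, g, seed = 22, track = "segments")
  f_s <- mean(coh_s$phenotype == "rough")
  expect_lt(abs(f_s - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 800))

  # identical seeds reproduce cohorts bit-exactly
  coh_l2 <- simulate_backcross_cohort(d, model, g, seed = 21, track = "loci")
  expect_identical(coh_l$alleles, coh_l2$alleles)
  expect_identical(coh_l$attempts, coh_l2$attempts)
})

test_that("recurrent backcrossing dilutes the non-recurrent genome ~ (1/2)^rounds", {
  s <- scaled_setup(0.25)
  seg <- spec_segregant(s$genome, scale = 0.25)
  by <- founder_strain(s$genome, "A", s$loci)
  neutral <- data.frame(chrom = c("chrI", "chrX"),
                        pos = round(c(115000, 373000) * 0.25))
  set.seed(33)
  fracs <- c()
  for (lin in 1:25) {
    d <- cross_design(seg, by, 16, selection = "rough", rounds = 6,
                      name = "rbc")
    coh <- simulate_backcross_cohort(d, s$model, s$genome, track = "loci",
                                     extra_positions = neutral)
    fracs <- c(fracs, colMeans(coh$origins == 2L))
  }
  expect_lt(abs(mean(fracs) - 2^-6), 0.04)
  # causal alleles are retained by the selection
  expect_true(all(coh$alleles[, "IRA2"] == "mut"))
})

test_that("read simulation matches its Poisson/binomial law", {
  s <- scaled_setup(0.25)
  panel <- make_snp_panel(s$genome, 800, seed = 2)
  seg <- spec_segregant(s$genome, scale = 0.25)
  by <- founder_strain(s$genome, "A", s$loci)
  d <- cross_design(seg, by, 40, name = "rd")
  coh <- simulate_backcross_cohort(d, s$model, s$genome, seed = 3,
                                   track = "loci",
                                   extra_positions = panel[, c("chrom", "pos")])
  rc <- simulate_reads(coh, panel, lambda = 4, epsilon = 0.01, seed = 4)
  depth <- rc$depth_A + rc$depth_B
  n_obs <- length(depth)
  expect_lt(abs(mean(depth) - 4), 3 * sqrt(4 / n_obs))

  # discordant-read fraction ~ epsilon
  support_true <- ifelse(rc$truth == 1L, rc$depth_A, rc$depth_B)
  disc <- sum(depth - support_true)
  tot <- sum(depth)
  expect_lt(abs(disc / tot - 0.01), 3 * sqrt(0.01 * 0.99 / tot))

  # epsilon = 0: every read supports the true origin
  rc0 <- simulate_reads(coh, panel, lambda = 8, epsilon = 0, seed = 5)
  expect_true(all(ifelse(rc0$truth == 1L, rc0$depth_B, rc0$depth_A) == 0L))
})

test_that("artifact injection shifts coverage and allele fractions as designed", {
  s <- scaled_setup(0.25)
  panel <- make_snp_panel(s$genome, 1000, seed = 6)
  seg <- spec_segregant(s$genome, scale = 0.25)
  by <- founder_strain(s$genome, "A", s$loci)
  d <- cross_design(seg, by, 10, name = "qc")
  coh <- simulate_backcross_cohort(d, s$model, s$genome, seed = 7,
                                   track = "loci",
                                   extra_positions = panel[, c("chrom", "pos")])
  rc <- simulate_reads(coh, panel, lambda = 4, epsilon = 0.005, seed = 8)

  rc2 <- inject_aneuploidy(rc, rc$ids[1], "chrIV", 2, seed = 9)
  j <- rc$chrom == "chrIV"
  m_on <- mean(rc2$depth_A[1, j] + rc2$depth_B[1, j])
  m_off <- mean(rc2$depth_A[1, !j] + rc2$depth_B[1, !j])
  expect_lt(abs(m_on - 8), 3 * sqrt(8 / sum(j)))
  expect_lt(abs(m_off - 4), 3 * sqrt(4 / sum(!j)))
  expect_error(inject_aneuploidy(rc, rc$ids[1], "chrIV", 0),
               class = "segmap_error_bad_artifact")

  # zero mixing fraction is the identity
  rc3 <- inject_contamination(rc, s$genome, rc$ids[2], 0, seed = 10)
  expect_identical(rc3$depth_A, rc$depth_A)

  # 50% opposite-origin contamination concentrates allele fractions near 0.5
  rc4 <- inject_contamination(rc, s$genome, rc$ids[2], 0.5,
                              contaminant = 3L - rc$truth[2, ], seed = 11)
  depth4 <- rc4$depth_A[2, ] + rc4$depth_B[2, ]
  deep <- depth4 >= 4
  fr_true <- ifelse(rc$truth[2, deep] == 1L,
                    rc4$depth_A[2, deep], rc4$depth_B[2, deep]) / depth4[deep]
  expect_lt(abs(mean(fr_true) - 0.5), 0.05)
  expect_error(inject_contamination(rc, s$genome, rc$ids[2], 1.5),
               class = "segmap_error_bad_artifact")
})

test_that("pooled controls are Mendelian except at selected markers", {
  s <- scaled_setup(0.25)
  panel <- make_snp_panel(s$genome, 1200, seed = 12)
  seg <- spec_segregant(s$genome, scale = 0.25, with_marker = TRUE)
  s3 <- founder_strain(s$genome, "B",
                       rbind(s$loci, data.frame(locus = s$markers$name,
                                                chrom = s$markers$chrom,
                                                pos = s$markers$pos)))
  # an unselected pool of a founder x founder cross is Mendelian genome-wide
  ext_loci <- seg$loci
  byf <- founder_strain(s$genome, "A", ext_loci)
  d0 <- cross_design(byf, s3, 600, name = "ctl0")
  ctl0 <- simulate_pooled_control(d0, s$model, s$genome, panel,
                                  lambda_pool = 200, n_pool = 600, seed = 13)
  fA <- ctl0$depth_A / (ctl0$depth_A + ctl0$depth_B)
  expect_lt(abs(mean(fA, na.rm = TRUE) - 0.5), 0.03)
  expect_lt(abs(mean(ctl0$depth_A + ctl0$depth_B) - 200),
            3 * sqrt(200 / nrow(panel)))

  d1 <- cross_design(seg, s3, 600, markers = s$markers, name = "ctl1")
  ctl1 <- simulate_pooled_control(d1, s$model, s$genome, panel,
                                  lambda_pool = 200, n_pool = 600, seed = 14)
  fA1 <- ctl1$depth_A / (ctl1$depth_A + ctl1$depth_B)
  jV <- which(ctl1$chrom == s$markers$chrom)
  near <- jV[which.min(abs(ctl1$pos[jV] - s$markers$pos))]
  expect_gt(fA1[near], 0.95)
  # frequency decays toward 1 - r(d) with distance (Haldane), where the
  # selected haplotype extends
  dist <- 30000
  mid <- jV[which.min(abs(ctl1$pos[jV] - (s$markers$pos + dist)))]
  pred <- 1 - haldane_r(abs(ctl1$pos[mid] - s$markers$pos),
                        s$genome$recomb_rate)
  expect_lt(abs(fA1[mid] - pred), 0.12)
})
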