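#' Reconstruct a segments-style genotype from per-site origins
#'
#' Builds a [new_segregant()] whose origin track is the run-length encoding
#' of known origins at an ordered set of sites, with segment boundaries at
#' midpoints between adjacent sites of different origin. Used to promote a
#' member of a fast (loci-track) cohort into a parent for a further cross.
#'
#' @param id new strain id.
#' @param origins integer vector (1/2) at the tracked sites.
#' @param positions data.frame (`chrom`, `pos`) of the sites.
#' @param genome genome map.
#' @param alleles named allele vector at the causal loci.
#' @param loci causal locus table.
#' @return a [new_segregant()].
#' @export
segregant_from_origins <- function(id, origins, positions, genome, alleles,
                                   loci = default_causal_loci()) {
  segs <- vector("list", nrow(genome$chromosomes))
  names(segs) <- genome$chromosomes$name
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[i]
    L <- genome$chromosomes$length[i]
    j <- which(positions$chrom == ch)
    if (length(j) == 0L) {
      segs[[ch]] <- list(ends = as.numeric(L), origin = 1L)
      next
    }
    o <- origins[j]
    p <- positions$pos[j]
    r <- rle(o)
    cuts <- cumsum(r$lengths)
    ends <- numeric(length(cuts))
    if (length(cuts) > 1L) {
      for (k in seq_len(length(cuts) - 1L)) {
        ends[k] <- floor((p[cuts[k]] + p[cuts[k] + 1L]) / 2)
      }
    }
    ends[length(cuts)] <- L
    segs[[ch]] <- list(ends = ends, origin = as.integer(r$values))
  }
  new_segregant(id, segs, alleles, loci, generation = "reconstructed")
}

# Truth table of causal loci per backcross: the alleles expected to be
# enriched among rough segregants of each cross.
.study_truth <- function(loci) {
  list(
    by_backcross = loci[loci$locus %in% c("TRR1", "FLO8", "IRA2"), ],
    s3_backcross = loci[loci$locus %in% c("MSS11", "END3"), ]
  )
}

#' Run the full two-backcross mapping experiment on synthetic data
#'
#' End-to-end pipeline at the design of the original experiment: sample a
#' rough F1 segregant; backcross it to both founders, collecting
#' phenotype-selected rough cohorts (92 to BY, 88 to 3S by default) under
#' selectable-marker filtering; simulate ~4x read counts; infer genotypes by
#' HMM with QC; scan for non-backcross-parent alleles at the 95% fixation
#' threshold; screen against pooled unselected controls; delimit loci by
#' carrier breakpoints; then run the conditional pipeline on the END3-3S
#' minor class (shared-allele scan, refinement with extra progeny, and a
#' second-generation backcross test of the candidates).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param config a [default_pipeline_config()]-style configuration.
#' @return list with cohorts, calls, locus tables, frequency tracks, the
#'   conditional-mapping results, recovery reports and a `summary` list.
#' @export
run_mapping_study <- function(seed = 1, config = default_pipeline_config(seed)) {
  cfg <- config
  genome <- build_default_genome(cfg$genome$scale, cfg$genome$recomb_rate)
  loci <- default_causal_loci(cfg$genome$scale)
  model <- default_phenotype_model(pi_alt = cfg$model$pi_alt,
                                   bumpy = cfg$model$bumpy,
                                   scale = cfg$genome$scale)
  markers <- sga_markers(cfg$genome$scale)
  panel <- make_snp_panel(genome, cfg$panel$n_snps, derive_seed(seed, "panel"))
  panel_pos <- panel[, c("chrom", "pos")]

  founder_mode <- if (is.null(cfg$founder)) "specified" else cfg$founder
  if (identical(founder_mode, "sampled")) {
    # realistic recombinant founder, re-drawn from the F1 under this seed
    by <- founder_strain(genome, "A", loci)
    s3 <- founder_strain(genome, "B", loci)
    seg0 <- sample_founder_segregant(
      genome, loci, required = reference_rough_genotype(),
      required_origins = markers[, c("chrom", "pos", "allele")],
      f = cfg$model$mut_carrier_fraction, seed = derive_seed(seed, "founder"))
  } else {
    # the study's backcrossed segregant is one fixed strain specified by its
    # causal genotype (plus the selection-cassette haplotype)
    ext_loci <- rbind(loci, data.frame(locus = markers$name,
                                       chrom = markers$chrom,
                                       pos = markers$pos,
                                       stringsAsFactors = FALSE))
    by <- founder_strain(genome, "A", ext_loci)
    s3 <- founder_strain(genome, "B", ext_loci)
    al <- c(reference_rough_genotype(),
            stats::setNames(markers$allele, markers$name))
    seg0 <- make_parent_strain(genome, al, ext_loci, background = "B",
                               id = "rough_segregant")
  }

  design_by <- cross_design(seg0, by, cfg$designs$by_backcross$n_rough,
                            selection = "rough", coverage = cfg$reads$lambda,
                            markers = markers, name = "BYbc")
  design_3s <- cross_design(seg0, s3, cfg$designs$s3_backcross$n_rough,
                            selection = "rough", coverage = cfg$reads$lambda,
                            markers = markers, name = "S3bc")
  coh_by <- simulate_backcross_cohort(design_by, model, genome,
                                      seed = derive_seed(seed, "cohort_by"),
                                      track = "loci", extra_positions = panel_pos)
  coh_3s <- simulate_backcross_cohort(design_3s, model, genome,
                                      seed = derive_seed(seed, "cohort_3s"),
                                      track = "loci", extra_positions = panel_pos)

  rc_by <- simulate_reads(coh_by, panel, cfg$reads$lambda, cfg$reads$epsilon,
                          seed = derive_seed(seed, "reads_by"))
  rc_3s <- simulate_reads(coh_3s, panel, cfg$reads$lambda, cfg$reads$epsilon,
                          seed = derive_seed(seed, "reads_3s"))
  hp <- hmm_params(epsilon = cfg$hmm$epsilon,
                   recomb_rate = cfg$genome$recomb_rate,
                   min_posterior = cfg$hmm$min_posterior,
                   min_switch = cfg$hmm$min_switch)
  calls_by <- infer_genotypes(rc_by, panel, hp)
  calls_3s <- infer_genotypes(rc_3s, panel, hp)
  pass_by <- calls_by$qc$id[calls_by$qc$pass]
  pass_3s <- calls_3s$qc$id[calls_3s$qc$pass]

  track_by <- allele_frequency_scan(calls_by, backcross_parent = "A",
                                    subset = pass_by)
  track_3s <- allele_frequency_scan(calls_3s, backcross_parent = "B",
                                    subset = pass_3s)
  loci_by <- detect_loci(track_by, cfg$mapping$threshold, cfg$mapping$min_run)
  loci_3s <- detect_loci(track_3s, cfg$mapping$threshold, cfg$mapping$min_run)

  ctl_by <- simulate_pooled_control(design_by, model, genome, panel,
                                    lambda_pool = cfg$control$lambda_pool,
                                    epsilon = cfg$reads$epsilon,
                                    n_pool = cfg$control$n_pool,
                                    seed = derive_seed(seed, "control_by"))
  ctl_3s <- simulate_pooled_control(design_3s, model, genome, panel,
                                    lambda_pool = cfg$control$lambda_pool,
                                    epsilon = cfg$reads$epsilon,
                                    n_pool = cfg$control$n_pool,
                                    seed = derive_seed(seed, "control_3s"))
  loci_by <- screen_against_control(loci_by, ctl_by,
                                    cfg$mapping$control_threshold)
  loci_3s <- screen_against_control(loci_3s, ctl_3s,
                                    cfg$mapping$control_threshold)

  delim_one <- function(loci_tab, calls, pass) {
    keep <- which(!loci_tab$artifact)
    lapply(keep, function(i) {
      iv <- delimit_locus(loci_tab[i, ], calls, genome, subset = pass)
      list(locus = loci_tab[i, ], interval = iv)
    })
  }
  delim_by <- delim_one(loci_by, calls_by, pass_by)
  delim_3s <- delim_one(loci_3s, calls_3s, pass_3s)

  truth <- .study_truth(loci)
  rec_by <- locus_recovery_report(loci_by, truth$by_backcross)
  rec_3s <- locus_recovery_report(loci_3s, truth$s3_backcross)

  # conditional pipeline on the END3-3S minor class of the 3S backcross
  end3 <- loci[loci$locus == "END3", ]
  part <- partition_by_focal_genotype(calls_3s, end3$chrom, end3$pos,
                                      subset = pass_3s)
  # sites strongly linked to an already-identified locus (or marker artifact)
  # are attributable to it: exclude the detected intervals plus a margin
  known <- rbind(as.data.frame(loci_by)[, c("chrom", "start", "end")],
                 as.data.frame(loci_3s)[, c("chrom", "start", "end")])
  known$start <- pmax(1, known$start - cfg$conditional$exclude_margin)
  known$end <- known$end + cfg$conditional$exclude_margin
  conditional <- list(minor_ids = part$B, candidates = NULL, confirmed = NULL)
  if (length(part$B) > 0L) {
    cands <- shared_allele_scan(calls_3s, part$B, allele = "A",
                                min_run = cfg$conditional$min_run,
                                exclude = known)
    if (nrow(cands) > 0L) {
      # follow-up genotyping is done with markers designed at will inside the
      # candidate regions (the real SNP set is an order of magnitude denser
      # than the mapping panel), emulated as a uniform typing grid plus the
      # panel sites
      step <- cfg$conditional$typing_step
      grids <- lapply(seq_len(nrow(cands)), function(i) {
        data.frame(chrom = cands$chrom[i],
                   pos = unique(round(seq(cands$start[i], cands$end[i],
                                          by = step))),
                   stringsAsFactors = FALSE)
      })
      in_regions <- rep(FALSE, nrow(panel))
      for (i in seq_len(nrow(cands))) {
        in_regions <- in_regions | (panel$chrom == cands$chrom[i] &
                                      panel$pos >= cands$start[i] &
                                      panel$pos <= cands$end[i])
      }
      sub_pos <- rbind(panel[in_regions, c("chrom", "pos")],
                       do.call(rbind, grids))
      sub_pos <- unique(sub_pos)
      ord <- order(match(sub_pos$chrom, genome$chromosomes$name), sub_pos$pos)
      sub_pos <- sub_pos[ord, , drop = FALSE]
      rownames(sub_pos) <- NULL
      sub_panel <- sub_pos

      # extra rough END3-3S progeny, typed at markers within each candidate
      extras <- NULL
      es <- derive_seed(seed, "extras")
      while (is.null(extras) || nrow(extras) < cfg$conditional$n_extra) {
        more <- simulate_backcross_cohort(
          cross_design(seg0, s3, 60, selection = "rough",
                       coverage = cfg$reads$lambda, markers = markers,
                       name = "S3bc_extra"),
          model, genome, seed = es, track = "loci", extra_positions = sub_pos)
        es <- es + 1L
        pick <- more$alleles[, "END3"] == "B"
        if (any(pick)) {
          extras <- rbind(extras, more$origins[pick, , drop = FALSE])
        }
      }
      extras <- extras[seq_len(cfg$conditional$n_extra), , drop = FALSE]
      rownames(extras) <- sprintf("extra_%02d", seq_len(nrow(extras)))
      cands <- refine_candidates(cands, as_genotype_calls(extras, sub_panel))

      # second-generation backcross of a minor-class segregant to 3S
      mi <- match(part$B[1], coh_3s$ids)
      parent2g <- segregant_from_origins(
        "minor_rough", coh_3s$origins[mi, ], coh_3s$positions, genome,
        coh_3s$alleles[mi, ], loci)
      d2r <- cross_design(parent2g, s3, cfg$conditional$n_rough2,
                          selection = "rough", coverage = cfg$reads$lambda,
                          markers = markers, name = "S3bc2_rough")
      d2s <- cross_design(parent2g, s3, cfg$conditional$n_smooth2,
                          selection = "smooth", coverage = cfg$reads$lambda,
                          markers = markers, name = "S3bc2_smooth")
      coh2r <- simulate_backcross_cohort(d2r, model, genome,
                                         seed = derive_seed(seed, "secondgen_rough"),
                                         track = "loci", extra_positions = sub_pos)
      coh2s <- simulate_backcross_cohort(d2s, model, genome,
                                         seed = derive_seed(seed, "secondgen_smooth"),
                                         track = "loci", extra_positions = sub_pos)
      calls2r <- as_genotype_calls(coh2r$origins, sub_panel, ids = coh2r$ids)
      calls2s <- as_genotype_calls(coh2s$origins, sub_panel, ids = coh2s$ids)
      tested <- second_generation_test(cands, calls2r, calls2s)
      conditional$candidates <- cands
      conditional$confirmed <- tested[tested$status == "confirmed", ,
                                      drop = FALSE]
      conditional$tested <- tested
    }
  }

  exp_by <- expected_phenotype_frequency(design_by, model, genome)
  exp_3s <- expected_phenotype_frequency(design_3s, model, genome)
  exp_minor <- expected_allele_given_phenotype(design_3s, model, genome,
                                               "END3", "B")
  summary <- list(
    seed = seed,
    n_rough_by = length(coh_by$ids), n_rough_3s = length(coh_3s$ids),
    raw_rough_freq_by = length(coh_by$ids) / coh_by$marker_pass,
    raw_rough_freq_3s = length(coh_3s$ids) / coh_3s$marker_pass,
    expected_rough_freq_by = exp_by,
    expected_rough_freq_3s = exp_3s,
    qc_pass_by = sum(calls_by$qc$pass), qc_pass_3s = sum(calls_3s$qc$pass),
    n_loci_by = sum(!loci_by$artifact), n_loci_3s = sum(!loci_3s$artifact),
    loci_by_chroms = loci_by$chrom[!loci_by$artifact],
    loci_3s_chroms = loci_3s$chrom[!loci_3s$artifact],
    recall_by = rec_by$recall, recall_3s = rec_3s$recall,
    minor_class_size = length(part$B),
    expected_minor_class = length(coh_3s$ids) * exp_minor,
    n_candidates = if (is.null(conditional$candidates)) 0L
                   else nrow(conditional$candidates),
    confirmed_chroms = if (is.null(conditional$confirmed)) character(0)
                       else conditional$confirmed$chrom
  )
  list(config = cfg, genome = genome, panel = panel, model = model,
       seg0 = seg0, cohorts = list(by = coh_by, s3 = coh_3s),
       reads = list(by = rc_by, s3 = rc_3s),
       calls = list(by = calls_by, s3 = calls_3s),
       tracks = list(by = track_by, s3 = track_3s),
       loci = list(by = loci_by, s3 = loci_3s),
       controls = list(by = ctl_by, s3 = ctl_3s),
       delimited = list(by = delim_by, s3 = delim_3s),
       recovery = list(by = rec_by, s3 = rec_3s),
       conditional = conditional,
       truth = truth,
       summary = summary)
}

#' Write a machine-readable pipeline summary as JSON
#'
#' @param result a [run_mapping_study()] result.
#' @param path output file.
#' @export
write_pipeline_summary <- function(result, path) {
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
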