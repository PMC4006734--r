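#' Write / read a SNP panel as TSV
#'
#' Columns `chrom`, `pos`, `allele_A`, `allele_B`; positions sorted within
#' chromosome. Round-trips losslessly.
#'
#' @param panel a [make_snp_panel()] panel.
#' @param path file path.
#' @export
write_snp_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_panel
#' @export
read_snp_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer",
                                         "character", "character"))
  if (!identical(names(df), c("chrom", "pos", "allele_A", "allele_B"))) {
    segmap_abort("segmap_error_malformed_header",
                 "expected columns chrom, pos, allele_A, allele_B")
  }
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      segmap_abort("segmap_error_unsorted_positions",
                   paste0("positions not strictly increasing on ", ch))
    }
  }
  if (any(df$allele_A == df$allele_B)) {
    segmap_abort("segmap_error_not_biallelic",
                 "allele_A and allele_B must differ at every site")
  }
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Write / read a hard-call genotype matrix as TSV
#'
#' Wide layout: an `id` column followed by one column per SNP (named
#' `chrom:pos`), values `A`, `B` or `N` (missing).
#'
#' @param calls a `genotype_calls` object (or integer matrix with 1/2/NA).
#' @param panel SNP panel aligned to the columns.
#' @param path file path.
#' @export
write_genotype_matrix <- function(calls, panel, path) {
  mat <- if (inherits(calls, "genotype_calls")) calls$calls else calls
  ids <- if (inherits(calls, "genotype_calls")) calls$ids else rownames(mat)
  lab <- matrix(c("A", "B")[mat], nrow(mat), ncol(mat))
  lab[is.na(mat)] <- "N"
  df <- data.frame(id = ids, lab, stringsAsFactors = FALSE)
  names(df) <- c("id", paste0(panel$chrom, ":", panel$pos))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @return `read_genotype_matrix`: list with integer matrix `calls`
#'   (1/2/NA), `ids`, `chrom`, `pos`.
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "id") {
    segmap_abort("segmap_error_malformed_header",
                 "first column must be 'id'")
  }
  keys <- strsplit(names(df)[-1], ":", fixed = TRUE)
  chrom <- vapply(keys, `[`, "", 1L)
  pos <- as.integer(vapply(keys, `[`, "", 2L))
  lab <- as.matrix(df[, -1, drop = FALSE])
  mat <- matrix(match(lab, c("A", "B")), nrow(lab), ncol(lab))
  rownames(mat) <- df$id
  list(calls = mat, ids = df$id, chrom = chrom, pos = pos)
}

#' Write / read per-segregant allele depths as long TSV
#'
#' Columns `segregant`, `chrom`, `pos`, `depth_A`, `depth_B`.
#'
#' @param rc a `read_counts` object.
#' @param path file path.
#' @export
write_read_counts <- function(rc, path) {
  n <- nrow(rc$depth_A)
  m <- ncol(rc$depth_A)
  df <- data.frame(
    segregant = rep(rc$ids, each = m),
    chrom = rep(rc$chrom, n),
    pos = rep(rc$pos, n),
    depth_A = as.vector(t(rc$depth_A)),
    depth_B = as.vector(t(rc$depth_B)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_counts
#' @param panel SNP panel the counts must align to.
#' @return `read_read_counts`: a `read_counts` object (without simulation
#'   truth).
#' @export
read_read_counts <- function(path, panel) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("segregant", "chrom", "pos", "depth_A", "depth_B")
  if (!identical(names(df), need)) {
    segmap_abort("segmap_error_malformed_header",
                 paste0("expected columns ", paste(need, collapse = ", ")))
  }
  ids <- unique(df$segregant)
  key <- paste(panel$chrom, panel$pos)
  m <- nrow(panel)
  dA <- matrix(0L, length(ids), m, dimnames = list(ids, NULL))
  dB <- matrix(0L, length(ids), m, dimnames = list(ids, NULL))
  idx <- match(paste(df$chrom, df$pos), key)
  if (anyNA(idx)) {
    segmap_abort("segmap_error_bad_panel",
                 "read-count file contains sites absent from the panel")
  }
  ri <- match(df$segregant, ids)
  dA[cbind(ri, idx)] <- df$depth_A
  dB[cbind(ri, idx)] <- df$depth_B
  structure(list(depth_A = dA, depth_B = dB, ids = ids,
                 chrom = panel$chrom, pos = panel$pos, truth = NULL,
                 lambda = NA_real_, epsilon = NA_real_),
            class = "read_counts")
}

#' Write / read phenotype labels as TSV
#'
#' @param ids segregant ids.
#' @param phenotype labels.
#' @param path file path.
#' @export
write_phenotypes <- function(ids, phenotype, path) {
  utils::write.table(data.frame(id = ids, phenotype = phenotype),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!identical(names(df), c("id", "phenotype"))) {
    segmap_abort("segmap_error_malformed_header",
                 "expected columns id, phenotype")
  }
  df
}

#' Export detected loci
#'
#' `write_loci_tsv` writes the full locus table; `write_loci_bed` writes
#' BED4+ rows (`chrom`, 0-based `start`, half-open `end`, name, peak
#' frequency), converting from the package's 1-based inclusive coordinates.
#'
#' @param loci a [detect_loci()] result.
#' @param path file path.
#' @export
write_loci_tsv <- function(loci, path) {
  utils::write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_loci_tsv
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$chrom,
                    start = as.integer(loci$start) - 1L,
                    end = as.integer(loci$end),
                    name = sprintf("%s_%s%s", loci$chrom, loci$allele,
                                   ifelse(loci$artifact, "_artifact", "")),
                    score = loci$peak_freq,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF with per-sample allele depths
#'
#' Accepts biallelic SNP records with an `AD` FORMAT field (REF depth, ALT
#' depth per sample); REF is taken as the "A" (BY-like) allele and ALT as
#' "B". Multiallelic records are rejected.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return a `read_counts` object.
#' @export
read_vcf_counts <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    segmap_abort("segmap_error_missing_dependency",
                 "reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE))) {
    segmap_abort("segmap_error_multiallelic",
                 "multiallelic VCF records are not supported")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || nrow(ad) == 0L) {
    segmap_abort("segmap_error_malformed_header",
                 "VCF lacks a per-sample AD field")
  }
  split_ad <- function(x, field) {
    out <- suppressWarnings(as.integer(vapply(
      strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE),
      `[`, "", field)))
    out[is.na(out)] <- 0L
    out
  }
  dA <- apply(ad, 2L, split_ad, field = 1L)
  dB <- apply(ad, 2L, split_ad, field = 2L)
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch], strictly = TRUE)) {
      segmap_abort("segmap_error_unsorted_positions",
                   paste0("VCF positions not strictly increasing on ", ch))
    }
  }
  structure(list(depth_A = t(dA), depth_B = t(dB), ids = colnames(ad),
                 chrom = chrom, pos = as.integer(pos), truth = NULL,
                 lambda = NA_real_, epsilon = NA_real_),
            class = "read_counts")
}

#' Pipeline configuration (YAML)
#'
#' A configuration names the genome/panel scale, the phenotype model
#' parameters, the cross designs, sequencing and HMM parameters, the mapping
#' thresholds and a mandatory master seed (there is no wall-clock seeding
#' anywhere in the package).
#'
#' @param path YAML file path.
#' @return validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg configuration list.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname read_pipeline_config
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) {
    segmap_abort("segmap_error_bad_config",
                 "config must carry an explicit seed")
  }
  defaults <- default_pipeline_config(seed = cfg$seed)
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot_cfg <- function(ok, msg) {
    if (!ok) segmap_abort("segmap_error_bad_config", msg)
  }
  stopifnot_cfg(cfg$mapping$threshold > 0 && cfg$mapping$threshold <= 1,
                "mapping threshold must lie in (0, 1]")
  stopifnot_cfg(cfg$mapping$min_run >= 1, "min_run must be >= 1")
  stopifnot_cfg(cfg$mapping$window >= 1, "window must be >= 1")
  stopifnot_cfg(cfg$hmm$epsilon >= 0 && cfg$hmm$epsilon < 0.5,
                "epsilon must lie in [0, 0.5)")
  stopifnot_cfg(cfg$hmm$min_posterior > 0.5 && cfg$hmm$min_posterior <= 1,
                "min_posterior must lie in (0.5, 1]")
  stopifnot_cfg(cfg$model$pi_alt >= 0 && cfg$model$pi_alt <= 1,
                "pi_alt must lie in [0, 1]")
  stopifnot_cfg(cfg$model$mut_carrier_fraction >= 0 &&
                  cfg$model$mut_carrier_fraction <= 1,
                "mut_carrier_fraction must lie in [0, 1]")
  stopifnot_cfg(cfg$reads$lambda > 0, "lambda must be > 0")
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

#' Default configuration of the two-backcross mapping experiment
#'
#' 16-chromosome genome at full scale, 5,000-SNP panel, default phenotype
#' model, 92 rough segregants from the backcross to BY and 88 from the
#' backcross to 3S, ~4x coverage at 0.5% read error, 95% fixation threshold,
#' 50-SNP control smoothing window.
#'
#' @param seed master seed.
#' @return configuration list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  cfg <- list(
    seed = seed,
    founder = "specified",
    genome = list(scale = 1, recomb_rate = 3.8e-6),
    panel = list(n_snps = 5000),
    model = list(pi_alt = 0.2, bumpy = FALSE, mut_carrier_fraction = 0.8),
    designs = list(
      by_backcross = list(n_rough = 92, parent = "BY"),
      s3_backcross = list(n_rough = 88, parent = "3S")
    ),
    reads = list(lambda = 4, epsilon = 0.005),
    hmm = list(epsilon = 0.005, min_posterior = 0.95, min_switch = 1e-6),
    mapping = list(threshold = 0.95, min_run = 3, window = 50,
                   control_threshold = 0.8),
    control = list(n_pool = 2000, lambda_pool = 200),
    conditional = list(min_run = 5, n_extra = 6, n_rough2 = 39,
                       n_smooth2 = 12, exclude_margin = 50000,
                       typing_step = 1000)
  )
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}
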