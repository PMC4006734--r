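#' Genome coordinate map
#'
#' A `genome_map` holds an ordered set of chromosomes with their lengths and a
#' uniform recombination rate (Morgans per bp). Coordinates throughout the
#' package are 1-based and inclusive; BED export converts to 0-based
#' half-open.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param recomb_rate Morgans per bp; default 3.8e-6 (~0.38 cM/kb, typical for
#'   *S. cerevisiae*, whose genetic map totals roughly 4,500 cM over 12 Mb).
#' @return object of class `genome_map`.
#' @export
genome_map <- function(chromosomes, recomb_rate = 3.8e-6) {
  if (!is.data.frame(chromosomes) ||
      !all(c("name", "length") %in% names(chromosomes))) {
    segmap_abort("segmap_error_bad_genome",
                 "chromosomes must be a data.frame with columns name, length")
  }
  if (anyDuplicated(chromosomes$name)) {
    segmap_abort("segmap_error_bad_genome", "chromosome names must be unique")
  }
  if (any(chromosomes$length <= 0)) {
    segmap_abort("segmap_error_bad_genome", "chromosome lengths must be > 0")
  }
  if (!is.numeric(recomb_rate) || length(recomb_rate) != 1L || recomb_rate <= 0) {
    segmap_abort("segmap_error_bad_genome", "recomb_rate must be a positive scalar")
  }
  chromosomes$name <- as.character(chromosomes$name)
  structure(
    list(chromosomes = chromosomes[, c("name", "length")],
         recomb_rate = recomb_rate,
         coordinates = "1-based-inclusive"),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %d chromosomes, %.2f Mb, %.2g M/bp\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              x$recomb_rate))
  invisible(x)
}

# S288c-like karyotype (bp), 16 chromosomes totalling ~12.07 Mb.
.yeast_karyotype <- c(
  chrI = 230218L,  chrII = 813184L,  chrIII = 316620L, chrIV = 1531933L,
  chrV = 576874L,  chrVI = 270161L,  chrVII = 1090940L, chrVIII = 562643L,
  chrIX = 439888L, chrX = 745751L,   chrXI = 666816L,  chrXII = 1078177L,
  chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L
)

#' Default 16-chromosome yeast-like genome
#'
#' Deterministically builds a genome map mimicking the *S. cerevisiae*
#' karyotype (16 chromosomes, ~12 Mb at `scale = 1`). `scale` shrinks every
#' chromosome proportionally, which is useful for fast tests.
#'
#' @param scale fraction of full chromosome lengths, in (0, 1].
#' @param recomb_rate Morgans per bp.
#' @return a [genome_map()].
#' @export
build_default_genome <- function(scale = 1, recomb_rate = 3.8e-6) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1) {
    segmap_abort("segmap_error_bad_scale", "scale must be in (0, 1]")
  }
  genome_map(
    data.frame(name = names(.yeast_karyotype),
               length = pmax(1, round(.yeast_karyotype * scale)),
               stringsAsFactors = FALSE),
    recomb_rate = recomb_rate
  )
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) {
    segmap_abort("segmap_error_unknown_chromosome",
                 paste0("unknown chromosome: ",
                        paste(chrom[is.na(i)], collapse = ", ")))
  }
  genome$chromosomes$length[i]
}

#' Build a SNP panel by uniform placement
#'
#' Places `n_snps` biallelic sites uniformly at random over the genome
#' (per-chromosome counts proportional to length in expectation), sorted and
#' unique by position. Stands in for an empirically ascertained SNP set
#' between two sequenced parents.
#'
#' @param genome a [genome_map()].
#' @param n_snps number of sites (>= 1, at most the total genome length).
#' @param seed integer seed or `NULL`.
#' @return data.frame of class `snp_panel` with columns `chrom`, `pos`,
#'   `allele_A`, `allele_B`.
#' @export
make_snp_panel <- function(genome, n_snps, seed = NULL) {
  total <- sum(genome$chromosomes$length)
  if (!is.numeric(n_snps) || n_snps < 1) {
    segmap_abort("segmap_error_bad_panel", "n_snps must be >= 1")
  }
  if (n_snps > total) {
    segmap_abort("segmap_error_bad_panel",
                 "n_snps exceeds total genome length")
  }
  use_seed(seed)
  n_snps <- as.integer(n_snps)
  chroms <- genome$chromosomes
  got <- data.frame(chrom = character(), pos = integer())
  while (nrow(got) < n_snps) {
    need <- n_snps - nrow(got)
    ci <- sample.int(nrow(chroms), need, replace = TRUE,
                     prob = chroms$length)
    pos <- as.integer(ceiling(stats::runif(need) * chroms$length[ci]))
    got <- unique(rbind(got, data.frame(chrom = chroms$name[ci], pos = pos,
                                        stringsAsFactors = FALSE)))
  }
  ord <- order(match(got$chrom, chroms$name), got$pos)
  got <- got[ord, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n_snps, replace = TRUE)
  shift <- sample.int(3L, n_snps, replace = TRUE)
  b <- bases[((match(a, bases) - 1L + shift) %% 4L) + 1L]
  panel <- data.frame(chrom = got$chrom, pos = got$pos,
                      allele_A = a, allele_B = b,
                      stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Genomic interval (1-based, inclusive)
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return object of class `interval`.
#' @export
interval <- function(chrom, start, end) {
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L) {
    segmap_abort("segmap_error_bad_interval", "interval fields must be scalars")
  }
  if (is.na(start) || is.na(end) || start > end) {
    segmap_abort("segmap_error_bad_interval", "interval requires start <= end")
  }
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end)),
            class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%s-%s\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ",")))
  invisible(x)
}

#' Intersect two intervals on the same chromosome
#'
#' @param a,b [interval()] objects.
#' @return their intersection.
#' @export
interval_intersect <- function(a, b) {
  if (a$chrom != b$chrom) {
    segmap_abort("segmap_error_chrom_mismatch",
                 "intervals lie on different chromosomes")
  }
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  if (s > e) {
    segmap_abort("segmap_error_empty_intersection",
                 sprintf("empty intersection on %s", a$chrom))
  }
  interval(a$chrom, s, e)
}

interval_contains <- function(x, chrom, pos) {
  x$chrom == chrom && pos >= x$start && pos <= x$end
}

interval_width <- function(x) x$end - x$start + 1

#' Smallest region bounded by recombination breakpoints
#'
#' Given, for each carrier of an enriched allele, the maximal interval around
#' a mapping peak over which that carrier holds the allele, returns the
#' region common to all carriers: the intersection of the intervals. This is
#' the minimum region delimited by recombination breakpoints among
#' individuals sharing the allele at the peak.
#'
#' @param carrier_intervals list of [interval()] on one chromosome.
#' @return the intersection [interval()].
#' @export
minimal_bounded_interval <- function(carrier_intervals) {
  if (length(carrier_intervals) == 0L) {
    segmap_abort("segmap_error_no_carriers", "no carrier intervals supplied")
  }
  Reduce(interval_intersect, carrier_intervals)
}
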