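#' Partition a cohort by genotype at a focal locus
#'
#' Splits segregants by their genotype at a focal position (e.g. END3) read
#' off the panel: the hard calls at the SNPs flanking the position must agree
#' and be non-missing, otherwise the individual is set aside. Requiring
#' flanking agreement guards against misclassifying individuals whose
#' recombination breakpoint falls between the focal gene and a single nearest
#' marker.
#'
#' @param calls a `genotype_calls` object.
#' @param chrom,pos focal locus position.
#' @param subset ids/indices to partition (default all).
#' @return list with character-id vectors `A`, `B`, `missing`, plus
#'   `site_index` (the flanking panel columns used) and `site_pos`.
#' @export
partition_by_focal_genotype <- function(calls, chrom, pos, subset = NULL) {
  rows <- .subset_rows(calls, subset)
  j <- which(calls$chrom == chrom)
  if (length(j) == 0L) {
    segmap_abort("segmap_error_unknown_chromosome",
                 paste0("no panel sites on ", chrom))
  }
  left <- j[calls$pos[j] <= pos]
  right <- j[calls$pos[j] >= pos]
  sites <- unique(c(if (length(left)) left[length(left)],
                    if (length(right)) right[1L]))
  g <- calls$calls[rows, sites, drop = FALSE]
  agree <- apply(g, 1L, function(x) {
    if (anyNA(x)) NA_integer_ else if (all(x == x[1L])) x[1L] else NA_integer_
  })
  if (all(is.na(agree))) {
    segmap_abort("segmap_error_missing_locus",
                 "focal locus entirely missing in the subset")
  }
  ids <- calls$ids[rows]
  list(A = ids[!is.na(agree) & agree == 1L],
       B = ids[!is.na(agree) & agree == 2L],
       missing = ids[is.na(agree)],
       site_index = sites, site_pos = calls$pos[sites])
}

# Mask panel sites covered by a set of intervals (list of interval or a
# locus_calls-style data.frame).
.exclusion_mask <- function(chrom, pos, exclude) {
  mask <- rep(FALSE, length(pos))
  if (is.null(exclude)) return(mask)
  if (is.data.frame(exclude)) {
    rows <- seq_len(nrow(exclude))
    for (i in rows) {
      mask <- mask | (chrom == exclude$chrom[i] &
                        pos >= exclude$start[i] & pos <= exclude$end[i])
    }
  } else {
    for (iv in exclude) {
      mask <- mask | (chrom == iv$chrom & pos >= iv$start & pos <= iv$end)
    }
  }
  mask
}

#' Scan for regions where a subcohort shares one parent's allele
#'
#' Finds maximal runs (at least `min_run` panel SNPs) over which every member
#' of the subcohort carries the named allele; missing calls do not veto
#' sharing. Sites inside `exclude` (previously identified causal loci and
#' marker-artifact regions) are removed first, so the output lists only
#' previously unidentified shared regions.
#'
#' @param calls a `genotype_calls` object.
#' @param subset ids/indices of the subcohort (non-empty).
#' @param allele `"A"` or `"B"`: the shared allele sought.
#' @param min_run minimum run length in SNPs (default 5, matching
#'   [detect_loci()]; at the default panel density a smaller subcohort's true
#'   shared region spans only a few tens of kb).
#' @param exclude intervals to subtract (list of [interval()] or a
#'   `locus_calls` data.frame).
#' @return data.frame of class `candidate_regions`: `chrom`, `start`, `end`,
#'   `n_snps`, `allele`, `status` (all `"candidate"`); supporting ids in
#'   `attr(, "support")`.
#' @export
shared_allele_scan <- function(calls, subset, allele = c("A", "B"),
                               min_run = 5, exclude = NULL) {
  allele <- match.arg(allele)
  rows <- .subset_rows(calls, subset)
  if (length(rows) == 0L) {
    segmap_abort("segmap_error_bad_subset", "empty subcohort")
  }
  code <- match(allele, c("A", "B"))
  g <- calls$calls[rows, , drop = FALSE]
  other <- colSums(g == (3L - code), na.rm = TRUE)
  seen <- colSums(!is.na(g))
  shared <- other == 0L & seen > 0L
  shared <- shared & !.exclusion_mask(calls$chrom, calls$pos, exclude)
  out <- list()
  for (ch in unique(calls$chrom)) {
    j <- which(calls$chrom == ch)
    runs <- true_runs(shared[j])
    runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = calls$pos[j[runs$start[i]]],
        end = calls$pos[j[runs$end[i]]],
        n_snps = runs$end[i] - runs$start[i] + 1L,
        allele = allele, status = "candidate",
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_snps = integer(), allele = character(), status = character(),
               stringsAsFactors = FALSE)
  attr(res, "support") <- calls$ids[rows]
  class(res) <- c("candidate_regions", "data.frame")
  res
}

# Per-site "all members carry the allele" indicator within one region.
# Missing calls do not veto sharing; sites nobody was typed at do.
.region_shared_sites <- function(calls, rows, region) {
  j <- which(calls$chrom == region$chrom &
               calls$pos >= region$start & calls$pos <= region$end)
  if (length(j) == 0L) return(list(sites = integer(0), shared = logical(0)))
  g <- calls$calls[rows, j, drop = FALSE]
  code <- match(region$allele, c("A", "B"))
  other <- colSums(g == (3L - code), na.rm = TRUE)
  seen <- colSums(!is.na(g))
  list(sites = j, shared = other == 0L & seen > 0L,
       typed = colSums(!is.na(g)) > 0L)
}

#' Refine candidate regions with additional genotyped individuals
#'
#' Additional progeny sharing the minor-class phenotype and focal genotype
#' are typed at markers within each candidate region. A region is refuted
#' when no site in it remains shared by every extra individual (missing
#' genotypes do not veto sharing); bounds are left untouched, since a
#' breakpoint inside a wide region does not disprove a causal site elsewhere
#' in it — narrowing to fixed-site spans happens at confirmation. A region
#' in which the extras were not typed at all is left unchanged with a
#' warning.
#'
#' @param regions a [shared_allele_scan()] result.
#' @param calls a `genotype_calls` object holding the extra individuals'
#'   genotypes at panel sites covering the regions.
#' @param subset ids/indices of the extra individuals (default all).
#' @return `regions` with `status` updated to `"refuted"` where disproved.
#' @export
refine_candidates <- function(regions, calls, subset = NULL) {
  if (nrow(regions) == 0L) return(regions)
  rows <- .subset_rows(calls, subset)
  for (i in seq_len(nrow(regions))) {
    if (regions$status[i] != "candidate") next
    sh <- .region_shared_sites(calls, rows, regions[i, ])
    if (length(sh$sites) == 0L || !any(sh$typed)) {
      warning(sprintf("region %s:%d-%d: extra individuals not typed there; left unchanged",
                      regions$chrom[i], regions$start[i], regions$end[i]))
      next
    }
    if (!any(sh$shared)) regions$status[i] <- "refuted"
  }
  regions
}

#' Confirm candidates in a second-generation backcross
#'
#' In a cross of a minor-class segregant to the recurrent parent, a candidate
#' is confirmed iff the shared allele is fixed (frequency 1.0 among typed
#' individuals) at some sites of the region among the rough individuals AND
#' is below fixation among the smooth controls there; a candidate fixed in
#' both classes is uninformative (marker-like) and is refuted, as is any
#' candidate with no rough-fixed site. Confirmed regions shrink to the span
#' of rough-fixed sites.
#'
#' @param regions a `candidate_regions` data.frame (only rows with status
#'   `"candidate"` are tested).
#' @param rough_calls a `genotype_calls` object for the rough individuals.
#' @param smooth_calls a `genotype_calls` object for the smooth controls.
#' @param rough_subset,smooth_subset ids/indices (default all).
#' @return `regions` with `status` set to `"confirmed"` or `"refuted"`.
#' @export
second_generation_test <- function(regions, rough_calls, smooth_calls,
                                   rough_subset = NULL, smooth_subset = NULL) {
  if (nrow(regions) == 0L) return(regions)
  rrows <- .subset_rows(rough_calls, rough_subset)
  srows <- .subset_rows(smooth_calls, smooth_subset)
  if (length(rrows) == 0L) {
    segmap_abort("segmap_error_bad_subset", "empty rough cohort")
  }
  for (i in seq_len(nrow(regions))) {
    if (regions$status[i] != "candidate") next
    shr <- .region_shared_sites(rough_calls, rrows, regions[i, ])
    if (length(shr$sites) == 0L || !any(shr$shared)) {
      regions$status[i] <- "refuted"
      next
    }
    fixed_sites <- shr$sites[shr$shared]
    shs <- .region_shared_sites(smooth_calls, srows, regions[i, ])
    smooth_fixed <- shs$shared[match(fixed_sites, shs$sites)]
    if (all(smooth_fixed, na.rm = TRUE)) {
      regions$status[i] <- "refuted"  # fixed in smooth controls too
      next
    }
    regions$status[i] <- "confirmed"
    regions$start[i] <- rough_calls$pos[fixed_sites[1L]]
    regions$end[i] <- rough_calls$pos[fixed_sites[length(fixed_sites)]]
    regions$n_snps[i] <- length(fixed_sites)
  }
  regions
}
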