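#' Wrap a hard-call matrix as a genotype_calls object
#'
#' Convenience for running the mapping stages directly on known (e.g.
#' simulated-truth or file-loaded) genotypes: posteriors are set to 1 for the
#' called state and the Viterbi path equals the calls.
#'
#' @param mat integer matrix (1 = A, 2 = B, NA = missing), segregants x SNPs.
#' @param panel SNP panel aligned to the columns.
#' @param ids segregant ids (default rownames).
#' @return a `genotype_calls` object.
#' @export
as_genotype_calls <- function(mat, panel, ids = rownames(mat)) {
  if (ncol(mat) != nrow(panel)) {
    segmap_abort("segmap_error_bad_panel", "matrix and panel dimensions differ")
  }
  if (is.null(ids)) ids <- sprintf("seg_%04d", seq_len(nrow(mat)))
  postA <- ifelse(is.na(mat), 0.5, ifelse(mat == 1L, 1, 0))
  n <- length(ids)
  qc <- data.frame(id = ids, contaminated_or_diploid = rep(FALSE, n),
                   aneuploid = rep(FALSE, n), no_data = rep(FALSE, n),
                   pass = rep(TRUE, n), stringsAsFactors = FALSE)
  structure(list(posterior_A = postA, calls = mat, viterbi = mat,
                 loglik = rep(NA_real_, nrow(mat)), qc = qc, coverage = NULL,
                 ids = ids, chrom = panel$chrom, pos = panel$pos,
                 params = NULL),
            class = "genotype_calls")
}

.subset_rows <- function(calls, subset) {
  if (is.null(subset)) return(seq_along(calls$ids))
  if (is.character(subset)) {
    i <- match(subset, calls$ids)
    if (anyNA(i)) {
      segmap_abort("segmap_error_bad_subset", "unknown segregant id in subset")
    }
    return(i)
  }
  as.integer(subset)
}

#' Frequency of the non-backcross-parent allele per SNP
#'
#' For every panel site, the fraction of included segregants (missing calls
#' excluded from the denominator) carrying the allele of the parent *not*
#' used in the backcross.
#'
#' @param calls a `genotype_calls` object.
#' @param backcross_parent `"A"` or `"B"`: the recurrent parent.
#' @param subset segregant ids (or indices) to include; default all.
#' @return data.frame of class `freq_track` with columns `chrom`, `pos`,
#'   `freq`, `n`; the scanned allele is kept in `attr(, "allele")`.
#' @export
allele_frequency_scan <- function(calls, backcross_parent = c("A", "B"),
                                  subset = NULL) {
  backcross_parent <- match.arg(backcross_parent)
  rows <- .subset_rows(calls, subset)
  if (length(rows) == 0L) {
    segmap_abort("segmap_error_bad_subset", "empty segregant subset")
  }
  target <- if (backcross_parent == "A") 2L else 1L
  g <- calls$calls[rows, , drop = FALSE]
  n <- colSums(!is.na(g))
  hits <- colSums(g == target, na.rm = TRUE)
  freq <- ifelse(n > 0L, hits / n, NA_real_)
  out <- data.frame(chrom = calls$chrom, pos = calls$pos, freq = freq, n = n,
                    stringsAsFactors = FALSE)
  attr(out, "allele") <- c("A", "B")[target]
  class(out) <- c("freq_track", "data.frame")
  out
}

#' Detect enriched loci from a frequency track
#'
#' Reports maximal runs of at least `min_run` consecutive SNPs whose
#' frequency is at or above `threshold` (the fixation-scan rule: "95%
#' frequency or higher"). Runs separated by fewer than `min_run`
#' sub-threshold SNPs are merged. The peak is the leftmost site of maximal
#' frequency; a locus is fixed iff its peak frequency equals 1.
#'
#' `min_run` guards against degenerate single-site artifacts (e.g. sites
#' where most calls are missing), not against binomial noise: at typical
#' selected-cohort sizes the per-site probability of reaching 0.95 under a
#' Mendelian 0.5 law is below 1e-15, so even one site would be safe. The
#' default of 3 keeps the guard while preserving sensitivity: around a fixed
#' causal allele the frequency stays above 0.95 only within roughly +/-14 kb
#' (where the recombination fraction to the locus passes 0.05), a window that
#' holds only a handful of SNPs on a ~2.4 kb-spaced panel and can be
#' truncated one-sided by a crossover in the selected parent.
#'
#' @param track a [allele_frequency_scan()] result.
#' @param threshold detection threshold (default 0.95).
#' @param min_run minimum number of above-threshold SNPs per locus.
#' @return data.frame of class `locus_calls`: `chrom`, `start`, `end`,
#'   `peak_pos`, `peak_freq`, `n_snps`, `allele`, `is_fixed`, `artifact`.
#' @export
detect_loci <- function(track, threshold = 0.95, min_run = 3) {
  allele <- attr(track, "allele")
  out <- list()
  for (ch in unique(track$chrom)) {
    j <- which(track$chrom == ch)
    f <- track$freq[j]
    above <- !is.na(f) & f >= threshold
    if (!any(above)) next
    runs <- true_runs(above)
    if (nrow(runs) > 1L) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
        if (gap < min_run) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- rbind(merged, runs[i, , drop = FALSE])
        }
      }
      runs <- merged
    }
    for (i in seq_len(nrow(runs))) {
      span <- runs$start[i]:runs$end[i]
      n_above <- sum(above[span])
      if (n_above < min_run) next
      fs <- f[span]
      peak_rel <- span[which.max(fs)]  # leftmost maximal site
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = track$pos[j[runs$start[i]]],
        end = track$pos[j[runs$end[i]]],
        peak_pos = track$pos[j[peak_rel]],
        peak_freq = f[peak_rel],
        n_snps = n_above,
        allele = allele,
        is_fixed = f[peak_rel] >= 1 - 1e-12,
        artifact = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               peak_pos = numeric(), peak_freq = numeric(),
               n_snps = integer(), allele = character(),
               is_fixed = logical(), artifact = logical(),
               stringsAsFactors = FALSE)
  class(res) <- c("locus_calls", "data.frame")
  res
}

#' Delimit a locus by recombination breakpoints among carriers
#'
#' Carriers are the subset members whose hard call at the peak SNP equals the
#' enriched allele. Each carrier contributes the maximal interval around the
#' peak over which its Viterbi path holds that allele (extended to the
#' chromosome ends when no breakpoint intervenes); the locus interval is the
#' intersection over carriers — the smallest region bounded by recombination
#' breakpoints among individuals sharing the allele at the peak.
#'
#' @param locus one row of a [detect_loci()] result.
#' @param calls a `genotype_calls` object.
#' @param genome the genome map (for chromosome ends).
#' @param subset segregant ids/indices to consider (default all).
#' @return an [interval()].
#' @export
delimit_locus <- function(locus, calls, genome, subset = NULL) {
  rows <- .subset_rows(calls, subset)
  ch <- locus$chrom
  jj <- which(calls$chrom == ch)
  pk <- which(calls$chrom == ch & calls$pos == locus$peak_pos)[1]
  if (is.na(pk)) {
    segmap_abort("segmap_error_bad_panel", "peak position absent from calls")
  }
  code <- match(locus$allele, c("A", "B"))
  carriers <- rows[!is.na(calls$calls[rows, pk]) &
                     calls$calls[rows, pk] == code]
  if (length(carriers) == 0L) {
    segmap_abort("segmap_error_no_carriers",
                 "no carriers of the enriched allele at the peak")
  }
  L <- chrom_length(genome, ch)
  kpos <- match(pk, jj)
  ivs <- lapply(carriers, function(i) {
    v <- calls$viterbi[i, jj]
    bad <- which(v != code)
    lefts <- bad[bad < kpos]
    rights <- bad[bad > kpos]
    # the carrier's breakpoint lies between the first discordant SNP and its
    # concordant neighbour; the region it bounds extends to that discordant
    # marker (exclusive), not merely to the last concordant SNP
    start <- if (length(lefts) == 0L) 1 else calls$pos[jj[max(lefts)]] + 1
    end <- if (length(rights) == 0L) L else calls$pos[jj[min(rights)]] - 1
    interval(ch, start, end)
  })
  minimal_bounded_interval(ivs)
}

#' Moving-average smoothing of a per-SNP series
#'
#' Centered moving average (via `stats::filter`) applied chromosome by
#' chromosome; edge positions with incomplete windows are returned missing.
#' The window is capped at each chromosome's series length.
#'
#' @param track a `freq_track` or any data.frame with `chrom`, `pos` and a
#'   numeric value column.
#' @param window window size in SNPs (default 50).
#' @param value column to smooth.
#' @return the track with the value column smoothed.
#' @export
smooth_track <- function(track, window = 50, value = "freq") {
  if (window < 1) segmap_abort("segmap_error_bad_params", "window must be >= 1")
  out <- track
  for (ch in unique(track$chrom)) {
    j <- which(track$chrom == ch)
    w <- min(window, length(j))
    sm <- stats::filter(track[[value]][j], rep(1 / w, w), sides = 2)
    out[[value]][j] <- as.numeric(sm)
  }
  out
}

#' Screen detected loci against an unselected control population
#'
#' A locus is flagged as an artifact of unintentional selection (e.g. a
#' selectable-marker cassette) when the control pool's depth-weighted
#' frequency of the same allele, aggregated over the panel sites inside the
#' locus interval, reaches `threshold`. Artifact loci are retained in the
#' table but excluded from the causal report.
#'
#' A truly causal locus sits near the Mendelian 0.5 in an unselected pool
#' while a selected marker is fixed there, so the default threshold of 0.8
#' separates the two with wide margins at typical pool depths.
#'
#' @param loci a [detect_loci()] result.
#' @param control a [simulate_pooled_control()]-style data.frame (`chrom`,
#'   `pos`, `depth_A`, `depth_B`) aligned to the panel.
#' @param threshold control frequency at or above which a locus is an artifact.
#' @return `loci` with the `artifact` column filled in.
#' @export
screen_against_control <- function(loci, control, threshold = 0.8) {
  if (nrow(loci) == 0L) return(loci)
  for (i in seq_len(nrow(loci))) {
    ch <- loci$chrom[i]
    j <- which(control$chrom == ch)
    if (length(j) == 0L) {
      segmap_abort("segmap_error_missing_control",
                   paste0("control data lacks chromosome ", ch))
    }
    inside <- j[control$pos[j] >= loci$start[i] &
                  control$pos[j] <= loci$end[i]]
    dal <- if (loci$allele[i] == "A") control$depth_A[inside] else
      control$depth_B[inside]
    tot <- control$depth_A[inside] + control$depth_B[inside]
    loci$artifact[i] <- sum(tot) > 0 && (sum(dal) / sum(tot)) >= threshold
  }
  loci
}

#' Fine-map a locus with multi-locus introgression strains
#'
#' Each strain (a product of recurrent backcrossing with phenotypic
#' selection) retains a short donor segment over the causal region. The
#' operation intersects, across strains, the donor-origin segment overlapping
#' the prior interval, returning the reduced interval.
#'
#' @param strains list of [new_segregant()] introgression strains.
#' @param prior an [interval()] from detection/delimitation.
#' @param donor_allele `"A"` or `"B"`: the non-recurrent (donor) parent.
#' @param genome genome map.
#' @param phenotypes optional phenotype labels; if given, all must be equal.
#' @return an [interval()] contained in `prior`.
#' @export
fine_map_introgressions <- function(strains, prior, donor_allele = c("A", "B"),
                                    genome, phenotypes = NULL) {
  donor_allele <- match.arg(donor_allele)
  if (!is.null(phenotypes) && length(unique(phenotypes)) > 1L) {
    segmap_abort("segmap_error_bad_subset",
                 "introgression strains must share the selected phenotype")
  }
  code <- match(donor_allele, c("A", "B"))
  ivs <- lapply(strains, function(s) {
    seg <- s$segments[[prior$chrom]]
    if (is.null(seg)) {
      segmap_abort("segmap_error_unknown_chromosome",
                   "strain lacks the prior's chromosome")
    }
    starts <- c(1, seg$ends[-length(seg$ends)] + 1)
    ends <- seg$ends
    keep <- which(seg$origin == code & ends >= prior$start & starts <= prior$end)
    if (length(keep) == 0L) {
      segmap_abort("segmap_error_empty_intersection",
                   "a strain retains no donor segment over the prior interval")
    }
    if (length(keep) > 1L) {
      ov <- pmin(ends[keep], prior$end) - pmax(starts[keep], prior$start)
      keep <- keep[which.max(ov)]
    }
    interval(prior$chrom, starts[keep], ends[keep])
  })
  minimal_bounded_interval(c(list(prior), ivs))
}
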