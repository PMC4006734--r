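#' HMM parameters for genotype inference
#'
#' @param epsilon per-read error probability, in `[0, 0.5)`.
#' @param recomb_rate Morgans per bp used for transitions.
#' @param min_posterior hard-call threshold in `(0.5, 1]`; a state is called
#'   when its posterior is `>=` the threshold (ties call the state).
#' @param min_switch floor on the between-site switch probability, so a true
#'   breakpoint between two distant adjacent SNPs never gets zero weight.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(epsilon = 0.005, recomb_rate = 3.8e-6,
                       min_posterior = 0.95, min_switch = 1e-6) {
  if (epsilon < 0 || epsilon >= 0.5) {
    segmap_abort("segmap_error_bad_params", "epsilon must lie in [0, 0.5)")
  }
  if (recomb_rate <= 0) {
    segmap_abort("segmap_error_bad_params", "recomb_rate must be > 0")
  }
  if (min_posterior <= 0.5 || min_posterior > 1) {
    segmap_abort("segmap_error_bad_params", "min_posterior must lie in (0.5, 1]")
  }
  structure(list(epsilon = epsilon, recomb_rate = recomb_rate,
                 min_posterior = min_posterior, min_switch = min_switch,
                 states = c("A", "B")),
            class = "hmm_params")
}

#' Binomial emission log-likelihood of allele counts
#'
#' `log Binom(depth_A | depth_A + depth_B, 1 - epsilon)` for state `"A"`,
#' symmetric for `"B"`. Zero-depth sites are uninformative (log-likelihood 0).
#' Count-level emissions are the information-preserving refinement of the
#' per-site BY read fraction: at fixed depth the binomial likelihood is a
#' monotone function of that fraction.
#'
#' @param depth_A,depth_B non-negative read counts (vectorized).
#' @param state `"A"` or `"B"`.
#' @param epsilon per-read error probability.
#' @return log-likelihood(s).
#' @export
emission_loglik <- function(depth_A, depth_B, state = c("A", "B"),
                            epsilon = 0.005) {
  state <- match.arg(state)
  if (epsilon < 0 || epsilon >= 0.5) {
    segmap_abort("segmap_error_bad_params", "epsilon must lie in [0, 0.5)")
  }
  if (any(depth_A < 0) || any(depth_B < 0)) {
    segmap_abort("segmap_error_bad_params", "read counts must be >= 0")
  }
  n <- depth_A + depth_B
  p <- if (state == "A") 1 - epsilon else epsilon
  stats::dbinom(depth_A, n, p, log = TRUE)
}

#' Between-site switch probability (Haldane)
#'
#' `r = (1 - exp(-2 c d)) / 2`; the full transition structure is the 2x2
#' stochastic matrix `[[1-r, r], [r, 1-r]]`.
#'
#' @param d distance in bp (>= 0, vectorized).
#' @param rate Morgans per bp.
#' @return switch probability(ies).
#' @export
transition_prob <- function(d, rate = 3.8e-6) {
  haldane_r(d, rate)
}

# Scaled forward-backward for one chromosome, vectorized over segregants.
# eA, eB: n x k emission likelihoods; r: length k-1 switch probabilities.
.fb_chrom <- function(eA, eB, r) {
  n <- nrow(eA)
  k <- ncol(eA)
  alphaA <- matrix(0, n, k)
  alphaB <- matrix(0, n, k)
  aA <- 0.5 * eA[, 1L]
  aB <- 0.5 * eB[, 1L]
  s <- aA + aB
  loglik <- log(s)
  aA <- aA / s
  aB <- aB / s
  alphaA[, 1L] <- aA
  alphaB[, 1L] <- aB
  if (k > 1L) {
    for (t in 2:k) {
      rt <- r[t - 1L]
      pA <- aA * (1 - rt) + aB * rt
      pB <- aB * (1 - rt) + aA * rt
      aA <- pA * eA[, t]
      aB <- pB * eB[, t]
      s <- aA + aB
      loglik <- loglik + log(s)
      aA <- aA / s
      aB <- aB / s
      alphaA[, t] <- aA
      alphaB[, t] <- aB
    }
  }
  postA <- matrix(0, n, k)
  postA[, k] <- alphaA[, k]
  if (k > 1L) {
    bA <- rep(1, n)
    bB <- rep(1, n)
    for (t in (k - 1L):1L) {
      rt <- r[t]
      xA <- eA[, t + 1L] * bA
      xB <- eB[, t + 1L] * bB
      bA <- (1 - rt) * xA + rt * xB
      bB <- (1 - rt) * xB + rt * xA
      s <- bA + bB
      bA <- bA / s
      bB <- bB / s
      num <- alphaA[, t] * bA
      postA[, t] <- num / (num + alphaB[, t] * bB)
    }
  }
  list(postA = postA, loglik = loglik)
}

# Viterbi decoding for one chromosome, vectorized over segregants (log space).
.viterbi_chrom <- function(lA, lB, r) {
  n <- nrow(lA)
  k <- ncol(lA)
  dA <- log(0.5) + lA[, 1L]
  dB <- log(0.5) + lB[, 1L]
  path <- matrix(1L, n, k)
  if (k == 1L) {
    path[, 1L] <- ifelse(dA >= dB, 1L, 2L)
    return(path)
  }
  ptrA <- matrix(FALSE, n, k)
  ptrB <- matrix(FALSE, n, k)
  lr <- log(r)
  l1r <- log1p(-r)
  for (t in 2:k) {
    fA <- dA + l1r[t - 1L]
    fB <- dB + lr[t - 1L]
    selA <- fA >= fB
    ptrA[, t] <- selA
    bestA <- ifelse(selA, fA, fB)
    fA2 <- dA + lr[t - 1L]
    fB2 <- dB + l1r[t - 1L]
    selB <- fA2 >= fB2
    ptrB[, t] <- selB
    bestB <- ifelse(selB, fA2, fB2)
    dA <- bestA + lA[, t]
    dB <- bestB + lB[, t]
  }
  cur <- ifelse(dA >= dB, 1L, 2L)
  path[, k] <- cur
  for (t in k:2L) {
    fromA <- ifelse(cur == 1L, ptrA[, t], ptrB[, t])
    cur <- ifelse(fromA, 1L, 2L)
    path[, t - 1L] <- cur
  }
  path
}

#' Per-chromosome coverage profile of one segregant
#'
#' Mean depth per chromosome and its ratio to the genome-wide mean, for
#' aneuploidy screening. Chromosomes without panel sites are reported as
#' missing.
#'
#' @param depth total depth per panel site (one segregant).
#' @param chrom chromosome of each site.
#' @param chromosomes optional full chromosome name vector (so empty
#'   chromosomes appear as `NA` rows).
#' @return data.frame with columns `chrom`, `n_sites`, `mean_depth`, `ratio`.
#' @export
chromosome_coverage_profile <- function(depth, chrom, chromosomes = NULL) {
  if (length(depth) == 0L) {
    segmap_abort("segmap_error_bad_params", "empty depth vector")
  }
  if (sum(depth) == 0) {
    segmap_abort("segmap_error_zero_depth", "segregant has zero total depth")
  }
  if (is.null(chromosomes)) chromosomes <- unique(chrom)
  gmean <- mean(depth)
  out <- data.frame(chrom = chromosomes, n_sites = NA_integer_,
                    mean_depth = NA_real_, ratio = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(chromosomes)) {
    j <- which(chrom == chromosomes[i])
    out$n_sites[i] <- length(j)
    if (length(j) > 0L) {
      out$mean_depth[i] <- mean(depth[j])
      out$ratio[i] <- out$mean_depth[i] / gmean
    }
  }
  out
}

#' QC screen of one segregant's read counts
#'
#' Flags evidence of contamination or diploidy (an excess of well-covered
#' sites with substantial minor-allele support: more than `max_het_rate` of
#' sites with depth >= `het_depth` showing a minor-read fraction >=
#' `het_frac`) and of aneuploidy (any chromosome whose mean depth departs
#' from the genome mean by more than the `cov_bounds` ratio band). Thresholds
#' default so that clean ~4x haploids essentially always pass.
#'
#' @param depth_A,depth_B counts per panel site for one segregant.
#' @param chrom chromosome per site.
#' @param het_depth minimum depth for the heterozygosity-like test.
#' @param het_frac minor-read fraction counted as heterozygous-like.
#' @param max_het_rate tolerated fraction of heterozygous-like sites.
#' @param cov_bounds allowed range of chromosome/genome coverage ratios.
#' @return list with logical flags `contaminated_or_diploid`, `aneuploid`,
#'   `no_data`, `pass`, plus the coverage `profile`.
#' @export
qc_segregant <- function(depth_A, depth_B, chrom, het_depth = 4,
                         het_frac = 0.25, max_het_rate = 0.05,
                         cov_bounds = c(0.5, 1.6)) {
  depth <- depth_A + depth_B
  if (length(depth) == 0L) {
    segmap_abort("segmap_error_bad_params", "empty read-count row")
  }
  if (sum(depth) == 0) {
    return(list(contaminated_or_diploid = FALSE, aneuploid = FALSE,
                no_data = TRUE, pass = FALSE, profile = NULL))
  }
  deep <- depth >= het_depth
  het_rate <- if (any(deep)) {
    mean(pmin(depth_A[deep], depth_B[deep]) / depth[deep] >= het_frac)
  } else 0
  contaminated <- het_rate > max_het_rate
  prof <- chromosome_coverage_profile(depth, chrom)
  ratios <- prof$ratio[!is.na(prof$ratio)]
  aneuploid <- any(ratios < cov_bounds[1] | ratios > cov_bounds[2])
  list(contaminated_or_diploid = contaminated, aneuploid = aneuploid,
       no_data = FALSE, pass = !contaminated && !aneuploid,
       profile = prof)
}

#' Infer per-SNP parental origin by forward-backward HMM
#'
#' Runs a two-state (A/B) hidden Markov model chromosome-by-chromosome over
#' each segregant's allele counts: binomial emissions on counts, Haldane
#' transition probabilities between adjacent SNPs (floored at
#' `params$min_switch`), uniform initial state. Produces posterior
#' probabilities, thresholded hard calls, Viterbi paths for breakpoint
#' extraction, per-segregant total data log-likelihoods, QC flags and
#' coverage profiles.
#'
#' @param rc a `read_counts` object (see [simulate_reads()] or
#'   [read_read_counts()]).
#' @param panel the SNP panel the counts are aligned to.
#' @param params an [hmm_params()].
#' @return object of class `genotype_calls`: `posterior_A` and integer
#'   matrices `calls` (1 = A, 2 = B, `NA` = missing) and `viterbi`
#'   (segregants x SNPs), `loglik`, `qc` data.frame, `coverage` data.frame,
#'   plus site coordinates.
#' @export
infer_genotypes <- function(rc, panel, params = hmm_params()) {
  if (!identical(length(rc$pos), nrow(panel)) ||
      !all(rc$pos == panel$pos & rc$chrom == panel$chrom)) {
    segmap_abort("segmap_error_bad_panel",
                 "read counts and panel are not aligned")
  }
  n <- nrow(rc$depth_A)
  m <- ncol(rc$depth_A)
  postA <- matrix(NA_real_, n, m)
  vit <- matrix(NA_integer_, n, m)
  loglik <- numeric(n)
  eps <- params$epsilon
  for (ch in unique(panel$chrom)) {
    j <- which(panel$chrom == ch)
    if (length(j) == 0L) next
    dA <- rc$depth_A[, j, drop = FALSE]
    dB <- rc$depth_B[, j, drop = FALSE]
    tot <- dA + dB
    lA <- stats::dbinom(dA, tot, 1 - eps, log = TRUE)
    lB <- stats::dbinom(dA, tot, eps, log = TRUE)
    r <- pmin(pmax(transition_prob(diff(panel$pos[j]), params$recomb_rate),
                   params$min_switch), 0.5)
    fb <- .fb_chrom(exp(lA), exp(lB), r)
    postA[, j] <- fb$postA
    loglik <- loglik + fb$loglik
    vit[, j] <- .viterbi_chrom(lA, lB, r)
  }
  calls <- matrix(NA_integer_, n, m)
  calls[postA >= params$min_posterior] <- 1L
  calls[(1 - postA) >= params$min_posterior] <- 2L

  qc <- data.frame(id = rc$ids, contaminated_or_diploid = FALSE,
                   aneuploid = FALSE, no_data = FALSE, pass = TRUE,
                   stringsAsFactors = FALSE)
  cov_list <- vector("list", n)
  for (i in seq_len(n)) {
    q <- qc_segregant(rc$depth_A[i, ], rc$depth_B[i, ], rc$chrom)
    qc$contaminated_or_diploid[i] <- q$contaminated_or_diploid
    qc$aneuploid[i] <- q$aneuploid
    qc$no_data[i] <- q$no_data
    qc$pass[i] <- q$pass
    if (q$no_data) {
      calls[i, ] <- NA_integer_
      vit[i, ] <- NA_integer_
    }
    if (!is.null(q$profile)) {
      prof <- q$profile
      prof$id <- rc$ids[i]
      cov_list[[i]] <- prof
    }
  }
  dimnames(postA) <- dimnames(calls) <- dimnames(vit) <- list(rc$ids, NULL)
  structure(list(posterior_A = postA, calls = calls, viterbi = vit,
                 loglik = loglik, qc = qc,
                 coverage = do.call(rbind, cov_list),
                 ids = rc$ids, chrom = rc$chrom, pos = rc$pos,
                 params = params),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  called <- mean(!is.na(x$calls))
  cat(sprintf("<genotype_calls> %d segregants x %d SNPs, %.1f%% hard-called, %d QC-pass\n",
              nrow(x$calls), ncol(x$calls), 100 * called, sum(x$qc$pass)))
  invisible(x)
}
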