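#' @noRd
# Exhaustive enumeration of offspring genotypes at the model loci (plus any
# selected markers) for a two-parent cross. Within a chromosome, transmission
# follows the exact marginal Markov chain of the crossover process (start
# parent 1/2 with probability 1/2, Haldane switch probabilities between
# adjacent tracked positions); chromosomes are independent. Returns one row
# per joint transmission pattern with its probability, the realized alleles,
# and per-class phenotype probabilities.
.enumerate_cross <- function(parent1, parent2, model, genome, markers = NULL) {
  loci <- model$loci[model$loci$locus %in% model_loci(model), , drop = FALSE]
  a1 <- parent1$alleles[loci$locus]
  a2 <- parent2$alleles[loci$locus]
  if (anyNA(a1) || anyNA(a2)) {
    segmap_abort("segmap_error_missing_locus",
                 "a parent lacks an allele at a model locus")
  }
  ent <- data.frame(chrom = loci$chrom, pos = loci$pos, name = loci$locus,
                    kind = "locus",
                    v1 = unname(a1), v2 = unname(a2),
                    req = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(markers) && nrow(markers) > 0L) {
    ent <- rbind(ent, data.frame(
      chrom = markers$chrom, pos = markers$pos, name = markers$name,
      kind = "marker",
      v1 = vapply(seq_len(nrow(markers)), function(i)
        origin_at(parent1, markers$chrom[i], markers$pos[i]), ""),
      v2 = vapply(seq_len(nrow(markers)), function(i)
        origin_at(parent2, markers$chrom[i], markers$pos[i]), ""),
      req = markers$allele, stringsAsFactors = FALSE))
  }
  chroms <- unique(ent$chrom)
  per_chrom <- lapply(chroms, function(ch) {
    e <- ent[ent$chrom == ch, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    k <- nrow(e)
    if (k > 16L) {
      segmap_abort("segmap_error_bad_model",
                   "too many tracked loci on one chromosome to enumerate")
    }
    pats <- as.matrix(expand.grid(rep(list(1:2), k)))
    r <- if (k > 1L) haldane_r(diff(e$pos), genome$recomb_rate) else numeric(0)
    w <- rep(0.5, nrow(pats))
    if (k > 1L) {
      for (j in 2:k) {
        sw <- pats[, j] != pats[, j - 1L]
        w <- w * ifelse(sw, r[j - 1L], 1 - r[j - 1L])
      }
    }
    list(entries = e, patterns = pats, weights = w)
  })
  idx <- expand.grid(lapply(per_chrom, function(pc) seq_len(nrow(pc$patterns))))
  n_comb <- nrow(idx)
  weight <- rep(1, n_comb)
  values <- matrix(NA_character_, n_comb, nrow(ent),
                   dimnames = list(NULL, paste0(ent$chrom, ":", ent$name)))
  colnames(values) <- ent$name
  for (c_i in seq_along(per_chrom)) {
    pc <- per_chrom[[c_i]]
    sel <- idx[[c_i]]
    weight <- weight * pc$weights[sel]
    for (j in seq_len(nrow(pc$entries))) {
      e <- pc$entries[j, ]
      par <- pc$patterns[sel, j]
      values[, e$name] <- ifelse(par == 1L, e$v1, e$v2)
    }
  }
  keep <- rep(TRUE, n_comb)
  mk <- ent[ent$kind == "marker", , drop = FALSE]
  for (j in seq_len(nrow(mk))) {
    keep <- keep & (values[, mk$name[j]] == mk$req[j])
  }
  if (!any(keep)) {
    segmap_abort("segmap_error_impossible_selection",
                 "no offspring genotype satisfies the selected markers")
  }
  weight <- weight[keep] / sum(weight[keep])
  values <- values[keep, , drop = FALSE]

  p_rough <- numeric(length(weight))
  p_bumpy <- numeric(length(weight))
  undecided <- rep(TRUE, length(weight))
  residual <- rep(1, length(weight))
  for (cl in model$clauses) {
    sat <- rep(TRUE, length(weight))
    for (loc in names(cl$requires)) {
      sat <- sat & (values[, loc] == cl$requires[[loc]])
    }
    hit <- sat & undecided
    p_rough[hit] <- cl$penetrance
    residual[hit] <- 1 - cl$penetrance
    undecided <- undecided & !sat
  }
  if (!is.null(model$bumpy_clause)) {
    sat <- rep(TRUE, length(weight))
    for (loc in names(model$bumpy_clause)) {
      sat <- sat & (values[, loc] == model$bumpy_clause[[loc]])
    }
    p_bumpy[sat] <- residual[sat]
  }
  list(values = values, weight = weight, p_rough = p_rough,
       p_bumpy = p_bumpy, p_smooth = 1 - p_rough - p_bumpy)
}

#' Exact phenotype-class probabilities of a cross
#'
#' Enumerates all transmission patterns of the model loci (treating loci on
#' the same chromosome as linked through the Haldane recombination fraction,
#' and conditioning on any selected markers) and sums clause-weighted
#' penetrances. Loci fixed between the parents contribute no factor.
#'
#' @param parent1,parent2 [new_segregant()] genotypes.
#' @param model a [phenotype_model()].
#' @param genome genome map.
#' @param markers optional selected-marker table (`name`, `chrom`, `pos`,
#'   `allele`) to condition on.
#' @return named numeric vector with elements `rough`, `bumpy`, `smooth`.
#' @export
expected_class_probabilities <- function(parent1, parent2, model, genome,
                                         markers = NULL) {
  en <- .enumerate_cross(parent1, parent2, model, genome, markers)
  c(rough = sum(en$weight * en$p_rough),
    bumpy = sum(en$weight * en$p_bumpy),
    smooth = sum(en$weight * en$p_smooth))
}

#' Exact expected phenotype frequency of a cross design
#'
#' @param design a [cross_design()] (its parents and markers are used).
#' @param model a [phenotype_model()].
#' @param genome genome map.
#' @param phenotype class whose probability to return.
#' @return probability.
#' @export
expected_phenotype_frequency <- function(design, model, genome,
                                         phenotype = "rough") {
  p <- expected_class_probabilities(design$parent1, design$parent2, model,
                                    genome, design$markers)
  if (!phenotype %in% names(p)) {
    segmap_abort("segmap_error_bad_params",
                 paste0("unknown phenotype class ", phenotype))
  }
  unname(p[phenotype])
}

#' Exact conditional allele probability given a phenotype
#'
#' `P(locus = allele | phenotype)` for offspring of a cross design, from the
#' same enumeration as [expected_phenotype_frequency()]. Used, e.g., for the
#' expected fraction of END3-3S individuals among rough segregants.
#'
#' @inheritParams expected_phenotype_frequency
#' @param locus model locus name.
#' @param allele allele label at that locus.
#' @return conditional probability.
#' @export
expected_allele_given_phenotype <- function(design, model, genome, locus,
                                            allele, phenotype = "rough") {
  en <- .enumerate_cross(design$parent1, design$parent2, model, genome,
                         design$markers)
  pcls <- switch(phenotype, rough = en$p_rough, bumpy = en$p_bumpy,
                 smooth = en$p_smooth,
                 segmap_abort("segmap_error_bad_params", "unknown phenotype class"))
  tot <- sum(en$weight * pcls)
  if (tot == 0) return(NA_real_)
  sum(en$weight * pcls * (en$values[, locus] == allele)) / tot
}

#' Genotype-phenotype concordance table
#'
#' Cross-tabulates genotype patterns over the causal loci against phenotype
#' classes, and flags discordant patterns: a genotype satisfying a
#' fully-penetrant clause yet showing non-rough individuals, or rough
#' individuals without any satisfied clause (e.g. when the spontaneous IRA2
#' allele is hidden and read as the parental allele).
#'
#' @param alleles character matrix (individuals x loci) of allele labels.
#' @param phenotype phenotype label per individual.
#' @param model a [phenotype_model()].
#' @return data.frame: one row per observed genotype pattern with per-class
#'   counts, the penetrance-1 clause indicator, and `discordant`.
#' @export
concordance_table <- function(alleles, phenotype, model) {
  if (length(phenotype) != nrow(alleles)) {
    segmap_abort("segmap_error_bad_params",
                 "phenotype labels and genotype rows differ in length")
  }
  if (anyNA(phenotype)) {
    segmap_abort("segmap_error_bad_params", "phenotype label missing")
  }
  loci <- intersect(colnames(alleles), model$loci$locus)
  if (nrow(alleles) == 0L) {
    return(data.frame(pattern = character(), n_rough = integer(),
                      n_smooth = integer(), n_bumpy = integer(),
                      full_penetrance_clause = logical(),
                      any_clause = logical(), discordant = logical(),
                      stringsAsFactors = FALSE))
  }
  pat <- apply(alleles[, loci, drop = FALSE], 1L, paste, collapse = "/")
  tab <- table(pattern = pat, phenotype = factor(phenotype,
                                                 levels = c("rough", "smooth", "bumpy")))
  pats <- rownames(tab)
  first <- match(pats, pat)
  sat_full <- logical(length(pats))
  sat_any <- logical(length(pats))
  for (i in seq_along(pats)) {
    al <- alleles[first[i], ]
    for (cl in model$clauses) {
      if (clause_satisfied(cl$requires, al)) {
        sat_any[i] <- TRUE
        if (cl$penetrance >= 1) sat_full[i] <- TRUE
        break
      }
    }
  }
  out <- data.frame(pattern = pats,
                    n_rough = as.integer(tab[, "rough"]),
                    n_smooth = as.integer(tab[, "smooth"]),
                    n_bumpy = as.integer(tab[, "bumpy"]),
                    full_penetrance_clause = sat_full,
                    any_clause = sat_any,
                    stringsAsFactors = FALSE)
  out$discordant <- (out$full_penetrance_clause &
                       (out$n_smooth + out$n_bumpy) > 0L) |
    (!out$any_clause & out$n_rough > 0L)
  rownames(out) <- NULL
  out
}

#' Per-clause penetrance estimates with exact binomial intervals
#'
#' @param alleles character matrix (individuals x loci).
#' @param phenotype phenotype label per individual.
#' @param model a [phenotype_model()].
#' @param conf.level confidence level for the exact (Clopper-Pearson) interval.
#' @return data.frame: one row per clause with counts, the proportion rough,
#'   and interval bounds.
#' @export
clause_penetrance_estimates <- function(alleles, phenotype, model,
                                        conf.level = 0.95) {
  res <- lapply(seq_along(model$clauses), function(ci) {
    cl <- model$clauses[[ci]]
    sat <- rep(TRUE, nrow(alleles))
    for (loc in names(cl$requires)) {
      sat <- sat & (alleles[, loc] == cl$requires[[loc]])
    }
    n <- sum(sat)
    x <- sum(sat & phenotype == "rough")
    if (n > 0L) {
      ci_b <- stats::binom.test(x, n, conf.level = conf.level)$conf.int
    } else {
      ci_b <- c(NA_real_, NA_real_)
    }
    data.frame(clause = ci, n_genotype = n, n_rough = x,
               penetrance_hat = if (n > 0L) x / n else NA_real_,
               lower = ci_b[1], upper = ci_b[2],
               true_penetrance = cl$penetrance)
  })
  do.call(rbind, res)
}

#' Score detected loci against simulated truth
#'
#' A truth locus is hit when any non-artifact detected interval contains its
#' position; a detected locus is a true positive when it contains some truth
#' position.
#'
#' @param loci a [detect_loci()] result (artifact rows are ignored).
#' @param truth data.frame (`locus`, `chrom`, `pos`) of causal positions.
#' @return list with `per_locus` (truth table with `hit`), `precision`
#'   (`NA` when nothing was detected) and `recall`.
#' @export
locus_recovery_report <- function(loci, truth) {
  det <- loci[!loci$artifact, , drop = FALSE]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(det$chrom == truth$chrom[i] &
          det$start <= truth$pos[i] & det$end >= truth$pos[i])
  }, logical(1))
  tp <- vapply(seq_len(nrow(det)), function(i) {
    any(truth$chrom == det$chrom[i] &
          truth$pos >= det$start[i] & truth$pos <= det$end[i])
  }, logical(1))
  per_locus <- truth
  per_locus$hit <- hit
  list(per_locus = per_locus,
       precision = if (nrow(det) == 0L) NA_real_ else mean(tp),
       recall = if (nrow(truth) == 0L) NA_real_ else mean(hit))
}
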