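#' Haldane map function
#'
#' Converts a physical distance into a recombination fraction under a
#' no-interference (Poisson) crossover process:
#' `r = (1 - exp(-2 * rate * d)) / 2`.
#'
#' @param d distance in bp (vectorized).
#' @param rate Morgans per bp.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d, rate) {
  if (any(d < 0)) segmap_abort("segmap_error_bad_distance", "distance must be >= 0")
  0.5 * (1 - exp(-2 * rate * d))
}

# One meiotic gamete pattern: per chromosome, crossover positions (Poisson
# with mean = map length in Morgans, uniform locations) and the starting
# parent of the chromatid.
.gamete_pattern <- function(genome) {
  chroms <- genome$chromosomes
  pat <- vector("list", nrow(chroms))
  names(pat) <- chroms$name
  for (i in seq_len(nrow(chroms))) {
    L <- chroms$length[i]
    nx <- stats::rpois(1L, genome$recomb_rate * L)
    xo <- if (nx > 0L) sort(stats::runif(nx, 0, L)) else numeric(0)
    pat[[i]] <- list(xo = xo, start = sample.int(2L, 1L))
  }
  pat
}

# Transmitting parent (1/2) at positions `pos` under one chromosome's pattern.
.parent_at <- function(pat_chrom, pos, complement = FALSE) {
  start <- if (complement) 3L - pat_chrom$start else pat_chrom$start
  par <- ifelse(findInterval(pos, pat_chrom$xo) %% 2L == 0L, start, 3L - start)
  as.integer(par)
}

# Assemble one haploid product of a p1 x p2 meiosis from a gamete pattern.
.meiosis_from_pattern <- function(p1, p2, genome, pattern, complement = FALSE,
                                  id = "offspring") {
  chroms <- genome$chromosomes
  segs <- vector("list", nrow(chroms))
  names(segs) <- chroms$name
  xos <- vector("list", nrow(chroms))
  names(xos) <- chroms$name
  for (i in seq_len(nrow(chroms))) {
    ch <- chroms$name[i]
    L <- chroms$length[i]
    pc <- pattern[[ch]]
    s1 <- p1$segments[[ch]]
    s2 <- p2$segments[[ch]]
    e <- sort(unique(c(pc$xo, s1$ends, s2$ends)))
    if (e[length(e)] < L) e <- c(e, L)
    mids <- (c(0, e[-length(e)]) + e) / 2
    par <- .parent_at(pc, mids, complement)
    o1 <- s1$origin[findInterval(mids, s1$ends, left.open = TRUE) + 1L]
    o2 <- s2$origin[findInterval(mids, s2$ends, left.open = TRUE) + 1L]
    orig <- ifelse(par == 1L, o1, o2)
    r <- rle(orig)
    segs[[ch]] <- list(ends = e[cumsum(r$lengths)], origin = as.integer(r$values))
    xos[[ch]] <- pc$xo
  }
  loci <- p1$loci
  alleles <- stats::setNames(character(nrow(loci)), loci$locus)
  for (k in seq_len(nrow(loci))) {
    par <- .parent_at(pattern[[loci$chrom[k]]], loci$pos[k], complement)
    alleles[k] <- if (par == 1L) p1$alleles[[loci$locus[k]]] else p2$alleles[[loci$locus[k]]]
  }
  new_segregant(id, segs, alleles, loci, generation = "offspring",
                crossovers = xos)
}

.check_parents <- function(p1, p2, genome) {
  ok <- identical(names(p1$segments), genome$chromosomes$name) &&
    identical(names(p2$segments), genome$chromosomes$name) &&
    identical(p1$loci$locus, p2$loci$locus)
  if (!ok) {
    segmap_abort("segmap_error_parent_mismatch",
                 "parents and genome are inconsistent (chromosomes or loci differ)")
  }
}

#' Simulate one meiotic product (spore) of a cross
#'
#' Crossovers per chromosome are Poisson with mean equal to the chromosome's
#' map length in Morgans, located uniformly; no interference, no obligate
#' crossover. The spore switches between the two parental haplotypes at
#' crossovers; alleles at the causal loci (including the spontaneous "mut"
#' allele) travel with their chromosome.
#'
#' @param parent1,parent2 haploid [new_segregant()] genotypes.
#' @param genome a [genome_map()].
#' @param seed optional integer seed.
#' @param id offspring id.
#' @return a [new_segregant()]; crossover positions are kept in
#'   `$crossovers`.
#' @export
simulate_meiosis <- function(parent1, parent2, genome, seed = NULL,
                             id = "offspring") {
  .check_parents(parent1, parent2, genome)
  use_seed(seed)
  .meiosis_from_pattern(parent1, parent2, genome, .gamete_pattern(genome),
                        id = id)
}

#' Simulate a tetrad (four spores of one meiosis)
#'
#' Built as two independent meiotic products plus their complements, so every
#' position segregates exactly 2:2. (Four-strand chromatid sampling is not
#' modeled; downstream statistics depend only on marginal recombination
#' fractions and the 2:2 constraint.)
#'
#' @inheritParams simulate_meiosis
#' @param id_prefix prefix for the four spore ids.
#' @return list of four [new_segregant()]s.
#' @export
simulate_tetrad <- function(parent1, parent2, genome, seed = NULL,
                            id_prefix = "spore") {
  .check_parents(parent1, parent2, genome)
  use_seed(seed)
  pat1 <- .gamete_pattern(genome)
  pat2 <- .gamete_pattern(genome)
  list(
    .meiosis_from_pattern(parent1, parent2, genome, pat1, FALSE, paste0(id_prefix, "_1")),
    .meiosis_from_pattern(parent1, parent2, genome, pat1, TRUE,  paste0(id_prefix, "_2")),
    .meiosis_from_pattern(parent1, parent2, genome, pat2, FALSE, paste0(id_prefix, "_3")),
    .meiosis_from_pattern(parent1, parent2, genome, pat2, TRUE,  paste0(id_prefix, "_4"))
  )
}

#' Cross design
#'
#' @param parent1,parent2 haploid [new_segregant()]s (parent2 is the
#'   recurrent/backcross parent when `rounds > 1`).
#' @param n_offspring cohort size (after selection, if any).
#' @param selection `"none"` or a phenotype class; meioses are drawn until
#'   `n_offspring` individuals of the class are collected.
#' @param coverage mean sequencing depth (lambda) intended for the cohort.
#' @param mut_carrier_fraction fraction of original F1 spores derived from a
#'   mut-carrying diploid lineage (used by [simulate_f1_spores()]).
#' @param rounds recurrent-backcross rounds (1 = a single backcross).
#' @param markers optional data.frame (`name`, `chrom`, `pos`, `allele`) of
#'   selected marker loci: every collected offspring must carry the stated
#'   allele, mimicking cassette-based selection of genotyped segregants.
#' @param name label used in offspring ids.
#' @return object of class `cross_design`.
#' @export
cross_design <- function(parent1, parent2, n_offspring,
                         selection = "none", coverage = 4,
                         mut_carrier_fraction = 0.8, rounds = 1,
                         markers = NULL, name = "cross") {
  if (n_offspring < 1) {
    segmap_abort("segmap_error_bad_design", "n_offspring must be >= 1")
  }
  if (coverage <= 0) {
    segmap_abort("segmap_error_bad_design", "coverage must be > 0")
  }
  if (mut_carrier_fraction < 0 || mut_carrier_fraction > 1) {
    segmap_abort("segmap_error_bad_design",
                 "mut_carrier_fraction must lie in [0, 1]")
  }
  structure(list(parent1 = parent1, parent2 = parent2,
                 n_offspring = as.integer(n_offspring), selection = selection,
                 coverage = coverage,
                 mut_carrier_fraction = mut_carrier_fraction,
                 rounds = as.integer(rounds), markers = markers, name = name),
            class = "cross_design")
}

.marker_pass_segments <- function(off, markers) {
  if (is.null(markers) || nrow(markers) == 0L) return(TRUE)
  all(vapply(seq_len(nrow(markers)), function(i) {
    origin_at(off, markers$chrom[i], markers$pos[i]) == markers$allele[i]
  }, logical(1)))
}

# ---- fast exact marginalization to a finite set of positions ("loci" track) ----

# Chain layout: per chromosome the sorted unique positions of all tracked
# entries; each entry maps to (chrom, column).
.locus_chain <- function(genome, entries) {
  entries$chrom <- as.character(entries$chrom)
  ci <- match(entries$chrom, genome$chromosomes$name)
  if (anyNA(ci)) {
    segmap_abort("segmap_error_unknown_chromosome",
                 "tracked position on a chromosome absent from the genome")
  }
  chain <- list()
  entries$col <- NA_integer_
  for (i in sort(unique(ci))) {
    ch <- genome$chromosomes$name[i]
    sel <- which(ci == i)
    upos <- sort(unique(entries$pos[sel]))
    chain[[ch]] <- upos
    entries$col[sel] <- match(entries$pos[sel], upos)
  }
  list(chain = chain, entries = entries)
}

# Draw transmitting-parent matrices (nb x k per chromosome): a Markov chain
# along the tracked positions with Haldane switch probabilities -- the exact
# marginal law of the Poisson crossover process at those positions.
.draw_transmission <- function(chain, genome, nb) {
  out <- vector("list", length(chain))
  names(out) <- names(chain)
  for (ch in names(chain)) {
    pos <- chain[[ch]]
    k <- length(pos)
    M <- matrix(0L, nb, k)
    cur <- sample.int(2L, nb, replace = TRUE)
    M[, 1L] <- cur
    if (k > 1L) {
      r <- haldane_r(diff(pos), genome$recomb_rate)
      for (j in 2:k) {
        sw <- stats::runif(nb) < r[j - 1L]
        cur[sw] <- 3L - cur[sw]
        M[, j] <- cur
      }
    }
    out[[ch]] <- M
  }
  out
}

# For a batch, realize tracked values: causal-locus alleles (character) and
# origins (integer 1/2) at marker/extra positions.
.realize_batch <- function(trans, layout, p1, p2) {
  ent <- layout$entries
  n <- nrow(trans[[1L]])
  loci_rows <- which(ent$kind == "locus")
  al <- matrix(NA_character_, n, length(loci_rows),
               dimnames = list(NULL, ent$name[loci_rows]))
  for (j in seq_along(loci_rows)) {
    e <- ent[loci_rows[j], ]
    M <- trans[[e$chrom]][, e$col]
    v1 <- p1$alleles[[e$name]]
    v2 <- p2$alleles[[e$name]]
    al[, j] <- ifelse(M == 1L, v1, v2)
  }
  pos_rows <- which(ent$kind != "locus")
  orig <- NULL
  if (length(pos_rows) > 0L) {
    orig <- matrix(0L, n, length(pos_rows))
    for (j in seq_along(pos_rows)) {
      e <- ent[pos_rows[j], ]
      M <- trans[[e$chrom]][, e$col]
      o1 <- match(origin_at(p1, e$chrom, e$pos), c("A", "B"))
      o2 <- match(origin_at(p2, e$chrom, e$pos), c("A", "B"))
      orig[, j] <- ifelse(M == 1L, o1, o2)
    }
  }
  list(alleles = al, origins = orig)
}

#' Simulate a backcross cohort under a phenotype model
#'
#' Draws meiotic offspring of `design$parent1 x design$parent2`, applies
#' selected-marker filtering and (optionally) phenotype selection, and
#' records the total number of meioses attempted so raw phenotype frequencies
#' remain recoverable. With `rounds > 1`, performs recurrent backcrossing:
#' each round keeps one marker-passing offspring of the selected class as the
#' next parent, and the final round yields the cohort.
#'
#' Two tracking modes are available. `track = "segments"` runs the full
#' crossover simulation and returns complete origin tracks per offspring.
#' `track = "loci"` simulates inheritance only at the causal loci, marker
#' positions and any `extra_positions` via the exact marginal Markov chain of
#' the crossover process (Haldane switch probabilities); it is orders of
#' magnitude faster and distributionally identical at the tracked positions.
#'
#' @param design a [cross_design()].
#' @param model a [phenotype_model()].
#' @param genome a [genome_map()].
#' @param seed optional integer seed.
#' @param track `"segments"` (full origin tracks) or `"loci"`.
#' @param extra_positions optional data.frame (`chrom`, `pos`) of additional
#'   positions to track in `"loci"` mode (e.g. a whole SNP panel).
#' @return object of class `cohort`: fields `segregants` (list, or `NULL` in
#'   loci mode), `alleles` (n x loci character matrix), `origins`/`positions`
#'   (origins at `extra_positions`, loci mode), `phenotype`, `ids`,
#'   `attempts` (total meioses drawn), `marker_pass`.
#' @export
simulate_backcross_cohort <- function(design, model, genome, seed = NULL,
                                      track = c("segments", "loci"),
                                      extra_positions = NULL) {
  track <- match.arg(track)
  use_seed(seed)
  sel <- design$selection
  if (!identical(sel, "none")) {
    p_sel <- expected_phenotype_frequency(design, model, genome, phenotype = sel)
    if (p_sel <= 0) {
      segmap_abort("segmap_error_impossible_selection",
                   sprintf("selection class '%s' has probability 0 under the model", sel))
    }
  } else {
    p_sel <- 1
  }

  parent1 <- design$parent1
  if (design$rounds > 1L) {
    for (round in seq_len(design$rounds - 1L)) {
      repeat {
        off <- simulate_meiosis(parent1, design$parent2, genome,
                                id = sprintf("%s_r%d", design$name, round))
        if (!.marker_pass_segments(off, design$markers)) next
        if (identical(sel, "none") ||
            assign_phenotype(off$alleles, model) == sel) break
      }
      off$generation <- sprintf("backcross_round%d", round)
      parent1 <- off
    }
  }

  n <- design$n_offspring
  if (track == "segments") {
    segregants <- vector("list", n)
    phen <- character(n)
    got <- 0L
    attempts <- 0L
    marker_pass <- 0L
    while (got < n) {
      attempts <- attempts + 1L
      off <- simulate_meiosis(parent1, design$parent2, genome)
      if (!.marker_pass_segments(off, design$markers)) next
      marker_pass <- marker_pass + 1L
      lab <- assign_phenotype(off$alleles, model)
      if (identical(sel, "none") || lab == sel) {
        got <- got + 1L
        off$id <- sprintf("%s_%04d", design$name, got)
        off$generation <- "backcross"
        segregants[[got]] <- off
        phen[got] <- lab
      }
    }
    al <- do.call(rbind, lapply(segregants, function(s) s$alleles))
    rownames(al) <- NULL
    res <- list(track = "segments", segregants = segregants, alleles = al,
                origins = NULL, positions = NULL,
                phenotype = phen, ids = vapply(segregants, `[[`, "", "id"),
                attempts = attempts, marker_pass = marker_pass,
                design = design, final_parent = parent1)
    class(res) <- "cohort"
    return(res)
  }

  # loci track
  loci <- parent1$loci
  entries <- data.frame(chrom = loci$chrom, pos = loci$pos,
                        name = loci$locus, kind = "locus",
                        stringsAsFactors = FALSE)
  if (!is.null(design$markers) && nrow(design$markers) > 0L) {
    entries <- rbind(entries,
                     data.frame(chrom = design$markers$chrom,
                                pos = design$markers$pos,
                                name = design$markers$name, kind = "marker",
                                stringsAsFactors = FALSE))
  }
  if (!is.null(extra_positions) && nrow(extra_positions) > 0L) {
    entries <- rbind(entries,
                     data.frame(chrom = extra_positions$chrom,
                                pos = extra_positions$pos,
                                name = sprintf("x%06d", seq_len(nrow(extra_positions))),
                                kind = "extra", stringsAsFactors = FALSE))
  }
  layout <- .locus_chain(genome, entries)
  marker_rows <- which(layout$entries$kind == "marker")
  extra_rows <- which(layout$entries$kind == "extra")

  keep_frac <- max(p_sel * if (length(marker_rows)) 0.5^length(marker_rows) else 1,
                   1e-4)
  alleles <- NULL
  origins <- NULL
  phen <- character(0)
  attempts <- 0L
  marker_pass <- 0L
  while (is.null(alleles) || nrow(alleles) < n) {
    need <- n - if (is.null(alleles)) 0L else nrow(alleles)
    nb <- max(200L, ceiling(1.3 * need / keep_frac))
    trans <- .draw_transmission(layout$chain, genome, nb)
    batch <- .realize_batch(trans, layout, parent1, design$parent2)
    mkpass <- rep(TRUE, nb)
    if (length(marker_rows) > 0L) {
      for (mr in marker_rows) {
        e <- layout$entries[mr, ]
        want <- match(design$markers$allele[match(e$name, design$markers$name)],
                      c("A", "B"))
        mkpass <- mkpass & (batch$origins[, match(mr, c(marker_rows, extra_rows))] == want)
      }
    }
    lab <- assign_phenotypes(batch$alleles, model)
    keep <- mkpass
    if (!identical(sel, "none")) keep <- keep & (lab == sel)
    kept_idx <- which(keep)
    if (length(kept_idx) >= need) {
      # stop counting at the meiosis that produced the n-th collected
      # offspring, so raw phenotype frequencies stay unbiased
      cut <- kept_idx[need]
      attempts <- attempts + cut
      marker_pass <- marker_pass + sum(mkpass[seq_len(cut)])
      keep <- keep & (seq_len(nb) <= cut)
    } else {
      attempts <- attempts + nb
      marker_pass <- marker_pass + sum(mkpass)
    }
    if (any(keep)) {
      alleles <- rbind(alleles, batch$alleles[keep, , drop = FALSE])
      phen <- c(phen, lab[keep])
      if (length(extra_rows) > 0L) {
        ex_cols <- match(extra_rows, c(marker_rows, extra_rows))
        origins <- rbind(origins, batch$origins[keep, ex_cols, drop = FALSE])
      }
    }
  }
  positions <- if (length(extra_rows) > 0L) {
    data.frame(chrom = layout$entries$chrom[extra_rows],
               pos = layout$entries$pos[extra_rows], stringsAsFactors = FALSE)
  } else NULL
  res <- list(track = "loci", segregants = NULL, alleles = alleles,
              origins = origins, positions = positions, phenotype = phen,
              ids = sprintf("%s_%04d", design$name, seq_len(n)),
              attempts = attempts, marker_pass = marker_pass,
              design = design, final_parent = parent1)
  class(res) <- "cohort"
  res
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d segregants (%s track), %d meioses attempted\n",
              length(x$ids), x$track, x$attempts))
  print(table(x$phenotype))
  invisible(x)
}

#' Per-SNP parental-origin matrix of a cohort
#'
#' @param cohort a [simulate_backcross_cohort()] result.
#' @param panel a [make_snp_panel()] panel.
#' @return integer matrix (segregants x SNPs; 1 = "A", 2 = "B").
#' @export
cohort_origin_matrix <- function(cohort, panel) {
  if (cohort$track == "segments") {
    O <- t(vapply(cohort$segregants, origin_at_panel, integer(nrow(panel)),
                  panel = panel))
    dimnames(O) <- list(cohort$ids, NULL)
    return(O)
  }
  key <- paste(panel$chrom, panel$pos)
  have <- paste(cohort$positions$chrom, cohort$positions$pos)
  idx <- match(key, have)
  if (anyNA(idx)) {
    segmap_abort("segmap_error_bad_panel",
                 "loci-track cohort does not track every panel position")
  }
  O <- cohort$origins[, idx, drop = FALSE]
  dimnames(O) <- list(cohort$ids, NULL)
  O
}

#' Simulate F1 spores of the original two-founder cross
#'
#' A fraction `f` of spores derive from a diploid lineage carrying the
#' spontaneous IRA2 allele on its 3S chromosome (the mutation having arisen
#' during outgrowth of the hybrid diploid before sporulation), so "mut"
#' segregates 1:1 against the BY allele within that fraction.
#'
#' @param genome a [genome_map()].
#' @param n number of spores.
#' @param loci causal locus table.
#' @param f mut-carrier fraction of the sporulated lineage.
#' @param seed optional seed.
#' @return list of [new_segregant()]s.
#' @export
simulate_f1_spores <- function(genome, n, loci = default_causal_loci(),
                               f = 0.8, seed = NULL) {
  use_seed(seed)
  by <- founder_strain(genome, "A", loci)
  s3 <- founder_strain(genome, "B", loci)
  s3m <- founder_strain(genome, "B", loci, ira2_mut = TRUE)
  lapply(seq_len(n), function(i) {
    p2 <- if (stats::runif(1) < f) s3m else s3
    off <- simulate_meiosis(by, p2, genome, id = sprintf("F1_%04d", i))
    off$generation <- "F1"
    off
  })
}

#' Sample an F1 segregant with a required causal genotype
#'
#' Draws F1 spores until one matches `required` at the causal loci (and, if
#' given, carries `required_origins`), yielding a realistic mosaic genotype
#' for the strain used to seed the backcrosses.
#'
#' @inheritParams simulate_f1_spores
#' @param required named character vector of required alleles;
#'   defaults to [reference_rough_genotype()].
#' @param required_origins optional data.frame (`chrom`, `pos`, `allele`) of
#'   required parental origins (e.g. the selection-cassette haplotype).
#' @param max_tries safety cap.
#' @return a [new_segregant()].
#' @export
sample_founder_segregant <- function(genome, loci = default_causal_loci(),
                                     required = reference_rough_genotype(),
                                     required_origins = NULL, f = 0.8,
                                     seed = NULL, max_tries = 1e5) {
  use_seed(seed)
  by <- founder_strain(genome, "A", loci)
  s3 <- founder_strain(genome, "B", loci)
  s3m <- founder_strain(genome, "B", loci, ira2_mut = TRUE)
  for (i in seq_len(max_tries)) {
    p2 <- if (stats::runif(1) < f) s3m else s3
    off <- simulate_meiosis(by, p2, genome)
    if (!all(off$alleles[names(required)] == required)) next
    if (!is.null(required_origins)) {
      ok <- all(vapply(seq_len(nrow(required_origins)), function(k) {
        origin_at(off, required_origins$chrom[k], required_origins$pos[k]) ==
          required_origins$allele[k]
      }, logical(1)))
      if (!ok) next
    }
    off$id <- "F1_rough"
    off$generation <- "F1"
    return(off)
  }
  segmap_abort("segmap_error_impossible_selection",
               "no F1 spore matched the required genotype within max_tries")
}

#' Simulate low-coverage read counts over a SNP panel
#'
#' Per site, total depth is Poisson(`lambda`); reads supporting the true
#' parental origin are Binomial(depth, 1 - `epsilon`), the remainder support
#' the other allele.
#'
#' @param cohort a [simulate_backcross_cohort()] result.
#' @param panel SNP panel.
#' @param lambda mean depth.
#' @param epsilon per-read error rate, in `[0, 0.5)`.
#' @param seed optional seed.
#' @return object of class `read_counts`: integer matrices `depth_A`,
#'   `depth_B` (segregants x SNPs), site coordinates, `truth` (the simulated
#'   origin matrix), `lambda`, `epsilon`.
#' @export
simulate_reads <- function(cohort, panel, lambda = 4, epsilon = 0.005,
                           seed = NULL) {
  if (lambda <= 0) segmap_abort("segmap_error_bad_design", "lambda must be > 0")
  if (epsilon < 0 || epsilon >= 0.5) {
    segmap_abort("segmap_error_bad_design", "epsilon must lie in [0, 0.5)")
  }
  use_seed(seed)
  O <- cohort_origin_matrix(cohort, panel)
  n <- nrow(O)
  m <- ncol(O)
  depth <- matrix(stats::rpois(n * m, lambda), n, m)
  correct <- matrix(stats::rbinom(n * m, as.vector(depth), 1 - epsilon), n, m)
  dA <- ifelse(O == 1L, correct, depth - correct)
  dB <- depth - dA
  dimnames(dA) <- dimnames(dB) <- list(cohort$ids, NULL)
  structure(list(depth_A = dA, depth_B = dB, ids = cohort$ids,
                 chrom = panel$chrom, pos = panel$pos, truth = O,
                 lambda = lambda, epsilon = epsilon),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("<read_counts> %d segregants x %d SNPs, mean depth %.2f\n",
              nrow(x$depth_A), ncol(x$depth_A),
              mean(x$depth_A + x$depth_B)))
  invisible(x)
}

#' Inject a whole-chromosome aneuploidy into simulated read counts
#'
#' Re-draws the target segregant's depths on one chromosome with the Poisson
#' mean multiplied by `copy_factor`, regenerating allele support from the
#' stored simulation truth.
#'
#' @param rc a [simulate_reads()] result.
#' @param id segregant id.
#' @param chrom chromosome.
#' @param copy_factor copy-number factor (> 0; 2 = disomy of a haploid).
#' @param seed optional seed.
#' @return modified `read_counts`.
#' @export
inject_aneuploidy <- function(rc, id, chrom, copy_factor, seed = NULL) {
  if (copy_factor <= 0) {
    segmap_abort("segmap_error_bad_artifact", "copy_factor must be > 0")
  }
  i <- match(id, rc$ids)
  if (is.na(i)) segmap_abort("segmap_error_bad_artifact", "unknown segregant id")
  use_seed(seed)
  j <- which(rc$chrom == chrom)
  if (length(j) == 0L) {
    segmap_abort("segmap_error_unknown_chromosome",
                 "no panel sites on target chromosome")
  }
  depth <- stats::rpois(length(j), rc$lambda * copy_factor)
  correct <- stats::rbinom(length(j), depth, 1 - rc$epsilon)
  dA <- ifelse(rc$truth[i, j] == 1L, correct, depth - correct)
  rc$depth_A[i, j] <- dA
  rc$depth_B[i, j] <- depth - dA
  rc
}

#' Inject cross-contamination into one segregant's read counts
#'
#' Each read is drawn from a contaminating genotype with probability
#' `fraction`; total site depths are unchanged. The default contaminant is a
#' random backcross-like genotype (a Markov chain along the panel with
#' Haldane switch probabilities and equal origin frequencies).
#'
#' @param rc a [simulate_reads()] result.
#' @param genome the genome map (for the contaminant's recombination process).
#' @param id segregant id.
#' @param fraction mixing fraction in `[0, 1]`.
#' @param contaminant optional integer vector (1/2) of contaminant origins at
#'   panel sites; `3 - truth` gives an opposite-origin contaminant.
#' @param seed optional seed.
#' @return modified `read_counts`.
#' @export
inject_contamination <- function(rc, genome, id, fraction,
                                 contaminant = NULL, seed = NULL) {
  if (fraction < 0 || fraction > 1) {
    segmap_abort("segmap_error_bad_artifact", "mix fraction must lie in [0, 1]")
  }
  i <- match(id, rc$ids)
  if (is.na(i)) segmap_abort("segmap_error_bad_artifact", "unknown segregant id")
  if (fraction == 0) return(rc)
  use_seed(seed)
  m <- length(rc$pos)
  if (is.null(contaminant)) {
    contaminant <- integer(m)
    for (ch in unique(rc$chrom)) {
      j <- which(rc$chrom == ch)
      pos <- rc$pos[j]
      cur <- sample.int(2L, 1L)
      o <- integer(length(j))
      o[1L] <- cur
      if (length(j) > 1L) {
        r <- haldane_r(diff(pos), genome$recomb_rate)
        sw <- stats::runif(length(j) - 1L) < r
        for (t in 2:length(j)) {
          if (sw[t - 1L]) cur <- 3L - cur
          o[t] <- cur
        }
      }
      contaminant[j] <- o
    }
  }
  depth <- rc$depth_A[i, ] + rc$depth_B[i, ]
  n_cont <- stats::rbinom(m, depth, fraction)
  n_own <- depth - n_cont
  own_corr <- stats::rbinom(m, n_own, 1 - rc$epsilon)
  cont_corr <- stats::rbinom(m, n_cont, 1 - rc$epsilon)
  own_A <- ifelse(rc$truth[i, ] == 1L, own_corr, n_own - own_corr)
  cont_A <- ifelse(contaminant == 1L, cont_corr, n_cont - cont_corr)
  rc$depth_A[i, ] <- own_A + cont_A
  rc$depth_B[i, ] <- depth - (own_A + cont_A)
  rc
}

#' Inject QC-failure artifacts into a read-count matrix
#'
#' @param rc a [simulate_reads()] result.
#' @param genome genome map.
#' @param aneuploid optional list(`id`, `chrom`, `copy_factor`).
#' @param contaminated optional list(`id`, `fraction`, `contaminant` (opt)).
#' @param seed optional seed.
#' @return modified `read_counts`.
#' @export
inject_artifacts <- function(rc, genome, aneuploid = NULL, contaminated = NULL,
                             seed = NULL) {
  use_seed(seed)
  if (!is.null(aneuploid)) {
    rc <- inject_aneuploidy(rc, aneuploid$id, aneuploid$chrom,
                            aneuploid$copy_factor)
  }
  if (!is.null(contaminated)) {
    rc <- inject_contamination(rc, genome, contaminated$id,
                               contaminated$fraction,
                               contaminated$contaminant)
  }
  rc
}

#' Simulate pooled sequencing of an unselected control population
#'
#' Pools `n_pool` unselected (but marker-selected, if markers are given)
#' offspring of the design's cross and sequences the pool to mean depth
#' `lambda_pool` per site. Selected markers distort the pooled frequencies
#' exactly as in the genotyped cohorts.
#'
#' @param design a [cross_design()] (its `markers` apply to the pool).
#' @param model phenotype model (needed only to honor the design interface).
#' @param genome genome map.
#' @param panel SNP panel.
#' @param lambda_pool mean pooled depth per site.
#' @param epsilon per-read error rate.
#' @param n_pool number of pooled individuals.
#' @param seed optional seed.
#' @return data.frame of class `pooled_counts` with columns `chrom`, `pos`,
#'   `depth_A`, `depth_B`.
#' @export
simulate_pooled_control <- function(design, model, genome, panel,
                                    lambda_pool = 200, epsilon = 0.005,
                                    n_pool = 2000, seed = NULL) {
  use_seed(seed)
  pool_design <- cross_design(design$parent1, design$parent2,
                              n_offspring = n_pool, selection = "none",
                              coverage = lambda_pool,
                              markers = design$markers,
                              name = paste0(design$name, "_control"))
  pool <- simulate_backcross_cohort(pool_design, model, genome,
                                    track = "loci",
                                    extra_positions = panel[, c("chrom", "pos")])
  O <- cohort_origin_matrix(pool, panel)
  fB <- colMeans(O == 2L)
  m <- nrow(panel)
  depth <- stats::rpois(m, lambda_pool)
  pB <- fB * (1 - epsilon) + (1 - fB) * epsilon
  dB <- stats::rbinom(m, depth, pB)
  out <- data.frame(chrom = panel$chrom, pos = panel$pos,
                    depth_A = depth - dB, depth_B = dB,
                    stringsAsFactors = FALSE)
  attr(out, "n_pool") <- n_pool
  class(out) <- c("pooled_counts", "data.frame")
  out
}
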