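#' Default causal loci of the rough-morphology architecture
#'
#' Seven named loci: the five mapped genes (TRR1 on chrIV, FLO8 on chrV,
#' MSS11 on chrXIII, END3 on chrXIV, IRA2 on chrXV, at their approximate gene
#' coordinates) plus the two complementation loci on chrVII and chrXV
#' (positions invented within the chromosomes; the second chrXV locus is
#' deliberately distinct from, and only loosely linked to, IRA2).
#'
#' @param scale genome scale factor matching [build_default_genome()].
#' @return data.frame with columns `locus`, `chrom`, `pos`.
#' @export
default_causal_loci <- function(scale = 1) {
  base <- data.frame(
    locus = c("TRR1", "FLO8", "ChrVII", "MSS11", "END3", "IRA2", "ChrXV"),
    chrom = c("chrIV", "chrV", "chrVII", "chrXIII", "chrXIV", "chrXV", "chrXV"),
    pos = c(1161000L, 380000L, 500000L, 590000L, 470000L, 170000L, 800000L),
    stringsAsFactors = FALSE
  )
  base$pos <- pmax(1L, as.integer(round(base$pos * scale)))
  base
}

#' Selected-marker loci mimicking an SGA-style selection cassette
#'
#' A single selectable marker near the CAN1 position on chrV, selecting the
#' BY-derived ("A") haplotype: every genotyped segregant must carry it, which
#' distorts local allele frequencies in mapping and control populations alike
#' without being causal for the phenotype.
#'
#' @param scale genome scale factor.
#' @return data.frame with columns `name`, `chrom`, `pos`, `allele`.
#' @export
sga_markers <- function(scale = 1) {
  data.frame(name = "can1_cassette", chrom = "chrV",
             pos = pmax(1L, as.integer(round(32000 * scale))),
             allele = "A", stringsAsFactors = FALSE)
}

#' Clause-based epistatic phenotype model
#'
#' A phenotype model is an ordered list of requirement clauses. Each clause
#' names required alleles at a set of loci and a penetrance: an individual
#' satisfying the first applicable clause is "rough" with that probability.
#' An optional bumpy clause assigns the "bumpy" label when satisfied and no
#' rough clause fired. Everyone else is "smooth".
#'
#' @param clauses list of `list(requires = named character vector,
#'   penetrance = probability)`.
#' @param loci data.frame (`locus`, `chrom`, `pos`) giving positions of every
#'   locus named in the clauses.
#' @param bumpy_clause optional named character vector of required alleles.
#' @return object of class `phenotype_model`.
#' @export
phenotype_model <- function(clauses, loci, bumpy_clause = NULL) {
  if (length(clauses) == 0L) {
    segmap_abort("segmap_error_bad_model", "clause list must be non-empty")
  }
  for (cl in clauses) {
    if (is.null(cl$requires) || is.null(names(cl$requires)) ||
        any(!nzchar(names(cl$requires)))) {
      segmap_abort("segmap_error_bad_model",
                   "each clause needs a named 'requires' vector")
    }
    if (!is.numeric(cl$penetrance) || cl$penetrance < 0 || cl$penetrance > 1) {
      segmap_abort("segmap_error_bad_model", "penetrance must lie in [0, 1]")
    }
  }
  named <- unique(c(unlist(lapply(clauses, function(cl) names(cl$requires))),
                    names(bumpy_clause)))
  missing <- setdiff(named, loci$locus)
  if (length(missing) > 0L) {
    segmap_abort("segmap_error_bad_model",
                 paste0("clause loci missing from loci table: ",
                        paste(missing, collapse = ", ")))
  }
  structure(list(clauses = clauses, loci = loci, bumpy_clause = bumpy_clause,
                 labels = c("rough", "smooth", "bumpy")),
            class = "phenotype_model")
}

#' Default rough-morphology phenotype model
#'
#' The final architecture of the trait: the primary five-gene genotype
#' (END3-BY, FLO8-3S, IRA2-mut, MSS11-BY, TRR1-3S) is fully penetrant; the
#' alternate genotype, in which END3-3S is complemented by BY alleles at the
#' chrVII and chrXV loci (with the other four requirements unchanged), is
#' rough with penetrance `pi_alt`. Allele labels: "A" = BY-derived,
#' "B" = 3S-derived, "mut" = the spontaneous IRA2 frameshift carried on a
#' 3S-origin chromosome.
#'
#' `pi_alt = 0.2` makes the expected number of END3-3S individuals among 88
#' rough 3S-backcross segregants about 4, matching the observed minor class.
#'
#' @param pi_alt penetrance of the alternate (END3-3S) clause.
#' @param bumpy if `TRUE`, adds the bumpy-subphenotype clause (TRR1-BY with
#'   the remaining primary requirements).
#' @param scale genome scale factor for locus positions.
#' @return a [phenotype_model()].
#' @export
default_phenotype_model <- function(pi_alt = 0.2, bumpy = FALSE, scale = 1) {
  clauses <- list(
    list(requires = c(END3 = "A", FLO8 = "B", IRA2 = "mut",
                      MSS11 = "A", TRR1 = "B"),
         penetrance = 1.0),
    list(requires = c(END3 = "B", ChrVII = "A", ChrXV = "A", FLO8 = "B",
                      IRA2 = "mut", MSS11 = "A", TRR1 = "B"),
         penetrance = pi_alt)
  )
  bc <- NULL
  if (isTRUE(bumpy)) {
    bc <- c(END3 = "A", FLO8 = "B", IRA2 = "mut", MSS11 = "A", TRR1 = "A")
  }
  phenotype_model(clauses, loci = default_causal_loci(scale), bumpy_clause = bc)
}

model_loci <- function(model) {
  unique(c(unlist(lapply(model$clauses, function(cl) names(cl$requires))),
           names(model$bumpy_clause)))
}

clause_satisfied <- function(requires, alleles) {
  all(alleles[names(requires)] == requires)
}

#' Assign a phenotype to one genotype
#'
#' Clauses are evaluated in order; the first whose requirements are met
#' determines the rough probability (its penetrance). If no rough clause
#' fires (or the penetrance draw fails) and the bumpy clause is satisfied,
#' the label is "bumpy"; otherwise "smooth". Uses the current RNG stream.
#'
#' @param alleles named character vector of alleles at (at least) the model loci.
#' @param model a [phenotype_model()].
#' @return one of `"rough"`, `"smooth"`, `"bumpy"`.
#' @export
assign_phenotype <- function(alleles, model) {
  need <- model_loci(model)
  if (!all(need %in% names(alleles)) || anyNA(alleles[need])) {
    segmap_abort("segmap_error_missing_locus",
                 "genotype lacks an allele at a model locus")
  }
  for (cl in model$clauses) {
    if (clause_satisfied(cl$requires, alleles)) {
      if (stats::runif(1) < cl$penetrance) return("rough")
      break  # at most one clause applies
    }
  }
  if (!is.null(model$bumpy_clause) &&
      clause_satisfied(model$bumpy_clause, alleles)) {
    return("bumpy")
  }
  "smooth"
}

# Vectorized phenotype assignment over an n x loci allele matrix.
assign_phenotypes <- function(allele_matrix, model) {
  n <- nrow(allele_matrix)
  if (n == 0L) return(character(0))
  need <- model_loci(model)
  if (!all(need %in% colnames(allele_matrix))) {
    segmap_abort("segmap_error_missing_locus",
                 "allele matrix lacks a model locus column")
  }
  out <- rep(NA_character_, n)
  decided <- rep(FALSE, n)
  for (cl in model$clauses) {
    sat <- rep(TRUE, n)
    for (loc in names(cl$requires)) {
      sat <- sat & (allele_matrix[, loc] == cl$requires[[loc]])
    }
    sat <- sat & !decided
    if (any(sat)) {
      rough <- sat & (stats::runif(n) < cl$penetrance)
      out[rough] <- "rough"
      decided <- decided | sat  # first satisfied clause decides
    }
  }
  rest <- is.na(out)
  if (any(rest)) {
    if (!is.null(model$bumpy_clause)) {
      sat <- rep(TRUE, n)
      for (loc in names(model$bumpy_clause)) {
        sat <- sat & (allele_matrix[, loc] == model$bumpy_clause[[loc]])
      }
      out[rest & sat] <- "bumpy"
      rest <- is.na(out)
    }
    out[rest] <- "smooth"
  }
  out
}

#' Construct a haploid segregant genotype
#'
#' A segregant carries, per chromosome, a run-length encoded parental-origin
#' track (`ends`: segment end positions; `origin`: 1 = "A", 2 = "B") plus a
#' named allele map at the causal loci (values "A", "B" or "mut").
#'
#' @param id character id.
#' @param segments named list (by chromosome) of `list(ends, origin)`.
#' @param alleles named character vector at causal loci.
#' @param loci data.frame (`locus`, `chrom`, `pos`).
#' @param generation free-form tag.
#' @param crossovers optional named list of crossover positions per chromosome.
#' @return object of class `segregant`.
#' @export
new_segregant <- function(id, segments, alleles, loci,
                          generation = "founder", crossovers = NULL) {
  structure(list(id = id, segments = segments, alleles = alleles,
                 loci = loci, generation = generation,
                 crossovers = crossovers),
            class = "segregant")
}

#' Founder strain genotype
#'
#' A non-recombinant haploid whose every chromosome carries a single parental
#' origin. `ira2_mut = TRUE` marks the strain as carrying the spontaneous
#' IRA2 frameshift (an allele functionally distinct from "B" but residing on
#' a 3S-origin chromosome).
#'
#' @param genome a [genome_map()].
#' @param origin `"A"` (BY-like) or `"B"` (3S-like).
#' @param loci causal locus table; defaults to [default_causal_loci()].
#' @param id strain id.
#' @param ira2_mut carry the spontaneous IRA2 allele.
#' @return a [new_segregant()].
#' @export
founder_strain <- function(genome, origin = c("A", "B"),
                           loci = default_causal_loci(), id = NULL,
                           ira2_mut = FALSE) {
  origin <- match.arg(origin)
  oi <- match(origin, c("A", "B"))
  segs <- lapply(genome$chromosomes$length,
                 function(L) list(ends = as.numeric(L), origin = oi))
  names(segs) <- genome$chromosomes$name
  alleles <- stats::setNames(rep(origin, nrow(loci)), loci$locus)
  if (isTRUE(ira2_mut)) {
    if (origin != "B") {
      segmap_abort("segmap_error_bad_model",
                   "the spontaneous IRA2 allele rides on a 3S-origin ('B') chromosome")
    }
    alleles["IRA2"] <- "mut"
  }
  if (is.null(id)) id <- if (origin == "A") "BY" else "3S"
  new_segregant(id, segs, alleles, loci, generation = "founder")
}

#' Construct a synthetic parent strain with a specified causal genotype
#'
#' Builds a haploid whose origin track is consistent with the requested
#' alleles: chromosomes carrying causal loci are mosaics switching origin at
#' midpoints between adjacent loci as needed ("mut" rides on a "B"-origin
#' chromosome), all other sequence takes the `background` origin. Useful when
#' a cross design specifies a parent by genotype rather than by ancestry;
#' [sample_founder_segregant()] produces the realistic recombinant
#' alternative.
#'
#' @param genome a [genome_map()].
#' @param alleles named allele vector ("A"/"B"/"mut") over the causal loci.
#' @param loci causal locus table.
#' @param background origin label for chromosomes/regions without causal loci.
#' @param id strain id.
#' @return a [new_segregant()].
#' @export
make_parent_strain <- function(genome, alleles, loci = default_causal_loci(),
                               background = "B", id = "synthetic_parent") {
  if (!all(loci$locus %in% names(alleles))) {
    segmap_abort("segmap_error_missing_locus",
                 "alleles must cover every causal locus")
  }
  bg <- match(background, c("A", "B"))
  origin_of <- function(al) if (al == "A") 1L else 2L  # "mut" -> B-origin
  segs <- vector("list", nrow(genome$chromosomes))
  names(segs) <- genome$chromosomes$name
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[i]
    L <- genome$chromosomes$length[i]
    rows <- loci[loci$chrom == ch, , drop = FALSE]
    if (nrow(rows) == 0L) {
      segs[[ch]] <- list(ends = as.numeric(L), origin = bg)
      next
    }
    rows <- rows[order(rows$pos), , drop = FALSE]
    orig <- vapply(alleles[rows$locus], origin_of, 1L)
    r <- rle(as.integer(orig))
    cuts <- cumsum(r$lengths)
    ends <- numeric(length(cuts))
    if (length(cuts) > 1L) {
      for (k in seq_len(length(cuts) - 1L)) {
        ends[k] <- floor((rows$pos[cuts[k]] + rows$pos[cuts[k] + 1L]) / 2)
      }
    }
    ends[length(cuts)] <- L
    segs[[ch]] <- list(ends = ends, origin = as.integer(r$values))
  }
  new_segregant(id, segs, alleles[loci$locus], loci,
                generation = "synthetic")
}

#' Parental origin at arbitrary positions
#'
#' @param g a [new_segregant()].
#' @param chrom chromosome name (scalar).
#' @param pos vector of positions.
#' @return character vector of `"A"`/`"B"`.
#' @export
origin_at <- function(g, chrom, pos) {
  seg <- g$segments[[chrom]]
  if (is.null(seg)) {
    segmap_abort("segmap_error_unknown_chromosome",
                 paste0("segregant has no chromosome ", chrom))
  }
  idx <- findInterval(pos, seg$ends, left.open = TRUE) + 1L
  c("A", "B")[seg$origin[idx]]
}

# Integer (1/2) origins of a segregant at panel sites, as a vector over the
# whole panel (ordered as the panel).
origin_at_panel <- function(g, panel) {
  out <- integer(nrow(panel))
  for (ch in unique(panel$chrom)) {
    i <- which(panel$chrom == ch)
    seg <- g$segments[[ch]]
    idx <- findInterval(panel$pos[i], seg$ends, left.open = TRUE) + 1L
    out[i] <- seg$origin[idx]
  }
  out
}

#' @export
print.segregant <- function(x, ...) {
  nseg <- sum(vapply(x$segments, function(s) length(s$ends), 1L))
  cat(sprintf("<segregant> %s (%s): %d origin segments over %d chromosomes\n",
              x$id, x$generation, nseg, length(x$segments)))
  al <- paste(names(x$alleles), x$alleles, sep = "=", collapse = " ")
  cat(" alleles:", al, "\n")
  invisible(x)
}

#' Causal genotype of the reference rough segregant
#'
#' The allele combination carried by the segregant used to seed the
#' backcrosses: rough via the primary clause, and additionally carrying the
#' BY alleles at both complementation loci.
#'
#' @return named character vector.
#' @export
reference_rough_genotype <- function() {
  c(END3 = "A", FLO8 = "B", IRA2 = "mut", MSS11 = "A", TRR1 = "B",
    ChrVII = "A", ChrXV = "A")
}
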