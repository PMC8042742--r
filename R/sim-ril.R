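# Forward simulation of multiparent RIL subpopulations.
#
# Haplotypes are founder-labelled segment lists per chromosome:
# list(end, fdr) where segment i covers (end[i-1], end[i]] in bp (end[0] = 0)
# and fdr[i] indexes the subpopulation's founder quadruple.  An individual is
# list(hap1, hap2), each a list with one segment list per chromosome.

founder_haplotype <- function(map, founder_idx) {
  lapply(seq_len(nrow(map$chromosomes)), function(i)
    list(end = map$chromosomes$length_bp[i], fdr = as.integer(founder_idx)))
}

# founder index of the segment containing bp position `pos` (boundary
# positions belong to the segment ending there, i.e. to the left)
.fdr_at <- function(hchr, pos) hchr$fdr[findInterval(pos, hchr$end, left.open = TRUE) + 1L]

.gamete_chr <- function(h1, h2, len_bp, len_morgan) {
  ncx <- stats::rpois(1L, len_morgan)
  cur <- sample.int(2L, 1L)
  if (ncx == 0L) return(if (cur == 1L) h1 else h2)
  # crossover positions uniform in genetic distance; the bp <-> cM map is
  # linear so genetic uniformity maps to physical uniformity
  cp <- sort.int(stats::runif(ncx)) * len_bp
  bounds <- c(cp, len_bp)
  ends <- numeric(0)
  fdr <- integer(0)
  lo <- 0
  for (b in bounds) {
    src <- if (cur == 1L) h1 else h2
    ks <- which(src$end > lo & src$end < b)
    ends <- c(ends, src$end[ks], b)
    jb <- findInterval(b, src$end, left.open = TRUE) + 1L
    fdr <- c(fdr, src$fdr[ks], src$fdr[jb])
    cur <- 3L - cur
    lo <- b
  }
  n <- length(ends)
  keep <- c(fdr[-1] != fdr[-n], TRUE)
  list(end = ends[keep], fdr = fdr[keep])
}

#' Sample a gamete from a diplotype
#'
#' Meiosis model: the number of crossovers per chromosome is Poisson with mean
#' equal to the chromosome's genetic length in Morgans (no interference);
#' crossover positions are uniform in genetic distance and mapped to bp by
#' linear interpolation; the starting homolog is chosen with probability 1/2.
#'
#' @param individual list with elements `hap1` and `hap2`, each a per-chromosome
#'   list of founder-labelled segments (`end`, `fdr`), as produced by
#'   [simulate_subpopulation()].
#' @param map a [genome_map()].
#' @return A haplotype: per-chromosome list of `(end, fdr)` segment lists that
#'   tiles every chromosome.
#' @export
sample_gamete <- function(individual, map) {
  nchr <- nrow(map$chromosomes)
  if (nchr == 0L) stop("empty genome map")
  lapply(seq_len(nchr), function(i)
    .gamete_chr(individual$hap1[[i]], individual$hap2[[i]],
                map$chromosomes$length_bp[i], map$chromosomes$length_morgan[i]))
}

.cross <- function(mother, father, map) {
  list(hap1 = sample_gamete(mother, map), hap2 = sample_gamete(father, map))
}

# total number of functional gene copies (over both homologs and all copies
# of one family) carried by an individual
.functional_copies <- function(ind, gene, founders) {
  tot <- 0L
  for (k in seq_len(nrow(gene$copies))) {
    chrom <- gene$copies$chrom[k]
    ci <- match(chrom, names(ind$chrom_index))
    if (is.na(ci)) stop("gene copy chromosome not in map: ", chrom)
    pos <- (gene$copies$start_bp[k] + gene$copies$end_bp[k]) / 2
    for (h in c("hap1", "hap2")) {
      f <- founders[.fdr_at(ind[[h]][[ci]], pos)]
      if (gene$founder_states[f, k] == "functional") tot <- tot + 1L
    }
  }
  tot
}

.is_viable <- function(ind, genes, founders) {
  for (g in genes) {
    if (!g$essential) next
    if (.functional_copies(ind, g, founders) == 0L &&
        stats::runif(1) < g$penetrance) return(FALSE)
  }
  TRUE
}

#' Construct a hybrid (or inbred) individual from founder indices
#'
#' @param map a [genome_map()].
#' @param f1,f2 founder indices of the two homologs (equal for an inbred).
#' @return An individual (`hap1`, `hap2`, `chrom_index`) usable with
#'   [sample_gamete()] and [simulate_offspring()].
#' @export
hybrid_individual <- function(map, f1, f2 = f1) {
  list(hap1 = founder_haplotype(map, f1), hap2 = founder_haplotype(map, f2),
       chrom_index = stats::setNames(seq_len(nrow(map$chromosomes)),
                                     map$chromosomes$id))
}

#' Simulate viable offspring of a single cross
#'
#' Draws offspring of `mother x father` (selfing when both are the same
#' individual), applying embryo-lethality selection: a zygote with zero
#' functional copies of an essential family dies with probability equal to
#' the family's penetrance and is redrawn, up to `max_tries` attempts each.
#'
#' @param mother,father individuals (e.g. [hybrid_individual()]).
#' @param genes list of [dup_gene_spec()].
#' @param founders founder names indexing the haplotype labels.
#' @param map a [genome_map()].
#' @param n number of viable offspring.
#' @param max_tries bounded retries per offspring.
#' @return List of `n` viable individuals.
#' @export
simulate_offspring <- function(mother, father, genes, founders, map, n,
                               max_tries = 1000) {
  lapply(seq_len(n), function(i) {
    for (try in seq_len(max_tries)) {
      ind <- .cross(mother, father, map)
      ind$chrom_index <- mother$chrom_index
      if (.is_viable(ind, genes, founders)) return(ind)
    }
    stop("unattainable viable offspring after ", max_tries, " tries")
  })
}

#' Simulate founder marker alleles for a subpopulation
#'
#' Draws biallelic marker alleles (0/1) for each founder at every map marker,
#' rejecting markers that would be monomorphic across the founder set (real
#' marker panels are selected to segregate among the founders).
#'
#' @param map a [genome_map()] with markers.
#' @param n_founders number of founders (rows).
#' @return List (per chromosome) of `n_founders x n_markers` 0/1 matrices.
#' @export
sim_founder_alleles <- function(map, n_founders = 4) {
  lapply(map$marker_pos, function(mp) {
    m <- length(mp)
    a <- matrix(stats::rbinom(n_founders * m, 1L, 0.5), n_founders, m)
    bad <- which(colSums(a) %in% c(0L, n_founders))
    while (length(bad)) {
      a[, bad] <- stats::rbinom(n_founders * length(bad), 1L, 0.5)
      bad <- bad[colSums(a[, bad, drop = FALSE]) %in% c(0L, n_founders)]
    }
    a
  })
}

#' Simulate a four-founder RIL subpopulation
#'
#' Follows the diallel design: two F1 hybrids (founder 1 x 2 and founder
#' 3 x 4) are crossed to give a four-way F1, which is selfed by single-seed
#' descent to generation `design$selfing_generations`.  At every generation an
#' individual with zero functional copies of an essential duplicated gene
#' family dies with probability equal to the family's penetrance and is
#' replaced by redrawing from the same parents, so lethality acts as embryo
#' selection within the line.  Observed marker genotypes are allele dosages
#' (0/1/2) with a symmetric per-allele flip error and uniform missingness.
#'
#' @param design a [cross_design()].
#' @param genes list of [dup_gene_spec()] objects (may be empty); their
#'   `founder_states` rows must cover the design's founders.
#' @param map a [genome_map()].
#' @param error_rate per-allele flip probability of an observed marker call.
#' @param missing_rate probability that a marker call is missing.
#' @param founder_alleles founder allele table as from [sim_founder_alleles()]
#'   (rows ordered as `design$founders`); simulated when `NULL`.
#' @param genotype logical; set `FALSE` to skip observed-marker generation
#'   (truth mosaics only), which is faster for large scans.
#' @param max_tries bounded number of redraws per generation before erroring
#'   out as unattainable.
#' @param seed optional integer seed.
#'
#' @return An object of class `ril_population`: list with `design`, `map`,
#'   `founders`, `founder_alleles`, `individuals` (each `list(hap1, hap2)`),
#'   and (unless `genotype = FALSE`) `genotypes` (individuals x markers dosage
#'   matrix with `NA` missing) and `marker_info` (chrom, pos).
#' @export
simulate_subpopulation <- function(design, genes = list(), map,
                                   error_rate = 0.005, missing_rate = 0.10,
                                   founder_alleles = NULL, genotype = TRUE,
                                   max_tries = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(genes, "dup_gene_spec")) genes <- list(genes)
  founders <- design$founders
  for (g in genes) {
    if (!all(founders %in% rownames(g$founder_states)))
      stop("founder states missing for some design founders in family ", g$family_id)
  }
  chrom_index <- stats::setNames(seq_len(nrow(map$chromosomes)), map$chromosomes$id)

  hy1 <- list(hap1 = founder_haplotype(map, 1L), hap2 = founder_haplotype(map, 2L),
              chrom_index = chrom_index)
  hy2 <- list(hap1 = founder_haplotype(map, 3L), hap2 = founder_haplotype(map, 4L),
              chrom_index = chrom_index)
  n_self <- design$selfing_generations - 1L

  draw_viable <- function(mother, father) {
    for (try in seq_len(max_tries)) {
      ind <- .cross(mother, father, map)
      ind$chrom_index <- chrom_index
      if (.is_viable(ind, genes, founders)) return(ind)
    }
    stop("unattainable viable offspring after ", max_tries, " tries")
  }

  individuals <- vector("list", design$target_n)
  for (i in seq_len(design$target_n)) {
    ind <- draw_viable(hy1, hy2)            # four-way F1
    for (gen in seq_len(n_self)) ind <- draw_viable(ind, ind)
    ind$viable <- TRUE
    individuals[[i]] <- ind
  }

  pop <- structure(list(design = design, map = map, founders = founders,
                        genes = genes, individuals = individuals,
                        error_rate = error_rate, missing_rate = missing_rate),
                   class = "ril_population")
  if (genotype) {
    if (is.null(founder_alleles)) founder_alleles <- sim_founder_alleles(map, 4)
    pop$founder_alleles <- founder_alleles
    obs <- observe_markers(pop, founder_alleles, error_rate, missing_rate)
    pop$genotypes <- obs$genotypes
    pop$marker_info <- obs$marker_info
  }
  pop
}

#' Observed marker dosages for a simulated population
#'
#' Reads the true founder label under each marker on both homologs, converts
#' to allele dosage via the founder allele table, then applies a symmetric
#' per-allele flip error and uniform missingness.
#'
#' @param pop a `ril_population`.
#' @param founder_alleles per-chromosome founder x marker 0/1 matrices.
#' @param error_rate per-allele flip probability.
#' @param missing_rate per-call missing probability.
#' @return list with `genotypes` (n x markers matrix, entries 0/1/2/NA) and
#'   `marker_info` data frame (`chrom`, `pos`).
#' @export
observe_markers <- function(pop, founder_alleles = pop$founder_alleles,
                            error_rate = pop$error_rate,
                            missing_rate = pop$missing_rate) {
  map <- pop$map
  nchr <- nrow(map$chromosomes)
  n <- length(pop$individuals)
  marker_info <- do.call(rbind, lapply(seq_len(nchr), function(ci)
    if (length(map$marker_pos[[ci]]))
      data.frame(chrom = map$chromosomes$id[ci], pos = map$marker_pos[[ci]])
    else NULL))
  m_tot <- nrow(marker_info)
  G <- matrix(NA_integer_, n, m_tot)
  col0 <- 0L
  for (ci in seq_len(nchr)) {
    mp <- map$marker_pos[[ci]]
    m <- length(mp)
    if (!m) next
    al <- founder_alleles[[ci]]
    for (i in seq_len(n)) {
      ind <- pop$individuals[[i]]
      f1 <- ind$hap1[[ci]]$fdr[findInterval(mp, ind$hap1[[ci]]$end, left.open = TRUE) + 1L]
      f2 <- ind$hap2[[ci]]$fdr[findInterval(mp, ind$hap2[[ci]]$end, left.open = TRUE) + 1L]
      a1 <- al[cbind(f1, seq_len(m))]
      a2 <- al[cbind(f2, seq_len(m))]
      if (error_rate > 0) {
        a1 <- xor(a1, stats::runif(m) < error_rate)
        a2 <- xor(a2, stats::runif(m) < error_rate)
      }
      g <- as.integer(a1) + as.integer(a2)
      if (missing_rate > 0) g[stats::runif(m) < missing_rate] <- NA_integer_
      G[i, col0 + seq_len(m)] <- g
    }
    col0 <- col0 + m
  }
  rownames(G) <- paste0(pop$design$label, "_", seq_len(n))
  list(genotypes = G, marker_info = marker_info)
}

#' True unordered founder pair of an individual at a genomic position
#'
#' @param ind an individual (`hap1`, `hap2`).
#' @param map a [genome_map()].
#' @param chrom chromosome id.
#' @param pos bp position.
#' @param founders founder names indexing the haplotype labels.
#' @return Character vector of two founder names, sorted.
#' @export
founder_pair_at <- function(ind, map, chrom, pos, founders) {
  ci <- match(chrom, map$chromosomes$id)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  sort(founders[c(.fdr_at(ind$hap1[[ci]], pos), .fdr_at(ind$hap2[[ci]], pos))])
}

#' True diplotype state segments of one simulated individual
#'
#' Overlays the two truth homologs and returns, per chromosome, the segments
#' of constant unordered founder pair, in BED-like 0-based half-open
#' coordinates.  These are the "perfect genotyping" blocks used to anchor
#' gene-pair loci directly on simulator truth.
#'
#' @param pop a `ril_population`.
#' @param i individual index.
#' @return A data frame with columns `chrom`, `start`, `end`, `founder1`,
#'   `founder2` (founder names, sorted within row), of class
#'   `haplotype_blocks`.
#' @export
truth_blocks <- function(pop, i) {
  ind <- pop$individuals[[i]]
  founders <- pop$founders
  out <- vector("list", nrow(pop$map$chromosomes))
  for (ci in seq_len(nrow(pop$map$chromosomes))) {
    h1 <- ind$hap1[[ci]]; h2 <- ind$hap2[[ci]]
    ends <- sort(unique(c(h1$end, h2$end)))
    f1 <- h1$fdr[findInterval(ends, h1$end, left.open = TRUE) + 1L]
    f2 <- h2$fdr[findInterval(ends, h2$end, left.open = TRUE) + 1L]
    lo <- pmin(f1, f2); hi <- pmax(f1, f2)
    n <- length(ends)
    keep <- if (n > 1) c(lo[-1] != lo[-n] | hi[-1] != hi[-n], TRUE) else TRUE
    ends2 <- ends[keep]
    out[[ci]] <- data.frame(chrom = pop$map$chromosomes$id[ci],
                            start = c(0, ends2[-length(ends2)]),
                            end = ends2,
                            founder1 = founders[lo[keep]],
                            founder2 = founders[hi[keep]],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("haplotype_blocks", "data.frame")
  res
}

#' @export
print.ril_population <- function(x, ...) {
  cat("RIL subpopulation", x$design$label, "-", length(x$individuals),
      "individuals, founders:", paste(x$founders, collapse = ", "), "\n")
  cat("  generation F", x$design$selfing_generations, ", ",
      sum(vapply(x$map$marker_pos, length, integer(1))), " markers\n", sep = "")
  invisible(x)
}
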