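#' Genome map for simulation and genotyping
#'
#' A genome map holds the physical and genetic length of each chromosome plus
#' the physical positions of the genotyping markers.  Genetic positions of
#' arbitrary base pairs are obtained by linear interpolation between the
#' chromosome ends, so 1 bp corresponds to `genetic_length / physical_length`
#' Morgans everywhere on a chromosome.
#'
#' @param chrom_ids character vector of chromosome identifiers.
#' @param lengths_bp physical chromosome lengths in base pairs (strictly
#'   positive).
#' @param lengths_morgan genetic chromosome lengths in Morgans (strictly
#'   positive).
#' @param marker_pos list (one element per chromosome) of strictly increasing
#'   marker positions in bp, or `NULL` for a map without markers.
#'
#' @return An object of class `genome_map`: a list with elements
#'   `chromosomes` (data frame with `id`, `length_bp`, `length_morgan`) and
#'   `marker_pos` (named list of numeric vectors).
#' @export
#' @examples
#' map <- genome_map(c("Chr1", "Chr2"), c(30e6, 20e6), c(1.2, 0.9))
genome_map <- function(chrom_ids, lengths_bp, lengths_morgan, marker_pos = NULL) {
  if (length(chrom_ids) == 0L) stop("empty genome map")
  if (length(lengths_bp) != length(chrom_ids) ||
      length(lengths_morgan) != length(chrom_ids))
    stop("chrom_ids, lengths_bp and lengths_morgan must have equal length")
  if (any(lengths_bp <= 0)) stop("physical lengths must be strictly positive")
  if (any(lengths_morgan < 0)) stop("genetic lengths must be non-negative")
  if (is.null(marker_pos)) {
    marker_pos <- rep(list(numeric(0)), length(chrom_ids))
  }
  if (length(marker_pos) != length(chrom_ids))
    stop("marker_pos must have one element per chromosome")
  names(marker_pos) <- chrom_ids
  for (i in seq_along(marker_pos)) {
    mp <- marker_pos[[i]]
    if (length(mp) && (any(diff(mp) <= 0) || mp[1] < 1 || mp[length(mp)] > lengths_bp[i]))
      stop("marker positions must be strictly increasing and inside chromosome ",
           chrom_ids[i])
  }
  structure(list(
    chromosomes = data.frame(id = as.character(chrom_ids),
                             length_bp = as.numeric(lengths_bp),
                             length_morgan = as.numeric(lengths_morgan),
                             stringsAsFactors = FALSE),
    marker_pos = marker_pos
  ), class = "genome_map")
}

#' Default five-chromosome map resembling an A. thaliana-scale genome
#'
#' Five chromosomes of 30.4, 19.7, 23.5, 18.6 and 27.0 Mb with genetic lengths
#' around 1 Morgan each, and `n_markers` equally spaced markers per chromosome.
#'
#' @param n_markers markers per chromosome (default 200).
#' @return A [genome_map()].
#' @export
default_genome_map <- function(n_markers = 200) {
  len_bp <- c(30.4e6, 19.7e6, 23.5e6, 18.6e6, 27.0e6)
  len_m  <- c(1.20, 0.90, 1.00, 0.95, 1.10)
  mp <- lapply(len_bp, function(L) round(seq(L / (n_markers + 1), L * n_markers / (n_markers + 1),
                                             length.out = n_markers)))
  genome_map(paste0("Chr", 1:5), len_bp, len_m, mp)
}

#' @export
print.genome_map <- function(x, ...) {
  nm <- vapply(x$marker_pos, length, integer(1))
  cat("Genome map:", nrow(x$chromosomes), "chromosomes,",
      sum(nm), "markers\n")
  df <- x$chromosomes
  df$n_markers <- nm
  print(df, row.names = FALSE)
  invisible(x)
}

#' Specification of a duplicated gene family
#'
#' Describes the copies of one duplicated gene family (their genomic
#' placement) together with the functional state of every copy in every
#' founder, and whether loss of all functional copies is lethal.
#'
#' @param family_id family identifier.
#' @param copies data frame with columns `copy_id`, `chrom`, `start_bp`,
#'   `end_bp`, and optionally `strand`, `tss_bp`, `tes_bp`.
#' @param founder_states matrix (founders x copies) of states, each cell one
#'   of `"functional"`, `"lof"`, `"silenced"`, `"absent"`.
#' @param essential logical; do zero-functional-copy genotypes die?
#' @param penetrance probability in `[0, 1]` that a zero-functional-copy
#'   genotype dies (only used when `essential`).
#'
#' @return An object of class `dup_gene_spec`.
#' @export
dup_gene_spec <- function(family_id, copies, founder_states,
                          essential = FALSE, penetrance = 1) {
  stopifnot(is.data.frame(copies),
            all(c("copy_id", "chrom", "start_bp", "end_bp") %in% names(copies)))
  if (any(copies$start_bp >= copies$end_bp))
    stop("copy start_bp must be < end_bp")
  founder_states <- as.matrix(founder_states)
  if (ncol(founder_states) != nrow(copies))
    stop("founder_states needs one column per copy")
  colnames(founder_states) <- copies$copy_id
  bad <- !(founder_states %in% c("functional", "lof", "silenced", "absent"))
  if (any(bad)) stop("invalid founder state: ", founder_states[bad][1])
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
  structure(list(family_id = family_id, copies = copies,
                 founder_states = founder_states,
                 essential = isTRUE(essential), penetrance = penetrance),
            class = "dup_gene_spec")
}

#' Midpoint anchor of a gene copy
#'
#' @param spec a [dup_gene_spec()].
#' @param copy copy index or id.
#' @return list with `chrom` and `midpoint_bp` (gene midpoint).
#' @export
copy_anchor <- function(spec, copy) {
  cp <- spec$copies[if (is.character(copy)) match(copy, spec$copies$copy_id) else copy, ]
  list(chrom = cp$chrom, midpoint_bp = (cp$start_bp + cp$end_bp) / 2)
}

#' Crossing design of a four-founder RIL subpopulation
#'
#' Two F1 hybrids, each produced by crossing two inbred founders, are crossed
#' to give a four-way hybrid which is then selfed by single-seed descent to
#' the stated generation.  A design labelled e.g. `"ABBA"` pairs founders
#' 1 + 2 into the first hybrid and 3 + 4 into the second.
#'
#' @param label subpopulation label.
#' @param founders character vector of exactly four distinct founder names,
#'   ordered so that the first two form hybrid 1 and the last two hybrid 2.
#' @param selfing_generations final generation number (e.g. 4 for F4, 6 for
#'   F6); must be at least 2.  `g` generations mean `g - 1` rounds of selfing
#'   after the four-way cross.
#' @param target_n number of viable RILs to produce.
#'
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(label, founders, selfing_generations = 6, target_n = 90) {
  founders <- as.character(founders)
  if (length(founders) != 4 || anyDuplicated(founders))
    stop("exactly four distinct founders required")
  if (selfing_generations < 2) stop("selfing_generations must be >= 2")
  if (target_n <= 0) stop("target_n must be positive")
  structure(list(label = label, founders = founders,
                 selfing_generations = as.integer(selfing_generations),
                 target_n = as.integer(target_n)),
            class = "cross_design")
}
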