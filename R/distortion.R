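# Segregation-distortion scan over unlinked duplicated gene pairs.
#
# Allele-pair counting convention: each individual contributes two counts.
# A double homozygote "aabb" adds 2 to o_ab; a genotype with heterozygosity
# is split positionally after sorting each locus's allele pair, so "abbc"
# adds 1 to o_ab and 1 to o_bc.  Because the two counts from one individual
# are nearly identical in highly inbred lines, the raw chi-square statistic
# on such tables is inflated by the duplication factor 1 + q, where q is the
# fraction of individuals whose two counts fall in one cell; the scan divides
# by that factor by default (scale = "individual"), with the uncorrected
# statistic available via scale = "pair".

#' Anchor pair of an unlinked duplicated gene pair
#'
#' For reference copies the anchor is the gene midpoint; for non-reference
#' copies it is the midpoint between the two closest flanking syntenic
#' regions (supplied by the caller as `mid2`).
#'
#' @param family_id family identifier.
#' @param chrom1,mid1 chromosome and midpoint (bp) of the first locus.
#' @param chrom2,mid2 chromosome and midpoint (bp) of the second locus.
#' @return A `gene_pair_locus` list.  The two loci must lie on different
#'   chromosomes (intrachromosomal pairs are excluded from the scan by
#'   design, to avoid linkage effects).
#' @export
gene_pair_locus <- function(family_id, chrom1, mid1, chrom2, mid2) {
  if (chrom1 == chrom2) stop("gene pair loci must be on different chromosomes")
  structure(list(family_id = family_id, chrom1 = chrom1, mid1 = mid1,
                 chrom2 = chrom2, mid2 = mid2), class = "gene_pair_locus")
}

#' Diplotype genotype at an anchor position
#'
#' Returns the unordered founder pair of the haplotype block containing the
#' anchor.  A midpoint falling exactly on a block boundary is assigned to
#' the left (lower-coordinate) block.  Anchors outside every block give
#' `NA`, and such individuals are excluded from allele-pair counts.
#'
#' @param blocks a `haplotype_blocks` data frame (0-based half-open).
#' @param chrom,midpoint_bp the anchor.
#' @return Character vector of two founder names (sorted), or `c(NA, NA)`.
#' @export
genotype_at_locus <- function(blocks, chrom, midpoint_bp) {
  b <- blocks[blocks$chrom == chrom, , drop = FALSE]
  j <- which(midpoint_bp > b$start & midpoint_bp <= b$end)
  if (!length(j)) return(c(NA_character_, NA_character_))
  j <- j[1L]
  sort(c(b$founder1[j], b$founder2[j]))
}

#' Count founder allele-pair combinations at a gene pair
#'
#' @param gt1,gt2 n x 2 character matrices of unordered founder genotypes at
#'   locus 1 and locus 2 (rows = individuals; `NA` rows are skipped).
#' @param founders1,founders2 founder name sets indexing the count table
#'   (defaults: founders observed).
#' @return An `allele_pair_table`: founders1 x founders2 integer matrix of
#'   counts `o_ij` with attributes `n_individuals` (individuals counted; the
#'   grand total is exactly twice this) and `n_skipped`.
#' @export
count_allele_pairs <- function(gt1, gt2, founders1 = NULL, founders2 = NULL) {
  gt1 <- rbind(gt1); gt2 <- rbind(gt2)
  stopifnot(nrow(gt1) == nrow(gt2), ncol(gt1) == 2, ncol(gt2) == 2)
  ok <- !is.na(gt1[, 1]) & !is.na(gt1[, 2]) & !is.na(gt2[, 1]) & !is.na(gt2[, 2])
  g1 <- gt1[ok, , drop = FALSE]; g2 <- gt2[ok, , drop = FALSE]
  # canonical (lexicographic) sort within each locus, then positional pairing
  x1 <- pmin(g1[, 1], g1[, 2]); x2 <- pmax(g1[, 1], g1[, 2])
  y1 <- pmin(g2[, 1], g2[, 2]); y2 <- pmax(g2[, 1], g2[, 2])
  if (is.null(founders1)) founders1 <- sort(unique(c(x1, x2)))
  if (is.null(founders2)) founders2 <- sort(unique(c(y1, y2)))
  f1 <- factor(c(x1, x2), levels = founders1)
  f2 <- factor(c(y1, y2), levels = founders2)
  o <- table(locus1 = f1, locus2 = f2)
  o <- matrix(as.integer(o), nrow(o), ncol(o),
              dimnames = list(founders1, founders2))
  # individuals whose two counts fall in one cell (double homozygotes):
  # drives the duplication factor of the calibrated test statistic
  n_dup <- sum(x1 == x2 & y1 == y2)
  structure(o, n_individuals = sum(ok), n_skipped = sum(!ok),
            n_duplicated = n_dup,
            class = c("allele_pair_table", "matrix"))
}

#' Expected allele-pair counts
#'
#' `method = "marginal"` uses the classical independence expectation
#' `e_ij = row_i * col_j / total`, which is robust to single-locus
#' segregation distortion; `method = "design"` uses the uniform design
#' expectation `total / cells`.
#'
#' @param o an [count_allele_pairs()] table (or plain count matrix).
#' @param method `"marginal"` (default) or `"design"`.
#' @return Numeric matrix `e` with attribute `method`; `sum(e) == sum(o)`.
#' @export
expected_pairs <- function(o, method = c("marginal", "design")) {
  method <- match.arg(method)
  tot <- sum(o)
  if (tot <= 0) stop("zero grand total")
  e <- if (method == "marginal")
    outer(rowSums(o), colSums(o)) / tot
  else matrix(tot / length(o), nrow(o), ncol(o), dimnames = dimnames(o))
  dimnames(e) <- dimnames(o)
  attr(e, "method") <- method
  e
}

.distortion_result <- function(stat, df, pop = NA_character_, n = NA_integer_) {
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p, q_value = NA_real_,
                 population = pop, n_individuals = n),
            class = "distortion_result")
}

#' @export
print.distortion_result <- function(x, ...) {
  cat(sprintf("Allele-pair distortion: chi^2 = %.4g, df = %d, p = %.3g",
              x$statistic, x$df, x$p_value))
  if (!is.na(x$q_value)) cat(sprintf(", q = %.3g", x$q_value))
  cat("\n")
  invisible(x)
}

#' Chi-square test of allele-pair segregation distortion (one population)
#'
#' Computes `chi^2 = sum (o - e)^2 / e` over cells; cells with `e = 0` and
#' `o = 0` are dropped, `e = 0` with `o > 0` is an error.  Degrees of
#' freedom: marginal expectations use `(r - 1)(c - 1)` with `r`, `c` the
#' numbers of nonzero marginal classes; design expectations use the number
#' of included cells minus one.  `scale = "individual"` divides the
#' statistic by the duplication factor `1 + q`, with `q` the fraction of
#' individuals whose two counts fall in the same cell (double homozygotes):
#' duplicated counts inflate the Pearson statistic by exactly that factor
#' under the null.  In a fully inbred population `q = 1` and the factor is 2,
#' which is also the fallback when the table does not carry the attribute.
#' `scale = "pair"` is the raw statistic on the table as counted.
#'
#' @param o observed count table ([count_allele_pairs()]).
#' @param e expected table ([expected_pairs()]); computed from `o` with
#'   `method` when missing.
#' @param method expectation method when `e` is not supplied.
#' @param scale `"pair"` (raw) or `"individual"` (duplication-calibrated).
#' @return A `distortion_result` with `statistic`, `df`, `p_value`.
#' @export
chisq_distortion <- function(o, e = NULL, method = c("marginal", "design"),
                             scale = c("pair", "individual")) {
  scale <- match.arg(scale)
  if (is.null(e)) e <- expected_pairs(o, method)
  method <- attr(e, "method")
  if (is.null(method)) method <- "marginal"
  if (any(e == 0 & o > 0)) stop("expected count 0 with observed count > 0")
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  if (scale == "individual") stat <- stat / .dup_factor(o)
  df <- if (method == "design") sum(keep) - 1L
  else (sum(rowSums(o) > 0) - 1L) * (sum(colSums(o) > 0) - 1L)
  df <- max(df, 1L)
  .distortion_result(stat, df, n = attr(o, "n_individuals"))
}

#' Population-wide distortion test across subpopulations
#'
#' Sums observed and expected allele-pair counts over subpopulations on the
#' union founder index set (expectations computed within each subpopulation
#' first, which absorbs population structure), then tests
#' `chi^2 = sum (So - Se)^2 / Se` over cells with `Se > 0`, with
#' `df = #cells - 1`.  With a single subpopulation this reduces to the
#' per-subpopulation test with design-style degrees of freedom.
#'
#' @param o_list list of observed count tables, one per subpopulation.
#' @param method expectation method within each subpopulation.
#' @param scale as in [chisq_distortion()].
#' @return A `distortion_result`.
#' @export
chisq_whole_population <- function(o_list, method = c("marginal", "design"),
                                   scale = c("pair", "individual")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  if (!length(o_list)) stop("empty subpopulation list")
  f1 <- sort(unique(unlist(lapply(o_list, rownames))))
  f2 <- sort(unique(unlist(lapply(o_list, colnames))))
  O <- matrix(0, length(f1), length(f2), dimnames = list(f1, f2))
  E <- O
  n_tot <- 0L
  for (o in o_list) {
    if (sum(o) == 0) next
    e <- expected_pairs(o, method)
    O[rownames(o), colnames(o)] <- O[rownames(o), colnames(o)] + o
    E[rownames(o), colnames(o)] <- E[rownames(o), colnames(o)] + e
    n_tot <- n_tot + (attr(o, "n_individuals") %||% (sum(o) / 2))
  }
  keep <- E > 0
  if (!any(keep)) stop("all expected counts zero")
  stat <- sum((O[keep] - E[keep])^2 / E[keep])
  if (scale == "individual") {
    nd <- sum(vapply(o_list, function(o) attr(o, "n_duplicated") %||% NA_integer_,
                     numeric(1)))
    stat <- stat / (if (is.na(nd) || n_tot == 0) 2 else 1 + nd / n_tot)
  }
  .distortion_result(stat, max(sum(keep) - 1L, 1L), pop = "whole", n = n_tot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# duplication factor 1 + q of an allele-pair table; 2 when unknown
.dup_factor <- function(o) {
  nd <- attr(o, "n_duplicated"); ni <- attr(o, "n_individuals")
  if (is.null(nd) || is.null(ni) || ni == 0) 2 else 1 + nd / ni
}

#' Screen gene pairs for segregation distortion across populations
#'
#' Runs the per-subpopulation test for every gene pair in every
#' subpopulation, in the supplied merged subpopulation groups (same-founder
#' subpopulations pooled by summing their count tables), and population-wide
#' across all subpopulations.  Benjamini-Hochberg FDR correction is applied
#' within each population's scan family; a pair is retained when any of its
#' q-values falls below `alpha`.
#'
#' @param block_sets named list (one element per subpopulation) of lists of
#'   `haplotype_blocks`, one per individual (HMM calls or simulator truth).
#' @param pairs list of [gene_pair_locus()] anchors.
#' @param merges optional named list of character vectors naming
#'   subpopulations to pool (e.g. `list(AB_EF = c("ABBA", "EFFE"))`).
#' @param alpha FDR threshold for retention.
#' @param method expectation method, see [expected_pairs()].
#' @param scale statistic calibration, see [chisq_distortion()]; the
#'   calibrated `"individual"` scale is the scan default.
#' @return A `distortion_scan` data frame with one row per (pair,
#'   population): `family_id`, `population`, `statistic`, `df`, `p`, `q`,
#'   `n_individuals`, plus a `retained` attribute-free logical column and an
#'   `excluded` attribute logging pairs that could not be genotyped.
#' @export
screen_gene_pairs <- function(block_sets, pairs, merges = NULL, alpha = 0.05,
                              method = c("marginal", "design"),
                              scale = c("individual", "pair")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (inherits(pairs, "gene_pair_locus")) pairs <- list(pairs)
  pops <- names(block_sets)
  excluded <- character(0)

  # observed tables: [[pair]][[pop]]
  tabs <- lapply(pairs, function(pr) {
    per_pop <- lapply(block_sets, function(blk_list) {
      gt1 <- t(vapply(blk_list, genotype_at_locus, character(2),
                      chrom = pr$chrom1, midpoint_bp = pr$mid1))
      gt2 <- t(vapply(blk_list, genotype_at_locus, character(2),
                      chrom = pr$chrom2, midpoint_bp = pr$mid2))
      if (all(is.na(gt1)) || all(is.na(gt2))) return(NULL)
      count_allele_pairs(gt1, gt2)
    })
    per_pop
  })

  rows <- list()
  for (k in seq_along(pairs)) {
    fam <- pairs[[k]]$family_id
    per_pop <- tabs[[k]]
    if (all(vapply(per_pop, is.null, logical(1)))) {
      excluded <- c(excluded, paste0(fam, ": no genotypable individuals at both loci"))
      next
    }
    for (p in pops) {
      o <- per_pop[[p]]
      if (is.null(o)) next
      r <- chisq_distortion(o, method = method, scale = scale)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam, population = p, statistic = r$statistic, df = r$df,
        p = r$p_value, n_individuals = attr(o, "n_individuals"))
    }
    if (!is.null(merges)) for (mn in names(merges)) {
      sub <- per_pop[merges[[mn]]]
      sub <- sub[!vapply(sub, is.null, logical(1))]
      if (!length(sub)) next
      f1 <- sort(unique(unlist(lapply(sub, rownames))))
      f2 <- sort(unique(unlist(lapply(sub, colnames))))
      O <- matrix(0L, length(f1), length(f2), dimnames = list(f1, f2))
      ni <- 0L; nd <- 0L
      for (o in sub) {
        O[rownames(o), colnames(o)] <- O[rownames(o), colnames(o)] + o
        ni <- ni + attr(o, "n_individuals")
        nd <- nd + (attr(o, "n_duplicated") %||% attr(o, "n_individuals"))
      }
      attr(O, "n_individuals") <- ni
      attr(O, "n_duplicated") <- nd
      class(O) <- c("allele_pair_table", "matrix")
      r <- chisq_distortion(O, method = method, scale = scale)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam, population = mn, statistic = r$statistic, df = r$df,
        p = r$p_value, n_individuals = ni)
    }
    if (length(pops) > 1L) {
      sub <- per_pop[!vapply(per_pop, is.null, logical(1))]
      r <- chisq_whole_population(sub, method = method, scale = scale)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam, population = "whole", statistic = r$statistic,
        df = r$df, p = r$p_value, n_individuals = r$n_individuals)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(family_id = character(0),
                                      population = character(0),
                                      statistic = numeric(0), df = integer(0),
                                      p = numeric(0), n_individuals = integer(0))
  res$q <- NA_real_
  for (p in unique(res$population)) {
    sel <- res$population == p
    res$q[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  ret <- tapply(res$q < alpha, res$family_id, any)
  res$retained <- as.logical(ret[res$family_id])
  attr(res, "alpha") <- alpha
  attr(res, "excluded") <- excluded
  class(res) <- c("distortion_scan", "data.frame")
  res
}

#' @export
print.distortion_scan <- function(x, ...) {
  nfam <- length(unique(x$family_id))
  nret <- length(unique(x$family_id[x$retained]))
  cat("Distortion scan:", nfam, "gene pairs x",
      length(unique(x$population)), "populations;",
      nret, "pairs retained at FDR <", attr(x, "alpha"), "\n")
  exc <- attr(x, "excluded")
  if (length(exc)) cat("Excluded:", paste(exc, collapse = "; "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Confirm loss-of-function potential in the founders
#'
#' Second filtering step: a distorted pair is kept as a candidate
#' incompatibility only if some founder is nonfunctional (lof, silenced or
#' absent) at copy 1 and some founder (possibly a different one) is
#' nonfunctional at copy 2, so that a cross could produce a genotype with
#' zero functional copies.
#'
#' @param screened a `distortion_scan` result (or a character vector of
#'   family ids).
#' @param specs named list of [dup_gene_spec()] objects keyed by family id.
#' @return For a scan input: the scan with extra logical columns
#'   `lof_confirmed` and `candidate` (`retained & lof_confirmed`).  For a
#'   character input: a named logical vector.
#' @export
confirm_lof_in_founders <- function(screened, specs) {
  check1 <- function(fam) {
    sp <- specs[[fam]]
    if (is.null(sp)) return(FALSE)
    st <- sp$founder_states
    nonf <- st %in% c("lof", "silenced", "absent")
    dim(nonf) <- dim(st)
    any(nonf[, 1]) && any(nonf[, 2])
  }
  if (is.character(screened))
    return(stats::setNames(vapply(screened, check1, logical(1)), screened))
  screened$lof_confirmed <- vapply(screened$family_id, check1, logical(1))
  screened$candidate <- screened$retained & screened$lof_confirmed
  screened
}
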