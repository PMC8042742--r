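# Promoter/gene-body methylation profiles and two-group Ward clustering.

#' Windowed cytosine methylation profile of one accession over one gene
#'
#' Computes, in 100-bp non-overlapping windows running in transcription
#' direction from `upstream` bp before the TSS to `downstream` bp after the
#' TES, the percentage of methylated cytosines per sequence context
#' (`100 * sum(methylated) / sum(total)` over the cytosines covered in the
#' window).  Windows without covered cytosines are `NA` and are imputed
#' before clustering.
#'
#' @param report data frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `context` (`CG`, `CHG`, `CHH`), `count_methylated`, `count_total` for
#'   one accession.
#' @param model a [gene_model()] (needs `tss` and `tes`).
#' @param upstream,downstream bp extension beyond TSS / TES (defaults 500 /
#'   300).
#' @param window window size in bp (default 100).
#' @return Numeric matrix windows x contexts (percent, `NA` where
#'   uncovered), with window 1 anchored at TSS - `upstream` in transcription
#'   direction.
#' @export
profile_methylation <- function(report, model, upstream = 500,
                                downstream = 300, window = 100) {
  if (is.null(model$tss) || is.null(model$tes)) stop("model without TSS/TES")
  gene_len <- abs(model$tes - model$tss) + 1L
  n_win <- ceiling((upstream + gene_len + downstream) / window)
  contexts <- c("CG", "CHG", "CHH")
  out <- matrix(NA_real_, n_win, 3, dimnames =
                  list(paste0("w", seq_len(n_win)), contexts))
  r <- report[report$chrom == model$chrom, , drop = FALSE]
  if (!nrow(r)) return(out)
  rel <- if (model$tss <= model$tes) r$pos - model$tss else model$tss - r$pos
  keep <- rel >= -upstream & rel <= gene_len - 1L + downstream
  r <- r[keep, , drop = FALSE]; rel <- rel[keep]
  if (!nrow(r)) return(out)
  win <- (rel + upstream) %/% window + 1L
  for (ctx in contexts) {
    sel <- r$context == ctx
    if (!any(sel)) next
    mm <- tapply(r$count_methylated[sel], win[sel], sum)
    tt <- tapply(r$count_total[sel], win[sel], sum)
    w <- as.integer(names(tt))
    pos <- tt > 0
    out[w[pos], ctx] <- 100 * mm[pos] / tt[pos]
  }
  out
}

#' Stack per-accession methylation profiles into a feature matrix
#'
#' @param profile_list named list of [profile_methylation()] matrices (same
#'   window grid).
#' @return accessions x features matrix with columns named
#'   `<context>.w<window>`.
#' @export
stack_methylation_profiles <- function(profile_list) {
  feats <- t(vapply(profile_list, function(p) {
    v <- as.vector(p)
    names(v) <- paste0(rep(colnames(p), each = nrow(p)), ".w",
                       rep(seq_len(nrow(p)), ncol(p)))
    v
  }, numeric(nrow(profile_list[[1]]) * ncol(profile_list[[1]]))))
  rownames(feats) <- names(profile_list)
  feats
}

# accession-wise per-context mean imputation of missing windows
.impute_profiles <- function(x) {
  ctx <- sub("\\..*$", "", colnames(x))
  for (i in seq_len(nrow(x))) {
    for (cc in unique(ctx)) {
      sel <- ctx == cc
      v <- x[i, sel]
      if (anyNA(v)) {
        m <- mean(v, na.rm = TRUE)
        if (is.nan(m)) m <- 0
        v[is.na(v)] <- m
        x[i, sel] <- v
      }
    }
  }
  x
}

#' Two-group Ward clustering of methylation profiles
#'
#' Euclidean distances over the concatenated window x context percent
#' vectors, Ward-linkage agglomeration (`hclust` method `ward.D2`), tree cut
#' into two groups.  The group with the higher mean promoter-region CG
#' methylation (windows from TSS - `upstream` to the TSS) is labelled
#' `hypermethylated`.  Accessions from different processing cohorts are
#' clustered separately when `cohort` is given.
#'
#' @param profiles accessions x features matrix as from
#'   [stack_methylation_profiles()] (columns `<context>.w<i>`); missing
#'   windows are imputed with the accession-wise context mean.
#' @param cohort optional factor splitting accessions into independently
#'   clustered cohorts.
#' @param promoter_windows indices of the promoter windows used for
#'   labelling (default: the windows covering the upstream region, assuming
#'   the default 500/100 grid, i.e. windows 1-5).
#' @return Factor of labels (`hypermethylated` / `unmethylated`) named by
#'   accession, with the `hclust` tree(s) in attribute `trees`.
#' @export
cluster_methylation_profiles <- function(profiles, cohort = NULL,
                                         promoter_windows = 1:5) {
  if (nrow(profiles) < 2) stop("need at least two accessions")
  if (is.null(cohort)) cohort <- factor(rep("all", nrow(profiles)))
  cohort <- as.factor(cohort)
  labels <- character(nrow(profiles))
  trees <- list()
  ctx <- sub("\\..*$", "", colnames(profiles))
  wins <- as.integer(sub("^.*\\.w", "", colnames(profiles)))
  prom_cg <- which(ctx == "CG" & wins %in% promoter_windows)
  for (ch in levels(cohort)) {
    sel <- which(cohort == ch)
    x <- .impute_profiles(profiles[sel, , drop = FALSE])
    if (nrow(x) < 2 || max(stats::dist(x)) == 0) {
      if (nrow(x) >= 2 && max(stats::dist(x)) == 0)
        warning("all profiles identical in cohort ", ch,
                "; single group labelled unmethylated")
      labels[sel] <- "unmethylated"
      next
    }
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    grp <- stats::cutree(hc, k = 2)
    m1 <- mean(x[grp == 1, prom_cg, drop = FALSE])
    m2 <- mean(x[grp == 2, prom_cg, drop = FALSE])
    hyper <- if (m1 >= m2) 1L else 2L
    labels[sel] <- ifelse(grp == hyper, "hypermethylated", "unmethylated")
    trees[[ch]] <- hc
  }
  res <- factor(labels, levels = c("hypermethylated", "unmethylated"))
  names(res) <- rownames(profiles)
  attr(res, "trees") <- trees
  res
}
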