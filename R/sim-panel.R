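# Synthetic accession panels with the variant / methylation / RNA / coverage
# structure the functional-allele calling and GWA stages consume.

#' Configuration of a synthetic accession panel
#'
#' @param n_accessions panel size.
#' @param n_groups number of discrete subpopulations (relatedness blocks).
#' @param fst drift parameter of the between-group allele-frequency
#'   divergence (Balding-Nichols style beta model).
#' @param n_markers number of biallelic markers for the kinship/GWA panel.
#' @param copy_freqs named list, one element per gene copy, each a named
#'   numeric of haplotype frequencies over `lof`, `silenced`, `absent`
#'   (the remainder is `functional`); per copy the sum must be <= 1.
#' @param modifier_freq background frequency of the rescuing extra-copy
#'   modifier among accessions that do not need it.
#' @param modifier_markers indices of the marker window tagging the modifier
#'   locus (default: 10 markers in the middle of the panel).
#' @param meth_means mean methylated fraction of the hypermethylated and
#'   unmethylated promoter classes, `c(hyper = 0.8, unmeth = 0.05)`.
#' @param meth_conc concentration of the Beta distributions around those
#'   means (larger = smaller dispersion).
#' @param dna_error,rna_error flip probabilities of the DNA / RNA
#'   variant-evidence flags.
#' @param depth_mean genome-wide mean sequencing depth.
#' @param region_len length (bp) of the coverage regions.
#' @return Object of class `accession_panel_config`.
#' @export
accession_panel_config <- function(n_accessions = 300, n_groups = 3,
                                   fst = 0.1, n_markers = 5000,
                                   copy_freqs = list(
                                     copy1 = c(lof = 0.3, silenced = 0.1, absent = 0.05),
                                     copy2 = c(lof = 0.1, silenced = 0.2, absent = 0.0)),
                                   modifier_freq = 0.05,
                                   modifier_markers = NULL,
                                   meth_means = c(hyper = 0.8, unmeth = 0.05),
                                   meth_conc = 100,
                                   dna_error = 0.01, rna_error = 0.01,
                                   depth_mean = 30, region_len = 500) {
  for (cf in copy_freqs) {
    if (any(cf < 0) || sum(cf) > 1)
      stop("copy haplotype frequencies must be non-negative and sum to <= 1")
    if (!all(names(cf) %in% c("lof", "silenced", "absent")))
      stop("copy_freqs names must be among lof, silenced, absent")
  }
  if (is.null(modifier_markers))
    modifier_markers <- seq(floor(n_markers / 2) - 4L, floor(n_markers / 2) + 5L)
  stopifnot(depth_mean > 0, n_accessions > 1, n_markers > 10)
  structure(as.list(environment()), class = "accession_panel_config")
}

# inbred (homozygous) dosages with discrete-subpopulation structure
.sim_structured_dosage <- function(n, m, groups, fst) {
  p0 <- stats::runif(m, 0.05, 0.95)
  G <- matrix(0L, n, m)
  shp <- (1 - fst) / fst
  for (g in seq_len(max(groups))) {
    rows <- which(groups == g)
    pg <- stats::rbeta(m, p0 * shp, (1 - p0) * shp)
    G[rows, ] <- matrix(2L * stats::rbinom(length(rows) * m, 1L, rep(pg, each = length(rows))),
                        length(rows), m)
  }
  dimnames(G) <- list(paste0("acc", seq_len(n)), paste0("m", seq_len(m)))
  G
}

#' Simulate a synthetic accession panel
#'
#' Generates, per accession: a haplotype class per gene copy (functional /
#' lof / silenced / absent) drawn from the configured frequencies; a
#' structured marker matrix for kinship and GWA; methylation reports with a
#' bimodal promoter class structure (silenced copies hypermethylated);
#' DNA/RNA variant-evidence flags for the lof haplotypes (silenced copies
#' give no RNA evidence); and coverage tracks whose normalized ratio scales
#' with the carried copy number.  Accessions whose copies are all
#' nonfunctional are made modifier carriers (they would not be viable
#' otherwise), and the modifier is tagged by a fixed marker window so that
#' a GWA on the phenotype recovers the locus; other accessions carry the
#' modifier at the background frequency.
#'
#' @param config an [accession_panel_config()].
#' @param gene a [dup_gene_spec()] with two copies used to shape the
#'   methylation window grid (optional; a default 1.2-kb two-copy model is
#'   used when `NULL`).
#' @param components character subset of
#'   `c("markers", "methylation", "rna", "coverage")` to generate (truth
#'   labels are always produced); trimming components makes large replicate
#'   studies cheap.
#' @param seed optional integer seed.
#' @return Object of class `accession_panel`: list with `truth` (data frame
#'   of copy states, modifier carriage, group, functional-copy count),
#'   `dosage`, `marker_info`, `methylation` (per-accession-copy report list),
#'   `gene_models`, `rna_evidence`, `coverage` (per accession: family track,
#'   modifier track), and `config`.
#' @export
simulate_accession_panel <- function(config, gene = NULL,
                                     components = c("markers", "methylation",
                                                    "rna", "coverage"),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_accessions
  acc <- paste0("acc", seq_len(n))
  groups <- rep(seq_len(config$n_groups), length.out = n)
  copies <- names(config$copy_freqs)

  states <- matrix("functional", n, length(copies), dimnames = list(acc, copies))
  for (j in seq_along(copies)) {
    cf <- config$copy_freqs[[j]]
    pr <- c(cf, functional = 1 - sum(cf))
    states[, j] <- sample(names(pr), n, TRUE, prob = pr)
  }
  n_functional <- rowSums(states == "functional")
  needs_modifier <- n_functional == 0
  modifier <- needs_modifier | stats::runif(n) < config$modifier_freq

  truth <- data.frame(accession = acc, group = groups,
                      stringsAsFactors = FALSE)
  for (j in seq_along(copies)) truth[[paste0("state_", copies[j])]] <- states[, j]
  truth$modifier_carrier <- modifier
  truth$n_functional_ref <- n_functional
  truth$phenotype <- as.integer(n_functional > 0)

  out <- list(truth = truth, config = config)

  if ("markers" %in% components) {
    G <- .sim_structured_dosage(n, config$n_markers, groups, config$fst)
    G[modifier, config$modifier_markers] <- 2L
    out$dosage <- G
    out$marker_info <- data.frame(chrom = "Chr1",
                                  pos = seq_len(config$n_markers) * 1000L,
                                  marker = colnames(G))
  }

  if (is.null(gene)) {
    gene <- dup_gene_spec("FAM1",
      data.frame(copy_id = copies[1:2], chrom = c("Chr1", "Chr3"),
                 start_bp = c(1e6, 2e6), end_bp = c(1e6 + 1199, 2e6 + 1199),
                 strand = "+", tss_bp = c(1e6, 2e6),
                 tes_bp = c(1e6 + 1199, 2e6 + 1199)),
      matrix("functional", 1, 2, dimnames = list("ref", copies[1:2])))
  }
  out$gene <- gene

  if ("methylation" %in% components) {
    out$methylation <- list()
    gm <- list()
    for (j in 1:2) {
      cp <- gene$copies[j, ]
      gm[[copies[j]]] <- gene_model(cp$copy_id, cp$chrom, cp$strand %||% "+",
                                    tss = cp$tss_bp %||% cp$start_bp,
                                    tes = cp$tes_bp %||% cp$end_bp,
                                    cds = data.frame(start = cp$start_bp + 100,
                                                     end = cp$start_bp + 999))
    }
    out$gene_models <- gm
    mm <- config$meth_means
    for (j in 1:2) {
      model <- gm[[j]]
      gene_len <- abs(model$tes - model$tss) + 1L
      n_win <- ceiling((500 + gene_len + 300) / 100)
      reports <- vector("list", n)
      for (i in seq_len(n)) {
        hyper <- states[i, j] == "silenced"
        mu <- if (hyper) mm[["hyper"]] else mm[["unmeth"]]
        frac <- stats::rbeta(n_win, mu * config$meth_conc,
                             (1 - mu) * config$meth_conc)
        rows <- lapply(seq_len(n_win), function(wk) {
          pos0 <- model$tss - 500 + (wk - 1L) * 100L
          ctx <- rep(c("CG", "CHG", "CHH"), each = 3)
          tot <- 1L + stats::rpois(9, 3)
          data.frame(chrom = model$chrom,
                     pos = pos0 + rep(c(10L, 40L, 70L), 3) + rep(0:2, 3),
                     strand = "+", context = ctx,
                     count_methylated = stats::rbinom(9, tot, frac[wk]),
                     count_total = tot, stringsAsFactors = FALSE)
        })
        reports[[i]] <- do.call(rbind, rows)
      }
      names(reports) <- acc
      out$methylation[[copies[j]]] <- reports
    }
  }

  if ("rna" %in% components) {
    ev <- list()
    for (j in 1:2) {
      has_lof <- states[, j] == "lof"
      silenced <- states[, j] == "silenced"
      dna <- has_lof
      flip <- stats::runif(n) < config$dna_error
      dna[flip] <- !dna[flip]
      rna <- has_lof & !silenced
      flip <- stats::runif(n) < config$rna_error
      rna[flip] <- !rna[flip]
      ev[[copies[j]]] <- data.frame(accession = acc, copy = copies[j],
                                    dna_present = dna, rna_present = rna,
                                    stringsAsFactors = FALSE)
    }
    out$rna_evidence <- do.call(rbind, ev)
    rownames(out$rna_evidence) <- NULL
  }

  if ("coverage" %in% components) {
    L <- config$region_len
    dm <- config$depth_mean
    fam_tracks <- vector("list", n)
    mod_tracks <- vector("list", n)
    for (i in seq_len(n)) {
      # reads from every carried family copy collapse onto a single-copy
      # reference region, so depth scales with the total copy count
      n_copies <- sum(states[i, ] != "absent") + as.integer(modifier[i])
      fam_tracks[[i]] <- coverage_track("Chr1", 0L, L,
        stats::rpois(L, dm * n_copies), genome_mean = dm)
      mod_depth <- if (modifier[i]) dm else 0.2
      mod_tracks[[i]] <- coverage_track("Chr4_alt", 0L, L,
        stats::rpois(L, mod_depth), genome_mean = dm)
    }
    names(fam_tracks) <- names(mod_tracks) <- acc
    out$coverage <- list(family = fam_tracks, modifier = mod_tracks)
  }

  class(out) <- "accession_panel"
  out
}

#' @export
print.accession_panel <- function(x, ...) {
  cat("Accession panel:", nrow(x$truth), "accessions,",
      x$config$n_groups, "groups\n")
  cols <- grep("^state_", names(x$truth), value = TRUE)
  for (cc in cols) {
    cat(" ", sub("state_", "", cc), ":")
    print(table(x$truth[[cc]]))
  }
  cat("  modifier carriers:", sum(x$truth$modifier_carrier), "\n")
  invisible(x)
}
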