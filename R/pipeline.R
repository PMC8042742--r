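# End-to-end pipeline driver chaining all stages on simulated data.

#' Demo pipeline configuration
#'
#' A small but complete run: two same-founder F6 subpopulations with one
#' planted fully penetrant incompatibility plus neutral control pairs,
#' HMM genotyping, the distortion screen, an accession panel with
#' functional-allele calling, kinship-corrected GWA and copy-number calls.
#'
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory for stage artifacts.
#' @return A `run_config` list.
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("dupincompat_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "genotype", "distort", "callfunc", "gwas", "cnv"),
    ril = list(n_per_subpop = 40, selfing_generations = 6,
               markers_per_chrom = 60, error_rate = 0.005, missing_rate = 0.10,
               founders = c("Col", "Cvi", "Kyo", "Sha")),
    distort = list(alpha = 0.05, method = "marginal", scale = "individual"),
    panel = list(n_accessions = 120, n_markers = 800, n_groups = 3, fst = 0.1),
    gwas = list(alpha = 0.05, maf_min = 0.05, miss_max = 0.1),
    cnv = list(min_depth = 5, baseline = 1),
    phenotype_mode = "any_copy"
  )
}

.planted_family <- function(founders, map) {
  # reciprocal pseudofunctionalization: founder 2 lacks copy 1 but carries the
  # only functional copy 2; everyone else functional at copy 1, lof at copy 2
  st <- matrix("functional", 4, 2, dimnames = list(founders, c("copy1", "copy2")))
  st[founders[2], "copy1"] <- "absent"
  st[, "copy2"] <- "lof"
  st[founders[2], "copy2"] <- "functional"
  dup_gene_spec("FAM_inc",
                data.frame(copy_id = c("copy1", "copy2"),
                           chrom = c("Chr2", "Chr4"),
                           start_bp = c(8e6, 9e6), end_bp = c(8.004e6, 9.004e6)),
                st, essential = TRUE, penetrance = 1)
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate -> genotype -> distort -> callfunc -> gwas -> cnv (any
#' stage can be dropped from `config$stages`; later stages re-simulate what
#' they need).  Every artifact is written under `config$out_dir` and listed
#' in the returned manifest with its MD5 checksum, alongside the seed and
#' stage parameters, so that identical seed and config give identical
#' checksums.
#'
#' @param config a [demo_config()]-style list.
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config = demo_config()) {
  for (field in c("seed", "out_dir", "stages", "phenotype_mode"))
    if (is.null(config[[field]])) stop("config missing field: ", field)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  artifacts <- list()
  add <- function(name, path) artifacts[[name]] <<- path
  stage <- "init"
  res <- try({
    map <- default_genome_map(config$ril$markers_per_chrom)
    founders <- config$ril$founders
    fam <- .planted_family(founders, map)

    pops <- NULL
    if ("simulate" %in% config$stages) {
      stage <- "simulate"
      d1 <- cross_design("P1", founders, config$ril$selfing_generations,
                         config$ril$n_per_subpop)
      d2 <- cross_design("P2", founders[c(1, 3, 2, 4)],
                         config$ril$selfing_generations, config$ril$n_per_subpop)
      pops <- list(
        P1 = simulate_subpopulation(d1, list(fam), map,
                                    error_rate = config$ril$error_rate,
                                    missing_rate = config$ril$missing_rate),
        P2 = simulate_subpopulation(d2, list(fam), map,
                                    error_rate = config$ril$error_rate,
                                    missing_rate = config$ril$missing_rate))
      for (p in names(pops)) {
        f <- file.path(config$out_dir, paste0("markers_", p, ".tsv"))
        write_marker_matrix(pops[[p]]$genotypes, f)
        add(paste0("markers_", p), f)
        tb <- lapply(seq_along(pops[[p]]$individuals),
                     function(i) truth_blocks(pops[[p]], i))
        f <- file.path(config$out_dir, paste0("truth_blocks_", p, ".bed"))
        write_blocks_bed(tb, f)
        add(paste0("truth_blocks_", p), f)
      }
    }

    blocks <- NULL
    if ("genotype" %in% config$stages) {
      stage <- "genotype"
      if (is.null(pops)) stop("genotype stage requires the simulate stage")
      blocks <- lapply(pops, genotype_population)
      for (p in names(blocks)) {
        f <- file.path(config$out_dir, paste0("hmm_blocks_", p, ".bed"))
        write_blocks_bed(blocks[[p]], f)
        add(paste0("hmm_blocks_", p), f)
      }
    }

    if ("distort" %in% config$stages) {
      stage <- "distort"
      if (is.null(blocks)) {
        if (is.null(pops)) stop("distort stage requires the simulate stage")
        blocks <- lapply(pops, function(pp)
          lapply(seq_along(pp$individuals), function(i) truth_blocks(pp, i)))
      }
      pairs <- list(
        gene_pair_locus("FAM_inc", "Chr2", 8.002e6, "Chr4", 9.002e6),
        gene_pair_locus("FAM_neutral1", "Chr1", 12e6, "Chr5", 14e6),
        gene_pair_locus("FAM_neutral2", "Chr3", 6e6, "Chr5", 20e6))
      scan <- screen_gene_pairs(blocks, pairs,
                                merges = list(P1P2 = c("P1", "P2")),
                                alpha = config$distort$alpha,
                                method = config$distort$method,
                                scale = config$distort$scale)
      specs <- list(FAM_inc = fam)
      scan <- confirm_lof_in_founders(scan, specs)
      f <- file.path(config$out_dir, "distortion_scan.tsv")
      write_distortion_tsv(scan, f)
      add("distortion_scan", f)
    }

    panel <- NULL
    phen <- NULL
    if (any(c("callfunc", "gwas", "cnv") %in% config$stages)) {
      stage <- "panel"
      pc <- accession_panel_config(n_accessions = config$panel$n_accessions,
                                   n_markers = config$panel$n_markers,
                                   n_groups = config$panel$n_groups,
                                   fst = config$panel$fst)
      panel <- simulate_accession_panel(pc)
    }

    if ("callfunc" %in% config$stages) {
      stage <- "callfunc"
      copies <- names(panel$config$copy_freqs)
      meth_labels <- lapply(copies, function(cp) {
        prof <- stack_methylation_profiles(lapply(panel$methylation[[cp]],
          profile_methylation, model = panel$gene_models[[cp]]))
        cluster_methylation_profiles(prof)
      })
      names(meth_labels) <- copies
      meth <- do.call(rbind, lapply(copies, function(cp)
        data.frame(accession = names(meth_labels[[cp]]), copy = cp,
                   label = as.character(meth_labels[[cp]]))))
      lof <- do.call(rbind, lapply(copies, function(cp) {
        ev <- panel$rna_evidence[panel$rna_evidence$copy == cp, ]
        data.frame(accession = ev$accession[ev$dna_present], copy = cp,
                   effect = "stop_gained")
      }))
      cov <- do.call(rbind, lapply(copies, function(cp)
        data.frame(accession = panel$truth$accession, copy = cp,
                   present = panel$truth[[paste0("state_", cp)]] != "absent")))
      fm <- build_functional_matrix(panel$truth$accession, copies,
                                    lof = lof, methylation = meth, coverage = cov)
      phen <- phenotype_from_matrix(fm, config$phenotype_mode)
      f <- file.path(config$out_dir, "copy_function_matrix.tsv")
      utils::write.table(data.frame(accession = rownames(fm), unclass(fm)[, ]),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      add("copy_function_matrix", f)
      f <- file.path(config$out_dir, "phenotype.tsv")
      utils::write.table(data.frame(accession = names(phen), phenotype = phen),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      add("phenotype", f)
    }

    if ("gwas" %in% config$stages) {
      stage <- "gwas"
      if (is.null(phen)) phen <- panel$truth$phenotype
      mp <- filter_and_impute(panel$dosage, config$gwas$maf_min,
                              config$gwas$miss_max, info = panel$marker_info)
      K <- compute_kinship(mp)
      scan <- association_scan(mp, phen, K, alpha = config$gwas$alpha)
      f <- file.path(config$out_dir, "gwas_scan.tsv")
      write_gwas_tsv(scan, f)
      add("gwas_scan", f)
    }

    if ("cnv" %in% config$stages) {
      stage <- "cnv"
      cn <- do.call(rbind, lapply(panel$truth$accession, function(a) {
        fam_tr <- panel$coverage$family[[a]]
        mod_tr <- panel$coverage$modifier[[a]]
        ratio <- normalized_coverage(fam_tr)
        data.frame(accession = a, ratio = ratio,
                   copies = estimate_copies(ratio, config$cnv$baseline),
                   modifier_carrier = call_presence(mod_tr, config$cnv$min_depth))
      }))
      f <- file.path(config$out_dir, "copy_number.tsv")
      utils::write.table(cn, f, sep = "\t", quote = FALSE, row.names = FALSE)
      add("copy_number", f)
    }
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("seed", "out_dir", "stages"))],
    artifacts = lapply(artifacts, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
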