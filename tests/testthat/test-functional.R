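# Effect classification, methylation clustering, pseudohet assignment and
# the functional-state matrix.

test_that("effect classifier handles the canonical variant classes", {
  m <- random_gene_model(seed = 40, n_exons = 2)
  intron <- c(m$cds$end[1] + 10L, m$cds$start[2] - 10L)
  # SNV in the intron body: none
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = intron[1], ref = "A", alt = "G"), m), "none")
  # variant outside the gene span: none, not an error
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = m$tes + 5000L, ref = "A", alt = "G"), m), "none")
  # start / stop codon hits
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = m$cds$start[1], ref = "A", alt = "C"), m), "start_lost")
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = m$cds$end[2], ref = "A", alt = "C"), m), "stop_lost")
  # splice donor (first 2 bp of the intron)
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = m$cds$end[1] + 1L, ref = "G", alt = "A"), m),
    "splice_damage")
  # splice acceptor (last 2 bp of the intron)
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = m$cds$start[2] - 2L, ref = "A", alt = "C"), m),
    "splice_damage")
  # 1-bp insertion mid-CDS: frameshift
  mid <- m$cds$start[1] + 7L
  ref1 <- substr(m$seq, mid - m$seq_start + 1L, mid - m$seq_start + 1L)
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = mid, ref = ref1, alt = paste0(ref1, "T")), m),
    "frameshift")
  # deletion of a whole CDS segment: cds_loss
  a <- m$cds$start[2] - 5L; b <- m$cds$end[2] + 3L
  refdel <- substr(m$seq, a - m$seq_start + 1L, b - m$seq_start + 1L)
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = a, ref = refdel, alt = substr(refdel, 1, 1)), m),
    "cds_loss")
})

test_that("SNV stop-gain calls agree with the codon-walk oracle", {
  set.seed(41)
  n_checked <- 0
  for (rep in 1:25) {
    m <- random_gene_model(n_exons = sample(2:3, 1))
    # random SNVs strictly inside the CDS, away from first/last codon
    for (v in 1:40) {
      k <- sample(nrow(m$cds), 1)
      pos <- sample((m$cds$start[k]):(m$cds$end[k]), 1)
      ci_first <- m$cds$start[1] + 2L
      ci_last <- m$cds$end[nrow(m$cds)] - 2L
      if (pos <= ci_first || pos >= ci_last) next
      ref <- substr(m$seq, pos - m$seq_start + 1L, pos - m$seq_start + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classify_variant_effect(list(chrom = "Chr1", pos = pos,
                                          ref = ref, alt = alt), m)
      want <- codon_walk_snv_oracle(m, pos, alt)
      expect_equal(got, want,
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 500)
})

test_that("indels in the CDS are frameshift iff length change is not 3k", {
  set.seed(42)
  m <- random_gene_model(n_exons = 2)
  for (len in c(1L, 2L, 4L)) {
    pos <- m$cds$start[1] + 9L
    ref <- substr(m$seq, pos - m$seq_start + 1L, pos - m$seq_start + 1L + len)
    expect_equal(classify_variant_effect(
      list(chrom = "Chr1", pos = pos, ref = ref, alt = substr(ref, 1, 1)), m),
      "frameshift")
  }
  # in-frame 3-bp deletion mid-exon: not a frameshift
  pos <- m$cds$start[1] + 9L
  ref <- substr(m$seq, pos - m$seq_start + 1L, pos - m$seq_start + 4L)
  expect_equal(classify_variant_effect(
    list(chrom = "Chr1", pos = pos, ref = ref, alt = substr(ref, 1, 1)), m),
    "none")
})

test_that("methylation windows compute percentages and flag empty windows", {
  model <- gene_model("g", "Chr1", "+", tss = 1001, tes = 1200,
                      cds = data.frame(start = 1021, end = 1180))
  # all methylated in window 1 (starts at tss-500 = 501)
  rep1 <- data.frame(chrom = "Chr1", pos = c(510, 550, 590), strand = "+",
                     context = "CG", count_methylated = c(3, 2, 4),
                     count_total = c(3, 2, 4))
  p <- profile_methylation(rep1, model)
  expect_equal(p["w1", "CG"], 100)
  expect_true(is.na(p["w2", "CG"]))             # nothing covered
  # mixed counts 3/10 -> 30.0
  rep2 <- data.frame(chrom = "Chr1", pos = 610, strand = "+", context = "CHG",
                     count_methylated = 3, count_total = 10)
  p2 <- profile_methylation(rep2, model)
  expect_equal(p2["w2", "CHG"], 30)
  # grid size: 500 + 200 + 300 = 1000 bp -> 10 windows
  expect_equal(nrow(p), 10)
  expect_error(profile_methylation(rep1, list(tss = NULL, tes = NULL)), "TSS")
})

test_that("two separated methylation classes are recovered exactly", {
  set.seed(43)
  n_win <- 10
  mk <- function(mu, n) t(replicate(n, {
    v <- pmax(pmin(rnorm(3 * n_win, mu, 5), 100), 0)
    names(v) <- paste0(rep(c("CG", "CHG", "CHH"), each = n_win), ".w", 1:n_win)
    v
  }))
  x <- rbind(mk(80, 20), mk(5, 20))
  rownames(x) <- paste0("acc", 1:40)
  truth <- rep(c("hypermethylated", "unmethylated"), each = 20)
  lab <- cluster_methylation_profiles(x)
  expect_equal(adjusted_rand_index(as.character(lab), truth), 1)
  expect_equal(as.character(lab), truth)
  # permutation invariance
  perm <- sample(40)
  lab2 <- cluster_methylation_profiles(x[perm, ])
  expect_equal(as.character(lab2), truth[perm])
})

test_that("n = 2 distinct profiles split one per group", {
  x <- rbind(acc1 = c(CG.w1 = 90, CG.w2 = 85, CHG.w1 = 80, CHG.w2 = 75),
             acc2 = c(CG.w1 = 2, CG.w2 = 4, CHG.w1 = 1, CHG.w2 = 3))
  lab <- cluster_methylation_profiles(x, promoter_windows = 1:2)
  expect_equal(as.character(lab), c("hypermethylated", "unmethylated"))
})

test_that("identical profiles give a single unmethylated group with a warning", {
  x <- matrix(10, 4, 6,
              dimnames = list(paste0("a", 1:4),
                              paste0(rep(c("CG", "CHG", "CHH"), each = 2), ".w", 1:2)))
  expect_warning(lab <- cluster_methylation_profiles(x), "identical")
  expect_true(all(lab == "unmethylated"))
})

test_that("small-n merge sequences equal the greedy Ward oracle", {
  set.seed(44)
  for (r in 1:5) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(n * 6), n, 6)
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    expect_identical(hclust_partitions(hc, n), ward_oracle_partitions(x))
  }
})

test_that("cohorts are clustered separately", {
  set.seed(45)
  n_win <- 6
  mk <- function(mu, n, shift = 0) t(replicate(n, {
    v <- pmax(pmin(rnorm(3 * n_win, mu + shift, 3), 100), 0)
    names(v) <- paste0(rep(c("CG", "CHG", "CHH"), each = n_win), ".w", 1:n_win)
    v
  }))
  # cohort B has a global +15 pipeline shift; joint clustering would split
  # on cohort, separate clustering recovers the class structure in each
  x <- rbind(mk(70, 10), mk(5, 10), mk(70, 10, 15), mk(5, 10, 15))
  rownames(x) <- paste0("acc", 1:40)
  cohort <- rep(c("A", "B"), each = 20)
  truth <- rep(rep(c("hypermethylated", "unmethylated"), each = 10), 2)
  lab <- cluster_methylation_profiles(x, cohort = cohort)
  expect_equal(as.character(lab), truth)
})

test_that("pseudoheterozygous variants are assigned by expression contrast", {
  # DNA+, RNA-, copy 2 silenced -> the silenced copy
  expect_equal(assign_pseudohet_variant(TRUE, FALSE, c(FALSE, TRUE)), 2L)
  # DNA+, RNA+, one copy silenced -> the expressed copy
  expect_equal(assign_pseudohet_variant(TRUE, TRUE, c(TRUE, FALSE)), 2L)
  # neither copy silenced: no contrast
  expect_true(is.na(assign_pseudohet_variant(TRUE, TRUE, c(FALSE, FALSE))))
  # both silenced: no contrast
  expect_true(is.na(assign_pseudohet_variant(TRUE, FALSE, c(TRUE, TRUE))))
  # absent in DNA: not a candidate at all
  expect_error(assign_pseudohet_variant(FALSE, FALSE, c(TRUE, FALSE)), "DNA")
})

test_that("functional matrix composes evidence with fixed precedence", {
  acc <- c("colType", "cviType", "silencedBoth", "clean")
  cp <- c("copy1", "copy2")
  lof <- data.frame(accession = c("colType", "silencedBoth"),
                    copy = c("copy2", "copy1"), effect = "stop_gained")
  meth <- data.frame(accession = c("silencedBoth"), copy = "copy2",
                     label = "hypermethylated")
  cov <- data.frame(accession = "cviType", copy = "copy1", present = FALSE)
  fm <- build_functional_matrix(acc, cp, lof, meth, cov)
  expect_equal(unname(fm["cviType", ]), c("absent", "functional"))
  expect_equal(unname(fm["colType", ]), c("functional", "lof"))
  expect_equal(unname(fm["silencedBoth", ]), c("lof", "silenced"))
  expect_equal(unname(fm["clean", ]), c("functional", "functional"))

  ph <- phenotype_from_matrix(fm, "any_copy")
  expect_equal(unname(ph), c(1L, 1L, 0L, 1L))
  ph_ref <- phenotype_from_matrix(fm, "reference_copy", reference_copy = "copy1")
  expect_equal(unname(ph_ref), c(1L, 0L, 0L, 1L))
  # reference silenced but paralog functional still scores 0
  fm2 <- build_functional_matrix("x", cp,
                                 methylation = data.frame(accession = "x",
                                                          copy = "copy1",
                                                          label = "hypermethylated"))
  expect_equal(unname(phenotype_from_matrix(fm2, "reference_copy",
                                            reference_copy = "copy1")), 0L)
  expect_equal(unname(phenotype_from_matrix(fm2, "any_copy")), 1L)
})

test_that("coverage-absent but RNA-expressed copies are flagged unknown", {
  cov <- data.frame(accession = "a1", copy = "copy1", present = FALSE)
  rna <- data.frame(accession = "a1", copy = "copy1", expressed = TRUE)
  fm <- build_functional_matrix("a1", c("copy1", "copy2"), coverage = cov,
                                rna_expressed = rna)
  expect_equal(unname(fm["a1", "copy1"]), "unknown")
  expect_match(attr(fm, "log"), "a1/copy1")
})

test_that("adding LoF evidence never makes a nonfunctional cell functional", {
  set.seed(46)
  acc <- paste0("a", 1:30)
  cp <- c("c1", "c2")
  meth <- data.frame(accession = sample(acc, 10), copy = sample(cp, 10, TRUE),
                     label = "hypermethylated")
  fm0 <- build_functional_matrix(acc, cp, methylation = meth)
  lof <- data.frame(accession = sample(acc, 12), copy = sample(cp, 12, TRUE),
                    effect = "frameshift")
  fm1 <- build_functional_matrix(acc, cp, lof = lof, methylation = meth)
  was_nonfunctional <- fm0 != "functional"
  expect_true(all(fm1[was_nonfunctional] != "functional"))
})
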