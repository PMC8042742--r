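# Allele-pair counting, chi-square distortion tests and the two-step screen.

toy_blocks <- function(chrom, boundaries, states) {
  # states: list of c(f1, f2) per segment
  df <- data.frame(chrom = chrom,
                   start = c(0, boundaries[-length(boundaries)]),
                   end = boundaries,
                   founder1 = vapply(states, `[`, "", 1),
                   founder2 = vapply(states, `[`, "", 2))
  class(df) <- c("haplotype_blocks", "data.frame")
  df
}

test_that("locus genotyping reads the containing block, boundary to the left", {
  blk <- rbind(toy_blocks("Chr1", c(5e5, 1e6), list(c("a", "a"), c("a", "b"))),
               toy_blocks("Chr2", 1e6, list(c("c", "c"))))
  class(blk) <- c("haplotype_blocks", "data.frame")
  expect_equal(genotype_at_locus(blk, "Chr1", 2e5), c("a", "a"))
  expect_equal(genotype_at_locus(blk, "Chr1", 7e5), c("a", "b"))
  # exactly on the internal boundary: left block wins
  expect_equal(genotype_at_locus(blk, "Chr1", 5e5), c("a", "a"))
  # outside any block -> unknown
  expect_equal(genotype_at_locus(blk, "Chr3", 1e5), c(NA_character_, NA_character_))
})

test_that("counting follows the printed convention and conserves totals", {
  f <- letters[1:4]
  o <- count_allele_pairs(matrix(c("a", "a"), 1), matrix(c("b", "b"), 1), f, f)
  expect_equal(o["a", "b"], 2L)           # "aabb" -> o_ab += 2
  expect_equal(sum(o), 2L)
  o <- count_allele_pairs(matrix(c("a", "b"), 1), matrix(c("b", "c"), 1), f, f)
  expect_equal(o["a", "b"], 1L)           # "abbc" -> o_ab += 1, o_bc += 1
  expect_equal(o["b", "c"], 1L)
  o <- count_allele_pairs(matrix(c("a", "b"), 1), matrix(c("b", "b"), 1), f, f)
  expect_equal(o["a", "b"], 1L)           # het x hom pairs with the repeat
  expect_equal(o["b", "b"], 1L)

  # conservation property over random genotypes with missingness
  set.seed(30)
  for (r in 1:20) {
    n <- sample(10:60, 1)
    gt1 <- matrix(sample(f, 2 * n, TRUE), n, 2)
    gt2 <- matrix(sample(f, 2 * n, TRUE), n, 2)
    gt1[sample(n, 2), ] <- NA
    o <- count_allele_pairs(gt1, gt2, f, f)
    expect_equal(sum(o), 2L * attr(o, "n_individuals"))
    expect_equal(attr(o, "n_individuals") + attr(o, "n_skipped"), n)
  }
})

test_that("expected tables match marginal and design constructions", {
  o <- matrix(2L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  e1 <- expected_pairs(o, "marginal")
  e2 <- expected_pairs(o, "design")
  expect_equal(unclass(e1), unclass(o), ignore_attr = TRUE)
  expect_equal(unclass(e2), unclass(o), ignore_attr = TRUE)
  o2 <- matrix(c(10, 0, 0, 10), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(unclass(expected_pairs(o2, "marginal"))),
               matrix(5, 2, 2), ignore_attr = TRUE)
  expect_equal(sum(expected_pairs(o2, "marginal")), sum(o2), tolerance = 1e-9)
  expect_error(expected_pairs(matrix(0, 2, 2)), "zero grand total")
})

test_that("marginal expectations absorb single-locus distortion, design does not", {
  # one founder over-represented at locus 1, loci independent
  set.seed(31)
  n <- 1e4
  f <- letters[1:4]
  x <- sample(f, n, TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  y <- sample(f, n, TRUE)
  gt1 <- cbind(x, x); gt2 <- cbind(y, y)   # fully inbred
  o <- count_allele_pairs(gt1, gt2, f, f)
  r_marg <- chisq_distortion(o, method = "marginal", scale = "individual")
  r_des <- chisq_distortion(o, method = "design", scale = "individual")
  expect_lt(r_marg$statistic, 3 * r_marg$df)
  expect_gt(r_des$statistic, 20 * r_des$df)
})

test_that("chi-square statistic, df and p match hand arithmetic and Pearson", {
  o <- matrix(c(10, 0, 0, 10), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- chisq_distortion(o)
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, 7.744216e-06, tolerance = 1e-6)
  # o == e gives 0 / p = 1
  oe <- matrix(5L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r0 <- chisq_distortion(oe)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # marginal Eq. 1 on a 2x2 equals the classical Pearson statistic
  set.seed(32)
  for (rpl in 1:10) {
    tab <- matrix(rpois(4, 20) + 1L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    r <- chisq_distortion(tab)
    oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(r$statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, oracle$p.value, tolerance = 1e-12)
  }
  # e = 0 with o > 0 is an error
  e <- matrix(c(5, 5, 5, 0), 2, 2)
  expect_error(chisq_distortion(matrix(c(5, 5, 5, 5), 2, 2), e), "expected count 0")
})

test_that("whole-population test reduces and combines correctly", {
  o <- matrix(c(10L, 0L, 0L, 10L), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  attr(o, "n_individuals") <- 10L
  # one subpopulation: equals the per-subpopulation statistic with cells-1 df
  r1 <- chisq_whole_population(list(o))
  r0 <- chisq_distortion(o)
  expect_equal(r1$statistic, r0$statistic)
  # everything at expectation -> 0
  u <- matrix(5L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(chisq_whole_population(list(u, u))$statistic, 0)
  # two subpopulations with opposite skews partially cancel:
  # Eq. 2 on the sums is below the sum of the two Eq. 1 statistics
  o2 <- o[2:1, ]
  rownames(o2) <- c("a", "b")
  attr(o2, "n_individuals") <- 10L
  r_sum <- chisq_distortion(o)$statistic + chisq_distortion(o2)$statistic
  r_whole <- chisq_whole_population(list(o, o2))$statistic
  expect_lt(r_whole, r_sum)
  expect_error(chisq_whole_population(list()), "empty")
})

test_that("neutral gene pairs give calibrated, roughly uniform p-values", {
  set.seed(33)
  map <- default_genome_map(0)
  des <- cross_design("N", letters[1:4], 6, 90)
  pvals <- numeric(0)
  for (r in 1:20) {
    pop <- simulate_subpopulation(des, list(), map, genotype = FALSE)
    blks <- lapply(seq_along(pop$individuals), function(i) truth_blocks(pop, i))
    combos <- utils::combn(5, 2)
    for (cc in seq_len(ncol(combos))) {
      c1 <- map$chromosomes$id[combos[1, cc]]
      c2 <- map$chromosomes$id[combos[2, cc]]
      p1 <- runif(1, 0.1, 0.9) * map$chromosomes$length_bp[combos[1, cc]]
      p2 <- runif(1, 0.1, 0.9) * map$chromosomes$length_bp[combos[2, cc]]
      gt1 <- t(vapply(blks, genotype_at_locus, character(2), chrom = c1, midpoint_bp = p1))
      gt2 <- t(vapply(blks, genotype_at_locus, character(2), chrom = c2, midpoint_bp = p2))
      o <- count_allele_pairs(gt1, gt2, letters[1:4], letters[1:4])
      pvals <- c(pvals, chisq_distortion(o, scale = "individual")$p_value)
    }
  }
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("screen excludes pairs that cannot be genotyped and logs them", {
  set.seed(34)
  map <- default_genome_map(0)
  des <- cross_design("N", letters[1:4], 6, 30)
  pop <- simulate_subpopulation(des, list(), map, genotype = FALSE)
  blks <- list(N = lapply(seq_along(pop$individuals),
                          function(i) truth_blocks(pop, i)))
  pairs <- list(gene_pair_locus("ok", "Chr1", 1e6, "Chr2", 1e6),
                gene_pair_locus("gone", "Chr9", 1e6, "Chr2", 1e6))
  sc <- screen_gene_pairs(blks, pairs)
  expect_true("ok" %in% sc$family_id)
  expect_false("gone" %in% sc$family_id)
  expect_match(attr(sc, "excluded"), "gone")
})

test_that("founder LoF confirmation keeps only pairs that can produce zero copies", {
  founders <- c("An", "C24", "Col", "Cvi", "Eri", "Kyo", "Ler", "Sha")
  # seven founders functional copy1 / lof copy2; the eighth lacks copy1 and
  # carries the only functional copy2
  st <- matrix("functional", 8, 2, dimnames = list(founders, c("c1", "c2")))
  st[, "c2"] <- "lof"
  st["Cvi", "c1"] <- "absent"
  st["Cvi", "c2"] <- "functional"
  sp_ok <- dup_gene_spec("HPA", data.frame(copy_id = c("c1", "c2"),
                                           chrom = c("Chr2", "Chr4"),
                                           start_bp = c(1, 1), end_bp = c(10, 10)), st)
  st2 <- st; st2[, "c1"] <- "functional"; st2["Cvi", "c1"] <- "functional"
  sp_bad <- dup_gene_spec("ALLFUNC", data.frame(copy_id = c("c1", "c2"),
                                                chrom = c("Chr2", "Chr4"),
                                                start_bp = c(1, 1), end_bp = c(10, 10)), st2)
  keep <- confirm_lof_in_founders(c("HPA", "ALLFUNC"),
                                  list(HPA = sp_ok, ALLFUNC = sp_bad))
  expect_true(keep[["HPA"]])
  expect_false(keep[["ALLFUNC"]])
})

test_that("a linked neutral pair distorted by hitchhiking is filtered in step two", {
  # plant a fully penetrant incompatibility; a second, all-functional pair
  # with one locus close to an incompatible copy shows distortion by linkage
  # but fails the founder-LoF confirmation
  set.seed(35)
  map <- default_genome_map(0)
  fam <- hpa_family()
  founders <- rownames(fam$founder_states)
  des1 <- cross_design("P1", founders, 6, 90)
  des2 <- cross_design("P2", founders[c(1, 3, 2, 4)], 6, 90)
  pop1 <- simulate_subpopulation(des1, list(fam), map, genotype = FALSE)
  pop2 <- simulate_subpopulation(des2, list(fam), map, genotype = FALSE)
  blks <- list(P1 = lapply(seq_along(pop1$individuals),
                           function(i) truth_blocks(pop1, i)),
               P2 = lapply(seq_along(pop2$individuals),
                           function(i) truth_blocks(pop2, i)))
  pairs <- list(gene_pair_locus("HPAlike", "Chr2", 8.002e6, "Chr4", 9.002e6),
                gene_pair_locus("linked", "Chr2", 8.4e6, "Chr4", 9.4e6))
  st_f <- fam$founder_states; st_f[] <- "functional"
  specs <- list(HPAlike = fam,
                linked = dup_gene_spec("linked",
                                       data.frame(copy_id = c("c1", "c2"),
                                                  chrom = c("Chr2", "Chr4"),
                                                  start_bp = c(8.4e6, 9.4e6),
                                                  end_bp = c(8.41e6, 9.41e6)),
                                       st_f))
  sc <- confirm_lof_in_founders(
    screen_gene_pairs(blks, pairs, merges = list(M = c("P1", "P2"))), specs)
  linked_rows <- sc[sc$family_id == "linked", ]
  expect_false(any(linked_rows$candidate))
  expect_true(any(sc$candidate[sc$family_id == "HPAlike"]))
})
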