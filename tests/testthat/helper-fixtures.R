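# Shared fixtures and independent oracles used across test files.

# small single-chromosome map for HMM unit tests
tiny_map <- function(n_markers = 20, len_bp = 1e6, len_m = 1) {
  genome_map("Chr1", len_bp, len_m,
             list(round(seq(len_bp / (n_markers + 1),
                            len_bp * n_markers / (n_markers + 1),
                            length.out = n_markers))))
}

# HPA-style reciprocally pseudofunctionalized family on a four-founder set:
# founder `carrier` lacks copy 1 but has the only functional copy 2
hpa_family <- function(founders = c("Col", "Cvi", "Kyo", "Sha"),
                       carrier = "Cvi", essential = TRUE, penetrance = 1) {
  st <- matrix("functional", length(founders), 2,
               dimnames = list(founders, c("copy1", "copy2")))
  st[carrier, "copy1"] <- "absent"
  st[, "copy2"] <- "lof"
  st[carrier, "copy2"] <- "functional"
  dup_gene_spec("HPAlike",
                data.frame(copy_id = c("copy1", "copy2"),
                           chrom = c("Chr2", "Chr4"),
                           start_bp = c(8e6, 9e6), end_bp = c(8.004e6, 9.004e6)),
                st, essential = essential, penetrance = penetrance)
}

# exhaustive path-sum posterior oracle: enumerates every state path
# (feasible for <= 6 markers with 10 states) and sums prior x transition x
# emission weights; kept independent of the forward-backward recursion
enumerate_posterior <- function(obs, alleles, d_morgan, states, params) {
  S <- nrow(states)
  m <- length(obs)
  stopifnot(S^m <= 2e6)
  eps <- params$error_rate
  p_hom <- function(s, o) {           # emission for a homozygous dosage s
    probs <- if (s == 0) c((1 - eps)^2, 2 * eps * (1 - eps), eps^2)
    else if (s == 2) c(eps^2, 2 * eps * (1 - eps), (1 - eps)^2)
    else c(eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps))
    probs[o + 1]
  }
  E <- matrix(1, m, S)
  for (t in seq_len(m)) {
    if (is.na(obs[t])) next
    for (s in seq_len(S))
      E[t, s] <- p_hom(alleles[states$f1[s], t] + alleles[states$f2[s], t], obs[t])
  }
  het <- states$f1 != states$f2
  prior <- numeric(S)
  prior[het] <- params$het_weight / sum(het)
  prior[!het] <- (1 - params$het_weight) / sum(!het)
  stay <- exp(-params$k * d_morgan)
  Tm <- lapply(stay, function(s) {
    M <- matrix((1 - s) / (S - 1), S, S); diag(M) <- s; M
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  w <- prior[grid[, 1]] * E[1, grid[, 1]]
  if (m > 1) for (t in 2:m)
    w <- w * Tm[[t - 1]][cbind(grid[, t - 1], grid[, t])] * E[t, grid[, t]]
  post <- vapply(seq_len(m), function(t) {
    s <- rowsum(w, grid[, t])
    out <- numeric(S)
    out[as.integer(rownames(s))] <- s
    out
  }, numeric(S))
  list(posterior = t(post) / sum(w), loglik = log(sum(w)))
}

# greedy minimum-variance-increase (Ward) agglomeration oracle: at each step
# merge the pair of clusters whose union minimally increases the total
# within-cluster sum of squares; returns the sequence of partitions
ward_oracle_partitions <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  parts <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_inc <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
      inc <- length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
      if (inc < best_inc) { best_inc <- inc; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    parts[[length(parts) + 1]] <- canonical_partition(clusters)
  }
  parts
}

canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, numeric(1), 1))]
}

# partition sequence implied by an hclust merge matrix
hclust_partitions <- function(hc, n) {
  merged_of <- vector("list", nrow(hc$merge))
  parts <- list()
  for (k in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[k, ],
                             function(v) if (v < 0) -v else merged_of[[v]]))
    merged_of[[k]] <- sort(members)
    assign <- seq_len(n)
    for (kk in seq_len(k)) assign[merged_of[[kk]]] <- n + kk
    parts[[k]] <- canonical_partition(unname(split(seq_len(n), assign)))
  }
  parts
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random gene model with sequence, for effect-classifier tests
random_gene_model <- function(seed = NULL, n_exons = 2) {
  if (!is.null(seed)) set.seed(seed)
  exon_len <- 3 * sample(8:20, n_exons, replace = TRUE)
  intron_len <- sample(40:80, n_exons - 1, replace = TRUE)
  tss <- 1000L
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- tss + 50L
  for (k in seq_len(n_exons)) {
    starts[k] <- pos
    ends[k] <- pos + exon_len[k] - 1L
    pos <- ends[k] + 1L + (if (k < n_exons) intron_len[k] else 0L)
  }
  tes <- ends[n_exons] + 60L
  seq_start <- tss - 600L
  total <- tes + 400L - seq_start + 1L
  sq <- paste(sample(c("A", "C", "G", "T"), total, TRUE), collapse = "")
  # force a clean ATG ... stop reading frame with no internal stops
  cds_len <- sum(exon_len)
  body <- unlist(lapply(seq_len(cds_len / 3 - 2), function(i)
    sample(c("GCT", "GGA", "TGC", "CTG", "ACC", "TCA", "AGG", "CAT"), 1)))
  cds_seq <- paste0("ATG", paste(body, collapse = ""), "TAA")
  # write cds_seq into the genomic sequence at the exon positions
  sq_chars <- strsplit(sq, "")[[1]]
  cds_chars <- strsplit(cds_seq, "")[[1]]
  ci <- 1L
  for (k in seq_len(n_exons)) for (g in starts[k]:ends[k]) {
    sq_chars[g - seq_start + 1L] <- cds_chars[ci]
    ci <- ci + 1L
  }
  gene_model("g1", "Chr1", "+", tss, tes,
             data.frame(start = starts, end = ends),
             seq = paste(sq_chars, collapse = ""), seq_start = seq_start)
}

# codon-walk oracle for SNVs inside the CDS: rebuild the mutated CDS and
# scan its reading frame for a premature stop
codon_walk_snv_oracle <- function(model, pos, alt) {
  cds <- model$cds
  sq <- model$seq
  ofs <- pos - model$seq_start + 1L
  substr(sq, ofs, ofs) <- alt
  pieces <- vapply(seq_len(nrow(cds)), function(k)
    substr(sq, cds$start[k] - model$seq_start + 1L,
           cds$end[k] - model$seq_start + 1L), character(1))
  cds_seq <- paste(pieces, collapse = "")
  codons <- substring(cds_seq, seq(1, nchar(cds_seq) - 2, 3),
                      seq(3, nchar(cds_seq), 3))
  internal <- codons[-length(codons)]
  if (any(internal %in% c("TAA", "TAG", "TGA"))) "stop_gained" else "none"
}
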