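# Founder-haplotype reconstruction by hidden Markov model.
#
# States are unordered founder pairs (10 for a four-founder subpopulation:
# 4 homozygous + 6 heterozygous).  Emissions model observed allele dosages
# under a symmetric per-allele flip error; transitions follow an exponential
# state-switch kernel in genetic distance.  Decoding uses the scaled
# forward-backward algorithm (per-marker normalization, not log space).

#' Enumerate the diplotype state space of a founder set
#'
#' All unordered founder pairs in canonical order: founders are sorted and
#' states listed lexicographically, e.g. `{a,b,c,d}` gives
#' `aa ab ac ad bb bc bd cc cd dd`.
#'
#' @param founders character vector of distinct founder names.
#' @return A data frame of class `state_space` with columns `f1`, `f2`
#'   (founder indices into the sorted founder set), `founder1`, `founder2`,
#'   `label`, and attribute `founders`.
#' @export
#' @examples
#' enumerate_states(c("a", "b", "c", "d"))  # 10 states
enumerate_states <- function(founders) {
  founders <- as.character(founders)
  if (anyDuplicated(founders)) stop("duplicate founders")
  if (length(founders) < 2) stop("need at least two founders")
  founders <- sort(founders)
  n <- length(founders)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  st <- data.frame(f1 = idx[, "row"], f2 = idx[, "col"])
  st$founder1 <- founders[st$f1]
  st$founder2 <- founders[st$f2]
  st$label <- paste0(st$founder1, "/", st$founder2)
  attr(st, "founders") <- founders
  class(st) <- c("state_space", "data.frame")
  st
}

#' HMM parameters for founder-haplotype decoding
#'
#' @param error_rate per-allele flip probability `epsilon` of a marker call,
#'   in (0, 0.5].
#' @param k state-switch scaling: the probability of leaving the current
#'   state over an interval of `d` Morgans is `1 - exp(-k d)`, spread
#'   uniformly over the other states.
#' @param het_weight total prior weight `h` on heterozygous states; the
#'   default `2^-5` is the expected residual heterozygosity of an F6 line
#'   (five rounds of selfing halve heterozygosity each round).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(error_rate = 0.005, k = 1, het_weight = 2^-5) {
  if (error_rate <= 0 || error_rate > 0.5) stop("error_rate must be in (0, 0.5]")
  if (k <= 0) stop("k must be positive")
  if (het_weight < 0 || het_weight >= 1) stop("het_weight must be in [0, 1)")
  structure(list(error_rate = error_rate, k = k, het_weight = het_weight),
            class = "hmm_params")
}

# prior over states: homozygous states share 1 - h, heterozygous share h
.state_prior <- function(states, het_weight) {
  het <- states$f1 != states$f2
  pr <- numeric(nrow(states))
  if (any(het)) {
    pr[het] <- het_weight / sum(het)
    pr[!het] <- (1 - het_weight) / sum(!het)
  } else pr[] <- 1 / nrow(states)
  pr
}

# emission matrix (markers x states): P(observed dosage | state) under
# independent per-allele flips with rate eps; missing (NA) rows are all 1
.emission_matrix <- function(obs, alleles, states, eps) {
  m <- length(obs)
  S <- nrow(states)
  # expected allele pair per state per marker
  E <- matrix(1, m, S)
  p_same <- c((1 - eps)^2, 2 * eps * (1 - eps), eps^2)  # P(o | s=0), o=0,1,2
  for (s in seq_len(S)) {
    a1 <- alleles[states$f1[s], ]
    a2 <- alleles[states$f2[s], ]
    tot <- a1 + a2
    e <- numeric(m)
    hom0 <- tot == 0L; hom2 <- tot == 2L; het <- tot == 1L
    e[hom0] <- p_same[obs[hom0] + 1L]
    e[hom2] <- rev(p_same)[obs[hom2] + 1L]
    e[het]  <- c(eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps))[obs[het] + 1L]
    e[is.na(obs)] <- 1
    E[, s] <- e
  }
  E
}

# apply the interval transition operator t(T) %*% v where
# T = stay * I + (1 - stay)/(S-1) * (J - I); T is symmetric
.transition_apply <- function(v, stay, S) {
  off <- (1 - stay) / (S - 1)
  off * sum(v) + (stay - off) * v
}

#' Posterior decoding of founder diplotype states
#'
#' Scaled forward-backward over the unordered-founder-pair state space.
#' Missing observations contribute a uniform emission (likelihood 1 in every
#' state).  Both the forward- and backward-pass log-likelihoods are returned;
#' they agree to numerical precision, which is used as an internal
#' consistency invariant.
#'
#' @param obs integer dosages (0/1/2) with `NA` for missing, one per marker.
#' @param alleles founders x markers 0/1 allele matrix (rows ordered as the
#'   sorted founder set of `states`).
#' @param d_morgan genetic distances between consecutive markers (length
#'   `length(obs) - 1`).
#' @param states a [enumerate_states()] state space.
#' @param params an [hmm_params()].
#' @return list with `posterior` (markers x states matrix, rows sum to 1),
#'   `loglik` (forward), `loglik_backward`, `states`.
#' @export
decode_posteriors <- function(obs, alleles, d_morgan, states,
                              params = hmm_params()) {
  m <- length(obs)
  if (m == 0L || all(is.na(obs))) stop("empty observation vector")
  if (length(d_morgan) != m - 1L) stop("need one genetic distance per marker interval")
  S <- nrow(states)
  E <- .emission_matrix(obs, alleles, states, params$error_rate)
  prior <- .state_prior(states, params$het_weight)
  stay <- exp(-params$k * d_morgan)

  alpha <- matrix(0, m, S)
  cc <- numeric(m)
  a <- prior * E[1L, ]
  cc[1L] <- sum(a)
  alpha[1L, ] <- a / cc[1L]
  if (m > 1L) for (t in 2:m) {
    a <- .transition_apply(alpha[t - 1L, ], stay[t - 1L], S) * E[t, ]
    cc[t] <- sum(a)
    alpha[t, ] <- a / cc[t]
  }

  beta <- matrix(0, m, S)
  beta[m, ] <- 1
  if (m > 1L) for (t in (m - 1L):1L) {
    b <- .transition_apply(E[t + 1L, ] * beta[t + 1L, ], stay[t], S)
    beta[t, ] <- b / cc[t + 1L]   # reuse forward scalers; keeps alpha*beta normalized
  }
  post <- alpha * beta
  post <- post / rowSums(post)

  # independent backward-pass likelihood with its own scaling
  bb <- rep(1, S); llb <- 0
  if (m > 1L) for (t in (m - 1L):1L) {
    bb <- .transition_apply(E[t + 1L, ] * bb, stay[t], S)
    s <- sum(bb); bb <- bb / s; llb <- llb + log(s)
  }
  llb <- llb + log(sum(prior * E[1L, ] * bb))

  list(posterior = post, loglik = sum(log(cc)), loglik_backward = llb,
       states = states)
}

#' Call haplotype blocks from posterior state probabilities
#'
#' Takes the maximum-a-posteriori state per marker (ties broken toward the
#' lowest canonical state index), merges consecutive markers in the same
#' state into runs, absorbs runs shorter than `min_markers` into the
#' flanking run whose state has the higher mean posterior over the short
#' run's markers, and places block boundaries at the midpoint between the
#' flanking markers of each state switch.  Markers whose MAP posterior falls
#' below `min_posterior` are treated as uninformative and do not seed runs.
#'
#' @param posterior markers x states matrix (rows sum to 1).
#' @param positions marker bp positions.
#' @param states the [enumerate_states()] used for decoding.
#' @param chrom chromosome id for the output.
#' @param chrom_len chromosome physical length (bp); blocks tile
#'   `[0, chrom_len)` in 0-based half-open coordinates.
#' @param min_posterior minimum MAP posterior for a marker to be used.
#' @param min_markers minimum run length; shorter runs are absorbed.
#' @return A `haplotype_blocks` data frame: `chrom`, `start`, `end`,
#'   `founder1`, `founder2`, `mean_posterior`, `n_markers`.  Breakpoint count
#'   is `nrow - 1`.
#' @export
call_blocks <- function(posterior, positions, states, chrom = "chr",
                        chrom_len = max(positions), min_posterior = 0,
                        min_markers = 1) {
  stopifnot(nrow(posterior) == length(positions))
  map_state <- max.col(posterior, ties.method = "first")
  map_p <- posterior[cbind(seq_along(map_state), map_state)]
  use <- map_p >= min_posterior
  if (!any(use)) use[] <- TRUE
  idx <- which(use)
  st <- map_state[idx]

  r <- rle(st)
  # absorb short runs into the flanking run with higher adjacent posterior
  while (length(r$lengths) > 1L && any(r$lengths < min_markers)) {
    j <- which(r$lengths < min_markers)
    j <- j[which.min(r$lengths[j])]
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    run_mk <- idx[lo[j]:hi[j]]
    left_s <- if (j > 1L) r$values[j - 1L] else NA_integer_
    right_s <- if (j < length(r$values)) r$values[j + 1L] else NA_integer_
    pick_left <- if (is.na(right_s)) TRUE
      else if (is.na(left_s)) FALSE
      else mean(posterior[run_mk, left_s]) >= mean(posterior[run_mk, right_s])
    r$values[j] <- if (pick_left) left_s else right_s
    r <- rle(inverse.rle(r))
  }
  hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
  n_runs <- length(r$values)
  bound <- if (n_runs > 1L)
    (positions[idx[hi[-n_runs]]] + positions[idx[lo[-1L]]]) / 2 else numeric(0)
  starts <- c(0, bound)
  ends <- c(bound, chrom_len)
  mp <- vapply(seq_len(n_runs), function(j)
    mean(posterior[idx[lo[j]:hi[j]], r$values[j]]), numeric(1))
  res <- data.frame(chrom = chrom, start = starts, end = ends,
                    founder1 = states$founder1[r$values],
                    founder2 = states$founder2[r$values],
                    mean_posterior = mp, n_markers = r$lengths,
                    stringsAsFactors = FALSE)
  class(res) <- c("haplotype_blocks", "data.frame")
  res
}

#' Genotype a whole simulated subpopulation with the HMM
#'
#' Runs [decode_posteriors()] and [call_blocks()] per individual and
#' chromosome, using the population's founder allele tables and genome map.
#'
#' @param pop a `ril_population` with observed `genotypes`.
#' @param params an [hmm_params()]; by default the error rate is taken from
#'   the population's simulation settings.
#' @param min_posterior,min_markers passed to [call_blocks()].
#' @return list of `haplotype_blocks` data frames, one per individual.
#' @export
genotype_population <- function(pop, params = NULL, min_posterior = 0,
                                min_markers = 2) {
  if (is.null(pop$genotypes)) stop("population has no observed genotypes")
  if (is.null(params))
    params <- hmm_params(error_rate = max(pop$error_rate, 1e-4))
  states <- enumerate_states(pop$founders)
  ord <- match(attr(states, "founders"), pop$founders)  # sorted -> design order
  map <- pop$map
  lapply(seq_len(nrow(pop$genotypes)), function(i) {
    per_chr <- lapply(seq_len(nrow(map$chromosomes)), function(ci) {
      mp <- map$marker_pos[[ci]]
      if (!length(mp)) return(NULL)
      cols <- which(pop$marker_info$chrom == map$chromosomes$id[ci])
      obs <- pop$genotypes[i, cols]
      al <- pop$founder_alleles[[ci]][ord, , drop = FALSE]  # rows in sorted order
      d <- diff(mp) / map$chromosomes$length_bp[ci] * map$chromosomes$length_morgan[ci]
      dec <- decode_posteriors(obs, al, d, states, params)
      call_blocks(dec$posterior, mp, states, chrom = map$chromosomes$id[ci],
                  chrom_len = map$chromosomes$length_bp[ci],
                  min_posterior = min_posterior, min_markers = min_markers)
    })
    res <- do.call(rbind, per_chr)
    class(res) <- c("haplotype_blocks", "data.frame")
    res
  })
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  cat("Haplotype blocks:", nrow(x), "blocks,",
      max(nrow(x) - length(unique(x$chrom)), 0), "breakpoints\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
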