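# Minimal loss-of-function effect classification for synthetic gene models.
# Coordinates are 1-based inclusive; indel representation follows VCF
# (anchored REF/ALT: the first base is shared context).

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

.revcomp <- function(x) {
  paste(rev(strsplit(.complement(x), "")[[1]]), collapse = "")
}

#' Gene model with CDS structure and reference sequence
#'
#' @param gene_id identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes transcription start / termination sites (genomic, 1-based;
#'   `tss > tes` on the minus strand).
#' @param cds data frame or matrix with columns `start`, `end` (genomic,
#'   1-based inclusive, ascending); total length should be a multiple of 3
#'   for a clean reading frame.
#' @param seq reference sequence of the region `[seq_start, seq_start +
#'   nchar(seq) - 1]` on the plus strand (required for premature-stop
#'   detection).
#' @param seq_start genomic coordinate of the first base of `seq`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", tss, tes, cds,
                       seq = NULL, seq_start = NULL) {
  cds <- as.data.frame(cds)
  stopifnot(all(c("start", "end") %in% names(cds)), all(cds$start <= cds$end))
  cds <- cds[order(cds$start), , drop = FALSE]
  span <- range(tss, tes)
  if (any(cds$start < span[1]) || any(cds$end > span[2]))
    stop("CDS outside the [TSS, TES] span")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = tss, tes = tes, cds = cds,
                 seq = seq, seq_start = seq_start),
            class = "gene_model")
}

# coding-strand CDS sequence of a model (needs seq)
.cds_sequence <- function(model) {
  if (is.null(model$seq)) return(NULL)
  pieces <- vapply(seq_len(nrow(model$cds)), function(k) {
    a <- model$cds$start[k] - model$seq_start + 1L
    b <- model$cds$end[k] - model$seq_start + 1L
    substr(model$seq, a, b)
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") .revcomp(s) else s
}

# coding index (1-based along the coding strand) of a genomic position
# inside the CDS; NA outside
.coding_index <- function(model, pos) {
  cl <- model$cds$end - model$cds$start + 1L
  offs <- cumsum(c(0L, cl))[seq_len(nrow(model$cds))]
  k <- which(pos >= model$cds$start & pos <= model$cds$end)
  if (!length(k)) return(NA_integer_)
  plus_idx <- offs[k] + (pos - model$cds$start[k]) + 1L
  if (model$strand == "-") sum(cl) - plus_idx + 1L else plus_idx
}

#' Classify the loss-of-function effect of a variant on a gene model
#'
#' Effect classes: `cds_loss` (deletion removing at least one full CDS
#' segment), `start_lost` / `stop_lost` (variant overlapping the first /
#' last codon), `stop_gained` (SNV creating an in-frame stop codon in the
#' CDS), `splice_damage` (variant within 2 bp of an intron boundary, the
#' canonical donor/acceptor dinucleotides), `frameshift` (indel changing the
#' CDS length by a non-multiple of 3), otherwise `none`.  The classes are
#' checked in that order; a variant outside the gene span is `none`.
#'
#' @param variant list or one-row data frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt` (VCF-style anchored alleles for indels).
#' @param model a [gene_model()].
#' @return Character scalar effect class.
#' @export
classify_variant_effect <- function(variant, model) {
  v <- as.list(variant)
  if (v$chrom != model$chrom) return("none")
  ref <- toupper(v$ref); alt <- toupper(v$alt)
  span <- range(model$tss, model$tes)
  v_end <- v$pos + nchar(ref) - 1L
  if (v_end < span[1] || v$pos > span[2]) return("none")

  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  is_del <- nchar(ref) > nchar(alt)
  is_ins <- nchar(alt) > nchar(ref)
  # interval of bases removed by a deletion (anchored first base shared)
  del <- if (is_del) c(v$pos + nchar(alt), v$pos + nchar(ref) - 1L) else NULL

  cds <- model$cds
  if (is_del && any(del[1] <= cds$start & del[2] >= cds$end))
    return("cds_loss")

  # first and last codon in genomic coordinates
  cl <- cds$end - cds$start + 1L
  total <- sum(cl)
  genomic_of_plus_idx <- function(i) {
    k <- max(which(cumsum(c(0L, cl)) < i)) # segment index
    cds$start[k] + (i - cumsum(c(0L, cl))[k] - 1L)
  }
  first3 <- if (model$strand == "+") vapply(1:3, genomic_of_plus_idx, numeric(1))
            else vapply(total:(total - 2L), genomic_of_plus_idx, numeric(1))
  last3 <- if (model$strand == "+") vapply((total - 2L):total, genomic_of_plus_idx, numeric(1))
           else vapply(3:1, genomic_of_plus_idx, numeric(1))
  hits <- function(positions) {
    if (is_del) any(positions >= del[1] & positions <= del[2])
    else any(positions >= v$pos & positions <= v_end)
  }
  if (hits(first3)) return("start_lost")
  if (hits(last3)) return("stop_lost")

  if (is_snv) {
    ci <- .coding_index(model, v$pos)
    if (!is.na(ci)) {
      cds_seq <- .cds_sequence(model)
      if (!is.null(cds_seq)) {
        base <- if (model$strand == "-") .complement(alt) else alt
        mut <- cds_seq
        substr(mut, ci, ci) <- base
        codon <- substr(mut, 3L * ((ci - 1L) %/% 3L) + 1L, 3L * ((ci - 1L) %/% 3L) + 3L)
        orig <- substr(cds_seq, 3L * ((ci - 1L) %/% 3L) + 1L, 3L * ((ci - 1L) %/% 3L) + 3L)
        if (codon %in% c("TAA", "TAG", "TGA") && !(orig %in% c("TAA", "TAG", "TGA")))
          return("stop_gained")
      }
    }
  }

  if (nrow(cds) > 1L) {
    splice_sites <- unlist(lapply(seq_len(nrow(cds) - 1L), function(k) {
      c(cds$end[k] + 1L, cds$end[k] + 2L, cds$start[k + 1L] - 2L, cds$start[k + 1L] - 1L)
    }))
    if (hits(splice_sites)) return("splice_damage")
  }

  if (is_del || is_ins) {
    in_cds <- function(p) any(p >= cds$start & p <= cds$end)
    if (is_del) {
      n_removed <- sum(vapply(del[1]:del[2], in_cds, logical(1)))
      if (n_removed > 0L && n_removed %% 3L != 0L) return("frameshift")
    } else {
      # insertion between pos and pos+1 lands in the CDS if both flanks do
      if (in_cds(v$pos) && in_cds(v$pos + 1L) &&
          (nchar(alt) - nchar(ref)) %% 3L != 0L) return("frameshift")
    }
  }
  "none"
}
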