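# Readers and writers for the pipeline's table dialects.
#
# Coordinate conventions: block/coverage files are BED-like, 0-based
# half-open; gene models are GFF3-like, 1-based inclusive; VCF and
# methylation reports are 1-based.

.stop_line <- function(file, line, msg) {
  stop(basename(file), " line ", line, ": ", msg, call. = FALSE)
}

#' Write / read a marker genotype matrix (TSV)
#'
#' Rows are individuals, columns are markers; dosage calls 0/1/2 with `NA`
#' for missing.  The first column `id` holds individual names.
#'
#' @param genotypes individuals x markers matrix.
#' @param file path.
#' @return `read_marker_matrix` returns the matrix with dimnames restored.
#' @export
write_marker_matrix <- function(genotypes, file) {
  df <- data.frame(id = rownames(genotypes) %||% seq_len(nrow(genotypes)),
                   genotypes, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_marker_matrix
#' @export
read_marker_matrix <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read haplotype blocks (BED-like, 0-based half-open)
#'
#' Columns: `chrom`, `start`, `end`, `founder1`, `founder2`, and optionally
#' `mean_posterior`, `n_markers`, `individual`.
#'
#' @param blocks a `haplotype_blocks` data frame (or a list of them, written
#'   with an `individual` column).
#' @param file path.
#' @export
write_blocks_bed <- function(blocks, file) {
  if (is.list(blocks) && !is.data.frame(blocks)) {
    nm <- names(blocks) %||% seq_along(blocks)
    blocks <- do.call(rbind, Map(function(b, n) {
      b$individual <- n; b
    }, blocks, nm))
  }
  utils::write.table(as.data.frame(blocks), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_blocks_bed
#' @export
read_blocks_bed <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "founder1", "founder2")
  if (!all(need %in% names(df)))
    .stop_line(file, 1, paste("missing column(s):",
                              paste(setdiff(need, names(df)), collapse = ", ")))
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad)) .stop_line(file, bad[1] + 1L, "invalid 0-based half-open interval")
  if ("individual" %in% names(df)) {
    out <- lapply(split(df, df$individual), function(b) {
      class(b) <- c("haplotype_blocks", "data.frame"); b
    })
    return(out)
  }
  class(df) <- c("haplotype_blocks", "data.frame")
  df
}

#' Write / read a minimal VCF v4.2
#'
#' The writer emits the fixed eight columns (no samples); the reader
#' (backed by vcfR) returns them as a data frame with `pos` numeric.
#'
#' @param variants data frame with `chrom`, `pos`, `id`, `ref`, `alt` and
#'   optionally `qual`, `filter`, `info`.
#' @param file path.
#' @export
write_minimal_vcf <- function(variants, file) {
  v <- variants
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(v$chrom), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  dot <- function(x, default = ".") {
    x <- as.character(x %||% default)
    ifelse(is.na(x), default, x)
  }
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                  v$chrom, as.integer(v$pos),
                  dot(v$id), v$ref, v$alt, dot(v$qual),
                  dot(v$filter, "PASS"), dot(v$info))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @rdname write_minimal_vcf
#' @export
read_minimal_vcf <- function(file) {
  l1 <- readLines(file, n = 1)
  if (!startsWith(l1, "##fileformat=VCF"))
    .stop_line(file, 1, "not a VCF: missing ##fileformat header")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  names(fix) <- tolower(names(fix))
  data.frame(chrom = fix$chrom, pos = as.integer(fix$pos), id = fix$id,
             ref = fix$ref, alt = fix$alt, qual = fix$qual,
             filter = fix$filter, info = fix$info, stringsAsFactors = FALSE)
}

#' Write / read a cytosine methylation report (TSV)
#'
#' Columns: `chrom`, `pos` (1-based), `strand`, `context` (CG/CHG/CHH),
#' `count_methylated`, `count_total`.  Rows with zero total are preserved
#' and flagged in attribute `zero_total`.
#'
#' @param report the report data frame.
#' @param file path.
#' @export
write_methylation_tsv <- function(report, file) {
  utils::write.table(report, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context", "count_methylated", "count_total")
  if (!all(need %in% names(df)))
    .stop_line(file, 1, paste("missing column(s):",
                              paste(setdiff(need, names(df)), collapse = ", ")))
  bad <- which(!df$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) .stop_line(file, bad[1] + 1L, "invalid context")
  bad <- which(df$count_methylated > df$count_total | df$count_methylated < 0)
  if (length(bad)) .stop_line(file, bad[1] + 1L, "methylated count exceeds total")
  attr(df, "zero_total") <- which(df$count_total == 0)
  df
}

#' Write / read a coverage track (bedGraph, 0-based half-open)
#'
#' Per-base depths are run-length encoded on write and expanded on read.
#'
#' @param track a [coverage_track()].
#' @param file path.
#' @param genome_mean the genome-wide mean depth (stored as a track line
#'   comment on write; required on read if absent from the file).
#' @export
write_bedgraph <- function(track, file) {
  r <- rle(track$depth)
  ends <- track$start + cumsum(r$lengths)
  starts <- c(track$start, ends[-length(ends)])
  lines <- c(sprintf("track type=bedGraph genome_mean=%g", track$genome_mean),
             sprintf("%s\t%d\t%d\t%g", track$chrom, starts, ends, r$values))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(file, genome_mean = NULL) {
  lines <- readLines(file)
  is_track <- startsWith(lines, "track")
  if (any(is_track) && is.null(genome_mean)) {
    m <- regmatches(lines[is_track][1],
                    regexec("genome_mean=([0-9.eE+-]+)", lines[is_track][1]))[[1]]
    if (length(m) == 2) genome_mean <- as.numeric(m[2])
  }
  if (is.null(genome_mean)) stop("genome_mean not in file; supply it")
  body <- lines[!is_track]
  parts <- strsplit(body, "\t")
  bad <- which(lengths(parts) != 4)
  if (length(bad)) .stop_line(file, bad[1] + sum(is_track), "expected 4 bedGraph fields")
  chrom <- vapply(parts, `[`, "", 1)
  starts <- as.integer(vapply(parts, `[`, "", 2))
  ends <- as.integer(vapply(parts, `[`, "", 3))
  vals <- as.numeric(vapply(parts, `[`, "", 4))
  depth <- rep(vals, ends - starts)
  coverage_track(chrom[1], starts[1], ends[length(ends)], depth, genome_mean)
}

#' Write / read gene models (GFF3-like, 1-based inclusive)
#'
#' One `gene` feature per model plus its `CDS` features; attributes carry
#' `ID` and `Parent`.
#'
#' @param models list of [gene_model()] objects.
#' @param file path.
#' @export
write_gff3_genes <- function(models, file) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(m$tss, m$tes)
    lines <- c(lines,
               sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chrom, span[1], span[2], m$strand, m$gene_id),
               sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                       m$chrom, m$cds$start, m$cds$end, m$strand, m$gene_id))
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_gff3_genes
#' @export
read_gff3_genes <- function(file) {
  lines <- readLines(file)
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t")
  bad <- which(lengths(parts) != 9)
  if (length(bad)) .stop_line(file, bad[1] + 1L, "expected 9 GFF3 fields")
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   type = vapply(parts, `[`, "", 3),
                   start = as.integer(vapply(parts, `[`, "", 4)),
                   end = as.integer(vapply(parts, `[`, "", 5)),
                   strand = vapply(parts, `[`, "", 7),
                   attr = vapply(parts, `[`, "", 9),
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", , drop = FALSE]
  out <- lapply(seq_len(nrow(genes)), function(i) {
    id <- sub("^ID=", "", genes$attr[i])
    cds <- df[df$type == "CDS" & df$attr == paste0("Parent=", id), , drop = FALSE]
    g <- genes[i, ]
    tss <- if (g$strand == "-") g$end else g$start
    tes <- if (g$strand == "-") g$start else g$end
    gene_model(id, g$chrom, g$strand, tss, tes,
               data.frame(start = cds$start, end = cds$end))
  })
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Write a distortion-scan results table (TSV)
#'
#' @param scan a `distortion_scan`.
#' @param file path.
#' @export
write_distortion_tsv <- function(scan, file) {
  utils::write.table(as.data.frame(scan), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write an association results table (TSV)
#'
#' @param scan a `gwas_scan`.
#' @param file path.
#' @export
write_gwas_tsv <- function(scan, file) {
  df <- as.data.frame(scan)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
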