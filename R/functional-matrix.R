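# Composition of variant, methylation, pseudoheterozygous and coverage
# evidence into per-accession, per-copy functional calls and GWA phenotypes.

#' Assign a pseudoheterozygous variant to a gene copy
#'
#' A pseudoheterozygous variant (an apparent het call produced by reads from
#' two near-identical copies collapsing onto one locus) is assigned by the
#' expression contrast between the copies: present in DNA but absent in RNA
#' with exactly one copy expression-silenced, it is assigned to the silenced
#' copy; present in both DNA and RNA with exactly one copy silenced, to the
#' expressed copy; otherwise it stays unassigned.  Both copies silenced
#' leaves no contrast, hence unassigned.
#'
#' @param dna_present logical; variant seen in DNA reads (must be `TRUE` for
#'   a pseudoheterozygous candidate; `FALSE` is an error).
#' @param rna_present logical; variant seen in RNA reads.
#' @param silenced logical vector of length 2: is each candidate copy
#'   expression-silenced (hypermethylated)?
#' @return Integer copy index (1 or 2), or `NA_integer_` when unassigned.
#' @export
assign_pseudohet_variant <- function(dna_present, rna_present, silenced) {
  stopifnot(length(silenced) == 2)
  if (!isTRUE(dna_present)) stop("not a pseudoheterozygous candidate: absent in DNA")
  if (sum(silenced) != 1L) return(NA_integer_)
  if (!rna_present) which(silenced) else which(!silenced)
}

#' Build the accession x copy functional-state matrix
#'
#' Per cell, evidence is composed in fixed precedence: `absent` when
#' coverage reports the copy deleted; else `lof` when any loss-of-function
#' effect is assigned to the copy; else `silenced` when the promoter is
#' hypermethylated; else `functional`.  Accessions without methylation data
#' are assumed expressed (no `silenced` call).  Coverage-absent copies with
#' RNA-expressed variant evidence are contradictory and become `unknown`.
#'
#' @param accessions character vector of accession ids (rows).
#' @param copies character vector of copy ids (columns).
#' @param lof data frame (`accession`, `copy`, `effect`) of assigned LoF
#'   effects (`effect != "none"`), or `NULL`.
#' @param methylation data frame (`accession`, `copy`, `label`) with label
#'   `hypermethylated` / `unmethylated`, or `NULL`.
#' @param coverage data frame (`accession`, `copy`, `present` logical), or
#'   `NULL` (all copies assumed present).
#' @param rna_expressed optional data frame (`accession`, `copy`,
#'   `expressed` logical) used only for the contradiction check.
#' @return A `copy_function_matrix`: character matrix with values in
#'   `functional`, `lof`, `silenced`, `absent`, `unknown`; attribute
#'   `provenance` records which evidence fired per cell, attribute `log`
#'   lists contradictions.
#' @export
build_functional_matrix <- function(accessions, copies, lof = NULL,
                                    methylation = NULL, coverage = NULL,
                                    rna_expressed = NULL) {
  m <- matrix("functional", length(accessions), length(copies),
              dimnames = list(accessions, copies))
  prov <- matrix("default", length(accessions), length(copies),
                 dimnames = list(accessions, copies))
  logs <- character(0)
  key <- function(df) cbind(match(df$accession, accessions), match(df$copy, copies))
  if (!is.null(methylation) && nrow(methylation)) {
    sel <- methylation$label == "hypermethylated"
    idx <- key(methylation[sel, , drop = FALSE])
    m[idx] <- "silenced"; prov[idx] <- "methylation"
  }
  if (!is.null(lof) && nrow(lof)) {
    sel <- lof$effect != "none"
    idx <- key(lof[sel, , drop = FALSE])
    m[idx] <- "lof"; prov[idx] <- "lof_variant"
  }
  if (!is.null(coverage) && nrow(coverage)) {
    sel <- !coverage$present
    idx <- key(coverage[sel, , drop = FALSE])
    m[idx] <- "absent"; prov[idx] <- "coverage"
    if (!is.null(rna_expressed) && nrow(rna_expressed)) {
      expr <- rna_expressed[rna_expressed$expressed, , drop = FALSE]
      eidx <- key(expr)
      conflict <- which(m[eidx] == "absent")
      if (length(conflict)) {
        cells <- eidx[conflict, , drop = FALSE]
        m[cells] <- "unknown"; prov[cells] <- "conflict"
        logs <- c(logs, paste0("absent by coverage but expressed in RNA: ",
                               accessions[cells[, 1]], "/", copies[cells[, 2]]))
      }
    }
  }
  structure(m, provenance = prov, log = logs,
            class = c("copy_function_matrix", "matrix"))
}

#' @export
print.copy_function_matrix <- function(x, ...) {
  cat("Copy function matrix:", nrow(x), "accessions x", ncol(x), "copies\n")
  tab <- table(factor(x, levels = c("functional", "lof", "silenced", "absent", "unknown")))
  print(tab)
  lg <- attr(x, "log")
  if (length(lg)) cat("Conflicts:", length(lg), "\n")
  invisible(x)
}

#' Binary phenotype from the functional-state matrix
#'
#' `mode = "any_copy"`: phenotype 1 when at least one copy is functional
#' (used when the reference genome carries both copies).  `mode =
#' "reference_copy"`: phenotype 1 when the designated reference copy is
#' functional (used when the reference carries only one copy and the
#' paralog's state is not scored).  Presence is coded 1, absence 0.
#'
#' @param m a [build_functional_matrix()] result.
#' @param mode `"any_copy"` or `"reference_copy"`.
#' @param reference_copy copy id, required for `mode = "reference_copy"`.
#' @return Named integer vector of 0/1 phenotypes.
#' @export
phenotype_from_matrix <- function(m, mode = c("any_copy", "reference_copy"),
                                  reference_copy = NULL) {
  mode <- match.arg(mode)
  if (mode == "any_copy") {
    ph <- as.integer(apply(m == "functional", 1, any))
  } else {
    if (is.null(reference_copy)) stop("reference_copy required")
    ph <- as.integer(m[, reference_copy] == "functional")
  }
  names(ph) <- rownames(m)
  ph
}
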