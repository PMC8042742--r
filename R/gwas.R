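# Binary-phenotype GWAS under a linear mixed model with kinship correction.
#
# The variance components of y = mu + g + e, g ~ N(0, sg2 K), e ~ N(0, se2 I)
# are estimated once by spectral REML on the null model; the per-marker scan
# then runs generalized least squares in the rotated (eigen) space with those
# components held fixed (single-fit approximation).  The per-marker residual
# scale is re-estimated, so with K = I the scan collapses exactly onto
# ordinary least squares.

#' Filter and impute a marker dosage panel
#'
#' Drops markers with minor allele frequency not above `maf_min` (computed on
#' non-missing calls) or missing rate not below `miss_max`, then imputes the
#' remaining missing entries with the marker mean dosage.
#'
#' @param dosage accessions x markers matrix with entries 0/1/2 or `NA`.
#' @param maf_min minimum (exclusive) minor allele frequency, default 0.05.
#' @param miss_max maximum (exclusive) missing rate, default 0.1.
#' @param info optional marker metadata data frame (`chrom`, `pos`, ...)
#'   subset alongside the dosage columns.
#' @return list of class `marker_panel` with `dosage` (no missing values),
#'   `info`, and `kept` (logical over input markers).
#' @export
filter_and_impute <- function(dosage, maf_min = 0.05, miss_max = 0.1,
                              info = NULL) {
  stopifnot(is.matrix(dosage))
  miss <- colMeans(is.na(dosage))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > maf_min & miss < miss_max
  if (!any(keep)) stop("no markers survive the MAF/missing-rate filters")
  X <- dosage[, keep, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  structure(list(dosage = X,
                 info = if (!is.null(info)) info[keep, , drop = FALSE] else NULL,
                 kept = keep),
            class = "marker_panel")
}

#' VanRaden-style genomic kinship matrix
#'
#' Centered-dosage cross-product scaled by `sum(2 p (1 - p))`:
#' `K = Z Z' / sum(2 p_j (1 - p_j))` with `Z = X - 2p`.  The diagonal
#' averages about 1 in an unstructured panel.
#'
#' @param panel a [filter_and_impute()] result or a complete dosage matrix.
#' @return Symmetric accessions x accessions `kinship_matrix`.
#' @export
compute_kinship <- function(panel) {
  X <- if (inherits(panel, "marker_panel")) panel$dosage else panel
  if (anyNA(X)) stop("kinship requires a complete (imputed) panel")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("panel has no polymorphic markers")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Z) / sum(2 * p * (1 - p))
  K <- (K + t(K)) / 2
  structure(K, class = c("kinship_matrix", "matrix"))
}

#' REML variance components of the null mixed model
#'
#' Fits `y = mu + g + e`, `g ~ N(0, sg2 K)`, `e ~ N(0, se2 I)` by restricted
#' maximum likelihood.  The variance ratio `delta = se2 / sg2` is profiled on
#' the spectral decomposition of `K`: a log10 grid over `[1e-5, 1e5]` locates
#' the optimum, refined by bounded scalar optimization (tolerance 1e-8).  The
#' binary phenotype is treated as quantitative.
#'
#' @param y numeric phenotype (binary 0/1 or quantitative).
#' @param K kinship matrix; small negative eigenvalues (within `-1e-6` of 0)
#'   are tolerated and clamped, more negative ones are an error.
#' @param X fixed-effect design matrix (default: intercept only).
#' @return Object of class `mlm_null`: list with `sigma_g2`, `sigma_e2`,
#'   `delta`, `loglik` (restricted), `h2`, and the cached eigen decomposition
#'   (`eigen_values`, `eigen_vectors`).
#' @export
fit_null_mlm <- function(y, K, X = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("kinship matrix is not positive semi-definite; smallest eigenvalues: ",
         paste(signif(utils::head(sort(eg$values), 3), 3), collapse = ", "))
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  restricted_ll <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * sg2) + (n - p) +
              sum(log(d + delta)) + determinant(XtWX)$modulus[1])
  }
  grid <- seq(-5, 5, length.out = 41)
  ll <- vapply(grid, restricted_ll, numeric(1))
  j <- which.max(ll)
  lo <- grid[max(j - 1L, 1L)]; hi <- grid[min(j + 1L, length(grid))]
  opt <- stats::optimize(restricted_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- 10^opt$maximum
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  sg2 <- sum(w * r^2) / (n - p)
  structure(list(sigma_g2 = sg2, sigma_e2 = delta * sg2, delta = delta,
                 h2 = sg2 / (sg2 + delta * sg2), loglik = opt$objective,
                 beta = beta, eigen_values = d, eigen_vectors = U),
            class = "mlm_null")
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf("Null mixed model: sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f), restricted logLik = %.4g\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$loglik))
  invisible(x)
}

#' Mixed-model association scan (single-fit approximation)
#'
#' Per marker, generalized least squares of the phenotype on dosage in the
#' eigenspace of `K`, with the variance ratio fixed from the null fit and the
#' residual scale re-estimated per marker; significance by a t test on
#' `n - 2` degrees of freedom.  With identity kinship this is exactly
#' ordinary least squares.  Markers that are constant after imputation get
#' `p = 1` and are flagged.
#'
#' @param panel a [filter_and_impute()] result or complete dosage matrix.
#' @param y phenotype vector.
#' @param K kinship matrix, or `NULL` for identity (plain OLS scan).
#' @param null a [fit_null_mlm()] fit; computed when `NULL` and `K` given.
#' @param alpha family-wise significance level for the Bonferroni threshold.
#' @return A `gwas_scan` data frame: per marker `beta`, `se`, `p`,
#'   `neglog10p` plus `chrom`/`pos` when available; attributes `threshold`
#'   (-log10 Bonferroni), `null` (variance components), `constant` (flagged
#'   markers).
#' @export
association_scan <- function(panel, y, K = NULL, null = NULL, alpha = 0.05) {
  X <- if (inherits(panel, "marker_panel")) panel$dosage else panel
  info <- if (inherits(panel, "marker_panel")) panel$info else NULL
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(K)) {
    U <- diag(n); d <- rep(1, n); delta <- 0
  } else {
    if (is.null(null)) null <- fit_null_mlm(y, K)
    U <- null$eigen_vectors; d <- null$eigen_values; delta <- null$delta
  }
  w <- 1 / (d + delta)
  ys <- drop(crossprod(U, y))
  one <- drop(crossprod(U, rep(1, n)))
  Xs <- crossprod(U, X)

  sw <- sum(w * one^2)
  swy <- sum(w * one * ys)
  swyy <- sum(w * ys^2)
  sx <- drop(crossprod(Xs * w, one))
  sxx <- colSums(w * Xs^2)
  sxy <- drop(crossprod(Xs * w, ys))

  vxx <- sxx - sx^2 / sw
  vxy <- sxy - sx * swy / sw
  vyy <- swyy - swy^2 / sw
  const <- vxx <= .Machine$double.eps * pmax(sxx, 1)
  beta <- ifelse(const, 0, vxy / vxx)
  rss <- pmax(vyy - beta^2 * vxx, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(ifelse(const, NA, sigma2 / vxx))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[const] <- 1
  pval[pval == 0] <- .Machine$double.xmin  # keep p in (0, 1]
  res <- data.frame(marker = colnames(X) %||% seq_len(ncol(X)),
                    beta = beta, se = se, p = pval,
                    neglog10p = -log10(pval))
  if (!is.null(info)) res <- cbind(info, res)
  attr(res, "threshold") <- bonferroni_threshold(alpha, ncol(X))
  attr(res, "null") <- if (!is.null(K)) null else NULL
  attr(res, "constant") <- which(const)
  class(res) <- c("gwas_scan", "data.frame")
  res
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param alpha family-wise error level in (0, 1).
#' @param marker_count number of tests (>= 1).
#' @return `-log10(alpha / marker_count)` at full precision (display rounds
#'   to 2 decimals).
#' @export
#' @examples
#' round(bonferroni_threshold(0.05, 238166), 2)  # 6.68
bonferroni_threshold <- function(alpha, marker_count) {
  stopifnot(alpha > 0, alpha < 1, marker_count >= 1)
  -log10(alpha / marker_count)
}

#' @export
print.gwas_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("GWAS scan: %d markers, Bonferroni -log10(p) threshold %.2f, %d significant\n",
              nrow(x), thr, sum(x$neglog10p > thr)))
  if (!is.null(attr(x, "null"))) print(attr(x, "null"))
  top <- as.data.frame(x)[order(x$p)[seq_len(min(5, nrow(x)))], ]
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Manhattan plot of a GWAS scan
#'
#' @param x a `gwas_scan` with `chrom` and `pos` columns.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gwas_scan <- function(x, ...) {
  if (is.null(x$chrom)) {
    xpos <- seq_len(nrow(x)); col <- "grey30"
  } else {
    chrom <- factor(x$chrom, levels = unique(x$chrom))
    offs <- c(0, cumsum(tapply(x$pos, chrom, max)))
    xpos <- x$pos + offs[as.integer(chrom)]
    col <- c("grey30", "steelblue")[1 + as.integer(chrom) %% 2]
  }
  graphics::plot(xpos, x$neglog10p, pch = 20, col = col,
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2, col = "red")
  invisible(x)
}
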