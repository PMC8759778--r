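#' Per-cell QC covariates
#'
#' Computes total UMIs, detected genes and the percentage of transcripts
#' from mitochondrial genes (identified by symbol prefix).
#'
#' @param counts genes x cells count matrix
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes
#' @return data.frame(barcode, n_umi, n_genes, pct_mito)
#' @export
computeCovariates <- function(counts, mito_prefix = "MT-") {
  n_umi <- Matrix::colSums(counts)
  if (any(n_umi == 0))
    .stopf("%d cell(s) with zero total UMIs; remove before computing covariates",
           sum(n_umi == 0))
  n_genes <- Matrix::colSums(counts > 0)
  mito <- startsWith(toupper(rownames(counts)), toupper(mito_prefix))
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  data.frame(barcode = colnames(counts), n_umi = as.numeric(n_umi),
             n_genes = as.numeric(n_genes),
             pct_mito = 100 * as.numeric(mito_umi) / as.numeric(n_umi),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell quality filter
#'
#' Retains cells with at least \code{min_genes} detected genes AND at least
#' \code{min_umis} transcripts; cells strictly below either threshold are
#' excluded.  The default profile (1000 genes / 2000 UMIs) matches the main
#' analysis; the \code{"rare_subset"} profile (500 / 1000) is the relaxed
#' filter used when rare subsets need more cells.
#'
#' @param counts genes x cells count matrix
#' @param min_genes,min_umis inclusive lower bounds
#' @param profile \code{"default"} or \code{"rare_subset"}; overrides the
#'   two thresholds when given
#' @return filtered count matrix
#' @export
qcFilter <- function(counts, min_genes = 1000, min_umis = 2000,
                     profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("default", "rare_subset"))
    if (profile == "rare_subset") { min_genes <- 500; min_umis <- 1000 }
    else { min_genes <- 1000; min_umis <- 2000 }
  }
  stopifnot(min_genes > 0, min_umis > 0)
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  keep <- n_genes >= min_genes & n_umi >= min_umis
  if (!any(keep))
    .stopf("QC filter removed all %d cells (min_genes=%d, min_umis=%d)",
           ncol(counts), min_genes, min_umis)
  counts[, keep, drop = FALSE]
}

#' Library-size normalization with log transform
#'
#' entry = log(1 + scale_factor * count / cell_total).  Zeros map to zeros
#' and cells with proportional count vectors map to identical profiles.
#'
#' @param counts genes x cells count matrix (QC'd; no zero-total cells)
#' @param scale_factor pseudo library size, default 1e4
#' @return sparse normalized matrix, genes x cells
#' @export
normalizeLog <- function(counts, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) .stopf("cell(s) with zero total counts; run qcFilter first")
  m <- methods::as(counts, "CsparseMatrix")
  ## scale each column then log1p, preserving sparsity
  m@x <- log1p(scale_factor * m@x / rep.int(tot, diff(m@p)))
  m
}

#' Regress out technical covariates
#'
#' Per-gene ordinary least-squares on [intercept, n_umi, pct_mito]; the
#' residual matrix is the batch-mitigated layer used for embedding and
#' clustering.  Residuals are orthogonal to both covariates.
#'
#' @param normalized genes x cells layer from \code{normalizeLog}
#' @param covariates data.frame from \code{computeCovariates}, matching cells
#' @return dense residual matrix, genes x cells
#' @export
regressOut <- function(normalized, covariates) {
  stopifnot(ncol(normalized) == nrow(covariates))
  X <- cbind(1, covariates$n_umi, covariates$pct_mito)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    .stopf("covariates are collinear or constant (rank %d < %d)",
           qrX$rank, ncol(X))
  Y <- t(as.matrix(normalized))            # cells x genes
  res <- t(qr.resid(qrX, Y))               # genes x cells
  dimnames(res) <- dimnames(normalized)
  res
}

#' Rank genes by binned standardized dispersion
#'
#' Dispersion (variance/mean of the normalized layer) is z-scored within 20
#' equal-frequency mean bins and genes are ranked by that standardized
#' dispersion; constant genes are never selected.  Deterministic.
#'
#' @param normalized genes x cells layer
#' @param n_top number of genes to return
#' @param n_bins number of equal-frequency mean bins
#' @return character vector of gene symbols, highest dispersion first
#' @export
selectVariableGenes <- function(normalized, n_top, n_bins = 20) {
  if (n_top <= 0) .stopf("n_top must be positive")
  if (n_top > nrow(normalized)) .stopf("n_top exceeds gene count")
  mu <- Matrix::rowSums(normalized) / ncol(normalized)
  ex2 <- Matrix::rowSums(normalized^2) / ncol(normalized)
  v <- ex2 - mu^2
  ok <- v > 0 & mu > 0
  disp <- rep(NA_real_, length(mu))
  disp[ok] <- v[ok] / mu[ok]
  idx <- which(ok)
  nb <- max(1, min(n_bins, floor(length(idx) / 2)))
  bins <- cut(rank(mu[idx], ties.method = "first"), breaks = nb, labels = FALSE)
  z <- rep(NA_real_, length(mu))
  for (b in unique(bins)) {
    sel <- idx[bins == b]
    m <- mean(disp[sel]); s <- stats::sd(disp[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (disp[sel] - m) / s
  }
  ord <- order(z, decreasing = TRUE, na.last = TRUE)
  ord <- ord[!is.na(z[ord])]
  rownames(normalized)[utils::head(ord, min(n_top, length(ord)))]
}

#' Union of variable and curated immune genes, restricted to the panel
#'
#' Case-insensitive matching against the matrix gene list; returns the
#' union in matrix order.  Immune genes absent from the matrix are dropped
#' with a logged count.
#'
#' @param variable_genes,immune_genes character vectors of symbols
#' @param matrix_genes the gene symbols present in the matrix
#' @return character vector in matrix order
#' @export
geneFilterUnion <- function(variable_genes, immune_genes, matrix_genes) {
  if (!length(variable_genes) && !length(immune_genes)) .stopf("both gene lists empty")
  want <- toupper(unique(c(variable_genes, immune_genes)))
  hit <- toupper(matrix_genes) %in% want
  absent <- setdiff(toupper(immune_genes), toupper(matrix_genes))
  if (length(absent))
    .msgf("%d immune gene(s) absent from matrix, dropped", length(absent))
  out <- matrix_genes[hit]
  if (!length(out)) .stopf("gene filter produced an empty list")
  out
}

#' Standardize genes
#'
#' Per-gene (x - mean)/sd with population (1/n) standard deviation so
#' rescaling is bit-reproducible; constant genes become all-zero with a
#' warning.  Optional symmetric clipping.
#'
#' @param layer genes x cells matrix
#' @param clip optional positive bound; values clipped to [-clip, clip]
#' @return dense scaled matrix, genes x cells
#' @export
scaleGenes <- function(layer, clip = NULL) {
  X <- as.matrix(layer)
  n <- ncol(X)
  mu <- rowMeans(X)
  sdev <- sqrt(rowMeans(X^2) - mu^2)
  const <- sdev <= 1e-12
  if (any(const))
    .warnf("%d constant gene(s) scaled to zero", sum(const))
  sdev[const] <- 1
  S <- (X - mu) / sdev
  S[const, ] <- 0
  if (!is.null(clip)) S <- pmin(pmax(S, -clip), clip)
  S
}

#' PCA cell embedding
#'
#' Centered PCA of cells over genes via SVD; components are ordered by
#' decreasing explained variance and signed so the largest-magnitude gene
#' loading of each component is positive.
#'
#' @param layer genes x cells matrix (typically the regress-out residuals)
#' @param k number of components, default 10
#' @return list(scores cells x k, loadings genes x k, var_explained)
#' @export
pcaEmbed <- function(layer, k = 10) {
  X <- t(as.matrix(layer))                 # cells x genes
  if (k > min(dim(X))) .stopf("k=%d exceeds min(cells, genes)=%d", k, min(dim(X)))
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = k, nv = k)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (k > rank) .stopf("k=%d exceeds numerical rank %d", k, rank)
  V <- sv$v; U <- sv$u; d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(d, k, k)
  rownames(scores) <- rownames(X)
  rownames(V) <- colnames(X)
  list(scores = scores, loadings = V,
       var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}
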