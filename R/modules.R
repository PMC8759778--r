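#' Balanced downsampling of cells across samples
#'
#' Every sample contributes exactly min(sample sizes) cells, drawn without
#' replacement, so module discovery is not skewed toward large samples.
#' Deterministic given the seed.
#'
#' @param barcodes character vector of cell barcodes
#' @param sample_labels sample id per cell (e.g. patient x time x subset)
#' @param seed integer seed
#' @return character vector of retained barcodes
#' @export
balancedDownsample <- function(barcodes, sample_labels, seed) {
  stopifnot(length(barcodes) == length(sample_labels))
  tab <- table(sample_labels)
  if (any(tab == 0)) .stopf("empty sample in downsampling")
  m <- min(tab)
  set.seed(seed)
  out <- unlist(lapply(split(barcodes, sample_labels), function(b) {
    if (length(b) == m) b else sample(b, m)
  }), use.names = FALSE)
  out
}

#' Soft-thresholding operator
#'
#' S(a, lam) = sign(a) * max(|a| - lam, 0), the proximal map of the L1
#' penalty used inside the sparse PCA solver.
#'
#' @param a numeric vector
#' @param lam nonnegative threshold
#' @export
softThreshold <- function(a, lam) {
  stopifnot(lam >= 0)
  sign(a) * pmax(abs(a) - lam, 0)
}

## L1 norm of S(a, lam) normalized to unit L2; decreasing in lam
.l1AfterThreshold <- function(a, lam) {
  v <- softThreshold(a, lam)
  n2 <- sqrt(sum(v^2))
  if (n2 == 0) 0 else sum(abs(v)) / n2
}

## smallest lam >= 0 with ||v(lam)||_1 <= c, by bisection
.bisectLambda <- function(a, c, tol = 1e-6, max_iter = 60) {
  if (.l1AfterThreshold(a, 0) <= c) return(0)
  lo <- 0; hi <- max(abs(a))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    l1 <- .l1AfterThreshold(a, mid)
    if (abs(l1 - c) <= tol) return(mid)
    if (l1 > c) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## deterministic leading right-singular-vector approximation by power
## iteration from a fixed start
.leadingV <- function(X, iters = 40) {
  p <- ncol(X)
  v <- rep(1 / sqrt(p), p)
  for (i in seq_len(iters)) {
    w <- drop(crossprod(X, X %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(v)
    w <- w / nw
    if (max(abs(w - v)) < 1e-9) { v <- w; break }
    v <- w
  }
  v
}

#' Sparse PCA by penalized rank-one matrix decomposition
#'
#' Finds successive rank-one factors (u, v, d) maximizing u'Xv subject to
#' ||u||2 <= 1, ||v||2 <= 1 and ||v||1 <= c, by alternating
#' u <- Xv/||Xv|| and v <- S(X'u, lambda)/||S(X'u, lambda)|| with lambda
#' chosen by bisection as the smallest value meeting the L1 budget.  After
#' convergence the matrix is deflated by d u v' and the next component is
#' fitted.  The sparse loading vectors are the gene modules; v is
#' initialized from the leading right singular vector of the current
#' deflated matrix (deterministic).
#'
#' @param X cells x genes matrix, each gene (column) centered
#' @param n_components number of modules, default 50
#' @param c L1 budget in [1, sqrt(p)]; default 0.3*sqrt(p)
#' @param max_iter,tol alternating-iteration controls
#' @return a \code{GeneModuleSet}
#' @export
sparsePca <- function(X, n_components = 50, c = NULL,
                      max_iter = 100, tol = 1e-6) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(c)) c <- 0.3 * sqrt(p)
  if (c < 1 || c > sqrt(p))
    .stopf("L1 budget c=%.3f outside [1, sqrt(p)=%.3f]", c, sqrt(p))
  if (n_components > min(dim(X)))
    .stopf("n_components exceeds min(cells, genes)")
  gm <- abs(colMeans(X))
  if (max(gm) > 1e-6)
    .stopf("input not centered per gene (max |mean| = %.2e)", max(gm))
  V <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  dvals <- numeric(n_components)
  for (comp in seq_len(n_components)) {
    v <- .leadingV(X)
    for (it in seq_len(max_iter)) {
      v_old <- v
      Xv <- drop(X %*% v)
      nu <- sqrt(sum(Xv^2))
      if (nu == 0) break
      u <- Xv / nu
      a <- drop(crossprod(X, u))
      lam <- .bisectLambda(a, c)
      v <- softThreshold(a, lam)
      nv <- sqrt(sum(v^2))
      if (nv == 0) break
      v <- v / nv
      if (max(abs(v - v_old)) < tol) break
    }
    Xv <- drop(X %*% v)
    nu <- sqrt(sum(Xv^2))
    u <- if (nu > 0) Xv / nu else rep(0, nrow(X))
    d <- drop(crossprod(u, X %*% v))
    ## sign convention: largest-magnitude loading positive
    s <- sign(v[which.max(abs(v))])
    if (length(s) && !is.na(s) && s < 0) { v <- -v; u <- -u }
    V[, comp] <- v
    dvals[comp] <- d
    X <- X - d * tcrossprod(u, v)
  }
  methods::new("GeneModuleSet", loadings = V, d = dvals, l1Budget = c,
               labels = paste0("module", seq_len(n_components)))
}

#' Module scores
#'
#' Cells x modules score matrix: the scaled expression layer multiplied by
#' the sparse loadings, exactly.
#'
#' @param scaled genes x cells standardized layer
#' @param modules a \code{GeneModuleSet} indexed by the same genes
#' @return numeric matrix cells x modules
#' @export
scoreModules <- function(scaled, modules) {
  L <- moduleLoadings(modules)
  if (!identical(rownames(scaled), rownames(L)))
    .stopf("gene sets of layer and modules do not match")
  S <- crossprod(as.matrix(scaled), L)     # cells x modules
  rownames(S) <- colnames(scaled)
  colnames(S) <- modules@labels
  S
}

#' Negative-control calibrated expression threshold
#'
#' The threshold for calling a cell "expressing" a module is the k-th
#' largest module score among negative-control (CD154-CD137-) cells, with
#' k = round(fpr * N); with the >= tie convention exactly k/N of negative
#' cells are called expressing in the absence of ties.  The Treg module
#' instead uses a fixed threshold (method "fixed").
#'
#' @param neg_scores numeric vector of negative-control module scores
#' @param fpr target false-positive rate, default 0.002
#' @param method "fpr_quantile" or "fixed"
#' @param fixed the constant threshold when method = "fixed" (Treg: 2.0)
#' @return list(threshold, method, fpr, k, n_neg)
#' @export
computeExpressionThreshold <- function(neg_scores, fpr = 0.002,
                                       method = c("fpr_quantile", "fixed"),
                                       fixed = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed)) .stopf("fixed method requires a threshold value")
    return(list(threshold = fixed, method = "fixed", fpr = NA_real_,
                k = NA_integer_, n_neg = length(neg_scores)))
  }
  N <- length(neg_scores)
  if (N == 0) .stopf("empty negative-control population")
  if (fpr <= 0 || fpr >= 1) .stopf("fpr must lie in (0, 1)")
  if (N < 1 / fpr)
    .warnf("only %d negative cells for fpr=%.4f (recommend >= %.0f)",
           N, fpr, 1 / fpr)
  k <- max(1L, as.integer(round(fpr * N)))
  thr <- sort(neg_scores, decreasing = TRUE)[k]
  achieved <- mean(neg_scores >= thr)
  if (achieved > k / N + 1e-12)
    .msgf("ties at the threshold inflate the negative rate to %.4f", achieved)
  list(threshold = thr, method = "fpr_quantile", fpr = fpr, k = k, n_neg = N)
}

#' Thresholds for every module against a negative-control population
#'
#' @param neg_scores cells x modules score matrix of negative-control cells
#' @param fpr target false-positive rate
#' @param fixed named numeric vector of fixed thresholds overriding the
#'   quantile rule for specific modules (e.g. \code{c(module1 = 2)})
#' @return data.frame(module, threshold, method, fpr)
#' @export
moduleThresholds <- function(neg_scores, fpr = 0.002, fixed = NULL) {
  mods <- colnames(neg_scores)
  out <- lapply(mods, function(m) {
    if (!is.null(fixed) && m %in% names(fixed))
      th <- computeExpressionThreshold(neg_scores[, m], method = "fixed",
                                       fixed = fixed[[m]])
    else
      th <- computeExpressionThreshold(neg_scores[, m], fpr = fpr)
    data.frame(module = m, threshold = th$threshold, method = th$method,
               fpr = th$fpr, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call module-expressing cells
#'
#' A cell expresses a module iff its score is >= the module threshold (the
#' tie convention that makes the negative-control calibration exact).
#'
#' @param scores cells x modules score matrix
#' @param thresholds data.frame from \code{moduleThresholds}
#' @return logical matrix cells x modules
#' @export
classifyExpressing <- function(scores, thresholds) {
  miss <- setdiff(colnames(scores), thresholds$module)
  if (length(miss)) .stopf("missing threshold for module(s): %s",
                           paste(miss, collapse = ", "))
  thr <- thresholds$threshold[match(colnames(scores), thresholds$module)]
  out <- sweep(scores, 2, thr, ">=")
  dimnames(out) <- dimnames(scores)
  out
}

#' Remove patient-dominated modules
#'
#' A module is removed when at least \code{max_share} of its expressing
#' cells come from a single patient; modules with zero expressing cells are
#' removed with a distinct reason.
#'
#' @param expressing logical cells x modules matrix
#' @param patient_labels patient id per cell
#' @param max_share dominance bound, default 0.60 (inclusive)
#' @return data.frame(module, retained, max_share, n_expressing, reason)
#' @export
patientDominanceFilter <- function(expressing, patient_labels, max_share = 0.60) {
  stopifnot(nrow(expressing) == length(patient_labels))
  out <- lapply(colnames(expressing), function(m) {
    e <- expressing[, m]
    n <- sum(e)
    if (n == 0)
      return(data.frame(module = m, retained = FALSE, max_share = NA_real_,
                        n_expressing = 0L, reason = "no_expressing_cells",
                        stringsAsFactors = FALSE))
    share <- max(table(patient_labels[e])) / n
    dominated <- share >= max_share
    data.frame(module = m, retained = !dominated, max_share = share,
               n_expressing = as.integer(n),
               reason = if (dominated) "patient_dominated" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Match discovered modules to reference gene sets
#'
#' For each reference set, the discovered module whose support has the
#' highest Jaccard index with it; used to identify Th1/Th2/Th17/Treg
#' modules among discovered components and to assess recovery on synthetic
#' cohorts.
#'
#' @param modules a \code{GeneModuleSet}
#' @param reference named list of gene-symbol vectors
#' @return data.frame(reference, module, jaccard)
#' @export
matchModules <- function(modules, reference) {
  L <- moduleLoadings(modules)
  supports <- apply(L != 0, 2, function(z) rownames(L)[z], simplify = FALSE)
  out <- lapply(names(reference), function(nm) {
    ref <- toupper(reference[[nm]])
    j <- vapply(supports, function(s) {
      s <- toupper(s)
      length(intersect(s, ref)) / length(union(s, ref))
    }, 0)
    data.frame(reference = nm, module = modules@labels[which.max(j)],
               jaccard = max(j), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
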