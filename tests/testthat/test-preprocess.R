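test_that("covariates: totals, detected genes and mito percentage", {
  m <- tinyCounts(matrix(c(5, 15, 0, 8, 10, 0), nrow = 3, byrow = FALSE),
                  genes = c("MT-CO1", "ACTB", "CD4"))
  cv <- computeCovariates(m)
  expect_equal(cv$n_umi, c(20, 18))
  expect_equal(cv$n_genes, c(2, 2))
  expect_equal(cv$pct_mito, c(25, 8 / 18 * 100))
  ## all-mito and no-mito extremes
  m2 <- tinyCounts(matrix(c(7, 0), 2), genes = c("MT-ND1", "ACTB"))
  expect_equal(computeCovariates(m2)$pct_mito, 100)
  m3 <- tinyCounts(matrix(c(7, 1), 2), genes = c("GZMB", "ACTB"))
  expect_equal(computeCovariates(m3)$pct_mito, 0)
  ## zero-total cell is an error
  m4 <- tinyCounts(matrix(c(1, 0), 1))
  expect_error(computeCovariates(m4), "zero total")
})

test_that("QC filter boundaries: strictly-below cells are removed, at-threshold retained", {
  set.seed(1)
  ## cell A: 999 genes / 5000 UMIs; cell B: exactly 1000 genes / 2000 UMIs
  nG <- 1200
  a <- c(rep(5, 999), rep(0, nG - 999)); a[1] <- 5 + (5000 - sum(a))
  b <- c(rep(2, 1000), rep(0, nG - 1000))
  stopifnot(sum(b) == 2000)
  m <- tinyCounts(cbind(a, b), barcodes = c("A", "B"))
  kept <- qcFilter(m, 1000, 2000)
  expect_identical(colnames(kept), "B")
  ## rare-subset profile keeps a 600-gene / 1500-UMI cell (and cell A,
  ## which clears the relaxed 500/1000 floors)
  cc <- c(rep(2, 600), rep(0, nG - 600)); cc[1] <- 2 + (1500 - sum(cc))
  m2 <- tinyCounts(cbind(a, cc), barcodes = c("A", "C"))
  expect_identical(colnames(qcFilter(m2, profile = "rare_subset")), c("A", "C"))
  expect_error(qcFilter(m2, 2000, 1e6), "removed all")
})

test_that("QC filter is monotone in both thresholds", {
  set.seed(2)
  m <- tinyCounts(matrix(rpois(50 * 30, 2), 50), barcodes = sprintf("C%02d", 1:30))
  base <- colnames(qcFilter(m, 10, 40))
  for (mg in c(12, 15, 20)) {
    expect_true(all(colnames(qcFilter(m, mg, 40)) %in% base))
    expect_true(all(colnames(qcFilter(m, 10, 40 + mg)) %in% base))
  }
})

test_that("log normalization: zeros fixed, library-size invariance, exact value", {
  m <- tinyCounts(matrix(c(0, 10, 5, 0, 20, 10), nrow = 3))
  nl <- normalizeLog(m, scale_factor = 1e4)
  expect_equal(nl[1, 1], 0)
  ## second cell is 2x the first: identical normalized profiles
  expect_equal(as.numeric(nl[, 1]), as.numeric(nl[, 2]))
  ## count == cell total with scale factor 1 gives log(2)
  m2 <- tinyCounts(matrix(c(7), 1))
  expect_equal(as.numeric(normalizeLog(m2, 1)[1, 1]), log(2))
})

test_that("regress-out residuals match the OLS normal-equations oracle and are orthogonal", {
  set.seed(3)
  n <- 40
  cov <- data.frame(n_umi = rpois(n, 1000), pct_mito = runif(n, 0, 10))
  Y <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(sprintf("G%d", 1:5), sprintf("C%02d", 1:n)))
  ## plant a gene exactly 2 x n_umi: residual must vanish
  Y[1, ] <- 2 * cov$n_umi
  R <- regressOut(Y, cov)
  expect_lt(max(abs(R[1, ])), 1e-8)
  ## oracle: residual = y - X (X'X)^{-1} X'y
  X <- cbind(1, cov$n_umi, cov$pct_mito)
  beta <- solve(crossprod(X), crossprod(X, Y[3, ]))
  expect_equal(unname(R[3, ]), unname(Y[3, ] - drop(X %*% beta)), tolerance = 1e-10)
  ## orthogonality to both covariates for every gene
  for (g in 1:5) {
    expect_lt(abs(sum(R[g, ] * cov$n_umi)) / (sqrt(sum(R[g, ]^2)) * sqrt(sum(cov$n_umi^2)) + 1e-12), 1e-6)
    expect_lt(abs(cor(R[g, ], cov$pct_mito)), 1e-6)
  }
  ## constant covariate is a rank error
  expect_error(regressOut(Y, transform(cov, pct_mito = 5)), "collinear")
})

test_that("variable-gene ranking finds a planted overdispersed gene and skips constants", {
  set.seed(4)
  n <- 400; G <- 200
  counts <- matrix(rpois(G * n, 2), G, n,
                   dimnames = list(sprintf("G%03d", 1:G), sprintf("C%03d", 1:n)))
  ## gene G001: negative binomial with matching mean but ~10x dispersion
  counts["G001", ] <- rnbinom(n, mu = 2, size = 0.25)
  counts["G002", ] <- 3                    # constant gene
  nl <- normalizeLog(tinyCounts(counts, genes = rownames(counts),
                                barcodes = colnames(counts)))
  top <- selectVariableGenes(nl, 10)
  expect_equal(top[1], "G001")
  expect_false("G002" %in% selectVariableGenes(nl, 199))
  expect_error(selectVariableGenes(nl, 0), "positive")
})

test_that("gene filter union respects matrix order and drops absent genes", {
  mat_genes <- c("A", "B", "C", "D")
  expect_equal(geneFilterUnion(c("A", "B"), c("B", "C"), mat_genes),
               c("A", "B", "C"))
  expect_message(out <- geneFilterUnion("A", c("B", "ZZZ"), mat_genes),
                 "1 immune gene")
  expect_equal(out, c("A", "B"))
  expect_equal(geneFilterUnion("D", "A", mat_genes), c("A", "D"))
})

test_that("gene scaling: population-sd formula, constant genes, idempotence", {
  Y <- matrix(c(1, 2, 3), 1, dimnames = list("G1", c("a", "b", "c")))
  S <- scaleGenes(Y)
  expect_equal(as.numeric(S), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_warning(S0 <- scaleGenes(matrix(5, 1, 3)), "constant")
  expect_equal(as.numeric(S0), c(0, 0, 0))
  set.seed(5)
  Y2 <- matrix(rnorm(50), 5, 10)
  S1 <- scaleGenes(Y2)
  expect_equal(scaleGenes(S1), S1, tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(S1))), 1e-8)
  expect_equal(unname(sqrt(rowMeans(S1^2))), rep(1, 5), tolerance = 1e-12)
})

test_that("PCA embedding recovers a planted rank-1 factor with fixed sign and ordered variance", {
  set.seed(6)
  u <- rnorm(60); v <- rnorm(25)
  X <- tcrossprod(v, u) + matrix(rnorm(25 * 60, sd = 1e-3), 25, 60)
  dimnames(X) <- list(sprintf("G%02d", 1:25), sprintf("C%02d", 1:60))
  pc <- pcaEmbed(X, 5)
  cs <- abs(cor(pc$scores[, 1], u))
  expect_gt(cs, 0.999)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  ## sign convention: largest-magnitude loading positive
  for (j in 1:5)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  expect_equal(ncol(pcaEmbed(X, 10)$scores), 10)
  expect_error(pcaEmbed(X, 26), "exceeds")
})
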