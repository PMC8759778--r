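test_that("balanced downsampling equalizes sample sizes deterministically", {
  set.seed(1)
  labels <- rep(c("s1", "s2", "s3"), c(100, 50, 80))
  bcs <- sprintf("C%03d", seq_along(labels))
  out <- balancedDownsample(bcs, labels, seed = 11)
  expect_equal(length(out), 150)
  expect_true(all(table(labels[match(out, bcs)]) == 50))
  expect_identical(out, balancedDownsample(bcs, labels, seed = 11))
  ## equal sizes: the full set comes back
  out2 <- balancedDownsample(bcs[1:60], rep(c("a", "b"), each = 30), seed = 1)
  expect_setequal(out2, bcs[1:60])
})

test_that("soft thresholding matches its closed form", {
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(-0.5, 1), 0)
  expect_equal(softThreshold(-3, 1), -2)
  a <- seq(-2, 2, by = 0.25)
  expect_equal(softThreshold(a, 0.5), sign(a) * pmax(abs(a) - 0.5, 0))
})

test_that("sparse PCA recovers a planted sparse rank-1 factor", {
  set.seed(2)
  n <- 80; p <- 40
  v <- rep(0, p); v[c(3, 9, 17, 25, 33)] <- 1 / sqrt(5)
  u <- rnorm(n); u <- u / sqrt(sum(u^2))
  X <- 6 * tcrossprod(u, v) + matrix(rnorm(n * p, sd = 1e-3), n, p)
  X <- sweep(X, 2, colMeans(X))
  colnames(X) <- sprintf("G%02d", 1:p)
  fit <- sparsePca(X, n_components = 1, c = sqrt(5))
  vhat <- moduleLoadings(fit)[, 1]
  expect_setequal(which(vhat != 0), c(3, 9, 17, 25, 33))
  expect_gt(abs(sum(vhat * v)), 0.999)
})

test_that("with a slack L1 budget the first component matches dense PCA", {
  set.seed(3)
  X <- matrix(rnorm(60 * 12), 60, 12) %*% diag(c(6, 3, rep(1, 10)))
  X <- sweep(X, 2, colMeans(X))
  colnames(X) <- sprintf("G%02d", 1:12)
  fit <- sparsePca(X, n_components = 2, c = sqrt(12))
  dense <- eigen(crossprod(X))$vectors[, 1]
  cosang <- abs(sum(moduleLoadings(fit)[, 1] * dense))
  expect_gt(cosang, 0.999)
  expect_gt(moduleD(fit)[1], moduleD(fit)[2])
})

test_that("sparse PCA enforces its constraints and rejects non-centered input", {
  set.seed(4)
  X <- sweep(matrix(rnorm(50 * 20), 50, 20), 2, colMeans(matrix(0, 1, 20)))
  X <- sweep(X, 2, colMeans(X))
  colnames(X) <- sprintf("G%02d", 1:20)
  fit <- sparsePca(X, n_components = 4, c = 2)
  L <- moduleLoadings(fit)
  expect_equal(unname(sqrt(colSums(L^2))), rep(1, 4), tolerance = 1e-8)
  expect_true(all(colSums(abs(L)) <= 2 + 1e-6))
  expect_error(sparsePca(X + 5, 2, c = 2), "not centered")
  expect_error(sparsePca(X, 2, c = 0.5), "outside")
})

test_that("alternating objective is non-decreasing within a component", {
  ## re-run the u/v alternation by hand on a random matrix and track u'Xv
  set.seed(5)
  X <- matrix(rnorm(40 * 15), 40, 15)
  X <- sweep(X, 2, colMeans(X))
  cbud <- 2.2
  v <- rep(1 / sqrt(15), 15)
  obj <- numeric()
  for (it in 1:25) {
    u <- drop(X %*% v); u <- u / sqrt(sum(u^2))
    a <- drop(crossprod(X, u))
    l1 <- function(lam) { w <- softThreshold(a, lam); s <- sqrt(sum(w^2))
                          if (s == 0) 0 else sum(abs(w)) / s }
    lo <- 0; hi <- max(abs(a))
    if (l1(0) > cbud) for (i in 1:60) { mid <- (lo + hi) / 2
      if (l1(mid) > cbud) lo <- mid else hi <- mid }
    v <- softThreshold(a, hi); v <- v / sqrt(sum(v^2))
    obj <- c(obj, drop(crossprod(u, X %*% v)))
  }
  expect_true(all(diff(obj) > -1e-8))
})

test_that("module scores are the exact product with the loadings and linear", {
  set.seed(6)
  S <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(sprintf("G%d", 1:8),
                                                    sprintf("C%02d", 1:30)))
  L <- matrix(0, 8, 3, dimnames = list(rownames(S), NULL))
  L[2, 1] <- 1                       # one-hot
  L[c(1, 5), 2] <- c(0.6, 0.8)
  mods <- methods::new("GeneModuleSet", loadings = L, d = c(1, 1, 0),
                       l1Budget = 2, labels = paste0("m", 1:3))
  sc <- scoreModules(S, mods)
  expect_equal(unname(sc[, 1]), unname(S[2, ]))
  expect_equal(unname(sc[, 3]), rep(0, 30))
  expect_equal(sc[, 1] + sc[, 2],
               drop(crossprod(S, L[, 1] + L[, 2])), tolerance = 1e-10)
  expect_error(scoreModules(S[8:1, ], mods), "do not match")
})

test_that("negative-control threshold is the round(fpr N)-th order statistic", {
  th <- computeExpressionThreshold(1:1000, fpr = 0.002)
  expect_equal(th$k, 2L)
  expect_equal(th$threshold, 999)
  expect_equal(mean(1:1000 >= th$threshold), 0.002)
  ## degenerate all-equal scores: everything expresses, with a tie message
  expect_message(thc <- computeExpressionThreshold(rep(1.5, 600), fpr = 0.002),
                 "ties")
  expect_equal(thc$threshold, 1.5)
  ## fixed-threshold variant ignores the negatives (Treg rule)
  thf <- computeExpressionThreshold(rnorm(100), method = "fixed", fixed = 2.0)
  expect_equal(thf$threshold, 2.0)
  expect_error(computeExpressionThreshold(numeric(0)), "empty")
  expect_error(computeExpressionThreshold(1:100, fpr = 0), "fpr")
  expect_warning(computeExpressionThreshold(1:100, fpr = 0.002), "recommend")
})

test_that("expression calls use >= and are monotone in the score", {
  sc <- matrix(c(1.9, 2.0, 2.1), 3, 1, dimnames = list(NULL, "m1"))
  thr <- data.frame(module = "m1", threshold = 2.0, method = "fpr_quantile",
                    fpr = 0.002)
  e <- classifyExpressing(sc, thr)
  expect_equal(as.vector(e), c(FALSE, TRUE, TRUE))
  e2 <- classifyExpressing(sc + 0.5, thr)
  expect_true(all(e2 >= e))
  expect_error(classifyExpressing(matrix(1, 1, 1, dimnames = list(NULL, "mX")),
                                  thr), "missing threshold")
})

test_that("patient-dominance filter removes modules at or above the 60% share", {
  mk <- function(shares) {
    n <- 100
    e <- matrix(TRUE, n, 1, dimnames = list(NULL, "m1"))
    pat <- rep(paste0("P", seq_along(shares)), round(shares * n))
    list(e = e[seq_along(pat), , drop = FALSE], pat = pat)
  }
  f <- function(shares) {
    x <- mk(shares)
    patientDominanceFilter(x$e, x$pat)$retained
  }
  expect_false(f(c(0.70, 0.30)))
  expect_true(f(c(0.50, 0.50)))
  expect_false(f(c(0.60, 0.40)))          # boundary: "at least 60%"
  ## zero expressing cells: removed with its own reason
  e0 <- matrix(FALSE, 10, 1, dimnames = list(NULL, "m1"))
  r <- patientDominanceFilter(e0, rep("P1", 10))
  expect_false(r$retained)
  expect_equal(r$reason, "no_expressing_cells")
})
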