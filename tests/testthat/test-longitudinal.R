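test_that("module clones require one expressing activated cell at any time point", {
  cells <- data.frame(
    barcode = sprintf("C%d", 1:6),
    clone_key = c("A", "A", "B", "B", "C", "D"),
    subset = c("CD154", "CD154", "CD137", "CD154", "DN", "CD154"))
  expr <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  out <- defineModuleClones(cells, expr)
  expect_equal(out, "A")                    # one expressing cell suffices
  ## DN expression does not qualify; monotone under adding expressing cells
  expr2 <- expr; expr2[4] <- TRUE
  expect_equal(defineModuleClones(cells, expr2), c("A", "B"))
})

test_that("clone trajectory means are grouped by patient and phase, missing stays missing", {
  cells <- data.frame(
    barcode = sprintf("C%d", 1:6), clone_key = "A",
    patient_id = "P01",
    time_point = c("BL", "BL", "MN", "MN", "AV", "AV"))
  sc <- c(2, 2, 1, 1, 3, 5)
  tr <- cloneModuleTrajectory(cells, sc, "A")
  expect_equal(tr$mean_score[tr$time_point == "BL"], 2)
  expect_equal(tr$mean_score[tr$time_point == "MN"], 1)
  expect_false("BU" %in% tr$time_point)     # missing phase absent, not zero
  ## adding a cell at the mean leaves the mean unchanged
  cells2 <- rbind(cells, data.frame(barcode = "C7", clone_key = "A",
                                    patient_id = "P01", time_point = "AV"))
  tr2 <- cloneModuleTrajectory(cells2, c(sc, 4), "A")
  expect_equal(tr2$mean_score[tr2$time_point == "AV"], 4)
})

test_that("fractional clonal expression enforces the 2-cell eligibility rule", {
  cells <- data.frame(
    barcode = sprintf("C%d", 1:7),
    clone_key = c("A", "A", "A", "A", "A", "B", "A"),
    patient_id = "P01",
    time_point = c("BL", "BL", "BL", "BL", "BU", "BL", "MN"),
    subset = c(rep("CD154", 6), "CD137"))
  expr <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fr <- fractionalClonalExpression(cells, expr, c(A = "Th2A-like", B = "Th17"))
  expect_equal(fr$fraction[fr$clone_key == "A" & fr$time_point == "BL"], 0.5)
  ## single-cell time points (A at BU, A at MN, B at BL) are excluded
  expect_false(any(fr$time_point %in% c("BU", "MN")))
  expect_false("B" %in% fr$clone_key)
  expect_equal(fr$subtype[fr$clone_key == "A"], "Th2A-like")
  ## all expressing yields 1
  fr2 <- fractionalClonalExpression(cells, rep(TRUE, 7), c(A = "x", B = "y"))
  expect_equal(fr2$fraction, 1)
})

test_that("temporal patterns require 4 cells within the sorted subset", {
  cells <- data.frame(
    clone_key = c(rep("A", 4), rep("B", 3), rep("C", 5)),
    time_point = c("BL", "BL", "MN", "MN", "BL", "BU", "MN", rep("BL", 4), "AV"),
    subset = "CD154")
  tp <- temporalPattern(cells, "CD154", min_cells = 4)
  expect_setequal(tp$clone_key, c("A", "C"))    # B has only 3 cells
  expect_equal(tp$pattern[tp$clone_key == "A"], "BL+MN")
  expect_equal(tp$pattern[tp$clone_key == "C"], "BL+AV")
})

test_that("suppression ratio is maintenance over buildup with NA propagation", {
  tr <- data.frame(patient_id = rep(c("P01", "P02", "P03"), each = 2),
                   time_point = rep(c("BU", "MN"), 3),
                   n_cells = 4,
                   mean_score = c(2, 1, 3, 3, 2, NA))
  tr <- tr[!is.na(tr$mean_score), ]
  r <- suppressionRatio(tr)
  expect_equal(r[["P01"]], 0.5)
  expect_equal(r[["P02"]], 1.0)
  expect_true(is.na(r[["P03"]]))            # missing MN
  ## near-zero denominator is flagged missing
  tr0 <- data.frame(patient_id = "P04", time_point = c("BU", "MN"),
                    n_cells = 2, mean_score = c(1e-12, 1))
  expect_true(is.na(suppressionRatio(tr0)[["P04"]]))
})

test_that("Spearman outcome correlation uses the 2/1/0 coding and average ranks", {
  ## untied outcomes: strict monotone values give rho exactly +/-1
  oc1 <- c(P1 = "TO", P3 = "PT", P4 = "TF", P5 = "PL")
  v1 <- c(P1 = 4, P3 = 2, P4 = 1, P5 = 100)            # placebo ignored
  out <- spearmanOutcome(v1, oc1)
  expect_equal(out$rho, 1)
  expect_equal(out$n, 3)
  expect_equal(spearmanOutcome(-v1, oc1)$rho, -1)
  ## tied outcome group: equals Pearson on average ranks (brute force)
  oc <- c(P1 = "TO", P2 = "TO", P3 = "PT", P4 = "TF", P5 = "PL")
  v3 <- c(P1 = 5, P2 = 1, P3 = 3, P4 = 2)
  out3 <- spearmanOutcome(v3, oc)
  rx <- rank(v3); ry <- rank(c(2, 2, 1, 0))
  expect_equal(out3$rho, cor(rx, ry))
  expect_error(spearmanOutcome(v1[1:2], oc1), "fewer than 3")
})

test_that("baseline PCA signature: planted direction, exact projection, constant module", {
  set.seed(31)
  pts <- sprintf("P%02d", 1:8)
  dir <- c(m1 = 3, m2 = -1, m3 = 0.5, m4 = 0)
  strength <- seq(-2, 2, length.out = 8)
  rows <- list()
  for (tp in c("BL", "MN")) for (i in seq_along(pts)) {
    vals <- strength[i] * dir + rnorm(4, sd = 0.01)
    vals["m4"] <- 7                          # constant module column
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = pts[i], time_point = tp, module = names(dir),
      mean_score = unname(vals))
  }
  means <- do.call(rbind, rows)
  sig <- baselineModulePca(means)
  cosang <- abs(sum(sig$loadings * dir / sqrt(sum(dir^2))))
  expect_gt(cosang, 0.99)
  expect_lt(abs(sig$loadings[["m4"]]), 0.05) # constant column ~ zero loading
  ## projecting baseline rows reproduces the fitted scores exactly
  bl <- sig$scores[sig$scores$time_point == "BL", ]
  M <- matrix(means$mean_score[means$time_point == "BL"], nrow = 8, byrow = TRUE)
  refit <- sweep(M, 2, sig$center) %*% sig$loadings
  expect_equal(unname(bl$pc1), unname(drop(refit)), tolerance = 1e-10)
  ## PC1 score ranks patients by planted strength at both time points
  for (tp in c("BL", "MN")) {
    s <- sig$scores[sig$scores$time_point == tp, ]
    expect_gt(abs(cor(s$pc1, strength, method = "spearman")), 0.95)
  }
})

test_that("IgE-gene correlation: exact tracking gene, unit invariance, null control", {
  set.seed(32)
  n_samp <- 12
  meta <- data.frame(barcode = sprintf("C%03d", 1:(n_samp * 5)),
                     patient_id = rep(sprintf("P%02d", 1:4), each = 15),
                     time_point = rep(rep(c("BL", "BU", "MN"), each = 5), 4))
  titer <- data.frame(patient_id = rep(sprintf("P%02d", 1:4), each = 3),
                      time_point = rep(c("BL", "BU", "MN"), 4),
                      ige_kU_L = exp(rnorm(12, 3, 1)))
  G <- 40
  X <- matrix(rexp(G * nrow(meta)), G, nrow(meta),
              dimnames = list(sprintf("G%03d", 1:G), meta$barcode))
  ## G001 average tracks the titer exactly
  key <- paste(meta$patient_id, meta$time_point)
  X["G001", ] <- titer$ige_kU_L[match(key, paste(titer$patient_id, titer$time_point))]
  out <- igeGeneCorrelation(X, meta, titer)
  expect_equal(out$rho[out$gene == "G001"], 1)
  ## titer unit change leaves every rho unchanged
  titer2 <- transform(titer, ige_kU_L = ige_kU_L * 2)
  out2 <- igeGeneCorrelation(X, meta, titer2)
  expect_equal(out$rho, out2$rho)
  ## independent noise genes essentially never reach adjusted significance
  expect_lte(sum(out$p_adj[out$gene != "G001"] < 0.05), 1)
})

test_that("Wilcoxon wrappers: exact enumeration at complete separation, paired extreme", {
  x <- 1:10; y <- 11:20
  out <- wilcoxonTest(x, y)
  expect_equal(out$p, 2 / choose(20, 10))   # exact two-sided enumeration
  ## paired, all differences positive: one of the two extreme outcomes
  d <- wilcoxonTest(1:10 + 1:10, 1:10, paired = TRUE)
  expect_equal(d$p, 2 / 2^10)
  ## identical groups
  same <- wilcoxonTest(c(1, 2, 3, 4), c(1, 2, 3, 4), paired = TRUE)
  expect_true(is.na(same$p) || same$p > 0.99)
  ## Bonferroni family scaling
  out2 <- wilcoxonTest(x, y, family_size = 5)
  expect_equal(out2$p_adj, 5 * out2$p)
  expect_error(wilcoxonTest(1:2, 3:4), "fewer than 3")
})
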