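test_that("count matrix round-trips through MatrixMarket in both orientations", {
  m <- tinyCounts(matrix(c(0, 3, 2, 0, 5, 1), nrow = 3))
  for (orient in c("genes_x_cells", "cells_x_genes")) {
    d <- withr::local_tempdir()
    p <- file.path(d, c("m.mtx", "g.tsv", "b.tsv"))
    writeCounts(m, p[1], p[2], p[3], orientation = orient)
    m2 <- readCounts(p[1], p[2], p[3], orientation = orient)
    expect_identical(as.matrix(m2), as.matrix(m))
    expect_identical(dimnames(m2), dimnames(m))
  }
})

test_that("readCounts rejects malformed inputs with informative errors", {
  d <- withr::local_tempdir()
  p <- file.path(d, c("m.mtx", "g.tsv", "b.tsv"))
  m <- tinyCounts(matrix(c(1, 2, 3, 4), 2))
  writeCounts(m, p[1], p[2], p[3])
  ## barcode count mismatch
  writeLines(c("C01", "C02", "C03"), p[3])
  expect_error(readCounts(p[1], p[2], p[3]), "3 entries.*2 cells")
  writeLines(c("C01", "C02"), p[3])
  ## negative entry, named by coordinate
  neg <- Matrix::Matrix(matrix(c(1, -2, 3, 4), 2), sparse = TRUE)
  Matrix::writeMM(neg, p[1])
  expect_error(readCounts(p[1], p[2], p[3]), "negative count at gene 2, cell 1")
  ## duplicate gene symbols after case folding
  writeCounts(m, p[1], p[2], p[3])
  writeLines(c("actb", "ACTB"), p[2])
  expect_error(readCounts(p[1], p[2], p[3]), "duplicate gene symbols")
})

test_that("metadata reader validates enums and per-patient outcome consistency", {
  d <- withr::local_tempdir()
  f <- file.path(d, "meta.tsv")
  ok <- tinyMeta(c("C01", "C02"), tp = "MN")
  write.table(ok, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(readCellMetadata(f)$time_point, c("MN", "MN"))

  bad <- ok; bad$time_point <- c("MN", "week12")
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readCellMetadata(f), "week12.*allowed.*BL")

  bad <- ok; bad$outcome <- c("TO", "TF")
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readCellMetadata(f), "inconsistent outcomes")

  bad <- ok[, names(ok) != "subset"]
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readCellMetadata(f), "missing column.*subset")
})

test_that("TCR reader normalizes CDR3 case and rejects bad records", {
  d <- withr::local_tempdir()
  f <- file.path(d, "tcr.tsv")
  ok <- tinyTcr("C01", cdr3 = "casslf")
  write.table(ok, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(readTcrTable(f)$cdr3_aa, "CASSLF")

  bad <- ok; bad$cdr3_aa <- "CASS1F"
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readTcrTable(f), "non-amino-acid")

  bad <- ok; bad$chain <- "TRG"
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readTcrTable(f), "TRG.*allowed.*TRA")
})

test_that("buildCohort enforces barcode containment and tolerates partial TCR", {
  m <- tinyCounts(matrix(1:20, 4), barcodes = sprintf("C%02d", 1:5))
  meta <- tinyMeta(sprintf("C%02d", 1:5))
  tcr <- tinyTcr(c("C01", "C02", "C03"))
  ch <- buildCohort(m, meta, tcr)
  expect_s4_class(ch, "Cohort")
  expect_equal(nCells(ch), 5)
  expect_equal(nrow(tcrTable(ch)), 3)     # 60% coverage retained, no error

  expect_error(buildCohort(m, meta, tinyTcr("C99")), "absent from count matrix")
  expect_error(buildCohort(m, tinyMeta(c(sprintf("C%02d", 1:5), "C99"))),
               "absent from count matrix")
  ## empty TCR table is a valid cohort
  ch0 <- buildCohort(m, meta)
  expect_equal(nrow(tcrTable(ch0)), 0)
  ## matrix cells without metadata are dropped, with a message
  expect_message(ch2 <- buildCohort(m, meta[1:3, ], tcr), "dropping 2")
  expect_equal(nCells(ch2), 3)
})

test_that("subsetCohort slices consistently, errors on empty selection, and commutes", {
  m <- tinyCounts(matrix(rpois(40, 4), 4), barcodes = sprintf("C%02d", 1:10))
  meta <- tinyMeta(sprintf("C%02d", 1:10),
                   patient = rep(c("P01", "P02"), 5),
                   subset = rep(c("CD154", "DN"), each = 5))
  meta$outcome <- ifelse(meta$patient_id == "P01", "TO", "PL")
  tcr <- tinyTcr(c("C01", "C06"))
  ch <- buildCohort(m, meta, tcr)

  s <- subsetCohort(ch, subset == "CD154")
  expect_true(all(cellMeta(s)$subset == "CD154"))
  expect_equal(colnames(cohortCounts(s)), cellMeta(s)$barcode)
  expect_true(all(tcrTable(s)$barcode %in% cellMeta(s)$barcode))
  expect_error(subsetCohort(ch, patient_id == "P99"), "zero cells")

  ab <- subsetCohort(subsetCohort(ch, subset == "CD154"), patient_id == "P01")
  ba <- subsetCohort(subsetCohort(ch, patient_id == "P01"), subset == "CD154")
  expect_identical(cellMeta(ab), cellMeta(ba))
  expect_identical(as.matrix(cohortCounts(ab)), as.matrix(cohortCounts(ba)))
})

test_that("subsetCohort preserves Cohort validity on random predicates", {
  set.seed(7)
  m <- tinyCounts(matrix(rpois(200, 3), 10), barcodes = sprintf("C%02d", 1:20))
  meta <- tinyMeta(sprintf("C%02d", 1:20),
                   patient = sample(c("P01", "P02", "P03"), 20, replace = TRUE),
                   tp = sample(c("BL", "MN"), 20, replace = TRUE))
  meta$outcome <- c(P01 = "TO", P02 = "PT", P03 = "TF")[meta$patient_id]
  ch <- buildCohort(m, meta, tinyTcr(sample(meta$barcode, 8)))
  for (i in 1:20) {
    keep <- runif(20) < runif(1, 0.2, 0.9)
    if (!any(keep)) next
    s <- subsetCohort(ch, keep = keep)
    expect_true(methods::validObject(s))
    expect_equal(nCells(s), sum(keep))
  }
})
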