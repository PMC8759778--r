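## small in-code fixtures shared across test files

tinyCounts <- function(values, genes = NULL, barcodes = NULL) {
  m <- Matrix::Matrix(values, sparse = TRUE)
  m <- methods::as(m, "CsparseMatrix")
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(barcodes)) barcodes <- sprintf("C%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, barcodes)
  m
}

tinyMeta <- function(barcodes, patient = "P01", tp = "BL", subset = "CD154",
                     outcome = "TO") {
  data.frame(barcode = barcodes, patient_id = patient, time_point = tp,
             subset = subset, outcome = outcome, stringsAsFactors = FALSE)
}

tinyTcr <- function(barcode, chain = "TRB", cdr3 = "CASSLF",
                    v = "TRBV9", j = "TRBJ1-1",
                    v_support = NULL, j_support = NULL) {
  data.frame(barcode = barcode, chain = chain, v_call = v, j_call = j,
             v_support = v_support %||% paste0(v, ":10"),
             j_support = j_support %||% paste0(j, ":10"),
             cdr3_aa = cdr3, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## independent oracle: minimum-penalty gapped CDR3 distance by exhaustive
## enumeration of all order-preserving placements of the shorter sequence
bruteTcrdist <- function(a, b) {
  P <- cdr3PenaltyMatrix()
  aa <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
  if (length(aa) > length(bb)) { tmp <- aa; aa <- bb; bb <- tmp }
  m <- length(aa); n <- length(bb)
  best <- Inf
  for (sel in utils::combn(n, m, simplify = FALSE)) {
    cost <- sum(P[cbind(match(aa, rownames(P)), match(bb[sel], rownames(P)))])
    best <- min(best, cost)
  }
  best + 8 * (n - m)
}

randomCdr3ForTest <- function(len) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

immuneListOf <- function(sim) {
  unique(c(unlist(sim$truth$modules), unlist(sim$truth$markers)))
}
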