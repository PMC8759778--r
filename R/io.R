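#' Read a UMI count matrix from MatrixMarket + sidecar TSVs
#'
#' Reads a coordinate-format MatrixMarket file together with one-column
#' gene and barcode files and returns a validated sparse count matrix in
#' the internal genes x cells orientation.  The on-disk orientation is
#' declared, not guessed.
#'
#' @param matrix_path path to the .mtx coordinate file
#' @param genes_path one gene symbol per line
#' @param barcodes_path one cell barcode per line
#' @param orientation on-disk orientation, \code{"genes_x_cells"} (default)
#'   or \code{"cells_x_genes"}
#' @return sparse dgCMatrix, genes x cells, with dimnames
#' @export
readCounts <- function(matrix_path, genes_path, barcodes_path,
                       orientation = c("genes_x_cells", "cells_x_genes")) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(matrix_path)
  if (orientation == "cells_x_genes") m <- Matrix::t(m)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(m) != length(genes))
    .stopf("gene file has %d entries but matrix has %d gene rows",
           length(genes), nrow(m))
  if (ncol(m) != length(barcodes))
    .stopf("barcode file has %d entries but matrix has %d cells",
           length(barcodes), ncol(m))
  if (anyDuplicated(barcodes)) .stopf("duplicate barcodes in %s", barcodes_path)
  if (anyDuplicated(toupper(genes)))
    .stopf("duplicate gene symbols after case-folding in %s", genes_path)
  if (length(m@x)) {
    neg <- which(m@x < 0)
    if (length(neg)) {
      ij <- Matrix::which(m < 0, arr.ind = TRUE)
      .stopf("negative count at gene %d, cell %d", ij[1, 1], ij[1, 2])
    }
    if (any(m@x != round(m@x))) .stopf("non-integer entries in count matrix")
  }
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a count matrix in the format readCounts() expects
#'
#' @param counts genes x cells sparse matrix with dimnames
#' @param matrix_path,genes_path,barcodes_path output paths
#' @param orientation on-disk orientation to emit
#' @export
writeCounts <- function(counts, matrix_path, genes_path, barcodes_path,
                        orientation = c("genes_x_cells", "cells_x_genes")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "cells_x_genes") Matrix::t(counts) else counts
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), matrix_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(matrix_path)
}

#' Read per-cell metadata
#'
#' Tab-separated with header; required columns \code{barcode},
#' \code{patient_id}, \code{time_point}, \code{subset}, \code{outcome}.
#' Time points are BL (baseline), BU (buildup), MN (maintenance),
#' AV (avoidance); subsets CD154/CD137/DN; outcomes TO (tolerance),
#' PT (partial tolerance), TF (treatment failure), PL (placebo).
#'
#' @param path TSV path
#' @return validated data.frame
#' @export
readCellMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "patient_id", "time_point", "subset", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$barcode)) .stopf("duplicate barcode in metadata")
  .checkEnum(df$time_point, TIME_POINTS, "time_point")
  .checkEnum(df$subset, SUBSETS, "subset")
  .checkEnum(df$outcome, OUTCOMES, "outcome")
  tab <- unique(df[, c("patient_id", "outcome")])
  if (anyDuplicated(tab$patient_id)) {
    bad <- tab$patient_id[duplicated(tab$patient_id)][1]
    .stopf("patient %s has inconsistent outcomes across cells", bad)
  }
  df[need]
}

#' Read a per-cell TCR chain table
#'
#' Tab-separated with header; columns \code{barcode}, \code{chain}
#' (TRA/TRB), \code{v_call}, \code{j_call}, \code{v_support},
#' \code{j_support} (serialized \code{"CALL:reads;CALL:reads"}) and
#' \code{cdr3_aa}.  CDR3 sequences are upper-cased and validated against
#' the 20-letter amino-acid alphabet.
#'
#' @param path TSV path
#' @return validated data.frame
#' @export
readTcrTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "chain", "v_call", "j_call",
            "v_support", "j_support", "cdr3_aa")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("TCR table missing column(s): %s", paste(miss, collapse = ", "))
  .checkEnum(df$chain, TCR_CHAINS, "chain")
  df$cdr3_aa <- toupper(df$cdr3_aa)
  ok <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), df$cdr3_aa)
  if (!all(ok))
    .stopf("CDR3 with non-amino-acid characters: %s", df$cdr3_aa[!ok][1])
  df[need]
}

#' Read per-(patient, time point) allergen-specific IgE titers
#' @param path CSV with columns patient_id, time_point, ige_kU_L
#' @export
readIge <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_point", "ige_kU_L")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("IgE table missing column(s): %s", paste(miss, collapse = ", "))
  .checkEnum(df$time_point, TIME_POINTS, "time_point")
  df[need]
}

#' Assemble a validated Cohort
#'
#' Barcodes are the sole join key.  Cells present in the count matrix but
#' absent from the metadata are dropped with a logged count (sorted-subset
#' exports commonly omit cells); a metadata barcode missing from the matrix
#' is an error.  Cells without TCR records are retained: chain recovery is
#' partial by design.
#'
#' @param counts genes x cells matrix from \code{readCounts}
#' @param meta data.frame from \code{readCellMetadata}
#' @param tcr optional data.frame from \code{readTcrTable}
#' @param ige optional data.frame from \code{readIge}
#' @return a \code{Cohort}
#' @export
buildCohort <- function(counts, meta, tcr = NULL, ige = NULL) {
  if (is.null(tcr)) tcr <- data.frame(barcode = character(), chain = character(),
    v_call = character(), j_call = character(), v_support = character(),
    j_support = character(), cdr3_aa = character())
  if (is.null(ige)) ige <- data.frame(patient_id = character(),
    time_point = character(), ige_kU_L = numeric())
  missing_from_matrix <- setdiff(meta$barcode, colnames(counts))
  if (length(missing_from_matrix))
    .stopf("%d metadata barcode(s) absent from count matrix (e.g. %s)",
           length(missing_from_matrix), missing_from_matrix[1])
  drop <- setdiff(colnames(counts), meta$barcode)
  if (length(drop)) {
    .msgf("dropping %d matrix cell(s) without metadata", length(drop))
    counts <- counts[, colnames(counts) %in% meta$barcode, drop = FALSE]
  }
  bad_tcr <- setdiff(tcr$barcode, colnames(counts))
  if (length(bad_tcr))
    .stopf("%d TCR barcode(s) absent from count matrix (e.g. %s)",
           length(bad_tcr), bad_tcr[1])
  methods::new("Cohort", counts = counts, meta = meta, tcr = tcr, ige = ige)
}

#' Subset a Cohort by a predicate over its metadata
#'
#' All components (counts, metadata, TCR records) are sliced consistently.
#' IgE entries are restricted to the surviving (patient, time point) pairs.
#'
#' @param cohort a \code{Cohort}
#' @param expr unquoted logical expression over metadata columns, e.g.
#'   \code{subset == "CD154"}
#' @param keep alternatively, a logical vector over metadata rows
#' @return a \code{Cohort}; error if no cell matches
#' @export
subsetCohort <- function(cohort, expr, keep = NULL) {
  meta <- cohort@meta
  if (is.null(keep)) {
    keep <- eval(substitute(expr), meta, parent.frame())
  }
  if (!is.logical(keep) || length(keep) != nrow(meta))
    .stopf("predicate must yield one logical per metadata row")
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) .stopf("predicate selects zero cells")
  meta2 <- meta[keep, , drop = FALSE]
  counts2 <- cohort@counts[, meta2$barcode, drop = FALSE]
  tcr2 <- cohort@tcr[cohort@tcr$barcode %in% meta2$barcode, , drop = FALSE]
  obs <- unique(paste(meta2$patient_id, meta2$time_point))
  ige2 <- cohort@ige[paste(cohort@ige$patient_id, cohort@ige$time_point) %in% obs, ,
                     drop = FALSE]
  methods::new("Cohort", counts = counts2, meta = meta2, tcr = tcr2, ige = ige2)
}
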