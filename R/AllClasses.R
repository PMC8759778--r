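#' @import methods
#' @importFrom Matrix Matrix readMM writeMM t colSums rowSums
NULL

## Closed vocabularies for the cohort design: four treatment phases, three
## sorted subsets (CD154+ activated effectors, CD137+ regulatory-like,
## CD154-CD137- negative control), four clinical outcomes.
TIME_POINTS <- c("BL", "BU", "MN", "AV")
SUBSETS     <- c("CD154", "CD137", "DN")
OUTCOMES    <- c("TO", "PT", "TF", "PL")
TCR_CHAINS  <- c("TRA", "TRB")
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")

#' Cohort: joined single-cell expression, metadata and TCR data
#'
#' The universal input object of the pipeline: a UMI count matrix (genes x
#' cells), per-cell metadata (patient, treatment phase, sorted subset,
#' clinical outcome), an optional per-cell TCR chain table and optional
#' per-(patient, time point) allergen-specific IgE titers.
#'
#' Counts are stored genes x cells (column = cell), the Bioconductor
#' orientation; reader functions accept either on-disk orientation.
#'
#' @slot counts sparse non-negative integer matrix, genes x cells, with
#'   unique gene symbols as rownames and unique cell barcodes as colnames.
#' @slot meta data.frame with columns \code{barcode}, \code{patient_id},
#'   \code{time_point} (BL/BU/MN/AV), \code{subset} (CD154/CD137/DN),
#'   \code{outcome} (TO/PT/TF/PL).
#' @slot tcr data.frame of per-cell chain records (may be empty): columns
#'   \code{barcode}, \code{chain} (TRA/TRB), \code{v_call}, \code{j_call},
#'   \code{v_support}, \code{j_support} (serialized \code{"CALL:reads;..."}),
#'   \code{cdr3_aa}.
#' @slot ige data.frame with columns \code{patient_id}, \code{time_point},
#'   \code{ige_kU_L}; may be empty.
#'
#' @exportClass Cohort
setClass("Cohort",
  representation(counts = "Matrix", meta = "data.frame",
                 tcr = "data.frame", ige = "data.frame"))

setValidity("Cohort", function(object) {
  msg <- character()
  cts <- object@counts
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must carry gene rownames and barcode colnames")
  else {
    if (anyDuplicated(colnames(cts)))
      msg <- c(msg, "duplicate cell barcodes in counts")
    if (anyDuplicated(toupper(rownames(cts))))
      msg <- c(msg, "duplicate gene symbols (case-insensitive) in counts")
  }
  if (length(cts@x) && min(cts@x) < 0)
    msg <- c(msg, "negative entries in counts")
  if (nrow(object@meta)) {
    bad <- setdiff(object@meta$barcode, colnames(cts))
    if (length(bad))
      msg <- c(msg, sprintf("%d metadata barcodes absent from counts (e.g. %s)",
                            length(bad), bad[1]))
    if (anyDuplicated(object@meta$barcode))
      msg <- c(msg, "duplicate barcodes in metadata")
    tab <- unique(object@meta[, c("patient_id", "outcome")])
    if (anyDuplicated(tab$patient_id))
      msg <- c(msg, "a patient carries more than one clinical outcome")
  }
  if (nrow(object@tcr)) {
    bad <- setdiff(object@tcr$barcode, colnames(cts))
    if (length(bad))
      msg <- c(msg, sprintf("%d TCR barcodes absent from counts (e.g. %s)",
                            length(bad), bad[1]))
  }
  if (nrow(object@ige) && nrow(object@meta)) {
    obs <- unique(paste(object@meta$patient_id, object@meta$time_point))
    key <- paste(object@ige$patient_id, object@ige$time_point)
    if (!all(key %in% obs))
      msg <- c(msg, "IgE keys outside observed (patient, time point) pairs")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Cohort compact description of the object
#' @param object a \code{Cohort}
#' @export
setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d genes x %d cells\n",
              nrow(object@counts), ncol(object@counts)))
  if (nrow(object@meta)) {
    cat(sprintf("  patients: %d | time points: %s | subsets: %s\n",
                length(unique(object@meta$patient_id)),
                paste(intersect(TIME_POINTS, object@meta$time_point), collapse = ","),
                paste(intersect(SUBSETS, object@meta$subset), collapse = ",")))
  }
  cat(sprintf("  TCR records: %d (%d cells) | IgE entries: %d\n",
              nrow(object@tcr),
              length(unique(object@tcr$barcode)),
              nrow(object@ige)))
})

#' Sparse gene modules from penalized PCA
#'
#' Holds the sparse loading vectors ("v") found by L1-penalized PCA, one
#' column per module, plus the per-component singular values d and the L1
#' budget used.  Every nonzero loading column has unit L2 norm and L1 norm
#' at most the budget.
#'
#' @slot loadings numeric matrix, genes x modules, with gene rownames.
#' @slot d numeric vector of per-component singular values.
#' @slot l1Budget the L1 budget c applied to every component.
#' @slot labels optional character descriptors, one per module.
#'
#' @exportClass GeneModuleSet
setClass("GeneModuleSet",
  representation(loadings = "matrix", d = "numeric",
                 l1Budget = "numeric", labels = "character"))

setValidity("GeneModuleSet", function(object) {
  msg <- character()
  L <- object@loadings
  if (is.null(rownames(L))) msg <- c(msg, "loadings must carry gene rownames")
  if (length(object@d) != ncol(L))
    msg <- c(msg, "one singular value per module required")
  l2 <- sqrt(colSums(L^2))
  nz <- l2 > 0
  if (any(abs(l2[nz] - 1) > 1e-8))
    msg <- c(msg, "nonzero loading columns must have unit L2 norm")
  if (any(colSums(abs(L)) > object@l1Budget + 1e-6))
    msg <- c(msg, "loading column exceeds the L1 budget")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModuleSet compact description
#' @param object a \code{GeneModuleSet}
#' @export
setMethod("show", "GeneModuleSet", function(object) {
  cat(sprintf("GeneModuleSet: %d modules over %d genes (L1 budget %.3f)\n",
              ncol(object@loadings), nrow(object@loadings), object@l1Budget))
  supp <- colSums(object@loadings != 0)
  cat(sprintf("  support sizes: median %d [%d, %d]\n",
              as.integer(stats::median(supp)), min(supp), max(supp)))
})
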