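#' Accessors for Cohort and GeneModuleSet objects
#'
#' @param x a \code{Cohort} or \code{GeneModuleSet}
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortCounts", function(x) standardGeneric("cohortCounts"))
#' @rdname accessors
#' @export
setMethod("cohortCounts", "Cohort", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("cellMeta", function(x) standardGeneric("cellMeta"))
#' @rdname accessors
#' @export
setMethod("cellMeta", "Cohort", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("tcrTable", function(x) standardGeneric("tcrTable"))
#' @rdname accessors
#' @export
setMethod("tcrTable", "Cohort", function(x) x@tcr)

#' @rdname accessors
#' @export
setGeneric("igeTable", function(x) standardGeneric("igeTable"))
#' @rdname accessors
#' @export
setMethod("igeTable", "Cohort", function(x) x@ige)

#' @rdname accessors
#' @export
setGeneric("moduleLoadings", function(x) standardGeneric("moduleLoadings"))
#' @rdname accessors
#' @export
setMethod("moduleLoadings", "GeneModuleSet", function(x) x@loadings)

#' @rdname accessors
#' @export
setGeneric("moduleD", function(x) standardGeneric("moduleD"))
#' @rdname accessors
#' @export
setMethod("moduleD", "GeneModuleSet", function(x) x@d)

#' Number of cells / genes in a Cohort
#' @param x a \code{Cohort}
#' @export
nCells <- function(x) ncol(x@counts)

#' @rdname nCells
#' @export
nGenes <- function(x) nrow(x@counts)
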