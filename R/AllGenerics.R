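#' @rdname TagSeqExperiment-class
#' @param x A `TagSeqExperiment`.
#' @export
setGeneric("normalizedCounts", function(x) standardGeneric("normalizedCounts"))

#' @rdname TagSeqExperiment-class
#' @export
setGeneric("geneStatus", function(x) standardGeneric("geneStatus"))

#' @rdname TagSeqExperiment-class
#' @export
setGeneric("housekeepingCounts", function(x) {
  standardGeneric("housekeepingCounts")
})

#' @rdname GeneModelSet-class
#' @param x A `GeneModelSet`.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Accessors for TagSeqExperiment and GeneModelSet
#'
#' @name accessors
#' @keywords internal
NULL

#' @rdname GeneModelSet-class
#' @export
setMethod("geneModels", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneIds", "GeneModelSet", function(x) {
  S4Vectors::mcols(x@genes)$gene_id
})

#' @rdname TagSeqExperiment-class
#' @export
setMethod("normalizedCounts", "TagSeqExperiment", function(x) {
  if (!"normalized" %in% SummarizedExperiment::assayNames(x)) {
    stop("no 'normalized' assay; run normalizeToHousekeeping() first")
  }
  SummarizedExperiment::assay(x, "normalized")
})

#' @rdname TagSeqExperiment-class
#' @export
setMethod("geneStatus", "TagSeqExperiment", function(x) {
  stats::setNames(
    SummarizedExperiment::rowData(x)$status,
    SummarizedExperiment::rowData(x)$gene_id
  )
})

#' @rdname TagSeqExperiment-class
#' @export
setMethod("housekeepingCounts", "TagSeqExperiment", function(x) {
  hk <- S4Vectors::metadata(x)$housekeeping
  if (is.null(hk)) {
    stop("no housekeeping metadata; run normalizeToHousekeeping() first")
  }
  hk
})
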