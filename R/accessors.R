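#' Accessors for divSplice classes
#'
#' Small accessor layer over the S4 containers: estimated counts, resample
#' stacks, divided counts, RTA overdispersions, library sizes and
#' normalization factors.
#'
#' @param object a [TxQuant-class], [DividedCounts-class],
#'   [RTAEstimate-class] or [DTUResults-class] object as appropriate.
#' @return The requested component (matrix, vector or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
txCounts <- function(object) SummarizedExperiment::assay(object, "counts")

#' @rdname accessors
#' @export
txResamples <- function(object) S4Vectors::metadata(object)$resamples

#' @rdname accessors
#' @export
txCatalog <- function(object)
    as.data.frame(SummarizedExperiment::rowData(object))

#' @rdname accessors
#' @export
dividedCounts <- function(object) SummarizedExperiment::assay(object, "divided")

#' @rdname accessors
#' @export
tauHat <- function(object) {
    if (is(object, "RTAEstimate")) {
        stats::setNames(object@tauHat, object@ids)
    } else {
        rd <- SummarizedExperiment::rowData(object)
        stats::setNames(rd$tau, rd$transcript_id)
    }
}

#' @rdname accessors
#' @export
resampleDF <- function(object) stats::setNames(object@resampleDF, object@ids)

#' @rdname accessors
#' @export
libSizes <- function(object)
    stats::setNames(SummarizedExperiment::colData(object)$libSize,
                    colnames(object))

#' @rdname accessors
#' @export
normFactors <- function(object)
    stats::setNames(SummarizedExperiment::colData(object)$normFactor,
                    colnames(object))

#' @rdname accessors
#' @export
effectiveLibSizes <- function(object) libSizes(object) * normFactors(object)

#' @rdname accessors
#' @export
geneResults <- function(object) object@geneTable

#' @rdname accessors
#' @export
transcriptResults <- function(object) object@transcriptTable
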