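#' Filter low-expressed transcripts
#'
#' Keep-mask over transcripts following the `filterByExpr` rule, computed on
#' the divided counts with effective library sizes: a transcript is kept if
#' its CPM exceeds the cutoff implied by `minCount` and the median library
#' size in at least `n_min` samples (the smallest group size), and its total
#' divided count reaches `minTotalCount`. The lenient variant
#' (`lenient = TRUE`) uses `minCount = 1`, `minTotalCount = 5`, retaining
#' transcripts with at least 1 count in at least half the samples of a
#' balanced two-group design.
#'
#' @param object a [DividedCounts-class].
#' @param groups factor of group labels, one per sample.
#' @param minCount minimum count per sample (default 10).
#' @param minTotalCount minimum total count across samples (default 15).
#' @param lenient logical; shortcut for `minCount = 1, minTotalCount = 5`.
#' @return logical keep-mask over transcripts.
#' @export
filterTranscripts <- function(object, groups, minCount = 10,
                              minTotalCount = 15, lenient = FALSE) {
    if (lenient) {
        minCount <- 1
        minTotalCount <- 5
    }
    groups <- as.factor(groups)
    if (length(groups) != ncol(object))
        stop("group labels must cover all samples")
    z <- dividedCounts(object)
    keep <- edgeR::filterByExpr(z, group = groups,
                                lib.size = effectiveLibSizes(object),
                                min.count = minCount,
                                min.total.count = minTotalCount)
    if (!any(keep))
        warning("all transcripts were filtered out")
    unname(keep)
}

#' TMM normalization factors and effective library sizes
#'
#' Computes trimmed-mean-of-M-values (TMM) normalization factors on the
#' divided counts (trim fractions 0.30 on M and 0.05 on A, precision
#' weighting, reference sample chosen by upper-quartile CPM) and stores them
#' in the object; factors are rescaled to geometric mean 1. Effective
#' library sizes are `libSize * normFactor` and serve as CPM denominators
#' and GLM offsets downstream.
#'
#' @param object a [DividedCounts-class] with >= 2 samples.
#' @return The object with updated `normFactor` in its `colData`.
#' @seealso [effectiveLibSizes()]
#' @export
normalizeLibSizes <- function(object) {
    z <- dividedCounts(object)
    if (ncol(z) < 2) stop("TMM normalization needs at least 2 samples")
    f <- edgeR::calcNormFactors(z, lib.size = libSizes(object),
                                method = "TMM")
    f <- f / exp(mean(log(f)))
    SummarizedExperiment::colData(object)$normFactor <- f
    validObject(object)
    object
}

#' Subset a DividedCounts object by a transcript mask
#'
#' Subsetting keeps the library sizes and normalization factors computed on
#' the full transcriptome (filtering must not change the CPM scale).
#'
#' @param object a [DividedCounts-class].
#' @param keep logical or integer index over transcripts.
#' @return the subsetted [DividedCounts-class].
#' @export
subsetTranscripts <- function(object, keep) {
    object[keep, ]
}
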