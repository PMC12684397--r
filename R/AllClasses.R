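#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' TxQuant: transcript quantifications with technical resamples
#'
#' Container for per-sample transcript quantifications (estimated counts,
#' possibly fractional) together with the per-sample technical resample
#' matrices (bootstrap or Gibbs re-draws of the quantification) needed to
#' estimate read-to-transcript-ambiguity (RTA) overdispersions. Extends
#' [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay
#' (transcripts in rows, samples in columns); the transcript-to-gene catalog
#' lives in `rowData` and the resample matrices in
#' `metadata(x)$resamples`, a list with one transcripts-by-B matrix per
#' sample in catalog row order.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("TxQuant", contains = "SummarizedExperiment")

.validTxQuant <- function(object) {
    msg <- NULL
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)))
        msg <- c(msg, "counts must be finite")
    else if (any(cts < 0))
        msg <- c(msg, "counts must be non-negative")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("transcript_id", "gene_id") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain transcript_id and gene_id")
    else if (anyDuplicated(rd$transcript_id))
        msg <- c(msg, "transcript_ids must be unique")
    res <- S4Vectors::metadata(object)$resamples
    if (length(res)) {
        if (length(res) != ncol(cts))
            msg <- c(msg, "need one resample matrix per sample")
        for (r in res) {
            if (nrow(r) != nrow(cts)) {
                msg <- c(msg, "resample matrices must have one row per transcript")
                break
            }
            if (ncol(r) < 2L) {
                msg <- c(msg, "at least B = 2 resamples per sample are required")
                break
            }
            if (any(r < 0)) {
                msg <- c(msg, "resample values must be non-negative")
                break
            }
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("TxQuant", .validTxQuant)

#' Construct a TxQuant object
#'
#' @param counts numeric matrix of estimated transcript counts (transcripts
#'   by samples). Fractional values are allowed: these are quantifier
#'   estimates, not integer read counts.
#' @param catalog data.frame with columns `transcript_id`, `gene_id` and
#'   optionally `length` and `effective_length`, one row per row of
#'   `counts`, in the same order.
#' @param resamples optional list of per-sample resample matrices
#'   (transcripts by B, B >= 2), in the same transcript order as `counts`.
#' @param sampleIds optional character vector of sample names.
#'
#' @return A [TxQuant-class] object.
#' @examples
#' cat <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g1"))
#' counts <- matrix(c(10, 5, 12, 4), 2, 2)
#' tq <- TxQuant(counts, cat)
#' @export
TxQuant <- function(counts, catalog, resamples = list(), sampleIds = NULL) {
    counts <- as.matrix(counts)
    if (nrow(counts) != nrow(catalog))
        stop("counts and catalog must have the same number of transcripts")
    if (is.null(sampleIds))
        sampleIds <- colnames(counts)
    if (is.null(sampleIds))
        sampleIds <- paste0("sample", seq_len(ncol(counts)))
    dimnames(counts) <- list(catalog$transcript_id, sampleIds)
    resamples <- lapply(resamples, function(r) {
        r <- as.matrix(r)
        rownames(r) <- catalog$transcript_id
        r
    })
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(counts = counts),
        rowData = S4Vectors::DataFrame(catalog),
        metadata = list(resamples = resamples)
    )
    new("TxQuant", se)
}

#' DividedCounts: RTA-divided transcript counts
#'
#' Transcript counts divided row-wise by their estimated RTA overdispersions
#' tau, ready for negative-binomial-style modelling. Extends
#' [SummarizedExperiment::SummarizedExperiment] with a `"divided"` assay;
#' `rowData` carries the catalog plus the `tau` used for division, `colData`
#' carries `libSize` (column sums of the divided counts) and `normFactor`
#' (TMM factors, geometric mean 1).
#'
#' @export
setClass("DividedCounts", contains = "SummarizedExperiment")

.validDividedCounts <- function(object) {
    msg <- NULL
    z <- SummarizedExperiment::assay(object, "divided")
    if (any(!is.finite(z)) || any(z < 0))
        msg <- c(msg, "divided counts must be finite and non-negative")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("libSize", "normFactor") %in% colnames(cd)))
        msg <- c(msg, "colData must contain libSize and normFactor")
    else {
        if (any(cd$libSize <= 0))
            msg <- c(msg, "library sizes must be positive")
        if (any(cd$normFactor <= 0))
            msg <- c(msg, "normalization factors must be positive")
    }
    if (!"tau" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must contain tau")
    if (is.null(msg)) TRUE else msg
}
setValidity("DividedCounts", .validDividedCounts)

#' RTAEstimate: per-transcript RTA overdispersions
#'
#' Moderated quasi-Poisson overdispersion estimates obtained from technical
#' resamples, with their pooled resample degrees of freedom.
#'
#' @slot ids transcript identifiers.
#' @slot tauHat estimated overdispersions (after moderation and flooring).
#' @slot resampleDF pooled resample residual df per transcript.
#' @slot priorDF moderation strength toward 1.
#' @slot floor lower bound applied to tauHat.
#' @slot floored logical, TRUE where the floor was active.
#' @export
setClass("RTAEstimate",
    representation(ids = "character", tauHat = "numeric",
                   resampleDF = "numeric", priorDF = "numeric",
                   floor = "numeric", floored = "logical"))

setValidity("RTAEstimate", function(object) {
    msg <- NULL
    n <- length(object@ids)
    if (length(object@tauHat) != n || length(object@resampleDF) != n ||
        length(object@floored) != n)
        msg <- c(msg, "slot lengths must agree")
    if (any(!is.finite(object@tauHat)))
        msg <- c(msg, "tauHat must be finite")
    else if (any(object@tauHat < object@floor))
        msg <- c(msg, "tauHat must respect the floor")
    if (any(object@resampleDF < 0))
        msg <- c(msg, "resample df must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' TranscriptFit: transcript-wise model fits
#'
#' Per-transcript fits of either weighted linear models on log2-CPM
#' (`backend = "lm"`) or quasi-negative-binomial GLMs on divided counts
#' (`backend = "nbglm"`). Coefficients are stored on the backend's natural
#' scale: log2 for `"lm"`, natural log for `"nbglm"` (result tables report
#' log2 in both cases).
#'
#' @slot ids transcript identifiers.
#' @slot geneIds gene identifier per transcript.
#' @slot coefficients transcripts-by-p coefficient matrix.
#' @slot unscaledVar transcripts-by-p unscaled coefficient variances v_gt.
#' @slot s2 residual variance (lm) or bias-adjusted mean deviance (nbglm).
#' @slot df adjusted residual degrees of freedom d_gt.
#' @slot fittedMean fitted means: of log2-CPM (lm) or of divided counts (nbglm).
#' @slot weights observation precision weights (lm backend; empty otherwise).
#' @slot design the n-by-p design matrix.
#' @slot counts the divided-count matrix the fit was computed on.
#' @slot backend `"lm"` or `"nbglm"`.
#' @slot dispersion global NB dispersion phi (nbglm; NA for lm).
#' @slot offsets log effective library sizes used as GLM offsets (nbglm).
#' @slot converged logical per transcript (nbglm IRLS convergence).
#' @export
setClass("TranscriptFit",
    representation(ids = "character", geneIds = "character",
                   coefficients = "matrix", unscaledVar = "matrix",
                   s2 = "numeric", df = "numeric", fittedMean = "matrix",
                   weights = "matrix", design = "matrix", counts = "matrix",
                   backend = "character", dispersion = "numeric",
                   offsets = "numeric", converged = "logical"))

setValidity("TranscriptFit", function(object) {
    msg <- NULL
    n <- length(object@ids)
    if (nrow(object@coefficients) != n || length(object@df) != n)
        msg <- c(msg, "per-transcript slots must agree in length")
    if (!object@backend %in% c("lm", "nbglm"))
        msg <- c(msg, "backend must be 'lm' or 'nbglm'")
    if (any(object@df < 0))
        msg <- c(msg, "residual df must be non-negative")
    ok <- object@df > 0 & is.finite(object@s2)
    if (any(object@unscaledVar[ok, , drop = FALSE] <= 0))
        msg <- c(msg, "unscaled variances must be positive where df > 0")
    if (is.null(msg)) TRUE else msg
})

#' GeneEBayes: empirical Bayes squeezed gene variances
#'
#' Gene-level pooled residual variances (or pooled mean deviances) shrunk
#' toward a common prior by unequal-df empirical Bayes moment matching.
#'
#' @slot geneIds gene identifiers.
#' @slot df pooled residual df d_g per gene.
#' @slot s2 pooled residual variance s2_g per gene.
#' @slot priorDF estimated prior df d0 (Inf allowed).
#' @slot priorVar estimated prior variance s0^2.
#' @slot posterior posterior variance estimates per gene.
#' @export
setClass("GeneEBayes",
    representation(geneIds = "character", df = "numeric", s2 = "numeric",
                   priorDF = "numeric", priorVar = "numeric",
                   posterior = "numeric"))

setValidity("GeneEBayes", function(object) {
    msg <- NULL
    if (length(object@geneIds) != length(object@posterior))
        msg <- c(msg, "slot lengths must agree")
    if (object@priorVar <= 0)
        msg <- c(msg, "prior variance must be positive")
    if (is.null(msg)) TRUE else msg
})

#' DTUResults: gene- and transcript-level differential usage tables
#'
#' @slot geneTable data.frame of gene-level statistics: consensus
#'   coefficient, F statistic with its df, F p-value, Simes p-value and
#'   BH-adjusted versions of both.
#' @slot transcriptTable data.frame of transcript-level statistics: relative
#'   log2 effect, leverage, t statistic, p-value and BH-adjusted p-value.
#' @slot backend which fit backend produced the tables.
#' @slot coef the tested coefficient index.
#' @export
setClass("DTUResults",
    representation(geneTable = "data.frame", transcriptTable = "data.frame",
                   backend = "character", coef = "integer"))

setValidity("DTUResults", function(object) {
    msg <- NULL
    tt <- object@transcriptTable
    gt <- object@geneTable
    if (nrow(tt) && (any(tt$P.Value < 0) || any(tt$P.Value > 1)))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (nrow(gt) && (any(gt$P.Value < 0) || any(gt$P.Value > 1)))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "TxQuant", function(object) {
    res <- S4Vectors::metadata(object)$resamples
    cat("TxQuant:", nrow(object), "transcripts,",
        length(unique(SummarizedExperiment::rowData(object)$gene_id)),
        "genes,", ncol(object), "samples\n")
    if (length(res))
        cat("  technical resamples: B =", ncol(res[[1]]), "per sample\n")
    else cat("  no technical resamples attached\n")
})

setMethod("show", "DividedCounts", function(object) {
    cat("DividedCounts:", nrow(object), "transcripts,", ncol(object),
        "samples\n")
    cat("  median tau:",
        signif(stats::median(SummarizedExperiment::rowData(object)$tau), 4),
        "| norm factor range:",
        paste(signif(range(SummarizedExperiment::colData(object)$normFactor), 4),
              collapse = " - "), "\n")
})

setMethod("show", "RTAEstimate", function(object) {
    cat("RTAEstimate:", length(object@ids), "transcripts\n")
    cat("  tau quartiles:",
        paste(signif(stats::quantile(object@tauHat, c(.25, .5, .75)), 4),
              collapse = " / "),
        "|", sum(object@floored), "floored at", object@floor, "\n")
})

setMethod("show", "TranscriptFit", function(object) {
    cat("TranscriptFit (", object@backend, "): ", length(object@ids),
        " transcripts, ", ncol(object@coefficients), " coefficients\n",
        sep = "")
    if (object@backend == "nbglm")
        cat("  global NB dispersion phi =", signif(object@dispersion, 4), "\n")
})

setMethod("show", "GeneEBayes", function(object) {
    cat("GeneEBayes:", length(object@geneIds), "genes | prior df =",
        signif(object@priorDF, 4), "| prior variance =",
        signif(object@priorVar, 4), "\n")
})

setMethod("show", "DTUResults", function(object) {
    cat("DTUResults (", object@backend, " backend, coefficient ",
        object@coef, ")\n", sep = "")
    cat("  ", nrow(object@geneTable), " genes tested, ",
        nrow(object@transcriptTable), " transcripts tested\n", sep = "")
    cat("  genes at Simes FDR < 0.05: ",
        sum(object@geneTable$FDR.Simes < 0.05), "\n", sep = "")
})
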