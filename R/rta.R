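#' Estimate RTA overdispersions from technical resamples
#'
#' Read-to-transcript ambiguity (RTA) — reads compatible with several
#' overlapping transcripts — inflates the technical variance of estimated
#' transcript counts in a quasi-Poisson fashion. The overdispersion tau of
#' each transcript is estimated from the quantifier's technical resamples
#' (bootstrap or Gibbs draws) by a pooled Pearson-type statistic:
#'
#' \deqn{D_t = \sum_i \sum_b (y_{tib} - \bar y_{ti})^2 / \bar y_{ti}}
#'
#' over samples i whose resample mean is positive, with pooled df
#' \eqn{r_t = \sum_i (B - 1)} over those samples. The raw dispersion
#' \eqn{D_t / r_t} is shrunk toward 1 (the value for unambiguous
#' transcripts) with `priorDF` pseudo-df and floored at `floor`, so
#' division never inflates counts:
#' \deqn{\hat\tau_t = \max(\mathrm{floor}, (D_t + \mathrm{priorDF}) /
#'   (r_t + \mathrm{priorDF})).}
#'
#' @param object a [TxQuant-class] with resamples attached.
#' @param priorDF moderation strength toward 1 (default 3).
#' @param floor lower bound for tau (default 1; 0 disables flooring).
#' @return An [RTAEstimate-class] object.
#' @seealso [divideCounts()]
#' @export
estimateRTA <- function(object, priorDF = 3, floor = 1) {
    res <- txResamples(object)
    if (!length(res))
        stop("TxQuant has no resamples; RTA estimation needs B >= 2 per sample")
    ids <- txCatalog(object)$transcript_id
    nT <- length(ids)
    D <- numeric(nT)
    r <- numeric(nT)
    for (m in res) {
        if (any(m < 0)) stop("negative resample values")
        B <- ncol(m)
        mu <- rowMeans(m)
        pos <- mu > 0
        ss <- rowSums((m - mu)^2)
        D[pos] <- D[pos] + ss[pos] / mu[pos]
        r[pos] <- r[pos] + (B - 1)
    }
    tau <- (D + priorDF) / (r + priorDF)
    tau[r == 0] <- floor
    floored <- tau < floor
    tau <- pmax(tau, floor)
    new("RTAEstimate", ids = ids, tauHat = tau, resampleDF = r,
        priorDF = priorDF, floor = floor, floored = floored)
}

#' Divide transcript counts by their RTA overdispersions
#'
#' Produces the divided counts z = y / tau, which behave approximately like
#' negative binomial counts and are fed to the downstream model fits as if
#' they were ordinary read counts. Library sizes are recomputed from the
#' divided counts; TMM normalization factors are initialized to 1 (set
#' later by [normalizeLibSizes()]).
#'
#' @param object a [TxQuant-class].
#' @param rta an [RTAEstimate-class] in the same transcript order (or a
#'   bare numeric vector of tau values).
#' @return A [DividedCounts-class] object.
#' @export
divideCounts <- function(object, rta) {
    cat <- txCatalog(object)
    if (is(rta, "RTAEstimate")) {
        if (!identical(rta@ids, cat$transcript_id))
            stop("transcript order differs between quantifications and RTA estimate")
        tau <- rta@tauHat
    } else {
        tau <- as.numeric(rta)
    }
    if (any(tau <= 0)) stop("tau must be positive")
    z <- txCounts(object) / tau
    lib <- colSums(z)
    if (any(lib <= 0)) stop("a sample has zero total divided count")
    cat$tau <- tau
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(divided = z),
        rowData = S4Vectors::DataFrame(cat),
        colData = S4Vectors::DataFrame(libSize = lib,
                                       normFactor = rep(1, ncol(z)),
                                       row.names = colnames(z)))
    new("DividedCounts", se)
}
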