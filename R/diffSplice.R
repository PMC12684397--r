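#' Simes gene-level p-value
#'
#' \eqn{\min_i (m \, p_{(i)} / i)} over the sorted transcript p-values of a
#' gene, capped at 1. Valid under positive dependence; more powerful than
#' the F-test when a single transcript stands out.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return a single p-value.
#' @examples simesP(c(0.01, 0.04))  # 0.02
#' @export
simesP <- function(p) {
    m <- length(p)
    if (m == 0) return(NA_real_)
    ps <- sort(p)
    min(1, min(m * ps / seq_len(m)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false discovery rate adjustment (`stats::p.adjust`,
#' `method = "BH"`), order-preserving.
#'
#' @param p vector of p-values.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

# per-gene index list over usable transcripts; drops single-transcript
# genes (no within-gene contrast exists for them)
.geneIndex <- function(geneIds, usable) {
    idx <- split(which(usable), geneIds[usable])
    idx[lengths(idx) >= 2]
}

.limmaDiffSplice <- function(fit, eb, coef) {
    beta <- fit@coefficients[, coef]
    v <- fit@unscaledVar[, coef]
    usable <- is.finite(beta) & is.finite(v) & v > 0
    if (any(!usable & is.finite(beta)))
        warning(sum(!usable), " transcript(s) with nonpositive unscaled ",
                "variance excluded from DTU tests")
    genes <- .geneIndex(fit@geneIds, usable)
    ebPost <- stats::setNames(eb@posterior, eb@geneIds)
    ebDf <- stats::setNames(eb@df, eb@geneIds)
    d0 <- eb@priorDF
    gRows <- vector("list", length(genes))
    tRows <- vector("list", length(genes))
    for (k in seq_along(genes)) {
        ix <- genes[[k]]
        g <- names(genes)[k]
        u <- 1 / v[ix]
        ug <- sum(u)
        bbar <- sum(u * beta[ix]) / ug
        h <- u / ug
        s2post <- ebPost[[g]]
        dfTot <- if (is.finite(d0)) d0 + ebDf[[g]] else Inf
        tstat <- (beta[ix] - bbar) / sqrt(1 - h) / sqrt(s2post * v[ix])
        pT <- 2 * stats::pt(-abs(tstat), df = dfTot)
        Tg <- length(ix)
        Fg <- sum((1 - h) * tstat^2) / (Tg - 1)
        pF <- stats::pf(Fg, Tg - 1, dfTot, lower.tail = FALSE)
        gRows[[k]] <- data.frame(gene_id = g, n_transcripts = Tg,
                                 consensus = bbar, F = Fg, df1 = Tg - 1,
                                 df2 = dfTot, P.Value = pF,
                                 P.Simes = simesP(pT),
                                 stringsAsFactors = FALSE)
        tRows[[k]] <- data.frame(transcript_id = fit@ids[ix], gene_id = g,
                                 logFC = beta[ix] - bbar, leverage = h,
                                 t = tstat, P.Value = pT,
                                 stringsAsFactors = FALSE)
    }
    list(gene = do.call(rbind, gRows), transcript = do.call(rbind, tRows))
}

# re-estimate the shared value of coefficient `coef` across the transcripts
# in `ix` by damped Fisher scoring: each round refits every transcript's
# free coefficients with the shared value absorbed into the offset, then
# moves the shared value by the pooled score over pooled information
.sharedCoefFit <- function(zrows, design, off, phi, coef, start,
                           tol = 1e-6, maxit = 50L, damp = 0.8,
                           etasStart = NULL) {
    xj <- design[, coef]
    bbar <- start
    nTx <- nrow(zrows)
    cfits <- vector("list", nTx)
    etas <- if (is.null(etasStart)) vector("list", nTx) else etasStart
    for (round in seq_len(maxit)) {
        U <- 0; I <- 0
        for (t in seq_len(nTx)) {
            cf <- .irlsNB(zrows[t, ], design, off, phi,
                          fixed = list(coef = coef, value = bbar),
                          etaStart = etas[[t]], computeBeta = FALSE)
            w <- cf$mu / (1 + phi * cf$mu)
            U <- U + sum(xj * (zrows[t, ] - cf$mu) / (1 + phi * cf$mu))
            I <- I + sum(xj^2 * w)
            cfits[[t]] <- cf
            etas[[t]] <- cf$eta
        }
        if (I <= 0) break
        step <- damp * U / I
        bbar <- bbar + step
        if (abs(step) < tol) break
    }
    list(value = bbar,
         deviance = sum(vapply(cfits, `[[`, numeric(1), "deviance")),
         devByTx = vapply(cfits, `[[`, numeric(1), "deviance"),
         etas = etas)
}

.edgerDiffSplice <- function(fit, eb, coef) {
    beta <- fit@coefficients[, coef]
    v <- fit@unscaledVar[, coef]
    usable <- is.finite(beta) & is.finite(v) & v > 0
    genes <- .geneIndex(fit@geneIds, usable)
    ebPost <- stats::setNames(eb@posterior, eb@geneIds)
    ebDf <- stats::setNames(eb@df, eb@geneIds)
    d0 <- eb@priorDF
    phi <- fit@dispersion
    design <- fit@design
    off <- fit@offsets
    z <- fit@counts
    gRows <- vector("list", length(genes))
    tRows <- vector("list", length(genes))
    for (k in seq_along(genes)) {
        ix <- genes[[k]]
        g <- names(genes)[k]
        Tg <- length(ix)
        u <- 1 / v[ix]
        bbar <- sum(u * beta[ix]) / sum(u)
        zg <- z[ix, , drop = FALSE]
        devFull <- vapply(seq_len(Tg), function(t)
            nbDeviance(zg[t, ], fit@fittedMean[ix[t], ], phi), numeric(1))
        nullFit <- .sharedCoefFit(zg, design, off, phi, coef, bbar)
        dDg <- max(0, nullFit$deviance - sum(devFull))
        s2post <- ebPost[[g]]
        dfTot <- if (is.finite(d0)) d0 + ebDf[[g]] else Inf
        Fg <- dDg / ((Tg - 1) * s2post)
        pF <- stats::pf(Fg, Tg - 1, dfTot, lower.tail = FALSE)
        # transcript level
        dDgt <- numeric(Tg)
        if (Tg == 2) {
            dDgt[] <- dDg
        } else if (Tg <= 10) {
            for (t in seq_len(Tg)) {
                others <- setdiff(seq_len(Tg), t)
                uo <- u[others]
                startO <- sum(uo * beta[ix][others]) / sum(uo)
                oneRem <- .sharedCoefFit(zg[others, , drop = FALSE], design,
                                         off, phi, coef, startO,
                                         etasStart = nullFit$etas[others])
                dDgt[t] <- max(0, nullFit$deviance -
                                   (devFull[t] + oneRem$deviance))
            }
        } else {
            dDgt <- pmax(0, nullFit$devByTx - devFull)
        }
        Fgt <- dDgt / s2post
        sgn <- sign(beta[ix] - bbar)
        sgn[sgn == 0] <- 1
        tstat <- sqrt(Fgt) * sgn
        pT <- stats::pf(Fgt, 1, dfTot, lower.tail = FALSE)
        gRows[[k]] <- data.frame(gene_id = g, n_transcripts = Tg,
                                 consensus = bbar / log(2), F = Fg,
                                 df1 = Tg - 1, df2 = dfTot,
                                 deltaDeviance = dDg, P.Value = pF,
                                 P.Simes = simesP(pT),
                                 stringsAsFactors = FALSE)
        tRows[[k]] <- data.frame(transcript_id = fit@ids[ix], gene_id = g,
                                 logFC = (beta[ix] - bbar) / log(2),
                                 leverage = u / sum(u), t = tstat,
                                 F = Fgt, deltaDeviance = dDgt,
                                 P.Value = pT, stringsAsFactors = FALSE)
    }
    list(gene = do.call(rbind, gRows), transcript = do.call(rbind, tRows))
}

#' Test genes and transcripts for differential transcript usage
#'
#' Within every gene expressing more than one transcript, tests whether the
#' transcript-wise estimates of the chosen coefficient differ among the
#' gene's transcripts — the hallmark of differential transcript usage.
#'
#' For the linear backend the test uses empirical Bayes moderated
#' statistics: with unscaled precisions \eqn{u_{gt} = 1/v_{gt}},
#' consensus \eqn{\hat\beta_g = \sum u \hat\beta / \sum u}, leverage
#' \eqn{h_{gt} = u_{gt}/u_g}, and squeezed gene variance
#' \eqn{\tilde s^2_g},
#' \deqn{\tilde t_{gt} = \frac{(\hat\beta_{gt} - \hat\beta_g)/\sqrt{1 -
#'   h_{gt}}}{\tilde s_g \sqrt{v_{gt}}}, \qquad
#'   \tilde F_g = \frac{1}{T_g - 1}\sum_t (1 - h_{gt}) \tilde t_{gt}^2,}
#' referred to t and F distributions on \eqn{d_{0g} + d_g} (denominator)
#' df. For the GLM backend, quasi-F statistics replace these: the gene
#' statistic is the deviance difference between the full fit and a null
#' fit constraining the coefficient to a shared value across the gene's
#' transcripts, divided by \eqn{(T_g - 1)\tilde s^2_g}; the transcript
#' statistic contrasts the all-equal null with a one-removed null that
#' frees only the transcript of interest (for genes with more than 10
#' transcripts a fast per-transcript approximation is used), and is signed
#' into a t-statistic by \eqn{\mathrm{sign}(\hat\beta_{gt} - \hat\beta_g)}.
#' Gene-level Simes p-values aggregate the transcript p-values; BH
#' adjustment is applied across genes (F and Simes separately) and across
#' all transcripts.
#'
#' @param fit a [TranscriptFit-class] from either backend.
#' @param coef index (or name) of the design coefficient to test.
#' @param winsorize passed to [squeezeVariances()].
#' @return A [DTUResults-class] with ranked gene and transcript tables.
#'   Relative effects (`logFC`, transcript coefficient minus gene
#'   consensus) are reported on the log2 scale for both backends.
#' @export
diffSpliceDTU <- function(fit, coef = 2L, winsorize = FALSE) {
    if (is.character(coef)) coef <- match(coef, colnames(fit@coefficients))
    coef <- as.integer(coef)
    if (is.na(coef) || coef < 1 || coef > ncol(fit@coefficients))
        stop("coef does not name a column of the design")
    pooled <- poolGeneVariances(fit)
    eb <- squeezeVariances(pooled$s2, pooled$df, pooled$gene_id,
                           winsorize = winsorize)
    res <- if (fit@backend == "lm") .limmaDiffSplice(fit, eb, coef)
           else .edgerDiffSplice(fit, eb, coef)
    gt <- res$gene
    tt <- res$transcript
    if (is.null(gt) || !nrow(gt))
        stop("no genes with at least two usable transcripts")
    gt$FDR <- bhAdjust(gt$P.Value)
    gt$FDR.Simes <- bhAdjust(gt$P.Simes)
    tt$FDR <- bhAdjust(tt$P.Value)
    ordG <- order(gt$P.Value, gt$gene_id)
    ordT <- order(tt$P.Value, tt$transcript_id)
    new("DTUResults", geneTable = gt[ordG, , drop = FALSE],
        transcriptTable = tt[ordT, , drop = FALSE],
        backend = fit@backend, coef = coef)
}

#' Extract ranked differential-usage tables
#'
#' @param results a [DTUResults-class].
#' @param level `"gene"` (F-test p-values), `"simes"` (Simes gene
#'   p-values) or `"transcript"`.
#' @param n maximum number of rows to return (default all).
#' @param fdrCutoff keep rows with BH-adjusted p at or below this cutoff.
#' @return data.frame sorted ascending by the level's raw p-value, ties
#'   broken by id.
#' @export
topSpliceDTU <- function(results, level = c("gene", "simes", "transcript"),
                         n = Inf, fdrCutoff = 1) {
    level <- match.arg(level)
    if (level == "transcript") {
        tab <- results@transcriptTable
        ord <- order(tab$P.Value, tab$transcript_id)
        tab <- tab[ord, , drop = FALSE]
        tab <- tab[tab$FDR <= fdrCutoff, , drop = FALSE]
    } else {
        tab <- results@geneTable
        if (level == "simes") {
            tab$P.Value <- tab$P.Simes
            tab$FDR <- tab$FDR.Simes
        }
        ord <- order(tab$P.Value, tab$gene_id)
        tab <- tab[ord, , drop = FALSE]
        tab <- tab[tab$FDR <= fdrCutoff, , drop = FALSE]
    }
    utils::head(tab, n)
}
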