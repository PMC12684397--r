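#' log2 counts-per-million transform
#'
#' \code{log2((z + 0.5) / (effectiveLib + 1) * 1e6)}, the standard
#' offset-stabilized log-CPM used by the linear-model backend.
#'
#' @param object a [DividedCounts-class], or a bare matrix if
#'   `effectiveLib` is supplied.
#' @param effectiveLib per-sample effective library sizes (taken from the
#'   object when omitted).
#' @return matrix of log2-CPM values, same dimensions as the counts.
#' @export
logCPM <- function(object, effectiveLib = NULL) {
    if (is(object, "DividedCounts")) {
        z <- dividedCounts(object)
        if (is.null(effectiveLib)) effectiveLib <- effectiveLibSizes(object)
    } else z <- as.matrix(object)
    t(log2(t(z + 0.5) / (effectiveLib + 1) * 1e6))
}

#' Mean-variance trend precision weights
#'
#' voom-style observation weights: each transcript is fit by ordinary least
#' squares on log2-CPM, a lowess curve (span 0.5) of the square-root
#' residual standard deviation against the mean log2-CPM is estimated
#' across transcripts, and each observation receives weight
#' (predicted sqrt-sd at its fitted log2-CPM)^-4, clipped to
#' \[1e-6, 1e6\]. With fewer than 10 transcripts the trend is unstable and
#' unit weights are returned with a warning.
#'
#' @param logcpm matrix of log2-CPM values.
#' @param design n-by-p design matrix.
#' @return list with `weights` (matrix like `logcpm`) and the `trend`
#'   function used.
#' @export
voomWeights <- function(logcpm, design) {
    nT <- nrow(logcpm)
    n <- ncol(logcpm)
    p <- ncol(design)
    unit <- function(msg) {
        warning(msg)
        list(weights = matrix(1, nT, n, dimnames = dimnames(logcpm)),
             trend = function(x) rep(1, length(x)))
    }
    if (nT < 10)
        return(unit("fewer than 10 transcripts: using unit precision weights"))
    fit <- stats::lm.fit(design, t(logcpm))
    resid <- t(fit$residuals)
    fitted <- logcpm - resid
    df <- n - p
    if (df < 1)
        return(unit("no residual df: using unit precision weights"))
    s <- sqrt(rowSums(resid^2) / df)
    abar <- rowMeans(logcpm)
    if (stats::sd(abar) < 1e-12 || all(s < 1e-12))
        return(unit("degenerate abundance or variance spread: unit weights"))
    lo <- stats::lowess(abar, sqrt(s), f = 0.5)
    predict1 <- function(x) {
        y <- stats::approx(lo$x, lo$y, xout = x, rule = 2, ties = "ordered")$y
        pmax(y, 1e-3)
    }
    w <- matrix(predict1(as.vector(fitted))^-4, nT, n,
                dimnames = dimnames(logcpm))
    w[] <- pmin(pmax(w, 1e-6), 1e6)
    list(weights = w, trend = predict1)
}

# residual-df penalty for treatment groups whose divided counts are all
# zero: each such group of size m contributes m - 1 structurally-zero
# residuals that would otherwise masquerade as precision
.zeroGroupPenalty <- function(z, groups) {
    if (is.null(groups)) return(numeric(nrow(z)))
    groups <- as.factor(groups)
    pen <- numeric(nrow(z))
    for (g in levels(groups)) {
        idx <- which(groups == g)
        if (length(idx) < 2) next
        allzero <- rowSums(z[, idx, drop = FALSE] > 0) == 0
        pen[allzero] <- pen[allzero] + (length(idx) - 1)
    }
    pen
}

#' Transcript-wise weighted linear models on log2-CPM
#'
#' The linear-model backend: computes log2-CPM, estimates mean-variance
#' trend precision weights (one trend pass, one refit — no iteration), and
#' fits a weighted least-squares model per transcript. The residual df of a
#' transcript is reduced by `m_k - 1` for every treatment group k (size
#' `m_k`) whose divided counts are entirely zero, preventing structural
#' zeros from deflating the residual variance; the residual variance uses
#' the adjusted df as denominator.
#'
#' @param object a [DividedCounts-class] (filtered and normalized).
#' @param design n-by-p full-rank design matrix.
#' @param groups optional factor of treatment groups used for zero-group
#'   detection (no df adjustment when NULL).
#' @param weights optional precomputed observation-weight matrix; computed
#'   by [voomWeights()] when NULL.
#' @return A [TranscriptFit-class] with `backend = "lm"`; coefficients are
#'   on the log2 scale.
#' @export
fitTranscriptLM <- function(object, design, groups = NULL, weights = NULL) {
    z <- dividedCounts(object)
    design <- as.matrix(design)
    n <- ncol(z)
    p <- ncol(design)
    if (nrow(design) != n) stop("design must have one row per sample")
    if (qr(design)$rank < p) stop("design matrix is not of full column rank")
    if (n <= p) stop("need more samples than coefficients")
    y <- logCPM(object)
    if (is.null(weights)) weights <- voomWeights(y, design)$weights
    nT <- nrow(z)
    beta <- matrix(NA_real_, nT, p, dimnames = list(rownames(z),
                                                    colnames(design)))
    v <- matrix(NA_real_, nT, p)
    fittedM <- matrix(NA_real_, nT, n, dimnames = dimnames(y))
    s2 <- numeric(nT)
    pen <- .zeroGroupPenalty(z, groups)
    df <- pmax(0, (n - p) - pen)
    for (t in seq_len(nT)) {
        w <- weights[t, ]
        fit <- stats::lm.wfit(design, y[t, ], w)
        if (fit$rank < p)
            stop("singular weighted design for transcript ", rownames(z)[t])
        beta[t, ] <- fit$coefficients
        XtWX <- crossprod(design * w, design)
        v[t, ] <- diag(chol2inv(chol(XtWX)))
        fittedM[t, ] <- fit$fitted.values
        rss <- sum(w * fit$residuals^2)
        s2[t] <- if (df[t] > 0) rss / df[t] else NA_real_
    }
    cat <- txCatalog(object)
    new("TranscriptFit", ids = cat$transcript_id, geneIds = cat$gene_id,
        coefficients = beta, unscaledVar = v, s2 = s2, df = df,
        fittedMean = fittedM, weights = weights, design = design,
        counts = z, backend = "lm", dispersion = NA_real_,
        offsets = log(effectiveLibSizes(object)),
        converged = rep(TRUE, nT))
}
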