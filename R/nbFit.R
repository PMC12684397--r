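#' Negative binomial deviance
#'
#' Residual deviance of counts `y` around fitted means `mu` under a
#' negative binomial model with dispersion `phi`:
#' \deqn{D = 2\sum\left[y\log(y/\mu) - (y + 1/\phi)\log\frac{1+\phi y}{1+\phi\mu}\right]}
#' with \eqn{y\log(y/\mu) = 0} at y = 0. As \eqn{\phi \to 0} this reduces
#' to the Poisson deviance \eqn{2\sum[y\log(y/\mu) - (y - \mu)]}; the
#' Poisson branch is used below `phi = 1e-10`. Fractional counts are
#' supported.
#'
#' @param y observed (possibly fractional) counts.
#' @param mu fitted means (clamped below at 1e-8).
#' @param phi NB dispersion, >= 0.
#' @return the total deviance (a non-negative scalar).
#' @export
nbDeviance <- function(y, mu, phi) {
    sum(.nbDevUnit(y, mu, phi))
}

.nbDevUnit <- function(y, mu, phi) {
    mu <- pmax(mu, 1e-8)
    ylogy <- ifelse(y > 0, y * log(y / mu), 0)
    if (phi < 1e-10) {
        d <- 2 * (ylogy - (y - mu))
    } else {
        d <- 2 * (ylogy - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
    }
    pmax(d, 0)
}

# NB log-likelihood (continuous in y via gamma functions); phi = 0 gives
# the Poisson log-likelihood
.nbLogLik <- function(y, mu, phi) {
    mu <- pmax(mu, 1e-8)
    if (phi < 1e-10)
        return(sum(y * log(mu) - mu - lgamma(y + 1)))
    r <- 1 / phi
    sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        y * log(phi * mu / (1 + phi * mu)) - r * log1p(phi * mu))
}

# One-transcript NB IRLS with log link. `fixed` optionally constrains
# coefficient `fixed$coef` to `fixed$value` (absorbed into the offset);
# the returned score/information for that coefficient drive the shared-
# coefficient consensus updates in the deviance-based DTU tests.
.irlsNB <- function(y, design, offset, phi, fixed = NULL,
                    maxit = 50L, tol = 1e-8, etaStart = NULL,
                    computeBeta = TRUE) {
    n <- length(y)
    X <- design
    off <- offset
    keep <- seq_len(ncol(design))
    if (!is.null(fixed)) {
        keep <- keep[-fixed$coef]
        off <- off + design[, fixed$coef] * fixed$value
        X <- design[, keep, drop = FALSE]
    }
    p <- ncol(X)
    beta <- rep(0, ncol(design))
    if (all(y == 0)) {
        eta <- rep(-745, n)
        bfree <- stats::lm.fit(X, eta - off)$coefficients
        bfree[is.na(bfree)] <- 0
        beta[keep] <- bfree
        if (!is.null(fixed)) beta[fixed$coef] <- fixed$value
        mu <- exp(pmin(eta, 700))
        return(list(beta = beta, mu = mu, eta = eta, deviance = 0,
                    XtWX = diag(1e-12, p), converged = TRUE,
                    free = keep))
    }
    if (is.null(etaStart)) {
        mu <- pmax(y, mean(y) / 10, 1e-4)
        eta <- log(mu)
    } else {
        eta <- etaStart
        mu <- exp(eta)
    }
    # the starting mu is saturated, not a model fit: the first IRLS step is
    # accepted unconditionally, halving applies from the second step on
    dev <- Inf
    conv <- FALSE
    x1 <- if (p == 1L) X[, 1L] else NULL
    for (it in seq_len(maxit)) {
        w <- pmax(mu / (1 + phi * mu), 1e-300)
        zwork <- (eta - off) + (y - mu) / mu
        if (any(!is.finite(zwork)) || any(!is.finite(w))) break
        if (p == 1L) {
            # single free coefficient: closed-form weighted LS step
            b1 <- sum(w * x1 * zwork) / sum(w * x1 * x1)
            if (!is.finite(b1)) break
            etaNew <- x1 * b1 + off
        } else {
            fit <- stats::lm.wfit(X, zwork, w)
            if (anyNA(fit$coefficients)) break
            etaNew <- drop(X %*% fit$coefficients) + off
        }
        etaNew <- pmin(pmax(etaNew, -745), 700)
        muNew <- exp(etaNew)
        devNew <- nbDeviance(y, muNew, phi)
        # step halving if the deviance increases
        half <- 0
        while (is.finite(dev) && devNew > dev + 1e-10 && half < 10) {
            etaNew <- (eta + etaNew) / 2
            muNew <- exp(etaNew)
            devNew <- nbDeviance(y, muNew, phi)
            half <- half + 1
        }
        done <- abs(dev - devNew) < tol * (abs(devNew) + 0.1)
        eta <- etaNew; mu <- muNew; dev <- devNew
        if (done) { conv <- TRUE; break }
    }
    if (computeBeta) {
        bfree <- qr.coef(qr(X), eta - off)
        bfree[is.na(bfree)] <- 0
        beta[keep] <- bfree
        if (!is.null(fixed)) beta[fixed$coef] <- fixed$value
    }
    w <- mu / (1 + phi * mu)
    list(beta = beta, mu = mu, eta = eta, deviance = dev,
         XtWX = crossprod(X * w, X), converged = conv, free = keep)
}

#' Estimate the global NB dispersion
#'
#' A single negative binomial dispersion phi shared by all transcripts,
#' estimated by maximizing the summed adjusted NB profile log-likelihood
#' with each transcript's means held at their fitted values (from a
#' Poisson fit of the same design). The adjustment subtracts half the
#' log-determinant of each transcript's expected information
#' (Cox-Reid style), removing the downward bias that plain profile
#' likelihood incurs from estimating p coefficients per transcript.
#' Transcripts with mean divided count below 1 are excluded from the
#' objective; the search is over phi in \[1e-6, 10\] by golden-section
#' (`stats::optimize`).
#'
#' @param object a [DividedCounts-class].
#' @param design n-by-p design matrix.
#' @return list with `phi` (scalar) and `mu` (fitted-mean matrix under the
#'   Poisson fit, rows = usable transcripts).
#' @export
estimateCommonDispersion <- function(object, design) {
    z <- dividedCounts(object)
    off <- log(effectiveLibSizes(object))
    use <- which(rowMeans(z) >= 1)
    if (!length(use)) {
        warning("no transcripts with mean count >= 1; returning phi = 0")
        return(list(phi = 0, mu = NULL))
    }
    design <- as.matrix(design)
    mu <- matrix(0, length(use), ncol(z))
    for (k in seq_along(use)) {
        mu[k, ] <- .irlsNB(z[use[k], ], design, off, phi = 0)$mu
    }
    y <- z[use, , drop = FALSE]
    p <- ncol(design)
    pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    Xprod <- design[, pairs[, 1], drop = FALSE] *
        design[, pairs[, 2], drop = FALSE]
    crPenalty <- function(phi) {
        W <- mu / (1 + phi * mu)
        E <- W %*% Xprod   # per-transcript packed X' W X entries
        if (p == 1L) {
            ld <- log(pmax(E[, 1], 1e-300))
        } else if (p == 2L) {
            ld <- log(pmax(E[, 1] * E[, 3] - E[, 2]^2, 1e-300))
        } else {
            ld <- apply(E, 1, function(e) {
                M <- matrix(0, p, p)
                M[cbind(pairs[, 1], pairs[, 2])] <- e
                M[cbind(pairs[, 2], pairs[, 1])] <- e
                d <- determinant(M, logarithm = TRUE)
                as.numeric(d$modulus)
            })
        }
        0.5 * sum(ld)
    }
    negll <- function(phi) -(.nbLogLik(y, mu, phi) - crPenalty(phi))
    opt <- stats::optimize(negll, interval = c(1e-6, 10), tol = 1e-6)
    phi <- opt$minimum
    if (negll(1e-6) <= opt$objective) phi <- 1e-6
    list(phi = phi, mu = mu)
}

# continuous residual-df adjustment: each observation contributes
# c_i = 1 - P(Y = 0 | mu_i, phi) df, so near-zero fitted values carry
# almost no information; d = max(0, sum(c) - p)
.adjustedResidDF <- function(mu, phi, p) {
    if (phi < 1e-10) p0 <- exp(-mu) else p0 <- (1 + phi * mu)^(-1 / phi)
    max(0, sum(1 - p0) - p)
}

#' Transcript-wise quasi-negative-binomial GLM fits
#'
#' The GLM backend: per-transcript log-link NB GLMs on divided counts with
#' log effective library sizes as offsets and a global dispersion phi
#' (IRLS, max 50 iterations, relative deviance tolerance 1e-8).
#' Residual df are adjusted continuously: observation i contributes
#' `1 - P(Y = 0 | mu_i, phi)` df, so transcripts whose fitted values are
#' very small but positive also lose df. The bias-adjusted mean deviance
#' `s2 = deviance / df` plays the role of the residual variance.
#' Coefficients are stored on the natural-log scale; result tables report
#' log2.
#'
#' @param object a [DividedCounts-class] (filtered and normalized).
#' @param design n-by-p full-rank design matrix.
#' @param dispersion global NB dispersion phi; estimated by
#'   [estimateCommonDispersion()] when NULL.
#' @return A [TranscriptFit-class] with `backend = "nbglm"`.
#' @export
fitTranscriptNB <- function(object, design, dispersion = NULL) {
    z <- dividedCounts(object)
    design <- as.matrix(design)
    n <- ncol(z)
    p <- ncol(design)
    if (nrow(design) != n) stop("design must have one row per sample")
    if (qr(design)$rank < p) stop("design matrix is not of full column rank")
    off <- log(effectiveLibSizes(object))
    if (is.null(dispersion))
        dispersion <- estimateCommonDispersion(object, design)$phi
    phi <- dispersion
    nT <- nrow(z)
    beta <- matrix(NA_real_, nT, p, dimnames = list(rownames(z),
                                                    colnames(design)))
    v <- matrix(NA_real_, nT, p)
    fittedM <- matrix(NA_real_, nT, n, dimnames = dimnames(z))
    s2 <- numeric(nT)
    df <- numeric(nT)
    conv <- logical(nT)
    for (t in seq_len(nT)) {
        fit <- .irlsNB(z[t, ], design, off, phi)
        if (!fit$converged)
            warning("IRLS did not converge for transcript ", rownames(z)[t],
                    "; using last iterate")
        beta[t, ] <- fit$beta
        vi <- tryCatch(diag(chol2inv(chol(fit$XtWX))),
                       error = function(e) rep(NA_real_, p))
        v[t, ] <- pmax(vi, 1e-12)
        fittedM[t, ] <- fit$mu
        df[t] <- .adjustedResidDF(fit$mu, phi, p)
        s2[t] <- if (df[t] > 0) fit$deviance / df[t] else NA_real_
        conv[t] <- fit$converged
    }
    cat <- txCatalog(object)
    new("TranscriptFit", ids = cat$transcript_id, geneIds = cat$gene_id,
        coefficients = beta, unscaledVar = v, s2 = s2, df = df,
        fittedMean = fittedM, weights = matrix(numeric(0), 0, 0),
        design = design, counts = z, backend = "nbglm", dispersion = phi,
        offsets = off, converged = conv)
}

#' Fitted transcripts-per-million from a GLM fit
#'
#' Recovers TPM values from the NB GLM fitted coefficients: for transcript
#' t and sample i the raw value is \eqn{\tau_t / L_t \exp(x_i^T \beta_t)}
#' (effective-library offset excluded, tau the RTA overdispersion, L the
#' effective transcript length), then one global constant scales all
#' entries so that the geometric mean of the per-sample TPM column totals
#' equals 1e6. Within-gene expression proportions are computed per sample;
#' genes with all-zero fitted values get missing proportions. Fold-changes
#' implied by the coefficients are preserved exactly.
#'
#' @param fit a [TranscriptFit-class] from [fitTranscriptNB()].
#' @param object the [DividedCounts-class] the fit was computed on (carries
#'   tau and effective lengths).
#' @return list with matrices `tpm` and `proportions` (transcripts by
#'   samples).
#' @export
fittedTPM <- function(fit, object) {
    if (fit@backend != "nbglm")
        stop("fitted TPM extraction requires the nbglm backend")
    cat <- txCatalog(object)
    if (!identical(cat$transcript_id, fit@ids))
        stop("fit and divided counts disagree on transcripts")
    if (is.null(cat$effective_length))
        stop("catalog lacks effective lengths")
    eta <- fit@coefficients %*% t(fit@design)
    raw <- (cat$tau / cat$effective_length) * exp(pmin(eta, 700))
    tots <- colSums(raw)
    C <- 1e6 / exp(mean(log(tots)))
    tpm <- raw * C
    dimnames(tpm) <- list(fit@ids, rownames(fit@design))
    geneTot <- rowsum(tpm, fit@geneIds)
    gt <- geneTot[match(fit@geneIds, rownames(geneTot)), , drop = FALSE]
    prop <- tpm / gt
    prop[gt == 0] <- NA_real_
    list(tpm = tpm, proportions = prop)
}
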