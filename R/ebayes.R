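#' Invert the trigamma function
#'
#' Newton solve of trigamma(x) = y for x > 0, initialized at 0.5 + 1/y.
#' Monotone and convex in 1/trigamma, so convergence takes a handful of
#' iterations. Values of y near 0 map to x = Inf.
#'
#' @param y positive value(s).
#' @return x with trigamma(x) = y.
#' @keywords internal
trigammaInverse <- function(y) {
    vapply(y, function(yi) {
        if (!is.finite(yi) || yi <= 0) return(Inf)
        if (yi > 1e7) return(1 / sqrt(yi))
        x <- 0.5 + 1 / yi
        for (i in 1:50) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
            x <- x + dif
            if (abs(dif) < 1e-8 * x) break
        }
        x
    }, numeric(1))
}

#' Empirical Bayes squeezing of gene variances with unequal df
#'
#' Genewise pooled residual variances (linear backend) or pooled mean
#' deviances (GLM backend) are shrunk toward a common prior under the
#' scaled-F hierarchical model \eqn{s^2_g \sim s_0^2 F(d_g, d_0)}. The
#' hyperparameters are estimated by moment matching on
#' \eqn{e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)}: the mean of e
#' identifies \eqn{s_0^2} given \eqn{d_0}, and
#' \eqn{\mathrm{var}(e) - \mathrm{mean}(\psi'(d_g/2)) = \psi'(d_0/2)} is
#' inverted for \eqn{d_0} by Newton on the trigamma. A non-positive
#' left-hand side gives \eqn{d_0 = \infty} (all genes share one variance);
#' values above 1e7 are treated as infinite. Posterior estimates are
#' \eqn{\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g)}; genes with
#' zero df get the prior.
#'
#' @param s2 per-gene pooled variances.
#' @param df per-gene pooled residual df.
#' @param geneIds gene identifiers (default names of `s2`).
#' @param winsorize logical; winsorize e at its 5\% and 95\% quantiles
#'   before moment matching (a light outlier protection, default off).
#' @return A [GeneEBayes-class] object.
#' @export
squeezeVariances <- function(s2, df, geneIds = names(s2),
                             winsorize = FALSE) {
    if (is.null(geneIds)) geneIds <- as.character(seq_along(s2))
    ok <- which(df > 0 & is.finite(s2) & s2 > 0)
    if (length(ok) < 2)
        stop("need at least 2 genes with positive df and variance")
    s2use <- s2[ok]
    e <- log(s2use) - digamma(df[ok] / 2) + log(df[ok] / 2)
    if (winsorize) {
        q <- stats::quantile(e, c(0.05, 0.95), names = FALSE)
        e <- pmin(pmax(e, q[1]), q[2])
        qs <- stats::quantile(s2use, c(0.05, 0.95), names = FALSE)
        s2use <- pmin(pmax(s2use, qs[1]), qs[2])
    }
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
    if (!is.finite(evar) || evar <= 0) {
        d0 <- Inf
        s02 <- mean(s2use)
    } else {
        d0 <- 2 * trigammaInverse(evar)
        if (d0 > 1e7) {
            d0 <- Inf
            s02 <- mean(s2use)
        } else {
            s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
        }
    }
    post <- rep(s02, length(s2))
    if (is.finite(d0)) {
        post[ok] <- (d0 * s02 + df[ok] * s2[ok]) / (d0 + df[ok])
    }
    new("GeneEBayes", geneIds = as.character(geneIds), df = as.numeric(df),
        s2 = as.numeric(s2), priorDF = d0, priorVar = s02,
        posterior = post)
}

#' Pool transcript residual variances within genes
#'
#' \eqn{d_g = \sum_t d_{gt}} and
#' \eqn{s^2_g = (1/d_g) \sum_t d_{gt} s^2_{gt}} over the transcripts of
#' each gene (transcripts with zero df contribute nothing).
#'
#' @param fit a [TranscriptFit-class].
#' @return data.frame with columns `gene_id`, `df`, `s2`.
#' @export
poolGeneVariances <- function(fit) {
    d <- fit@df
    s2 <- fit@s2
    contrib <- ifelse(d > 0 & is.finite(s2), d * s2, 0)
    duse <- ifelse(d > 0 & is.finite(s2), d, 0)
    dg <- rowsum(duse, fit@geneIds)
    num <- rowsum(contrib, fit@geneIds)
    s2g <- ifelse(dg > 0, num / pmax(dg, 1e-300), NA_real_)
    data.frame(gene_id = rownames(dg), df = as.numeric(dg),
               s2 = as.numeric(s2g), stringsAsFactors = FALSE)
}
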