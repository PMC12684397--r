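design6 <- cbind(Intercept = 1, group = rep(0:1, each = 3))

test_that("NB deviance obeys its closed form, Poisson limit and unimodality", {
    y <- c(3, 5)
    mu <- c(4, 4)
    # y = mu gives zero
    expect_equal(nbDeviance(y, y, 0.1), 0)
    # phi -> 0 equals the Poisson deviance
    poisDev <- 2 * sum(y * log(y / mu) - (y - mu))
    expect_equal(nbDeviance(y, mu, 1e-12), poisDev, tolerance = 1e-6)
    expect_equal(nbDeviance(y, mu, 0), poisDev, tolerance = 1e-12)
    # strictly increasing as mu moves away from y
    grid <- seq(0.2, 3, by = 0.1)
    dleft <- vapply(rev(grid[grid < 1]), function(f)
        nbDeviance(y, y * f, 0.05), numeric(1))
    dright <- vapply(grid[grid > 1], function(f)
        nbDeviance(y, y * f, 0.05), numeric(1))
    expect_true(all(diff(dleft) > 0))
    expect_true(all(diff(dright) > 0))
})

test_that("saturated-in-groups NB fits reproduce group means and closed-form deviance", {
    set.seed(31)
    z <- matrix(rpois(6 * 6, 80), 6, 6)
    dv <- makeDivided(z)
    # force equal offsets so fitted means are interpretable directly
    SummarizedExperiment::colData(dv)$libSize <- rep(1e6, 6)
    phi <- 0.05
    fit <- fitTranscriptNB(dv, design6, dispersion = phi)
    gm <- cbind(rowMeans(z[, 1:3]), rowMeans(z[, 4:6]))
    expect_equal(unname(fit@fittedMean[, c(1, 4)]), unname(gm),
                 tolerance = 1e-6)
    for (t in 1:3)
        expect_equal(nbDeviance(z[t, ], fit@fittedMean[t, ], phi),
                     fit@s2[t] * fit@df[t], tolerance = 1e-8)
    # intercept-only: fitted mean equals the arithmetic mean
    fit0 <- fitTranscriptNB(dv, design6[, 1, drop = FALSE],
                            dispersion = phi)
    expect_equal(unname(fit0@fittedMean[, 1]), unname(rowMeans(z)),
                 tolerance = 1e-6)
})

test_that("NB GLM coefficients agree with an independent GLM fitter", {
    skip_if_not_installed("edgeR")
    set.seed(32)
    z <- matrix(rnbinom(8 * 6, mu = 120, size = 1 / 0.08), 8, 6)
    dv <- makeDivided(z)
    phi <- 0.08
    fit <- fitTranscriptNB(dv, design6, dispersion = phi)
    off <- log(effectiveLibSizes(dv))
    ref <- edgeR::glmFit(z, design6, dispersion = phi,
                         offset = off, prior.count = 0)
    expect_equal(unname(fit@coefficients), unname(ref$coefficients),
                 tolerance = 1e-4)
    expect_equal(unname(fit@fittedMean), unname(ref$fitted.values),
                 tolerance = 1e-4)
})

test_that("all-zero transcripts get near-zero fitted means and zero deviance", {
    z <- rbind(rep(0, 6), rep(25, 6))
    dv <- makeDivided(z)
    fit <- fitTranscriptNB(dv, design6, dispersion = 0.05)
    expect_true(all(fit@fittedMean[1, ] < 1e-300))
    expect_equal(fit@df[1], 0)
    expect_true(is.na(fit@s2[1]))
})

test_that("continuous residual df interpolates between 0 and n - p", {
    irls <- divSplice:::.adjustedResidDF
    expect_equal(irls(rep(60, 6), 0.05, 2), 4, tolerance = 1e-4)
    expect_equal(irls(rep(1e-7, 6), 0.05, 2), 0)
    # P(0) = 1/2 at mu = log(2) under Poisson: each observation carries 1/2 df
    expect_equal(irls(rep(log(2), 4), 0, 1), 1, tolerance = 1e-12)
    # monotone non-decreasing in every mu
    d1 <- irls(c(1, 2, 3, 4), 0.1, 1)
    d2 <- irls(c(1, 2, 3.5, 4), 0.1, 1)
    expect_gte(d2, d1)
})

test_that("global dispersion estimation recovers the simulation truth", {
    set.seed(33)
    nT <- 2000
    lam <- exp(runif(nT, log(20), log(2000)))
    zP <- matrix(rpois(nT * 6, rep(lam, 6)), nT, 6)
    dvP <- makeDivided(zP)
    expect_lt(estimateCommonDispersion(dvP, design6)$phi, 0.01)
    zN <- matrix(rnbinom(nT * 6, mu = rep(lam, 6), size = 1 / 0.05), nT, 6)
    dvN <- makeDivided(zN)
    phiN <- estimateCommonDispersion(dvN, design6)$phi
    expect_gt(phiN, 0.035)
    expect_lt(phiN, 0.065)
    # constant counts: no overdispersion detectable, estimate at the floor
    z1 <- matrix(40, 1, 6)
    phi1 <- estimateCommonDispersion(makeDivided(z1),
                                     design6[, 1, drop = FALSE])$phi
    expect_lte(phi1, 1e-6 + 1e-9)
})

test_that("phi = 0 reduces the NB machinery to its Poisson counterpart", {
    set.seed(34)
    y <- rpois(6, 50)
    mu <- rep(48, 6)
    expect_equal(nbDeviance(y, mu, 0), nbDeviance(y, mu, 1e-14),
                 tolerance = 1e-8)
    adf <- divSplice:::.adjustedResidDF
    expect_equal(adf(mu, 0, 2), adf(mu, 1e-14, 2), tolerance = 1e-8)
    z <- matrix(rpois(4 * 6, 100), 4, 6)
    dv <- makeDivided(z)
    f0 <- fitTranscriptNB(dv, design6, dispersion = 0)
    fe <- fitTranscriptNB(dv, design6, dispersion = 1e-12)
    expect_equal(f0@coefficients, fe@coefficients, tolerance = 1e-6)
})

test_that("fitted TPM recovers coefficient fold-changes and the scaling contract", {
    # two-transcript gene, two conditions, saturated design
    set.seed(35)
    z <- rbind(c(200, 210, 190, 400, 420, 390),
               c(100, 95, 105, 100, 102, 98),
               c(1000, 1010, 990, 1000, 990, 1010))
    dv <- makeDivided(z, geneIds = c("g1", "g1", "g2"))
    rd <- SummarizedExperiment::rowData(dv)
    rd$effective_length <- c(1000, 500, 2000)
    rd$tau <- c(1.5, 1, 2)
    SummarizedExperiment::rowData(dv) <- rd
    fit <- fitTranscriptNB(dv, design6, dispersion = 0.01)
    out <- fittedTPM(fit, dv)
    # geometric mean of column totals is 1e6
    expect_equal(exp(mean(log(colSums(out$tpm)))), 1e6, tolerance = 1e-6)
    # TPM ratio condition B / condition A equals exp(beta_2) per transcript
    gamma <- exp(fit@coefficients[, 2])
    expect_equal(unname(out$tpm[, 4] / out$tpm[, 1]), unname(gamma),
                 tolerance = 1e-8)
    # proportions sum to 1 within genes
    expect_equal(unname(colSums(out$proportions[1:2, ])), rep(1, 6),
                 tolerance = 1e-12)
})

test_that("equal fold-changes give equal proportions in both conditions", {
    # both transcripts of the gene shift two-fold: delta = 1
    z <- rbind(c(200, 200, 200, 400, 400, 400),
               c(100, 100, 100, 200, 200, 200),
               c(500, 500, 500, 500, 500, 500))
    dv <- makeDivided(z, geneIds = c("g1", "g1", "g2"))
    fit <- fitTranscriptNB(dv, design6, dispersion = 1e-6)
    out <- fittedTPM(fit, dv)
    expect_equal(out$proportions[1, 1], out$proportions[1, 4],
                 tolerance = 1e-6)
    expect_equal(out$proportions[2, 1], out$proportions[2, 4],
                 tolerance = 1e-6)
})
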