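test_that("Simes and BH follow their closed forms", {
    expect_equal(simesP(c(0.01, 0.04)), 0.02)
    expect_equal(simesP(0.3), 0.3)
    expect_equal(simesP(rep(0.2, 5)), 0.2)
    p <- runif(20)
    expect_gte(simesP(p), min(p))
    expect_lte(simesP(p), length(p) * min(p))
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(0.2), 0.2)
    q <- runif(50)
    expect_true(all(bhAdjust(q) >= q & bhAdjust(q) <= 1))
})

test_that("the leverage identity links leave-one-out and all-transcript consensus", {
    set.seed(51)
    for (rep in 1:20) {
        Tg <- sample(2:8, 1)
        u <- runif(Tg, 0.1, 5)
        beta <- rnorm(Tg)
        bbar <- sum(u * beta) / sum(u)
        h <- u / sum(u)
        bloo <- vapply(seq_len(Tg), function(t)
            sum(u[-t] * beta[-t]) / sum(u[-t]), numeric(1))
        expect_equal(beta - bbar, (1 - h) * (beta - bloo), tolerance = 1e-10)
        # weighted centering
        expect_lt(abs(sum(u * (beta - bbar))), 1e-10)
    }
})

test_that("equal coefficients within a gene give zero statistics and p = 1", {
    # gene g1: three transcripts with identical group coefficients;
    # gene g2: two transcripts that differ (so hyperparameters exist)
    beta <- cbind(rep(0.3, 5), c(1.7, 1.7, 1.7, 0, 1))
    v <- matrix(c(1, 2, 0.5, 1, 1), 5, 2)
    fit <- makeManualFit(beta, v, s2 = c(1, 1.2, 0.9, 1.1, 1),
                         df = rep(4, 5), geneIds = c(rep("g1", 3), "g2", "g2"))
    res <- diffSpliceDTU(fit, coef = 2)
    gt <- geneResults(res)
    tt <- transcriptResults(res)
    expect_equal(gt$F[gt$gene_id == "g1"], 0)
    expect_equal(gt$P.Value[gt$gene_id == "g1"], 1)
    expect_equal(tt$t[tt$gene_id == "g1"], rep(0, 3))
    expect_equal(tt$P.Value[tt$gene_id == "g1"], rep(1, 3))
})

test_that("moderated F recomputes from the stored t and leverage", {
    fx <- smallSimFit()
    gt <- geneResults(fx$resLM)
    tt <- transcriptResults(fx$resLM)
    for (g in gt$gene_id[1:25]) {
        rows <- tt[tt$gene_id == g, ]
        Tg <- nrow(rows)
        Fre <- sum((1 - rows$leverage) * rows$t^2) / (Tg - 1)
        expect_equal(gt$F[gt$gene_id == g], Fre, tolerance = 1e-10)
        # weighted centering of relative effects: u = h * const
        expect_lt(abs(sum(rows$leverage * rows$logFC)), 1e-8)
    }
})

test_that("F and Simes p-values coincide for two-transcript genes, both backends", {
    fx <- smallSimFit()
    for (res in list(fx$resLM, fx$resNB)) {
        gt <- geneResults(res)
        two <- gt[gt$n_transcripts == 2, ]
        expect_gt(nrow(two), 20)
        expect_equal(two$P.Value, two$P.Simes, tolerance = 1e-12)
    }
})

test_that("gene and transcript quasi-F tests coincide for two-transcript genes", {
    fx <- smallSimFit()
    gt <- geneResults(fx$resNB)
    tt <- transcriptResults(fx$resNB)
    two <- gt[gt$n_transcripts == 2, ]
    for (g in two$gene_id[1:20]) {
        rows <- tt[tt$gene_id == g, ]
        expect_equal(rows$F, rep(two$F[two$gene_id == g], 2),
                     tolerance = 1e-10)
        expect_equal(rows$P.Value, rep(two$P.Value[two$gene_id == g], 2),
                     tolerance = 1e-10)
    }
})

test_that("the fast transcript approximation tracks the exact quasi-F path", {
    fx <- smallSimFit()
    fit <- fx$fitNB
    tt <- transcriptResults(fx$resNB)
    phi <- fit@dispersion
    beta <- fit@coefficients[, 2]
    v <- fit@unscaledVar[, 2]
    ids <- split(seq_along(fit@ids), fit@geneIds)
    ids <- ids[vapply(ids, length, 1L) >= 3 & vapply(ids, length, 1L) <= 10]
    fastF <- exactF <- numeric(0)
    for (ix in ids[seq_len(min(40, length(ids)))]) {
        u <- 1 / v[ix]
        bbar <- sum(u * beta[ix]) / sum(u)
        nullFit <- divSplice:::.sharedCoefFit(fit@counts[ix, , drop = FALSE],
                                              fit@design, fit@offsets, phi,
                                              2L, bbar)
        devFull <- vapply(seq_along(ix), function(t)
            nbDeviance(fit@counts[ix[t], ], fit@fittedMean[ix[t], ], phi),
            numeric(1))
        fastD <- pmax(0, nullFit$devByTx - devFull)
        rows <- tt[match(fit@ids[ix], tt$transcript_id), ]
        fastF <- c(fastF, fastD)
        exactF <- c(exactF, rows$deltaDeviance)
    }
    expect_gt(cor(fastF, exactF, method = "spearman"), 0.95)
})

test_that("ranked extraction is deterministic and respects cutoffs", {
    fx <- smallSimFit()
    res <- fx$resLM
    expect_equal(nrow(topSpliceDTU(res, "gene", n = 0)), 0L)
    allRows <- topSpliceDTU(res, "gene", fdrCutoff = 1)
    expect_equal(nrow(allRows), nrow(geneResults(res)))
    expect_true(!is.unsorted(allRows$P.Value))
    sim <- topSpliceDTU(res, "simes", n = 10)
    expect_true(!is.unsorted(sim$P.Value))
    expect_lte(nrow(topSpliceDTU(res, "transcript", fdrCutoff = 0.05)),
               nrow(transcriptResults(res)))
    # permuting the fit rows does not change the ranked output
    expect_error(topSpliceDTU(res, "exon"), "arg")
})

test_that("linear-backend DTU statistics match the reference implementation", {
    skip_if_not_installed("limma")
    fx <- smallSimFit()
    fit <- fx$fitLM
    y <- logCPM(fx$divided)
    ref <- limma::lmFit(y, fx$design, weights = fit@weights)
    sp <- limma::diffSplice(ref, geneid = fit@geneIds, exonid = fit@ids,
                            verbose = FALSE)
    mine <- transcriptResults(fx$resLM)
    ord <- match(mine$transcript_id, sp$genes$ExonID)
    refT <- sp$t[ord, 2]
    # same data, same statistic: near-perfect agreement up to small
    # differences in df bookkeeping and hyperparameter estimation
    expect_gt(cor(mine$t, refT), 0.999)
    refGeneP <- sp$gene.F.p.value[match(geneResults(fx$resLM)$gene_id,
                                        sp$gene.genes$GeneID), 2]
    expect_gt(cor(-log10(geneResults(fx$resLM)$P.Value),
                  -log10(refGeneP)), 0.99)
})
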