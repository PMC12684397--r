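test_that("catalog generation is deterministic and has the declared shape", {
    cfg <- simConfig(nGenes = 1000, seed = 61)
    a <- buildSimCatalog(cfg)
    b <- buildSimCatalog(cfg)
    expect_identical(a, b)
    expect_equal(length(unique(a$catalog$gene_id)), 1000L)
    nTx <- table(a$catalog$gene_id)
    expect_true(all(nTx >= 1 & nTx <= 10))
    expect_gt(mean(nTx >= 2), 0.5)
    expect_true(all(a$catalog$effective_length >= 300 &
                    a$catalog$effective_length <= 10000))
    expect_equal(sum(a$baselineTPM), 1e6)
})

test_that("dispersion draws invert to the declared chi-squared distribution", {
    set.seed(62)
    cfg <- simConfig()
    phi <- drawDispersions(1e5, cfg)
    expect_true(all(phi > 0))
    x <- cfg$bcvDF * cfg$priorBCV^2 / phi
    expect_equal(mean(x), cfg$bcvDF, tolerance = 0.01)
})

test_that("truth assignment enforces the exact fold-change rules", {
    cfg <- simConfig(nGenes = 600, seed = 63)
    info <- buildSimCatalog(cfg)
    tr <- assignTruth(info, cfg)
    truth <- tr$truth
    byGene <- split(seq_len(nrow(truth)), truth$gene_id)
    counts <- table(factor(tr$geneTruth$category,
                           c("null", "dtu_only", "dge_dtu", "dge_only")))
    expect_equal(as.integer(counts[-1]), as.integer(cfg$split))
    for (g in tr$geneTruth$gene_id[tr$geneTruth$category == "dtu_only"][1:30]) {
        ix <- byGene[[g]]
        ratio <- tr$tpmB[ix] / tr$tpmA[ix]
        flagged <- truth$is_DTU[ix]
        expect_equal(sum(flagged), 2L)
        expect_setequal(round(ratio[flagged], 10), c(2, 0.5))
        expect_equal(ratio[!flagged], rep(1, sum(!flagged)))
        expect_equal(sum(tr$tpmB[ix]), sum(tr$tpmA[ix]), tolerance = 1e-9)
    }
    for (g in tr$geneTruth$gene_id[tr$geneTruth$category == "dge_only"][1:30]) {
        ix <- byGene[[g]]
        ratio <- tr$tpmB[ix] / tr$tpmA[ix]
        expect_true(all(abs(ratio - 2) < 1e-12) ||
                    all(abs(ratio - 0.5) < 1e-12))
        expect_false(any(truth$is_DTU[ix]))
        propA <- tr$tpmA[ix] / sum(tr$tpmA[ix])
        propB <- tr$tpmB[ix] / sum(tr$tpmB[ix])
        expect_equal(propA, propB, tolerance = 1e-12)
    }
    dgeDtu <- tr$geneTruth$gene_id[tr$geneTruth$category == "dge_dtu"]
    for (g in dgeDtu[1:30]) {
        ix <- byGene[[g]]
        expect_true(all(truth$is_DTU[ix]))
        expect_equal(sum(truth$is_DE[ix]), 1L)
    }
    # direction balance is close to 50/50 over many genes
    dirs <- truth$direction[truth$is_DE]
    expect_gt(mean(dirs == "up"), 0.4)
    expect_lt(mean(dirs == "up"), 0.6)
})

test_that("null mode leaves expected TPM identical across groups", {
    cfg <- simConfig(nGenes = 100, seed = 64)
    info <- buildSimCatalog(cfg)
    tr <- assignTruth(info, cfg, nullMode = TRUE)
    expect_identical(tr$tpmA, tr$tpmB)
    expect_true(all(tr$geneTruth$category == "null"))
    expect_false(any(tr$truth$is_DTU))
})

test_that("count generation reproduces the quasi-Poisson variance construction", {
    # fixed mu = 400 per transcript, tau = 4, negligible biological noise:
    # 2000 replicate draws across transcripts/samples have var/mean near 4
    nT <- 200
    info <- list(catalog = data.frame(transcript_id = paste0("t", 1:nT),
                                      gene_id = paste0("g", 1:nT),
                                      length = 1000L,
                                      effective_length = rep(1000, nT)),
                 baselineTPM = rep(1e6 / nT, nT))
    cfg <- simConfig(nGenes = nT, split = c(0, 0, 0), samplesPerGroup = 5,
                     libSizes = 400 * nT, B = 2,
                     tauSpec = function(n) rep(4, n))
    set.seed(65)
    tr <- assignTruth(info, cfg, nullMode = TRUE)
    sim <- simulateCounts(tr, info, cfg, phi = rep(1e-10, nT))
    y <- as.vector(txCounts(sim$quant))
    expect_equal(length(y), 2000L)
    expect_gt(var(y) / mean(y), 3.2)
    expect_lt(var(y) / mean(y), 4.8)
    expect_equal(mean(y), 400, tolerance = 0.05)
    # tau = 1 with large mu approaches the Poisson coefficient of variation
    cfg1 <- cfg; cfg1$tauSpec <- function(n) rep(1, n)
    sim1 <- simulateCounts(tr, info, cfg1, phi = rep(1e-10, nT))
    y1 <- as.vector(txCounts(sim1$quant))
    cv <- sd(y1) / mean(y1)
    expect_equal(cv, 1 / sqrt(400), tolerance = 0.2)
    # column sums track the configured library size
    expect_true(all(abs(colSums(txCounts(sim1$quant)) - 400 * nT)
                    <= 3 * sqrt(400 * nT)))
})

test_that("a fixed seed makes the full generator byte-identical", {
    cfg <- simConfig(nGenes = 40, samplesPerGroup = 2, B = 3, seed = 66)
    s1 <- simulateDTUDataset(cfg)
    s2 <- simulateDTUDataset(cfg)
    expect_identical(txCounts(s1$quant), txCounts(s2$quant))
    expect_identical(txResamples(s1$quant), txResamples(s2$quant))
    expect_identical(s1$truth, s2$truth)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeFixtureBundle(s1, d1, force = TRUE)
    writeFixtureBundle(s2, d2, force = TRUE)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("performance evaluation computes FDR, power and type I error exactly", {
    # fabricated results: 95 true discoveries, 5 false, on a known truth
    gt <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     n_transcripts = 2L, consensus = 0,
                     F = 1, df1 = 1, df2 = 10,
                     P.Value = c(rep(0.001, 100), seq(0.2, 0.99,
                                                      length.out = 100)),
                     P.Simes = c(rep(0.001, 100), seq(0.2, 0.99,
                                                      length.out = 100)))
    gt$FDR <- bhAdjust(gt$P.Value)
    gt$FDR.Simes <- bhAdjust(gt$P.Simes)
    tt <- data.frame(transcript_id = sprintf("t%03d", 1:200),
                     gene_id = gt$gene_id, logFC = 0, leverage = 0.5,
                     t = 0, P.Value = gt$P.Value)
    tt$FDR <- bhAdjust(tt$P.Value)
    res <- new("DTUResults", geneTable = gt, transcriptTable = tt,
               backend = "lm", coef = 2L)
    truth <- data.frame(transcript_id = tt$transcript_id,
                        gene_id = gt$gene_id,
                        category = c(rep("dtu_only", 95),
                                     rep("null", 105)),
                        is_DE = FALSE,
                        is_DTU = c(rep(TRUE, 95), rep(FALSE, 105)),
                        direction = NA_character_)
    perf <- evaluatePerformance(res, truth, cutoffs = 0.05)
    gene <- perf[perf$level == "gene_F", ]
    expect_equal(gene$TP, 95)
    expect_equal(gene$FP, 5)
    expect_equal(gene$FDR, 0.05)
    expect_equal(gene$power, 1)
    expect_equal(gene$typeI, 5 / 105)
    cfd <- cumulativeFalseDiscoveries(res, truth, "gene")
    expect_equal(cfd[100], 5)
    expect_equal(max(cfd), 105)
    # id mismatch is an error
    expect_error(evaluatePerformance(res, truth[-1, ], 0.05), "missing")
})

test_that("uniform p-values on a pure null give nominal type I error", {
    set.seed(67)
    n <- 4000
    p <- runif(n)
    gt <- data.frame(gene_id = sprintf("g%05d", 1:n), n_transcripts = 2L,
                     consensus = 0, F = 1, df1 = 1, df2 = 10,
                     P.Value = p, P.Simes = p)
    gt$FDR <- bhAdjust(p); gt$FDR.Simes <- gt$FDR
    tt <- data.frame(transcript_id = sprintf("t%05d", 1:n),
                     gene_id = gt$gene_id, logFC = 0, leverage = 0.5,
                     t = 0, P.Value = p, FDR = bhAdjust(p))
    res <- new("DTUResults", geneTable = gt, transcriptTable = tt,
               backend = "lm", coef = 2L)
    truth <- data.frame(transcript_id = tt$transcript_id,
                        gene_id = gt$gene_id, category = "null",
                        is_DE = FALSE, is_DTU = FALSE,
                        direction = NA_character_)
    perf <- evaluatePerformance(res, truth, cutoffs = 0.05)
    band <- 2.576 * sqrt(0.05 * 0.95 / n)
    expect_lt(abs(perf$typeI[perf$level == "gene_F"] - 0.05), band)
})
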