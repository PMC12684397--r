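# deterministic in-code fixtures shared across test files

# tiny 2-gene / 4-transcript quantification with resamples
makeTinyQuant <- function(B = 5, seed = 42) {
    set.seed(seed)
    catalog <- data.frame(
        transcript_id = c("t1", "t2", "t3", "t4"),
        gene_id = c("g1", "g1", "g2", "g2"),
        length = c(1200L, 900L, 2000L, 1500L),
        effective_length = c(1000, 700, 1800, 1300),
        stringsAsFactors = FALSE)
    counts <- matrix(c(100, 50, 80, 20,
                       120, 40, 90, 25,
                       110, 45, 70, 30), nrow = 4,
                     dimnames = list(catalog$transcript_id,
                                     c("s1", "s2", "s3")))
    resamples <- lapply(seq_len(ncol(counts)), function(i)
        matrix(rpois(4 * B, counts[, i]), 4, B,
               dimnames = list(catalog$transcript_id,
                               paste0("rep", seq_len(B)))))
    TxQuant(counts, catalog, resamples, colnames(counts))
}

# a DividedCounts object from an arbitrary count matrix (tau = 1)
makeDivided <- function(z, geneIds = NULL) {
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(z)))
    catalog <- data.frame(transcript_id = paste0("t", seq_len(nrow(z))),
                          gene_id = geneIds,
                          length = 1000L, effective_length = 1000,
                          stringsAsFactors = FALSE)
    tq <- TxQuant(z, catalog)
    divideCounts(tq, rep(1, nrow(z)))
}

# a hand-built linear-backend TranscriptFit with fabricated statistics,
# for exercising the moderated-statistic algebra in isolation
makeManualFit <- function(beta, v, s2, df, geneIds) {
    nT <- nrow(beta)
    n <- 6L
    new("TranscriptFit",
        ids = paste0("t", seq_len(nT)), geneIds = geneIds,
        coefficients = beta, unscaledVar = v, s2 = s2, df = df,
        fittedMean = matrix(0, nT, n), weights = matrix(1, nT, n),
        design = cbind(1, rep(0:1, each = 3)),
        counts = matrix(1, nT, n),
        backend = "lm", dispersion = NA_real_, offsets = rep(0, n),
        converged = rep(TRUE, nT))
}

# cached small simulated dataset + fits: built once per test run
.fixtureEnv <- new.env(parent = emptyenv())
smallSimFit <- function() {
    if (!is.null(.fixtureEnv$sim)) return(.fixtureEnv$sim)
    cfg <- simConfig(nGenes = 400, samplesPerGroup = 5, B = 30, seed = 99)
    sim <- simulateDTUDataset(cfg)
    rta <- estimateRTA(sim$quant)
    divided <- normalizeLibSizes(divideCounts(sim$quant, rta))
    keep <- filterTranscripts(divided, sim$groups)
    dk <- subsetTranscripts(divided, keep)
    design <- stats::model.matrix(~sim$groups)
    fitLM <- fitTranscriptLM(dk, design, groups = sim$groups)
    fitNB <- fitTranscriptNB(dk, design)
    out <- list(sim = sim, divided = dk, design = design,
                fitLM = fitLM, fitNB = fitNB,
                resLM = diffSpliceDTU(fitLM),
                resNB = diffSpliceDTU(fitNB))
    .fixtureEnv$sim <- out
    out
}
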