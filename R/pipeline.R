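#' Run the full DTU pipeline
#'
#' The three-step analysis in one call: (1) estimate RTA overdispersions
#' from the technical resamples and divide the counts; (2) filter
#' low-expressed transcripts and compute TMM effective library sizes on
#' the divided counts; (3) fit transcript-wise models with the chosen
#' backend and test differential usage with moderated (linear backend) or
#' deviance quasi-F (GLM backend) statistics. Optionally writes ranked
#' `genes.tsv` and `transcripts.tsv` plus a JSON run manifest.
#'
#' @param quant a [TxQuant-class] with resamples attached.
#' @param groups factor of treatment groups, one per sample (used for the
#'   default design, filtering and zero-group df adjustment).
#' @param design optional n-by-p design matrix; defaults to
#'   `model.matrix(~groups)`.
#' @param backend `"lm"` (weighted linear models on log2-CPM) or `"nbglm"`
#'   (quasi-negative-binomial GLMs).
#' @param coef coefficient to test (default 2, the group effect).
#' @param minCount,minTotalCount,lenient filtering parameters, see
#'   [filterTranscripts()].
#' @param normalize compute TMM factors (default TRUE).
#' @param priorDF,floor RTA estimation parameters, see [estimateRTA()].
#' @param winsorize outlier-protected empirical Bayes, see
#'   [squeezeVariances()].
#' @param outDir optional output directory for result tables and manifest.
#' @return invisibly, a list with `results` ([DTUResults-class]), `fit`,
#'   `divided` (filtered [DividedCounts-class]), `rta` and `keep` mask.
#' @export
runDTUPipeline <- function(quant, groups, design = NULL,
                           backend = c("lm", "nbglm"), coef = 2L,
                           minCount = 10, minTotalCount = 15,
                           lenient = FALSE, normalize = TRUE, priorDF = 3,
                           floor = 1, winsorize = FALSE, outDir = NULL) {
    backend <- match.arg(backend)
    groups <- as.factor(groups)
    if (is.null(design)) design <- stats::model.matrix(~groups)
    rta <- estimateRTA(quant, priorDF = priorDF, floor = floor)
    divided <- divideCounts(quant, rta)
    if (normalize) divided <- normalizeLibSizes(divided)
    keep <- filterTranscripts(divided, groups, minCount = minCount,
                              minTotalCount = minTotalCount,
                              lenient = lenient)
    dividedKept <- subsetTranscripts(divided, keep)
    fit <- if (backend == "lm")
        fitTranscriptLM(dividedKept, design, groups = groups)
    else fitTranscriptNB(dividedKept, design)
    results <- diffSpliceDTU(fit, coef = coef, winsorize = winsorize)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeResultTable(topSpliceDTU(results, "gene"),
                         file.path(outDir, "genes.tsv"))
        writeResultTable(topSpliceDTU(results, "transcript"),
                         file.path(outDir, "transcripts.tsv"))
        manifest <- list(package = "divSplice",
                         version = as.character(utils::packageVersion("divSplice")),
                         backend = backend, coef = coef,
                         nSamples = ncol(quant),
                         nTranscriptsInput = nrow(quant),
                         nTranscriptsKept = sum(keep),
                         filter = list(minCount = minCount,
                                       minTotalCount = minTotalCount,
                                       lenient = lenient),
                         rta = list(priorDF = priorDF, floor = floor),
                         dispersion = fit@dispersion)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(list(results = results, fit = fit, divided = dividedKept,
                   rta = rta, keep = keep))
}

#' Run a simulation benchmark
#'
#' For each replicate seed, simulates a dataset, runs the full pipeline
#' with the requested backends and scores the calls against the simulation
#' truth; metrics are averaged across replicates.
#'
#' @param config a [simConfig()] (its `seed` is the base seed; replicate r
#'   uses `seed + r - 1`).
#' @param backends character vector among `"lm"`, `"nbglm"`.
#' @param reps number of replicate simulations.
#' @param nullMode simulate without any differential signal (type I error
#'   study).
#' @param cutoffs FDR / p cutoffs to evaluate.
#' @param lenient use lenient filtering.
#' @param outDir optional directory to write `metrics.tsv`.
#' @return list with `perRep` (all replicate rows) and `mean` (metrics
#'   averaged over replicates per backend, level and cutoff).
#' @export
runBenchmark <- function(config = simConfig(seed = 1),
                         backends = c("lm", "nbglm"), reps = 5,
                         nullMode = FALSE, cutoffs = c(0.05),
                         lenient = FALSE, outDir = NULL) {
    baseSeed <- if (is.null(config$seed)) 1L else config$seed
    rows <- list()
    for (r in seq_len(reps)) {
        cfg <- config
        cfg$seed <- baseSeed + r - 1L
        sim <- simulateDTUDataset(cfg, nullMode = nullMode)
        for (bk in backends) {
            run <- runDTUPipeline(sim$quant, sim$groups, backend = bk,
                                  lenient = lenient)
            perf <- evaluatePerformance(run$results, sim$truth,
                                        cutoffs = cutoffs)
            perf$backend <- bk
            perf$rep <- r
            perf$seed <- cfg$seed
            rows <- c(rows, list(perf))
        }
    }
    perRep <- do.call(rbind, rows)
    agg <- stats::aggregate(perRep[c("TP", "FP", "FDR", "power", "typeI")],
                            by = perRep[c("backend", "level", "cutoff")],
                            FUN = mean)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(agg, file.path(outDir, "metrics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(perRep = perRep, mean = agg)
}
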