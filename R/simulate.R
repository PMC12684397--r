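#' Simulation configuration
#'
#' Parameters of the count-level DTU simulator. The defaults are a
#' desk-scale version of the benchmark design: 3000 genes with the number
#' of differential genes scaled proportionally from the full design (12715
#' genes with 4500 differential genes split equally into DTU-only,
#' DGE+DTU and DGE-only), two-fold changes, gamma-distributed true
#' sample-wise TPMs with transcript dispersions (squared BCV) drawn from a
#' scaled inverse chi-squared distribution (prior BCV 0.25, df 40), five
#' samples per group, library size 1e6, and B = 100 technical resamples
#' per sample. [fullScaleConfig()] restores the full-size design.
#'
#' @param nGenes number of genes.
#' @param split integer vector of length 3: numbers of DTU-only, DGE+DTU
#'   and DGE-only genes. Default: `nGenes * 1500/12715` each, rounded.
#' @param foldChange fold change applied to differential transcripts (> 1).
#' @param priorBCV prior biological coefficient of variation.
#' @param bcvDF df of the inverse chi-squared dispersion distribution.
#' @param samplesPerGroup biological replicates per group.
#' @param libSizes one or two library sizes; samples alternate between the
#'   two values (unbalanced design when they differ).
#' @param B number of technical resamples per sample.
#' @param tauSpec function(nTranscripts) drawing true RTA overdispersions;
#'   the default gives tau = 1 with probability 0.5 (unambiguous
#'   transcripts) and 1 + Exp(mean 1.5) otherwise.
#' @param seed integer seed for reproducibility (NULL: do not seed).
#' @return list of class `simConfig`.
#' @export
simConfig <- function(nGenes = 3000, split = NULL, foldChange = 2,
                      priorBCV = 0.25, bcvDF = 40, samplesPerGroup = 5,
                      libSizes = c(1e6, 1e6), B = 100, tauSpec = NULL,
                      seed = NULL) {
    if (is.null(split))
        split <- rep(round(nGenes * 1500 / 12715), 3)
    if (length(split) != 3 || any(split < 0))
        stop("split must be 3 non-negative counts (dtu_only, dge_dtu, dge_only)")
    if (foldChange <= 1) stop("foldChange must exceed 1")
    if (is.null(tauSpec))
        tauSpec <- function(n) {
            tau <- rep(1, n)
            amb <- stats::runif(n) < 0.5
            tau[amb] <- 1 + stats::rgamma(sum(amb), shape = 1, scale = 1.5)
            tau
        }
    structure(list(nGenes = nGenes, split = split, foldChange = foldChange,
                   priorBCV = priorBCV, bcvDF = bcvDF,
                   samplesPerGroup = samplesPerGroup, libSizes = libSizes,
                   B = B, tauSpec = tauSpec, seed = seed),
              class = "simConfig")
}

#' Full-scale simulation configuration
#'
#' The full benchmark design: 12715 genes, 4500 differential genes split
#' 1500/1500/1500, unbalanced library sizes of 25 and 100 million reads.
#'
#' @param samplesPerGroup replicates per group (3, 5 or 10 in the
#'   benchmark scenarios).
#' @param seed integer seed.
#' @param ... further arguments passed to [simConfig()].
#' @export
fullScaleConfig <- function(samplesPerGroup = 5, seed = NULL, ...) {
    simConfig(nGenes = 12715, split = c(1500, 1500, 1500),
              samplesPerGroup = samplesPerGroup,
              libSizes = c(25e6, 100e6), seed = seed, ...)
}

#' Build a simulated transcript catalog with baseline expression
#'
#' Genes carry 1-10 transcripts (zero-truncated geometric, mean about
#' 3.3); baseline expected TPM values are drawn log-normal
#' (meanlog 1.5, sdlog 2) — a heavy-tailed abundance distribution — and
#' normalized to sum to 1e6; effective lengths are log-uniform on
#' \[300, 10000\] nt.
#'
#' @param config a [simConfig()] list; its seed (if any) is applied first,
#'   so a fixed seed reproduces the catalog exactly.
#' @return list with `catalog` (data.frame) and `baselineTPM` (per
#'   transcript).
#' @export
buildSimCatalog <- function(config) {
    if (!is.null(config$seed)) set.seed(config$seed)
    nG <- config$nGenes
    nTx <- pmin(10L, 1L + stats::rgeom(nG, prob = 0.3))
    geneIds <- sprintf("G%06d", seq_len(nG))
    gid <- rep(geneIds, nTx)
    tid <- paste0(gid, ".", unlist(lapply(nTx, seq_len)))
    total <- sum(nTx)
    baseline <- exp(stats::rnorm(total, mean = 1.5, sd = 2))
    baseline <- baseline / sum(baseline) * 1e6
    efflen <- exp(stats::runif(total, log(300), log(10000)))
    catalog <- data.frame(transcript_id = tid, gene_id = gid,
                          length = round(efflen) + 200L,
                          effective_length = efflen,
                          stringsAsFactors = FALSE)
    list(catalog = catalog, baselineTPM = baseline)
}

#' Draw transcript-level dispersions
#'
#' Squared biological coefficients of variation phi_t drawn from a scaled
#' inverse chi-squared distribution:
#' `bcvDF * priorBCV^2 / phi_t ~ chi-squared(bcvDF)`.
#'
#' @param n number of transcripts.
#' @param config a [simConfig()] list (uses `priorBCV` and `bcvDF`).
#' @return vector of n positive dispersions.
#' @export
drawDispersions <- function(n, config = simConfig()) {
    config$bcvDF * config$priorBCV^2 / stats::rchisq(n, df = config$bcvDF)
}

#' Assign differential-usage and differential-expression truth
#'
#' Selects the configured numbers of multi-transcript genes and modifies
#' their group-B expected TPM:
#' * DTU-only genes have two transcripts set to baselines (a, 2a)
#'   preserving their combined expression, then swapped in group B — each
#'   changes exactly `foldChange`-fold while the gene total is unchanged;
#'   only those two transcripts are flagged differentially used.
#' * DGE+DTU genes have one transcript scaled by `foldChange` (up or down)
#'   in group B; all transcripts of the gene are flagged differentially
#'   used, since the others' proportions necessarily change.
#' * DGE-only genes have all transcripts scaled by the same factor; none
#'   are differentially used.
#' Up- and down-regulation are assigned 50/50. `nullMode` leaves every
#' expected TPM identical across groups.
#'
#' @param catalogInfo output of [buildSimCatalog()].
#' @param config a [simConfig()] list.
#' @param nullMode logical; generate a pure-null truth.
#' @return list with `tpmA`/`tpmB` (expected TPM per transcript and
#'   group), `truth` (per-transcript flags) and `geneTruth` (per-gene
#'   category).
#' @export
assignTruth <- function(catalogInfo, config, nullMode = FALSE) {
    catalog <- catalogInfo$catalog
    tpmA <- catalogInfo$baselineTPM
    tpmB <- tpmA
    gid <- catalog$gene_id
    nTx <- table(gid)[unique(gid)]
    category <- stats::setNames(rep("null", length(nTx)), names(nTx))
    isDE <- isDTU <- logical(nrow(catalog))
    direction <- rep(NA_character_, nrow(catalog))
    fc <- config$foldChange
    if (!nullMode) {
        multi <- names(nTx)[nTx >= 2]
        need <- sum(config$split)
        if (length(multi) < need)
            stop("need ", need, " multi-transcript genes but only ",
                 length(multi), " are available")
        chosen <- sample(multi, need)
        cats <- rep(c("dtu_only", "dge_dtu", "dge_only"), config$split)
        category[chosen] <- cats
        txOf <- split(seq_len(nrow(catalog)), gid)
        for (k in seq_along(chosen)) {
            g <- chosen[k]
            ix <- txOf[[g]]
            if (cats[k] == "dtu_only") {
                pair <- sample(ix, 2)
                a <- sum(tpmA[pair]) / (1 + fc)
                tpmA[pair] <- c(a, fc * a)
                tpmB[pair] <- c(fc * a, a)
                isDTU[pair] <- TRUE
                isDE[pair] <- TRUE
                direction[pair] <- c("up", "down")
            } else if (cats[k] == "dge_dtu") {
                t1 <- sample(ix, 1)
                up <- stats::runif(1) < 0.5
                tpmB[t1] <- tpmA[t1] * if (up) fc else 1 / fc
                isDTU[ix] <- TRUE
                isDE[t1] <- TRUE
                direction[t1] <- if (up) "up" else "down"
            } else {
                up <- stats::runif(1) < 0.5
                tpmB[ix] <- tpmA[ix] * if (up) fc else 1 / fc
                isDE[ix] <- TRUE
                direction[ix] <- if (up) "up" else "down"
            }
        }
    }
    truth <- data.frame(transcript_id = catalog$transcript_id,
                        gene_id = gid,
                        category = unname(category[gid]),
                        is_DE = isDE, is_DTU = isDTU,
                        direction = direction, stringsAsFactors = FALSE)
    geneTruth <- data.frame(gene_id = names(category),
                            category = unname(category),
                            stringsAsFactors = FALSE)
    list(tpmA = tpmA, tpmB = tpmB, truth = truth, geneTruth = geneTruth)
}

#' Simulate counts and technical resamples
#'
#' For each sample, true transcript TPMs are drawn from a gamma
#' distribution with mean equal to the group expected TPM and squared CV
#' phi_t; expected read counts allocate the library size proportionally to
#' TPM times effective length; raw counts emulate RTA overdispersion as
#' `tau * Poisson(mu / tau)` (variance tau times the mean), and each of
#' the B technical resamples re-draws `tau * Poisson(y / tau)` around the
#' observed count. True tau values are drawn once per transcript from the
#' config's `tauSpec`. Counts are kept fractional, as quantifier estimates
#' are.
#'
#' @param truthObj output of [assignTruth()].
#' @param catalogInfo output of [buildSimCatalog()].
#' @param config a [simConfig()] list.
#' @param phi per-transcript dispersions (drawn via [drawDispersions()]
#'   when NULL).
#' @return list with `quant` (a [TxQuant-class] with resamples), `tau`
#'   (true overdispersions), `phi`, `groups` (factor) and `libSizes`.
#' @export
simulateCounts <- function(truthObj, catalogInfo, config, phi = NULL) {
    catalog <- catalogInfo$catalog
    nT <- nrow(catalog)
    if (is.null(phi)) phi <- drawDispersions(nT, config)
    n <- 2L * config$samplesPerGroup
    groups <- factor(rep(c("A", "B"), each = config$samplesPerGroup))
    libs <- rep_len(config$libSizes, n)
    tau <- config$tauSpec(nT)
    counts <- matrix(0, nT, n)
    resamples <- vector("list", n)
    efflen <- catalog$effective_length
    for (i in seq_len(n)) {
        expTPM <- if (groups[i] == "A") truthObj$tpmA else truthObj$tpmB
        tpmTrue <- stats::rgamma(nT, shape = 1 / phi,
                                 rate = 1 / (phi * expTPM))
        frac <- tpmTrue * efflen
        mu <- libs[i] * frac / sum(frac)
        y <- tau * stats::rpois(nT, mu / tau)
        counts[, i] <- y
        resamples[[i]] <- tau * matrix(stats::rpois(nT * config$B,
                                                    rep(y / tau, config$B)),
                                       nT, config$B)
        colnames(resamples[[i]]) <- paste0("rep", seq_len(config$B))
    }
    sampleIds <- paste0(rep(c("A", "B"), each = config$samplesPerGroup),
                        seq_len(config$samplesPerGroup))
    colnames(counts) <- sampleIds
    names(resamples) <- sampleIds
    quant <- TxQuant(counts, catalog, resamples, sampleIds)
    list(quant = quant, tau = tau, phi = phi, groups = groups,
         libSizes = libs)
}

#' Simulate a complete DTU dataset
#'
#' Seeds the random stream (if the config has a seed), builds the catalog,
#' assigns truth and generates counts plus resamples: the one-call
#' interface to the generator.
#'
#' @param config a [simConfig()] list.
#' @param nullMode logical; no differential usage or expression.
#' @return list with `quant`, `truth`, `geneTruth`, `tau`, `phi`,
#'   `groups`, `catalogInfo`, `config`.
#' @export
simulateDTUDataset <- function(config = simConfig(), nullMode = FALSE) {
    if (!is.null(config$seed)) set.seed(config$seed)
    catalogInfo <- buildSimCatalog(config)
    truthObj <- assignTruth(catalogInfo, config, nullMode = nullMode)
    sim <- simulateCounts(truthObj, catalogInfo, config)
    list(quant = sim$quant, truth = truthObj$truth,
         geneTruth = truthObj$geneTruth, tau = sim$tau, phi = sim$phi,
         groups = sim$groups, catalogInfo = catalogInfo, config = config)
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' One quantification table (`quant.sf` dialect) and one resample TSV per
#' sample, plus `catalog.tsv`, `truth.tsv` and `config.json`. Content is
#' deterministic for a fixed config seed.
#'
#' @param sim output of [simulateDTUDataset()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return invisibly, a character vector of the written paths.
#' @export
writeFixtureBundle <- function(sim, dir, force = FALSE) {
    if (dir.exists(dir) && length(list.files(dir)) && !force)
        stop("directory ", dir, " is not empty (use force = TRUE)")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    catalog <- txCatalog(sim$quant)
    counts <- txCounts(sim$quant)
    res <- txResamples(sim$quant)
    paths <- character(0)
    for (i in seq_len(ncol(counts))) {
        sid <- colnames(counts)[i]
        tpm <- counts[, i] / catalog$effective_length
        tpm <- tpm / sum(tpm) * 1e6
        qt <- data.frame(Name = catalog$transcript_id,
                         Length = catalog$length,
                         EffectiveLength = catalog$effective_length,
                         TPM = tpm, NumReads = counts[, i])
        qf <- file.path(dir, paste0(sid, "_quant.sf"))
        utils::write.table(qt, qf, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        rt <- data.frame(Name = catalog$transcript_id, res[[i]],
                         check.names = FALSE)
        rf <- file.path(dir, paste0(sid, "_boot.tsv"))
        utils::write.table(rt, rf, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, qf, rf)
    }
    cf <- file.path(dir, "catalog.tsv")
    utils::write.table(catalog, cf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tf <- file.path(dir, "truth.tsv")
    utils::write.table(sim$truth, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jf <- file.path(dir, "config.json")
    cfg <- unclass(sim$config)
    cfg$tauSpec <- NULL
    jsonlite::write_json(cfg, jf, auto_unbox = TRUE, digits = NA)
    invisible(c(paths, cf, tf, jf))
}

#' Evaluate DTU calls against simulation truth
#'
#' For each FDR cutoff and level (gene-level F, gene-level Simes,
#' transcript-level t), counts true and false discoveries among the tested
#' features, the observed FDR `FP / max(1, TP + FP)`, the power
#' `TP / positives`, and the type I error (fraction of true-null features
#' with raw p at or below the cutoff). Gene-level positives are the
#' DTU-only and DGE+DTU genes; transcript-level positives are the
#' transcripts flagged differentially used.
#'
#' @param results a [DTUResults-class].
#' @param truth per-transcript truth table from the simulator.
#' @param cutoffs FDR (and type-I) cutoffs to evaluate.
#' @return data.frame with one row per level and cutoff.
#' @export
evaluatePerformance <- function(results, truth, cutoffs = c(0.01, 0.05, 0.1)) {
    gt <- geneResults(results)
    tt <- transcriptResults(results)
    if (!all(gt$gene_id %in% truth$gene_id))
        stop("result genes missing from truth table")
    if (!all(tt$transcript_id %in% truth$transcript_id))
        stop("result transcripts missing from truth table")
    geneCat <- truth$category[match(gt$gene_id, truth$gene_id)]
    genePos <- geneCat %in% c("dtu_only", "dge_dtu")
    txPos <- truth$is_DTU[match(tt$transcript_id, truth$transcript_id)]
    one <- function(level, fdr, rawp, pos, cutoff) {
        call <- fdr <= cutoff
        TP <- sum(call & pos)
        FP <- sum(call & !pos)
        data.frame(level = level, cutoff = cutoff, TP = TP, FP = FP,
                   FDR = FP / max(1, TP + FP),
                   power = if (any(pos)) TP / sum(pos) else NA_real_,
                   typeI = if (any(!pos)) mean(rawp[!pos] <= cutoff)
                           else NA_real_,
                   stringsAsFactors = FALSE)
    }
    out <- list()
    for (cu in cutoffs) {
        out <- c(out,
                 list(one("gene_F", gt$FDR, gt$P.Value, genePos, cu),
                      one("gene_Simes", gt$FDR.Simes, gt$P.Simes, genePos, cu),
                      one("transcript", tt$FDR, tt$P.Value, txPos, cu)))
    }
    do.call(rbind, out)
}

#' Cumulative false discoveries along a ranked list
#'
#' @param results a [DTUResults-class].
#' @param truth per-transcript truth table.
#' @param level `"gene"`, `"simes"` or `"transcript"`.
#' @return integer vector: cumulative count of false discoveries when the
#'   top k features are called, k = 1..n.
#' @export
cumulativeFalseDiscoveries <- function(results, truth,
                                       level = c("gene", "simes",
                                                 "transcript")) {
    level <- match.arg(level)
    tab <- topSpliceDTU(results, level = level)
    if (level == "transcript") {
        pos <- truth$is_DTU[match(tab$transcript_id, truth$transcript_id)]
    } else {
        cat <- truth$category[match(tab$gene_id, truth$gene_id)]
        pos <- cat %in% c("dtu_only", "dge_dtu")
    }
    cumsum(!pos)
}
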