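#' Read a quantifier transcript quantification table
#'
#' Reads the standard 5-column tab-separated quantification output
#' (`quant.sf` dialect) written by Salmon-style quantifiers: columns
#' `Name`, `Length`, `EffectiveLength`, `TPM`, `NumReads`. Row order is
#' preserved; `NumReads` may be fractional.
#'
#' @param path path to the tab-separated file.
#' @return A data.frame with columns `transcript_id`, `length`,
#'   `effective_length`, `tpm`, `counts`, in file order.
#' @examples
#' f <- tempfile(fileext = ".sf")
#' writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
#'              "t1\t1000\t800\t5.0\t10"), f)
#' readQuantTable(f)
#' @export
readQuantTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE)
    wanted <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
    missing <- setdiff(wanted, colnames(tab))
    if (length(missing))
        stop("quantification file ", path, " is missing column(s): ",
             paste(missing, collapse = ", "))
    num <- function(col) {
        x <- suppressWarnings(as.numeric(tab[[col]]))
        bad <- which(is.na(x) & !is.na(tab[[col]]) & tab[[col]] != "NA")
        if (length(bad))
            stop("non-numeric value in column ", col, " at data row ",
                 bad[1], " of ", path)
        x
    }
    data.frame(transcript_id = tab$Name,
               length = num("Length"),
               effective_length = num("EffectiveLength"),
               tpm = num("TPM"),
               counts = num("NumReads"),
               stringsAsFactors = FALSE)
}

#' Read a technical resample matrix
#'
#' Reads a tab-separated per-sample resample matrix: first column `Name`
#' (transcript id), remaining B >= 2 columns numeric resampled counts. Rows
#' are reordered to match `expectedIds` (the catalog order).
#'
#' @param path path to the TSV file.
#' @param expectedIds character vector of transcript ids defining the
#'   required row order.
#' @return numeric matrix (transcripts by B) in `expectedIds` order.
#' @export
readResampleMatrix <- function(path, expectedIds) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (ncol(m) < 2L)
        stop("resample matrix ", path, " has B = ", ncol(m),
             " columns; at least 2 resamples are required for RTA estimation")
    missing <- setdiff(expectedIds, ids)
    if (length(missing))
        stop("resample matrix ", path, " is missing transcript(s), first: ",
             missing[1])
    rownames(m) <- ids
    m[expectedIds, , drop = FALSE]
}

#' Read a transcript-to-gene catalog
#'
#' Two-column TSV `transcript_id`, `gene_id`, with optional `length` and
#' `effective_length` columns.
#'
#' @param path path to the TSV file.
#' @param stripVersions strip trailing ".N" version suffixes from transcript
#'   ids (default FALSE: ids are matched as exact strings).
#' @return data.frame catalog.
#' @export
readCatalog <- function(path, stripVersions = FALSE) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    if (!all(c("transcript_id", "gene_id") %in% colnames(tab)))
        stop("catalog must have columns transcript_id and gene_id")
    tab$transcript_id <- as.character(tab$transcript_id)
    tab$gene_id <- as.character(tab$gene_id)
    if (stripVersions)
        tab$transcript_id <- sub("\\.[0-9]+$", "", tab$transcript_id)
    if (anyDuplicated(tab$transcript_id))
        stop("duplicate transcript_id in catalog")
    tab
}

#' Assemble a TxQuant object from per-sample quantification files
#'
#' Convenience loader mirroring the catch-style import step: reads one
#' quantification table and one resample matrix per sample, checks that all
#' samples share the catalog's transcript set, and returns a [TxQuant-class].
#'
#' @param quantFiles character vector of quantification file paths.
#' @param resampleFiles character vector of resample matrix paths, parallel
#'   to `quantFiles` (or NULL for no resamples).
#' @param catalog data.frame catalog as from [readCatalog()]; if NULL, the
#'   catalog (ids, lengths) is taken from the first quantification file with
#'   each transcript its own gene.
#' @param sampleIds sample names (default: file base names).
#' @return A [TxQuant-class] object.
#' @export
readQuantBundle <- function(quantFiles, resampleFiles = NULL, catalog = NULL,
                            sampleIds = NULL) {
    quants <- lapply(quantFiles, readQuantTable)
    if (is.null(sampleIds))
        sampleIds <- make.unique(basename(dirname(quantFiles)))
    ids <- quants[[1]]$transcript_id
    for (q in quants)
        if (!identical(q$transcript_id, ids))
            stop("quantification files do not share the same transcript set/order")
    if (is.null(catalog)) {
        catalog <- data.frame(transcript_id = ids, gene_id = ids,
                              length = quants[[1]]$length,
                              effective_length = quants[[1]]$effective_length,
                              stringsAsFactors = FALSE)
    } else {
        missing <- setdiff(catalog$transcript_id, ids)
        if (length(missing))
            stop("quantifications are missing catalog transcript(s), first: ",
                 missing[1])
        ord <- match(catalog$transcript_id, ids)
        quants <- lapply(quants, function(q) q[ord, , drop = FALSE])
        ids <- catalog$transcript_id
        if (!"length" %in% colnames(catalog))
            catalog$length <- quants[[1]]$length
        if (!"effective_length" %in% colnames(catalog))
            catalog$effective_length <- quants[[1]]$effective_length
    }
    counts <- vapply(quants, function(q) q$counts, numeric(length(ids)))
    counts <- matrix(counts, nrow = length(ids),
                     dimnames = list(ids, sampleIds))
    resamples <- list()
    if (!is.null(resampleFiles)) {
        if (length(resampleFiles) != length(quantFiles))
            stop("need one resample file per quantification file")
        resamples <- lapply(resampleFiles, readResampleMatrix,
                            expectedIds = ids)
        names(resamples) <- sampleIds
    }
    TxQuant(counts, catalog, resamples, sampleIds)
}

#' Write a ranked result table
#'
#' Writes a gene- or transcript-level result table as TSV with 12
#' significant digits, after verifying it is sorted ascending by raw
#' p-value with ties broken by id (the ranked-table contract).
#'
#' @param table data.frame as produced by [topSpliceDTU()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeResultTable <- function(table, path) {
    idcol <- intersect(c("transcript_id", "gene_id"), colnames(table))[1]
    if (nrow(table) > 1) {
        ord <- order(table$P.Value, table[[idcol]])
        if (!identical(ord, seq_len(nrow(table))))
            table <- table[ord, , drop = FALSE]
    }
    num <- vapply(table, is.numeric, logical(1))
    table[num] <- lapply(table[num], signif, digits = 12)
    ok <- tryCatch({
        utils::write.table(table, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("could not write ", path, ": ",
                          conditionMessage(ok))
    invisible(path)
}
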