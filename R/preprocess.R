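#' Read a droplet-style count matrix (MatrixMarket triplet or dense table)
#'
#' Reads either a 10X-style trio (`matrix.mtx`, `genes.tsv`/`features.tsv`,
#' `barcodes.tsv`, possibly gzipped) from a directory, or a single dense
#' TSV/CSV with gene rows and cell columns. Mitochondrial genes are flagged
#' by prefix (default "MT-", case-insensitive) or by an explicit file with
#' one gene id per line.
#'
#' @param path directory containing the MTX trio, or a dense matrix file.
#' @param mito either a prefix string (genes whose id starts with it are
#'   mitochondrial) or a path to a one-gene-per-line file.
#' @return a \code{SingleCellExperiment} with assay "counts" and a logical
#'   `rowData(x)$mito` column.
#' @export
readCounts <- function(path, mito = "MT-") {
    if (dir.exists(path)) {
        pick <- function(stem) {
            hits <- list.files(path, pattern = paste0("^", stem), full.names = TRUE)
            if (!length(hits)) stop("no ", stem, " file found under ", path)
            hits[1L]
        }
        m <- as(Matrix::readMM(pick("matrix.mtx")), "CsparseMatrix")
        gf <- pick("(genes|features)\\.tsv")
        genes <- utils::read.delim(gf, header = FALSE, stringsAsFactors = FALSE)
        ids <- if (ncol(genes) >= 2) genes[[2L]] else genes[[1L]]
        ids <- make.unique(as.character(ids))
        bc <- utils::read.delim(pick("barcodes\\.tsv"), header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
        dimnames(m) <- list(ids, as.character(bc))
        counts <- as.matrix(m)
    } else {
        sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                row.names = 1L, check.names = FALSE)
        counts <- as.matrix(df)
    }
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be nonnegative integers")
    mitoFlags <- resolveMitoFlags(rownames(counts), mito)
    makeCountSCE(counts, mitoFlags)
}

resolveMitoFlags <- function(ids, mito) {
    if (length(mito) == 1L && file.exists(mito)) {
        mt <- readLines(mito)
        ids %in% mt
    } else {
        startsWith(toupper(ids), toupper(mito))
    }
}

makeCountSCE <- function(counts, mitoFlags) {
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts))
    SummarizedExperiment::rowData(sce)$mito <- mitoFlags
    sce
}

getCounts <- function(cm) {
    if (is(cm, "SummarizedExperiment")) {
        m <- as.matrix(SummarizedExperiment::assay(cm, "counts"))
        mito <- SummarizedExperiment::rowData(cm)$mito
        if (is.null(mito)) mito <- rep(FALSE, nrow(m))
    } else {
        m <- as.matrix(cm)
        mito <- rep(FALSE, nrow(m))
    }
    if (any(m < 0) || any(m != round(m)))
        stop("counts must be nonnegative integers")
    list(counts = m, mito = as.logical(mito))
}

#' Quality-control filter on cells
#'
#' Keeps a cell iff it detects at least `minGenes` genes (raw count > 0) AND
#' its mitochondrial read fraction is strictly below `maxMito`. Genes are
#' untouched at this step. Idempotent.
#'
#' @param cm a \code{SingleCellExperiment} with assay "counts" and logical
#'   `rowData()$mito`, or a plain count matrix (then no gene is mitochondrial).
#' @param minGenes inclusive lower bound on genes detected per cell.
#' @param maxMito exclusive upper bound on the mitochondrial count fraction.
#' @return list with `counts` (the filtered object, same class as input) and
#'   `report` (data.frame: cell_id, genes_detected, mito_fraction, kept;
#'   thresholds in `attr(report, "thresholds")`).
#' @export
qcFilter <- function(cm, minGenes = 1000L, maxMito = 0.05) {
    if (minGenes < 0) stop("minGenes must be nonnegative")
    if (maxMito < 0 || maxMito > 1) stop("maxMito must lie in [0, 1]")
    cc <- getCounts(cm)
    genesDetected <- colSums(cc$counts > 0)
    tot <- colSums(cc$counts)
    mitoFrac <- ifelse(tot > 0, colSums(cc$counts[cc$mito, , drop = FALSE]) / tot, 0)
    kept <- genesDetected >= minGenes & mitoFrac < maxMito
    report <- data.frame(
        cell_id = colnames(cc$counts),
        genes_detected = as.integer(genesDetected),
        mito_fraction = as.numeric(mitoFrac),
        kept = kept, row.names = NULL, stringsAsFactors = FALSE)
    attr(report, "thresholds") <- list(minGenes = minGenes, maxMito = maxMito)
    out <- if (is(cm, "SummarizedExperiment")) cm[, kept] else
        cm[, kept, drop = FALSE]
    list(counts = out, report = report)
}

#' Library-size normalization with a 1.1 pseudocount
#'
#' Removes mitochondrial genes, recomputes the total read count per cell
#' (TRC_c) on the reduced matrix, and sets
#' `LSC_gc = log2(RCM_gc * maxC / TRC_c + 1.1)` where `maxC = max_c TRC_c`.
#' The output is strictly positive (minimum log2(1.1)), and back-transforming
#' conserves the rescaled library size: `sum_g (2^LSC - 1.1) = maxC` for every
#' cell.
#'
#' @inheritParams qcFilter
#' @return a \code{SingleCellExperiment} with assay "logcounts"; provenance
#'   (transform, pseudocount, maxC) in `metadata()$provenance`.
#' @export
normalizeLibrary <- function(cm) {
    cc <- getCounts(cm)
    counts <- cc$counts[!cc$mito, , drop = FALSE]
    trc <- colSums(counts)
    if (any(trc <= 0))
        stop("cell(s) with zero non-mitochondrial counts: ",
             paste(utils::head(colnames(counts)[trc <= 0], 5), collapse = ", "))
    maxC <- max(trc)
    lsc <- log2(sweep(counts, 2, maxC / trc, "*") + 1.1)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(logcounts = lsc))
    S4Vectors::metadata(sce)$provenance <- list(
        transform = "library", pseudocount = 1.1, maxC = maxC)
    sce
}

#' log2 normalization of an FPKM matrix
#'
#' Elementwise `log2(FPKM + 1)`.
#'
#' @param fpkm nonnegative genes x cells matrix.
#' @return a \code{SingleCellExperiment} with assay "logcounts" and provenance
#'   metadata.
#' @export
normalizeFPKM <- function(fpkm) {
    m <- as.matrix(fpkm)
    if (any(m < 0)) stop("FPKM values must be nonnegative")
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(logcounts = log2(m + 1)))
    S4Vectors::metadata(sce)$provenance <- list(
        transform = "fpkm", pseudocount = 1)
    sce
}

#' Select highly variable/expressed genes
#'
#' Genes with mean expression strictly above `meanThresh` AND standard
#' deviation (denominator n - 1) strictly above `sdThresh` on the
#' log-normalized scale.
#'
#' @param expr normalized genes x cells matrix or container (see
#'   [srProfile()] for accepted types).
#' @param meanThresh,sdThresh strict lower bounds.
#' @return character vector of selected gene ids.
#' @export
selectHVG <- function(expr, meanThresh = 1, sdThresh = 1) {
    X <- getExprMatrix(expr)
    if (ncol(X) < 2L) stop("HVG selection needs at least 2 cells")
    mu <- rowMeans(X)
    sd <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
    rownames(X)[mu > meanThresh & sd > sdThresh]
}

#' Optional gene-identifier mapping
#'
#' Applies a two-column mapping table (from, to) to the rownames of a
#' normalized matrix; unmapped genes are dropped with a message, duplicate
#' targets aggregated by mean.
#'
#' @param expr normalized matrix or container.
#' @param map data.frame with columns `from`, `to`.
#' @return matrix with mapped rownames.
#' @export
mapGeneIds <- function(expr, map) {
    X <- getExprMatrix(expr)
    idx <- match(rownames(X), map$from)
    drop <- is.na(idx)
    if (any(drop))
        message(sum(drop), " gene(s) without a mapping were dropped")
    X <- X[!drop, , drop = FALSE]
    tgt <- as.character(map$to[idx[!drop]])
    if (anyDuplicated(tgt)) {
        X <- rowsum(X, tgt) / as.vector(table(tgt)[sort(unique(tgt))])
        X
    } else {
        rownames(X) <- tgt
        X
    }
}
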