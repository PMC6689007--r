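#' Expression-weighted random-walk machinery
#'
#' A cell's strictly positive expression vector x (aligned to the network's
#' genes) weights each edge (i, j) by x_i * x_j; normalizing rows yields the
#' stochastic matrix P_ij = x_j / (Ax)_i over the neighbors of i. The entropy
#' rate of this walk, evaluated under its stationary distribution
#' pi_i = x_i (Ax)_i / (x' A x), is the signaling entropy rate Sr.
#'
#' @name entropy-core
NULL

# Validate and align an expression vector to a network; returns named numeric.
checkExpressionVector <- function(x, net) {
    stopifnot(is(net, "GeneNetwork"))
    ids <- geneIds(net)
    if (!is.null(names(x))) {
        if (!all(ids %in% names(x)))
            stop("expression vector is missing ", sum(!(ids %in% names(x))),
                 " network gene(s)")
        x <- x[ids]
    } else if (length(x) != length(ids)) {
        stop("expression vector length (", length(x),
             ") does not match the network (", length(ids), " genes)")
    }
    if (any(!is.finite(x)) || any(x <= 0))
        stop("expression values must be strictly positive and finite; ",
             "offending gene(s): ",
             paste(utils::head(ids[!is.finite(x) | x <= 0], 5), collapse = ", "))
    stats::setNames(as.numeric(x), ids)
}

#' Transition matrix of the expression-weighted walk
#'
#' `P_ij = x_j / (Ax)_i` for j a neighbor of i, 0 elsewhere; every row sums
#' to 1 and the sparsity pattern equals the adjacency's. Rescaling x leaves
#' P unchanged.
#'
#' @param x strictly positive expression vector aligned to `net` (names
#'   optional; if named, reordered by gene id).
#' @param net a connected [GeneNetwork-class].
#' @return sparse row-stochastic matrix.
#' @export
transitionMatrix <- function(x, net) {
    x <- checkExpressionVector(x, net)
    A <- adjacencyMatrix(net)
    Ax <- as.numeric(A %*% x)
    if (any(Ax <= 0))
        stop("a network node has no expressed neighbor; is the network ",
             "connected?")
    P <- Matrix::Diagonal(x = 1 / Ax) %*% A %*% Matrix::Diagonal(x = x)
    dimnames(P) <- dimnames(A)
    as(P, "CsparseMatrix")
}

#' Stationary distribution of the expression-weighted walk
#'
#' Closed form `pi_i = x_i (Ax)_i / (x' A x)`; satisfies pi P = pi and the
#' detailed-balance condition pi_i P_ij = pi_j P_ji.
#'
#' @inheritParams transitionMatrix
#' @return named probability vector.
#' @export
stationaryDistribution <- function(x, net) {
    x <- checkExpressionVector(x, net)
    Ax <- as.numeric(adjacencyMatrix(net) %*% x)
    p <- x * Ax
    stats::setNames(p / sum(p), geneIds(net))
}

#' Signaling entropy rate of one cell
#'
#' `Sr = -sum_i pi_i sum_j P_ij ln P_ij` (natural logarithm; terms with
#' P_ij = 0 contribute 0). Computed without materializing P:
#' `sum_j P_ij ln P_ij = (A (x ln x))_i / (Ax)_i - ln (Ax)_i`.
#'
#' @inheritParams transitionMatrix
#' @return nonnegative scalar (nats).
#' @export
entropyRate <- function(x, net) {
    x <- checkExpressionVector(x, net)
    A <- adjacencyMatrix(net)
    Ax <- as.numeric(A %*% x)
    Axlx <- as.numeric(A %*% (x * log(x)))
    h <- log(Ax) - Axlx / Ax          # local Shannon entropy of row i
    pi <- x * Ax / sum(x * Ax)
    max(sum(pi * h), 0)
}

#' Normalized signaling entropy rate
#'
#' `SR = Sr / maxSr`, in (0, 1]; equals 1 exactly when the weighted walk
#' coincides with the maximal-entropy walk (e.g. uniform expression on a
#' regular graph).
#'
#' @inheritParams transitionMatrix
#' @param maxSr maximum entropy rate of the same network (from
#'   [maxEntropyRate()]); computed if missing.
#' @return scalar in (0, 1].
#' @export
normalizedSR <- function(x, net, maxSr = NULL) {
    if (is.null(maxSr)) maxSr <- maxEntropyRate(net)$maxSr
    if (!is.finite(maxSr) || maxSr <= 0)
        stop("maxSr must be positive; networks with fewer than 2 connected ",
             "nodes have no entropy to normalize")
    entropyRate(x, net) / maxSr
}

# Extract a genes x cells numeric matrix from a SingleCellExperiment /
# SummarizedExperiment (preferring "logcounts") or pass a matrix through.
getExprMatrix <- function(expr) {
    if (is(expr, "SummarizedExperiment")) {
        nm <- SummarizedExperiment::assayNames(expr)
        a <- if ("logcounts" %in% nm) "logcounts" else nm[1L]
        m <- as.matrix(SummarizedExperiment::assay(expr, a))
    } else {
        m <- as.matrix(expr)
    }
    if (is.null(rownames(m))) stop("expression matrix must have gene rownames")
    if (is.null(colnames(m)))
        colnames(m) <- sprintf("cell%d", seq_len(ncol(m)))
    m
}

#' Per-cell signaling entropy profile
#'
#' Intersects the network with the matrix's genes (largest connected
#' component), validates strict positivity of the retained expression values,
#' computes `maxSr` once, and then each cell's Sr, SR and base-2 logit-SR.
#' Cells are processed by one vectorized sparse computation, so results do
#' not depend on cell order or chunking; SR is invariant to global rescaling
#' of a cell's profile.
#'
#' @param expr genes x cells matrix of strictly positive normalized
#'   expression, or a \code{SingleCellExperiment}/\code{SummarizedExperiment}
#'   carrying one (assay "logcounts" preferred).
#' @param net a [GeneNetwork-class]; intersected with the matrix's genes.
#' @return an [SRProfile-class].
#' @examples
#' net <- simulateNetwork(30, seed = 1)
#' x <- matrix(rexp(30 * 5) + 0.1, 30, 5,
#'             dimnames = list(geneIds(net), paste0("c", 1:5)))
#' srProfile(x, net)
#' @export
srProfile <- function(expr, net) {
    X <- getExprMatrix(expr)
    net <- intersectWithGenes(net, rownames(X))
    X <- X[geneIds(net), , drop = FALSE]
    bad <- which(!is.finite(X) | X <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop("nonpositive expression after network alignment, e.g. gene '",
             rownames(X)[bad[1, 1]], "' in cell '", colnames(X)[bad[1, 2]],
             "'; normalized inputs must be strictly positive")
    A <- adjacencyMatrix(net)
    mx <- maxEntropyRate(net)
    AX <- as.matrix(A %*% X)
    AXlX <- as.matrix(A %*% (X * log(X)))
    H <- log(AX) - AXlX / AX                   # per-node row entropies
    Pi <- X * AX
    Pi <- sweep(Pi, 2, colSums(Pi), "/")       # stationary measure per cell
    sr <- pmax(colSums(Pi * H), 0)
    srn <- sr / mx$maxSr
    lg <- ifelse(srn < 1, log2(srn / (1 - srn)), Inf)
    new("SRProfile", cellIds = colnames(X), sr = unname(sr),
        maxSr = mx$maxSr, srn = unname(srn), logitSr = unname(lg))
}
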