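#' Select the root cell (maximal potency)
#'
#' The root is the cell of highest normalized entropy rate; ties go to the
#' smallest cell index.
#'
#' @param sr an [SRProfile-class] or a numeric vector of SR values.
#' @return 1-based integer index of the root cell.
#' @export
selectRoot <- function(sr) {
    v <- if (is(sr, "SRProfile")) SR(sr) else as.numeric(sr)
    if (!length(v)) stop("empty SR vector")
    as.integer(which.max(v))  # first maximum = smallest index on ties
}

#' Diffusion map of a cell population
#'
#' Builds a symmetric k-nearest-neighbor graph on Euclidean distances, a
#' Gaussian kernel with per-cell bandwidth equal to the median distance to
#' the cell's k nearest neighbors, applies density normalization (alpha = 1:
#' the kernel is divided by the outer product of its row sums), row-
#' normalizes, and eigendecomposes the conjugate symmetric operator. The
#' trivial constant eigenvector (eigenvalue 1) is excluded; the top `nDCs`
#' nontrivial eigenpairs are returned with components normalized to be
#' orthonormal under the sampling measure. Component signs are fixed so the
#' entry of largest magnitude is positive.
#'
#' @param x cells in rows: a cells x features numeric matrix, or a genes x
#'   cells container (\code{SingleCellExperiment}/matrix with gene rownames),
#'   which is transposed internally.
#' @param k number of nearest neighbors (default 30).
#' @param nDCs number of diffusion components to retain (default 10).
#' @param sigma optional fixed kernel bandwidth (scalar or per-cell vector)
#'   overriding the adaptive median-kNN-distance rule.
#' @return a [DiffusionResult-class] (without pseudotime).
#' @export
diffusionMap <- function(x, k = 30L, nDCs = 10L, sigma = NULL) {
    if (is(x, "SummarizedExperiment")) x <- t(getExprMatrix(x))
    x <- as.matrix(x)
    n <- nrow(x)
    if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                     n, ")")
    D <- as.matrix(stats::dist(x))
    if (is.null(sigma)) {
        # per-cell bandwidth: median distance to the k nearest neighbors
        sigma <- vapply(seq_len(n), function(i)
            stats::median(sort(D[i, -i])[seq_len(k)]), numeric(1))
    } else {
        sigma <- rep_len(as.numeric(sigma), n)
    }
    sigma <- pmax(sigma, 1e-12)
    # symmetric kNN mask (union of neighborhoods)
    knnMask <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        ord <- order(D[i, ])
        nbr <- setdiff(ord, i)[seq_len(k)]
        knnMask[i, nbr] <- TRUE
    }
    knnMask <- knnMask | t(knnMask)
    K <- exp(-D^2 / (2 * outer(sigma, sigma)))
    K[!knnMask] <- 0
    diag(K) <- 1
    # alpha = 1 density normalization
    q <- rowSums(K)
    W <- K / outer(q, q)
    d <- rowSums(W)
    S <- W / outer(sqrt(d), sqrt(d))     # conjugate symmetric operator
    eig <- eigen(S, symmetric = TRUE)
    nEig <- min(nDCs + 1L, n)
    vals <- eig$values[seq_len(nEig)]
    vecs <- eig$vectors[, seq_len(nEig), drop = FALSE]
    psi <- vecs / sqrt(d)                # right eigenvectors of P = D^-1 W
    # normalize: orthonormal under the sampling measure mu = d / sum(d)
    mu <- d / sum(d)
    nrm <- sqrt(colSums(mu * psi^2))
    psi <- sweep(psi, 2, nrm, "/")
    # drop the trivial constant component (eigenvalue 1)
    vals <- vals[-1L]
    psi <- psi[, -1L, drop = FALSE]
    if (any(vals >= 1 - 1e-10))
        warning("a nontrivial eigenvalue is numerically 1; the kNN graph ",
                "may be disconnected - consider a larger k")
    # deterministic sign: largest-magnitude entry positive
    for (j in seq_len(ncol(psi))) {
        m <- which.max(abs(psi[, j]))
        if (psi[m, j] < 0) psi[, j] <- -psi[, j]
    }
    rownames(psi) <- rownames(x)
    colnames(psi) <- paste0("DC", seq_len(ncol(psi)))
    new("DiffusionResult", eigenvalues = vals, components = psi,
        kernelParams = list(k = as.integer(k), bandwidths = sigma,
                            samplingMeasure = mu),
        rootIndex = NA_integer_, dpt = numeric())
}

#' Diffusion pseudotime from a root cell
#'
#' Spectral closed form over the retained nontrivial eigenpairs:
#' `dpt(i) = sqrt( sum_l (lambda_l / (1 - lambda_l))^2 (psi_l(i) -
#' psi_l(root))^2 )`. Zero at the root and symmetric as a pairwise distance.
#'
#' @param dmap a [DiffusionResult-class].
#' @param root 1-based root cell index (e.g. from [selectRoot()]).
#' @return the [DiffusionResult-class] with `rootIndex` and `dpt` filled; the
#'   numeric pseudotime is in `dpt(dmap)` slot accessor [pseudotime()].
#' @export
diffusionPseudotime <- function(dmap, root) {
    stopifnot(is(dmap, "DiffusionResult"))
    n <- nrow(dmap@components)
    root <- as.integer(root)
    if (is.na(root) || root < 1L || root > n)
        stop("root index out of range [1, ", n, "]")
    lam <- dmap@eigenvalues
    w <- lam / (1 - lam)
    delta <- sweep(dmap@components, 2, dmap@components[root, ], "-")
    dpt <- sqrt(as.numeric((delta^2) %*% (w^2)))
    dmap@rootIndex <- root
    dmap@dpt <- dpt
    dmap
}

#' Pseudotime accessor
#' @param object a [DiffusionResult-class] with pseudotime computed.
#' @return numeric vector (named by cell ids when available).
#' @export
setGeneric("pseudotime", function(object) standardGeneric("pseudotime"))

#' @rdname pseudotime
#' @export
setMethod("pseudotime", "DiffusionResult", function(object) {
    if (!length(object@dpt)) stop("pseudotime not computed yet")
    stats::setNames(object@dpt, rownames(object@components))
})

#' Find trajectory tip cells
#'
#' The global tip is the cell of maximal pseudotime; when cluster labels are
#' given, a tip is also reported per non-peripheral cluster (argmax of dpt
#' within the cluster). Ties go to the smallest cell index.
#'
#' @param dpt numeric pseudotime vector, or a [DiffusionResult-class] with
#'   pseudotime computed.
#' @param clusterLabels optional integer labels (0 = peripheral).
#' @return list with `global` (index) and `perCluster` (named integer vector,
#'   empty when no labels are given).
#' @export
findTips <- function(dpt, clusterLabels = NULL) {
    if (is(dpt, "DiffusionResult")) dpt <- pseudotime(dpt)
    dpt <- as.numeric(dpt)
    global <- which.max(dpt)
    per <- integer(0)
    if (!is.null(clusterLabels)) {
        cl <- sort(unique(clusterLabels[clusterLabels != 0L]))
        if (length(cl)) {
            per <- vapply(cl, function(k) {
                idx <- which(clusterLabels == k)
                idx[which.max(dpt[idx])]
            }, integer(1))
            names(per) <- paste0("cluster", cl)
        }
    }
    list(global = global, perCluster = per)
}
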