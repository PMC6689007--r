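#' Embed cells in two dimensions (t-SNE over a PCA reduction)
#'
#' Reduces the HVG expression matrix to `initialDims` principal components
#' and runs Barnes-Hut t-SNE. Deterministic given `seed`. Any external 2-D
#' coordinates can be used downstream instead; the clustering `eps` is
#' scale-dependent on the embedding.
#'
#' @param expr normalized genes x cells matrix or container (cells are
#'   embedded, i.e. columns).
#' @param initialDims number of PCs fed to t-SNE (default 30).
#' @param perplexity t-SNE perplexity (default 30); needs
#'   `ncells - 1 >= 3 * perplexity`.
#' @param maxIter maximum t-SNE iterations (default 1000).
#' @param seed integer seed.
#' @return cells x 2 matrix (rownames = cell ids) with the parameters in
#'   `attr(, "params")`.
#' @export
embedCells <- function(expr, initialDims = 30L, perplexity = 30,
                       maxIter = 1000L, seed = 42L) {
    X <- getExprMatrix(expr)
    n <- ncol(X)
    if (n - 1 < 3 * perplexity)
        stop("too few cells (", n, ") for perplexity ", perplexity,
             "; need ncells - 1 >= 3 * perplexity")
    set.seed(as.integer(seed))
    d <- min(initialDims, n - 1L, nrow(X))
    pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE, rank. = d)$x
    ts <- Rtsne::Rtsne(pc, dims = 2, perplexity = perplexity,
                       max_iter = as.integer(maxIter), pca = FALSE,
                       verbose = FALSE, check_duplicates = FALSE)
    coords <- ts$Y
    dimnames(coords) <- list(colnames(X), c("dim1", "dim2"))
    attr(coords, "params") <- list(initialDims = d, perplexity = perplexity,
                                   maxIter = maxIter, seed = seed)
    coords
}

#' Density-based clustering of an embedding (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distances: a core point has at least `minPts`
#' points (itself included) within `eps`; clusters are the connected
#' components of core points at distance <= eps; non-core points within eps
#' of a core point join the cluster of their nearest core point (so the
#' partition does not depend on input order); remaining points are
#' "peripheral" (label 0). Clusters are renumbered by descending size (ties
#' by smallest member index) so labels are order-stable.
#'
#' @param coords cells x d numeric matrix (typically the 2-D embedding).
#' @param eps neighborhood radius.
#' @param minPts minimum neighborhood size for a core point.
#' @return integer vector of cluster labels (0 = peripheral), named by the
#'   rownames of `coords`.
#' @export
clusterEmbedding <- function(coords, eps = 5, minPts = 15L) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    D <- as.matrix(stats::dist(coords))
    nb <- D <= eps
    core <- rowSums(nb) >= minPts
    labels <- integer(n)
    if (any(core)) {
        ci <- which(core)
        g <- igraph::graph_from_adjacency_matrix(
            nb[ci, ci, drop = FALSE] * 1, mode = "undirected", diag = FALSE)
        comp <- igraph::components(g)$membership
        labels[ci] <- comp
        # border points: nearest core point within eps decides the cluster
        border <- which(!core)
        for (b in border) {
            reach <- ci[nb[b, ci]]
            if (length(reach)) {
                nearest <- reach[which.min(D[b, reach])]
                labels[b] <- labels[nearest]
            }
        }
        # renumber by descending size; ties by smallest member index
        tab <- table(labels[labels > 0])
        ids <- as.integer(names(tab))
        firstIdx <- vapply(ids, function(k) which(labels == k)[1L], integer(1))
        ord <- ids[order(-as.integer(tab), firstIdx)]
        labels <- ifelse(labels > 0, match(labels, ord), 0L)
    }
    stats::setNames(as.integer(labels), rownames(coords))
}

#' Cross-tabulate potency states against cell-type clusters
#'
#' A (potency state, cluster) pair qualifies as a cell-state iff it contains
#' at least `minCells` cells. Peripheral cells (cluster label 0) are
#' tabulated in their own column but never qualify.
#'
#' @param clusterLabels integer cluster labels (0 = peripheral).
#' @param potencyLabels integer potency-state labels, same length.
#' @param minCells qualification threshold (default 5).
#' @return data.frame with columns state, cluster, n, qualifies; the
#'   contingency row/column sums equal the state and cluster sizes.
#' @export
cellStateTable <- function(clusterLabels, potencyLabels, minCells = 5L) {
    if (length(clusterLabels) != length(potencyLabels))
        stop("cluster and potency label vectors must have equal length")
    st <- factor(potencyLabels, levels = sort(unique(potencyLabels)))
    cl <- factor(clusterLabels, levels = sort(unique(clusterLabels)))
    tab <- table(state = st, cluster = cl)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("state", "cluster", "n")
    df$state <- as.integer(df$state)
    df$cluster <- as.integer(as.character(df$cluster))
    df$qualifies <- df$n >= minCells & df$cluster != 0L
    attr(df, "minCells") <- minCells
    df[order(df$state, df$cluster), , drop = FALSE]
}

# Scott's rule bandwidth for a 2-D Gaussian KDE, per coordinate.
scottBandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 6)

#' Cell-density surface over the embedding
#'
#' Gaussian-kernel 2-D density of a subset of cells (e.g. one potency state)
#' on a `gridSize` x `gridSize` lattice spanning the bounding box of ALL
#' cells, so surfaces for different potency states share an extent and are
#' directly comparable as elevation maps. Bandwidths follow Scott's rule on
#' the subset; the grid is renormalized to integrate to exactly 1.
#'
#' @param coords cells x 2 matrix (all cells; defines the shared extent).
#' @param subset logical or integer index of the cells whose density is
#'   estimated (default all).
#' @param gridSize lattice resolution per axis (default 100).
#' @param bandwidth optional length-2 numeric overriding Scott's rule.
#' @return list with `x`, `y` (grid axes), `z` (gridSize x gridSize density),
#'   `bandwidth`, `n`.
#' @export
densitySurface <- function(coords, subset = NULL, gridSize = 100L,
                           bandwidth = NULL) {
    coords <- as.matrix(coords)
    if (is.null(subset)) subset <- seq_len(nrow(coords))
    pts <- coords[subset, , drop = FALSE]
    if (nrow(pts) < 2L)
        stop("density estimation needs at least 2 cells in the subset")
    if (is.null(bandwidth))
        bandwidth <- c(scottBandwidth(pts[, 1]), scottBandwidth(pts[, 2]))
    bandwidth <- pmax(bandwidth, 1e-8 * max(diff(range(coords[, 1])),
                                            diff(range(coords[, 2])), 1))
    gx <- seq(min(coords[, 1]), max(coords[, 1]), length.out = gridSize)
    gy <- seq(min(coords[, 2]), max(coords[, 2]), length.out = gridSize)
    kx <- outer(gx, pts[, 1], function(g, p)
        stats::dnorm((g - p) / bandwidth[1])) / bandwidth[1]
    ky <- outer(gy, pts[, 2], function(g, p)
        stats::dnorm((g - p) / bandwidth[2])) / bandwidth[2]
    z <- kx %*% t(ky) / nrow(pts)
    dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
    total <- sum(z) * dx * dy
    z <- z / total
    list(x = gx, y = gy, z = z, bandwidth = bandwidth, n = nrow(pts))
}

#' Build the full cell-density landscape
#'
#' Convenience wrapper: embeds cells (unless coordinates are supplied),
#' clusters the embedding, tabulates (potency state, cluster) cell-states,
#' and computes one density surface per potency state over a shared extent.
#'
#' @param expr normalized genes x cells matrix or container (HVG-reduced
#'   recommended); ignored when `coords` is given.
#' @param potencyLabels integer potency-state label per cell.
#' @param coords optional precomputed cells x 2 coordinates.
#' @param eps,minPts DBSCAN parameters.
#' @param minCells cell-state qualification threshold.
#' @param gridSize density-lattice resolution.
#' @param ... passed to [embedCells()] (perplexity, seed, ...).
#' @return a [LandscapeResult-class].
#' @export
computeLandscape <- function(expr = NULL, potencyLabels, coords = NULL,
                             eps = 5, minPts = 15L, minCells = 5L,
                             gridSize = 100L, ...) {
    if (is.null(coords)) {
        if (is.null(expr)) stop("supply either expr or coords")
        coords <- embedCells(expr, ...)
    }
    coords <- as.matrix(coords)
    if (length(potencyLabels) != nrow(coords))
        stop("potencyLabels must have one entry per cell")
    cl <- clusterEmbedding(coords, eps = eps, minPts = minPts)
    cst <- cellStateTable(cl, potencyLabels, minCells = minCells)
    states <- sort(unique(potencyLabels))
    grids <- lapply(states, function(s) {
        idx <- which(potencyLabels == s)
        if (length(idx) >= 2L)
            densitySurface(coords, idx, gridSize = gridSize) else NULL
    })
    names(grids) <- paste0("PS", states)
    new("LandscapeResult", coords = coords, clusterLabels = unname(cl),
        cellStateTable = cst, densityGrids = grids,
        params = list(eps = eps, minPts = minPts, minCells = minCells,
                      gridSize = gridSize,
                      embedding = attr(coords, "params")))
}
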