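#' Read an undirected network from a two-column edge list
#'
#' Parses a tab/space-delimited two-column edge list of gene identifiers into
#' a [GeneNetwork-class]. Duplicate edges (in either orientation) are
#' collapsed and self-loops dropped; genes are ordered lexicographically so
#' the result is independent of file order. A header line is detected
#' heuristically: if the first line's tokens look like column names (e.g.
#' "from to", "gene1 gene2", "source target") it is skipped.
#'
#' @param path path to the edge-list file (gzip transparent via R connections).
#' @param undirected logical; edges are always symmetrized (kept for
#'   interface clarity; directed networks are out of scope).
#' @return a [GeneNetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\tc"), f)
#' net <- readEdgeList(f)
#' numNodes(net)  # 3
#' @export
readEdgeList <- function(path, undirected = TRUE) {
    if (!isTRUE(undirected))
        stop("only undirected networks are supported")
    lines <- readLines(path)
    lines <- sub("\r$", "", lines)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("empty edge-list file: ", path)
    toks <- strsplit(trimws(lines), "[\t ,;]+")
    # header heuristic: first non-comment line made of typical column names
    headerish <- c("from", "to", "gene1", "gene2", "genea", "geneb",
                   "source", "target", "node1", "node2", "protein1",
                   "protein2")
    if (all(tolower(toks[[1]]) %in% headerish) && length(toks) > 1L) {
        toks <- toks[-1L]
        lineno <- lineno[-1L]
    }
    bad <- which(vapply(toks, function(t)
        length(t) != 2L || any(!nzchar(t)), logical(1)))
    if (length(bad))
        stop("malformed edge list at line ", lineno[bad[1L]], " of ", path,
             ": expected two nonempty identifiers")
    from <- vapply(toks, `[`, character(1), 1L)
    to   <- vapply(toks, `[`, character(1), 2L)
    edgeListNetwork(from, to)
}

# Build a GeneNetwork from parallel from/to vectors: symmetrize, dedup,
# drop self-loops, order genes lexicographically.
edgeListNetwork <- function(from, to) {
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    ids <- sort(unique(c(from, to)), method = "radix")
    if (!length(ids)) stop("edge list contains no non-self-loop edges")
    i <- match(from, ids); j <- match(to, ids)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(length(ids), length(ids)),
                              dimnames = list(ids, ids), use.last.ij = FALSE)
    A@x[] <- 1  # duplicate edges summed by sparseMatrix; reset to binary
    new("GeneNetwork", adjacency = Matrix::drop0(A))
}

# igraph view of the adjacency (mode undirected); used for component analysis.
asIgraph <- function(net) {
    igraph::graph_from_adjacency_matrix(adjacencyMatrix(net),
                                        mode = "undirected", diag = FALSE)
}

#' Largest connected component of a network
#'
#' Returns the induced subnetwork on the largest connected component. Ties in
#' component size are broken in favour of the component containing the
#' lexicographically smallest gene identifier.
#'
#' @param net a [GeneNetwork-class].
#' @return a connected [GeneNetwork-class].
#' @export
largestConnectedComponent <- function(net) {
    stopifnot(is(net, "GeneNetwork"))
    if (numNodes(net) == 0L) stop("empty network")
    comp <- igraph::components(asIgraph(net))
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1L) {
        # genes are stored lexicographically, so the first gene belonging to
        # any candidate component identifies the tie-winner
        first <- match(cand, comp$membership)  # smallest index per component
        cand <- cand[which.min(first)]
    }
    keep <- comp$membership == cand
    A <- adjacencyMatrix(net)[keep, keep, drop = FALSE]
    new("GeneNetwork", adjacency = A)
}

#' Restrict a network to a gene set
#'
#' Induces the subgraph on the intersection of the network's genes with
#' `geneIds`, then extracts the largest connected component (the entropy-rate
#' machinery requires a connected substrate).
#'
#' @param net a [GeneNetwork-class].
#' @param geneIds character vector of gene identifiers to keep.
#' @return a connected [GeneNetwork-class] with at least 2 nodes.
#' @export
intersectWithGenes <- function(net, geneIds) {
    stopifnot(is(net, "GeneNetwork"))
    keep <- geneIds(net) %in% geneIds
    if (!any(keep))
        stop("no genes shared between the network and the supplied gene set")
    A <- adjacencyMatrix(net)[keep, keep, drop = FALSE]
    sub <- new("GeneNetwork", adjacency = Matrix::drop0(A))
    lcc <- largestConnectedComponent(sub)
    if (numNodes(lcc) < 2L)
        stop("intersection with the gene set leaves a component of <2 ",
             "connected genes; the entropy rate is undefined")
    lcc
}

# TRUE iff the network is connected.
isConnectedNetwork <- function(net) {
    numNodes(net) > 0L && igraph::components(asIgraph(net))$no == 1L
}

#' Dominant (Perron) eigenpair of the adjacency matrix
#'
#' Computes the largest adjacency eigenvalue lambda and its entrywise-positive
#' unit eigenvector v by power iteration on A + I (the shift makes the
#' dominant eigenvalue strictly separated even on bipartite graphs, where
#' -lambda is also an eigenvalue of A). The start vector is all-ones, so the
#' result is run-to-run identical.
#'
#' @param net a connected [GeneNetwork-class] with >= 2 nodes.
#' @param tol relative residual tolerance on `max|Av - lambda v| <= tol * lambda`.
#' @param maxIter iteration cap.
#' @return list with `lambda` (positive scalar) and `v` (positive unit-norm
#'   named vector).
#' @export
dominantEigenpair <- function(net, tol = 1e-12, maxIter = 100000L) {
    stopifnot(is(net, "GeneNetwork"))
    if (numNodes(net) < 2L)
        stop("dominant eigenpair requires a network with at least 2 nodes")
    if (!isConnectedNetwork(net))
        stop("network is disconnected; extract the largest connected ",
             "component first (largestConnectedComponent)")
    A <- adjacencyMatrix(net)
    n <- nrow(A)
    v <- rep(1 / sqrt(n), n)
    lambda <- NA_real_
    for (it in seq_len(maxIter)) {
        w <- as.numeric(A %*% v) + v       # (A + I) v
        w <- w / sqrt(sum(w * w))
        Av <- as.numeric(A %*% w)
        lambda <- sum(w * Av)              # Rayleigh quotient
        if (max(abs(Av - lambda * w)) <= tol * max(lambda, 1)) {
            v <- w
            break
        }
        v <- w
    }
    Av <- as.numeric(A %*% v)
    if (max(abs(Av - lambda * v)) > 1e-10 * max(lambda, 1))
        stop("power iteration failed to converge to the requested tolerance")
    v <- abs(v)  # Perron vector is entrywise positive
    list(lambda = lambda, v = stats::setNames(v, geneIds(net)))
}

#' Maximum entropy rate of a network
#'
#' Among all random walks compatible with the topology, the entropy rate is
#' maximized by the walk `P_ij = A_ij v_j / (lambda v_i)` where (lambda, v)
#' is the dominant adjacency eigenpair; its rate is `ln lambda` and its
#' stationary distribution is `pi_i = v_i^2`.
#'
#' @param net a connected [GeneNetwork-class].
#' @return list with `maxSr` (nats), `P` (sparse stochastic matrix of the
#'   maximal-entropy walk), `pi` (its stationary distribution), `lambda`, `v`.
#' @export
maxEntropyRate <- function(net) {
    eig <- dominantEigenpair(net)
    A <- adjacencyMatrix(net)
    v <- eig$v
    P <- Matrix::Diagonal(x = 1 / (eig$lambda * v)) %*% A %*%
        Matrix::Diagonal(x = v)
    dimnames(P) <- dimnames(A)
    list(maxSr = log(eig$lambda),
         P = as(P, "CsparseMatrix"),
         pi = stats::setNames(v^2, geneIds(net)),
         lambda = eig$lambda, v = v)
}
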