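# Small named graphs and dense brute-force oracles used across tests.

netFromEdges <- function(from, to) {
    ids <- sort(unique(c(from, to)))
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    A[cbind(from, to)] <- 1
    A[cbind(to, from)] <- 1
    GeneNetwork(A)
}

pathNetwork <- function(n) {
    ids <- sprintf("n%02d", seq_len(n))
    netFromEdges(ids[-n], ids[-1])
}

cycleNetwork <- function(n) {
    ids <- sprintf("n%02d", seq_len(n))
    netFromEdges(ids, ids[c(2:n, 1)])
}

starNetwork <- function(nLeaves) {
    ids <- c("hub", sprintf("l%02d", seq_len(nLeaves)))
    netFromEdges(rep("hub", nLeaves), ids[-1])
}

triangleNetwork <- function() netFromEdges(c("a", "b", "c"), c("b", "c", "a"))

# --- independent dense oracles -------------------------------------------

# entropy rate by direct double sum over a dense transition matrix
oracleEntropyRate <- function(P, pi) {
    P <- as.matrix(P)
    pi <- unname(as.numeric(pi))
    s <- 0
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
        if (P[i, j] > 0) s <- s - pi[i] * P[i, j] * log(P[i, j])
    s
}

# stationary distribution as the left Perron eigenvector of dense P
oracleStationary <- function(P) {
    e <- eigen(t(as.matrix(P)))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    v / sum(v)
}

# dense dominant eigenpair of the adjacency
oracleEigen <- function(net) {
    e <- eigen(as.matrix(adjacencyMatrix(net)), symmetric = TRUE)
    list(lambda = e$values[1], v = abs(e$vectors[, 1]))
}

# dense transition matrix straight from the definition p_ij = x_j / (Ax)_i
oracleTransition <- function(x, net) {
    A <- as.matrix(adjacencyMatrix(net))
    Ax <- as.numeric(A %*% x)
    P <- A * rep(x, each = nrow(A))   # A_ij * x_j
    sweep(P, 1, Ax, "/")
}
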