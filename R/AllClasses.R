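#' @import methods
#' @importFrom Matrix Matrix Diagonal t colSums rowSums diag isSymmetric
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GeneNetwork: an undirected, unweighted interaction network over genes
#'
#' Stores a binary, symmetric, zero-diagonal adjacency matrix (sparse) whose
#' row/column names are gene identifiers. This is the substrate on which the
#' signaling entropy rate is computed: the expression profile of a cell
#' weights the edges of this network and thereby defines a random walk.
#'
#' @slot adjacency a symmetric sparse \code{dgCMatrix} with entries in
#'   \{0, 1\}, zero diagonal, and unique gene identifiers as dimnames.
#'
#' @seealso [readEdgeList()], [largestConnectedComponent()],
#'   [dominantEigenpair()], [maxEntropyRate()]
#' @export
setClass("GeneNetwork", slots = c(adjacency = "dgCMatrix"))

setValidity("GeneNetwork", function(object) {
    A <- object@adjacency
    msg <- character()
    if (nrow(A) != ncol(A))
        msg <- c(msg, "adjacency must be square")
    ids <- rownames(A)
    if (nrow(A) > 0) {
        if (is.null(ids) || anyNA(ids) || any(ids == ""))
            msg <- c(msg,
                     "gene identifiers (dimnames) must be present and nonempty")
        else if (anyDuplicated(ids))
            msg <- c(msg, "gene identifiers must be unique")
    }
    if (!identical(rownames(A), colnames(A)))
        msg <- c(msg, "row and column gene identifiers must agree")
    if (!Matrix::isSymmetric(A, checkDN = FALSE))
        msg <- c(msg, "adjacency must be symmetric")
    if (any(Matrix::diag(A) != 0))
        msg <- c(msg, "adjacency must have a zero diagonal")
    if (length(A@x) && !all(A@x %in% c(0, 1)))
        msg <- c(msg, "adjacency entries must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneNetwork from an adjacency matrix
#'
#' Genes are reordered lexicographically so that network construction is
#' deterministic regardless of input order. Explicit zeros are dropped.
#'
#' @param adjacency a square symmetric 0/1 matrix (dense or sparse) with gene
#'   identifiers as dimnames.
#' @return a [GeneNetwork-class] object.
#' @export
GeneNetwork <- function(adjacency) {
    A <- Matrix::Matrix(adjacency, sparse = TRUE)
    A <- as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    A <- Matrix::drop0(A)
    ids <- rownames(A)
    if (is.null(ids)) stop("adjacency must carry gene identifiers as dimnames")
    ord <- order(ids, method = "radix")
    A <- A[ord, ord, drop = FALSE]
    new("GeneNetwork", adjacency = A)
}

#' SRProfile: per-cell signaling entropy rate and its normalizations
#'
#' Holds, for every cell, the entropy rate `Sr` (nats) of the
#' expression-weighted random walk, the network-wide maximum `maxSr = ln
#' lambda` (lambda the largest adjacency eigenvalue), the normalized rate
#' `SR = Sr / maxSr` in (0, 1], and the base-2 logit `log2(SR / (1 - SR))`.
#'
#' @slot cellIds character vector of cell identifiers.
#' @slot sr per-cell entropy rate in nats.
#' @slot maxSr scalar maximum entropy rate of the network (nats).
#' @slot srn per-cell normalized entropy rate, in (0, 1].
#' @slot logitSr per-cell base-2 logit of the normalized rate.
#' @seealso [srProfile()], [SR()], [logitSR()]
#' @export
setClass("SRProfile", slots = c(
    cellIds = "character",
    sr      = "numeric",
    maxSr   = "numeric",
    srn     = "numeric",
    logitSr = "numeric"
))

setValidity("SRProfile", function(object) {
    n <- length(object@cellIds)
    msg <- character()
    if (length(object@sr) != n || length(object@srn) != n ||
        length(object@logitSr) != n)
        msg <- c(msg, "sr, srn and logitSr must have one value per cell")
    if (length(object@maxSr) != 1L || !is.finite(object@maxSr) ||
        object@maxSr <= 0)
        msg <- c(msg, "maxSr must be a single positive number")
    if (n > 0 && (any(object@srn <= 0) || any(object@srn > 1 + 1e-12)))
        msg <- c(msg, "normalized entropy rate must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' PotencyModel: a 1-D Gaussian mixture over logit-SR values
#'
#' Components ("potency states") are ordered by ascending mean, so state 1
#' (PS1) is the least and state K (PSK) the most potent. The BIC table uses
#' the convention `BIC = -2 loglik + p log(n)`; the selected K minimizes it.
#'
#' @slot K selected number of potency states.
#' @slot means,sds,weights per-component parameters, mean-ascending order.
#' @slot bicTable named numeric vector of BIC per candidate K (NA where the
#'   fit failed).
#' @slot posteriors cells x K state-membership probabilities.
#' @slot labels hard state assignment per cell (1..K, ascending potency).
#' @slot logLik log-likelihood of the selected model.
#' @slot varModel "V" (unequal variances) or "E" (equal).
#' @seealso [inferPotencyStates()], [assignState()]
#' @export
setClass("PotencyModel", slots = c(
    K          = "integer",
    means      = "numeric",
    sds        = "numeric",
    weights    = "numeric",
    bicTable   = "numeric",
    posteriors = "matrix",
    labels     = "integer",
    logLik     = "numeric",
    varModel   = "character"
))

setValidity("PotencyModel", function(object) {
    msg <- character()
    K <- object@K
    if (length(object@means) != K || length(object@sds) != K ||
        length(object@weights) != K)
        msg <- c(msg, "means, sds and weights must have length K")
    if (abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "mixture weights must sum to 1")
    if (K > 1 && any(diff(object@means) < 0))
        msg <- c(msg, "component means must be ascending")
    if (ncol(object@posteriors) != K)
        msg <- c(msg, "posteriors must have K columns")
    if (nrow(object@posteriors) > 0) {
        rs <- rowSums(object@posteriors)
        if (max(abs(rs - 1)) > 1e-9)
            msg <- c(msg, "each posterior row must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' LandscapeResult: clusters, cell-states and density surfaces
#'
#' @slot coords cells x 2 embedding coordinates (rownames = cell ids).
#' @slot clusterLabels integer per cell; 0 is the reserved peripheral label
#'   for cells not assigned to any density-based cluster.
#' @slot cellStateTable data.frame with one row per (potency state, cluster)
#'   pair: counts and a `qualifies` flag (count >= minCells, never for the
#'   peripheral column).
#' @slot densityGrids named list of per-potency-state KDE grids (each a list
#'   with x, y, z, bandwidth, n), all over a shared extent.
#' @slot params parameters used (eps, minPts, minCells, grid size, seed, ...).
#' @export
setClass("LandscapeResult", slots = c(
    coords         = "matrix",
    clusterLabels  = "integer",
    cellStateTable = "data.frame",
    densityGrids   = "list",
    params         = "list"
))

#' DiffusionResult: diffusion components and pseudotime
#'
#' @slot eigenvalues retained nontrivial eigenvalues, descending, all < 1.
#' @slot components cells x nDCs diffusion components (trivial constant
#'   component excluded), orthonormal under the sampling measure.
#' @slot kernelParams list: k, per-cell bandwidths.
#' @slot rootIndex index of the root cell (NA until assigned).
#' @slot dpt per-cell diffusion pseudotime from the root (empty until
#'   computed).
#' @seealso [diffusionMap()], [diffusionPseudotime()], [findTips()]
#' @export
setClass("DiffusionResult", slots = c(
    eigenvalues  = "numeric",
    components   = "matrix",
    kernelParams = "list",
    rootIndex    = "integer",
    dpt          = "numeric"
))

#' SignedSignature: a gene signature with +1/-1 signs
#'
#' @slot gene gene identifiers (no duplicates).
#' @slot sign +1 for upregulated, -1 for downregulated genes.
#' @seealso [buildSignedSignature()], [signatureScore()]
#' @export
setClass("SignedSignature", slots = c(gene = "character", sign = "numeric"))

setValidity("SignedSignature", function(object) {
    msg <- character()
    if (length(object@gene) != length(object@sign))
        msg <- c(msg, "gene and sign must have equal length")
    if (anyDuplicated(object@gene))
        msg <- c(msg, "duplicate genes are not allowed in a signature")
    if (length(object@sign) && !all(object@sign %in% c(-1, 1)))
        msg <- c(msg, "signs must be +1 or -1")
    if (length(msg)) msg else TRUE
})

#' Construct a SignedSignature
#' @param gene character vector of gene ids.
#' @param sign numeric vector of +1 / -1, parallel to `gene`.
#' @return a [SignedSignature-class].
#' @export
SignedSignature <- function(gene, sign) {
    new("SignedSignature", gene = as.character(gene), sign = as.numeric(sign))
}

#' GseaResult: rank-based enrichment with a Monte-Carlo null
#'
#' @slot esCurve running enrichment statistic along the ranking (starts and
#'   ends at 0; position 0 prepended).
#' @slot maxES observed maximum of the running statistic.
#' @slot nes maxES divided by the mean of the Monte-Carlo null maxima.
#' @slot p upper-tail p-value from a Gaussian approximation to the null.
#' @slot nMC number of Monte-Carlo reshuffles.
#' @slot nullMean,nullSd moments of the Monte-Carlo null maxima.
#' @seealso [gseaMC()]
#' @export
setClass("GseaResult", slots = c(
    esCurve  = "numeric",
    maxES    = "numeric",
    nes      = "numeric",
    p        = "numeric",
    nMC      = "integer",
    nullMean = "numeric",
    nullSd   = "numeric"
))

#' FixtureBundle: a seeded synthetic dataset with ground truth
#'
#' Everything needed to test the pipeline without downloads: a network, an
#' expression (or count) matrix, and per-cell ground truth (potency parameter
#' t, mixture state, branch, arclength - whichever the generator plants).
#' Regeneration with the same seed and parameters is bit-identical.
#'
#' @slot network a [GeneNetwork-class] (may be an empty 0-node network for
#'   generators that do not produce one).
#' @slot expression genes x cells matrix of strictly positive expression
#'   (empty for count-only bundles).
#' @slot counts a \code{SingleCellExperiment} of raw counts, or NULL.
#' @slot groundTruth data.frame keyed by cell id.
#' @slot seed the seed used.
#' @slot params generator parameters.
#' @export
setClass("FixtureBundle", slots = c(
    network     = "GeneNetwork",
    expression  = "matrix",
    counts      = "ANY",
    groundTruth = "data.frame",
    seed        = "integer",
    params      = "list"
))
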