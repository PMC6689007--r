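#' Simulate a connected random gene network
#'
#' Erdos-Renyi G(n, p) or preferential-attachment (Barabasi-Albert) topology,
#' resampled until connected (bounded retries). Gene ids are zero-padded
#' ("g0001", ...), so lexicographic and numeric orders agree. A pure function
#' of (parameters, seed).
#'
#' @param nGenes number of genes (>= 10).
#' @param model "erdos_renyi" or "preferential_attachment".
#' @param density edge probability for Erdos-Renyi (default 0.08) or edges
#'   added per step for preferential attachment (rounded to >= 1).
#' @param seed integer seed.
#' @param maxRetries resampling cap for connectivity (default 100).
#' @return a connected [GeneNetwork-class].
#' @export
simulateNetwork <- function(nGenes, model = c("erdos_renyi",
                                              "preferential_attachment"),
                            density = 0.08, seed = 1L, maxRetries = 100L) {
    model <- match.arg(model)
    if (nGenes < 10L) stop("nGenes must be at least 10")
    set.seed(as.integer(seed))
    for (try in seq_len(maxRetries)) {
        g <- switch(model,
            erdos_renyi = igraph::sample_gnp(nGenes, density),
            preferential_attachment = igraph::sample_pa(
                nGenes, m = max(1L, round(density * nGenes / 2)),
                directed = FALSE))
        if (igraph::components(g)$no == 1L) {
            A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
            A <- as(as(A, "dMatrix"), "CsparseMatrix")
            ids <- sprintf("g%0*d", nchar(as.character(nGenes)), seq_len(nGenes))
            dimnames(A) <- list(ids, ids)
            return(new("GeneNetwork", adjacency = Matrix::drop0(A)))
        }
    }
    stop("could not sample a connected network in ", maxRetries, " tries; ",
         "increase density")
}

# inverse base-2 logit
invLogit2 <- function(y) 2^y / (1 + 2^y)

#' Simulate a population with a planted potency gradient
#'
#' Each cell receives a latent potency parameter t in (0, 1): its logit
#' (base 2) is drawn from an `nStates`-component Gaussian mixture with unit
#' component variances and means `separation` apart. Expression is a convex
#' combination `(1 - t) * module profile + t * uniform profile`, multiplied
#' by lognormal noise: low-potency cells concentrate expression on a
#' state-specific gene module (uneven signaling flux, low entropy rate) while
#' high-potency cells express uniformly (maximal flux spread, high entropy
#' rate). Ground truth records t, the mixture state and the logit value.
#'
#' @param net a [GeneNetwork-class] giving the gene universe.
#' @param nCells number of cells (default 200).
#' @param nStates number of planted potency states (default 3).
#' @param separation distance between adjacent mixture means in units of the
#'   component standard deviation (default 4).
#' @param noiseSd standard deviation of the lognormal noise on the log scale
#'   (default 0.2).
#' @param moduleFrac fraction of genes in each state-specific module
#'   (default 0.1).
#' @param contrast expression ratio of in-module to out-of-module genes in
#'   the fully committed (t = 0) profile (default 50).
#' @param seed integer seed.
#' @return a [FixtureBundle-class]; `groundTruth` has columns cell, t, y,
#'   state.
#' @export
simulatePotencyPopulation <- function(net, nCells = 200L, nStates = 3L,
                                      separation = 4, noiseSd = 0.2,
                                      moduleFrac = 0.1, contrast = 50,
                                      seed = 1L) {
    stopifnot(is(net, "GeneNetwork"))
    if (nStates < 2L) stop("nStates must be at least 2")
    set.seed(as.integer(seed))
    ids <- geneIds(net)
    nG <- length(ids)
    # mixture on the logit scale, centered, unit sds
    centers <- (seq_len(nStates) - (nStates + 1) / 2) * separation
    state <- sample.int(nStates, nCells, replace = TRUE)
    y <- stats::rnorm(nCells, centers[state], 1)
    t <- invLogit2(y)
    # one gene module per state; committed profile is concentrated on it
    nMod <- max(2L, round(moduleFrac * nG))
    modules <- lapply(seq_len(nStates), function(s)
        sample.int(nG, nMod))
    profiles <- vapply(modules, function(m) {
        p <- rep(1, nG); p[m] <- contrast
        p / mean(p)
    }, numeric(nG))
    uniform <- rep(1, nG)
    X <- vapply(seq_len(nCells), function(c) {
        base <- (1 - t[c]) * profiles[, state[c]] + t[c] * uniform
        base * exp(stats::rnorm(nG, 0, noiseSd))
    }, numeric(nG))
    dimnames(X) <- list(ids, sprintf("cell%04d", seq_len(nCells)))
    new("FixtureBundle", network = net, expression = X, counts = NULL,
        groundTruth = data.frame(cell = colnames(X), t = t, y = y,
                                 state = state, stringsAsFactors = FALSE),
        seed = as.integer(seed),
        params = list(nCells = nCells, nStates = nStates,
                      separation = separation, noiseSd = noiseSd,
                      moduleFrac = moduleFrac, contrast = contrast))
}

#' Simulate a Y-shaped bifurcating trajectory
#'
#' Cells sit on a latent Y graph (stem segment splitting into branches A and
#' B) in profile space: the root vertex profile is a shrunk Perron
#' (dominant-eigenvector) profile of the accompanying network - the profile
#' whose expression-weighted walk approaches the maximal-entropy walk, so
#' signaling entropy peaks at the root but stays strictly below 1 (finite
#' logit) - and the two terminal profiles concentrate expression on disjoint
#' gene modules (low entropy). A cell's expression is the linear
#' interpolation along its segment plus Gaussian noise (floored at a small
#' positive constant so entropy computations remain valid; with
#' `noiseSd = 0` cells lie exactly on the three segments). The first cell is
#' pinned noise-free at the root vertex (arclength 0), making the planted
#' maximal-potency root unambiguous.
#'
#' @param nCells total cells (default 300; split stem/A/B proportional to
#'   `branchLengths`).
#' @param branchLengths latent lengths of (stem, A, B) (default c(1, 1, 1)).
#' @param noiseSd Gaussian noise sd in profile space (default 0.02, small
#'   relative to the inter-cell spacing along the segments so the planted
#'   local ordering of cells survives the noise).
#' @param nGenes number of genes (default 60).
#' @param seed integer seed.
#' @return a [FixtureBundle-class]; `groundTruth` has columns cell, branch
#'   ("stem", "A", "B"), arclength (from the root) and t (planted potency,
#'   decreasing with arclength).
#' @export
simulateBifurcation <- function(nCells = 300L, branchLengths = c(1, 1, 1),
                                noiseSd = 0.02, nGenes = 60L, seed = 1L) {
    if (length(branchLengths) != 3L || any(branchLengths <= 0))
        stop("branchLengths must be 3 positive lengths (stem, A, B)")
    set.seed(as.integer(seed))
    nG <- nGenes
    net <- simulateNetwork(nG, density = max(0.1, 4 / nG), seed = seed)
    ids <- geneIds(net)
    # root vertex: shrunk Perron profile (near-maximal entropy, SR < 1);
    # terminal vertices: disjoint low-entropy gene modules
    third <- floor(nG / 3)
    modA <- seq_len(third)
    modB <- seq_len(third) + third
    mkProfile <- function(module, contrast = 8) {
        p <- rep(0.25, nG); p[module] <- contrast
        p / mean(p) * 4            # mean expression level 4
    }
    v <- dominantEigenpair(net)$v
    vRoot <- unname(v^0.95)
    vRoot <- vRoot / mean(vRoot) * 4
    vA <- mkProfile(modA)
    vB <- mkProfile(modB)
    vMid <- 0.5 * vRoot + 0.25 * vA + 0.25 * vB
    tot <- sum(branchLengths)
    nPer <- pmax(2L, round(nCells * branchLengths / tot))
    nPer[1L] <- nCells - sum(nPer[-1L])
    segs <- list(stem = list(from = vRoot, to = vMid, off = 0),
                 A = list(from = vMid, to = vA, off = branchLengths[1]),
                 B = list(from = vMid, to = vB, off = branchLengths[1]))
    segLen <- c(branchLengths[1], branchLengths[2], branchLengths[3])
    cells <- list(); branch <- character(0); arc <- numeric(0)
    for (s in 1:3) {
        # stratified (jittered-grid) positions: even coverage of the segment
        # without near-duplicate arclengths, so the planted cell order is
        # locally resolvable
        u <- (seq_len(nPer[s]) - stats::runif(nPer[s])) / nPer[s]
        if (s == 1L) u[1L] <- 0   # pin the planted root cell
        pos <- vapply(u, function(f)
            (1 - f) * segs[[s]]$from + f * segs[[s]]$to, numeric(nG))
        cells[[s]] <- pos
        branch <- c(branch, rep(names(segs)[s], nPer[s]))
        arc <- c(arc, segs[[s]]$off + u * segLen[s])
    }
    X <- do.call(cbind, cells)
    if (noiseSd > 0) {
        X <- X + matrix(stats::rnorm(length(X), 0, noiseSd), nrow(X))
        X[, 1L] <- cells[[1L]][, 1L]   # the pinned root cell stays noise-free
    }
    X <- pmax(X, 0.05)
    dimnames(X) <- list(ids, sprintf("cell%04d", seq_len(ncol(X))))
    gt <- data.frame(cell = colnames(X), branch = branch, arclength = arc,
                     t = 1 - arc / max(arc), stringsAsFactors = FALSE)
    new("FixtureBundle", network = net, expression = X, counts = NULL,
        groundTruth = gt, seed = as.integer(seed),
        params = list(nCells = ncol(X), branchLengths = branchLengths,
                      noiseSd = noiseSd, nGenes = nG))
}

#' Simulate a droplet-style count matrix with QC boundary cells
#'
#' Negative-binomial counts with Bernoulli dropout, a designated block of
#' mitochondrial genes ("MT-" prefixed), and two planted boundary cells: one
#' detecting exactly `qcMinGenes` genes with zero mitochondrial counts (must
#' be kept by an inclusive minimum-genes rule) and one with a mitochondrial
#' fraction exactly equal to `qcMaxMito` (must be removed by a strict
#' less-than rule).
#'
#' @param nGenes,nCells matrix dimensions (defaults 200 x 100).
#' @param mitoFractionRange range of per-cell mitochondrial expression
#'   intensity (default c(0.01, 0.1)).
#' @param dropout Bernoulli zeroing probability (default 0.3).
#' @param qcMinGenes,qcMaxMito thresholds at which the boundary cells are
#'   planted (defaults 50 and 0.05).
#' @param seed integer seed.
#' @return a [FixtureBundle-class] whose `counts` is a
#'   \code{SingleCellExperiment} (assay "counts", logical `rowData()$mito`);
#'   `params$boundaryCells` names the two planted cells.
#' @export
simulateCounts10x <- function(nGenes = 200L, nCells = 100L,
                              mitoFractionRange = c(0.01, 0.1),
                              dropout = 0.3, qcMinGenes = 50L,
                              qcMaxMito = 0.05, seed = 1L) {
    if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
    if (qcMinGenes > nGenes) stop("qcMinGenes cannot exceed nGenes")
    set.seed(as.integer(seed))
    nMito <- max(2L, round(0.05 * nGenes))
    width <- nchar(as.character(nGenes))
    ids <- c(sprintf("MT-g%0*d", width, seq_len(nMito)),
             sprintf("g%0*d", width, seq_len(nGenes - nMito)))
    mito <- startsWith(ids, "MT-")
    geneMu <- stats::rlnorm(nGenes, meanlog = 1, sdlog = 1)
    counts <- matrix(stats::rnbinom(nGenes * nCells,
                                    mu = rep(geneMu, nCells), size = 2),
                     nrow = nGenes)
    keepMask <- matrix(stats::rbinom(nGenes * nCells, 1, 1 - dropout),
                       nrow = nGenes)
    counts <- counts * keepMask
    # scale mitochondrial load per cell into the requested intensity range
    mitoScale <- stats::runif(nCells, mitoFractionRange[1], mitoFractionRange[2])
    counts[mito, ] <- matrix(stats::rnbinom(
        nMito * nCells, mu = rep(mitoScale * 100, each = nMito), size = 2),
        nrow = nMito)
    # planted boundary cell 1: exactly qcMinGenes genes detected, zero mito
    b1 <- nCells - 1L
    counts[, b1] <- 0L
    nonMitoIdx <- which(!mito)
    counts[nonMitoIdx[seq_len(qcMinGenes)], b1] <- 5L
    # planted boundary cell 2: mito fraction exactly qcMaxMito
    b2 <- nCells
    counts[, b2] <- 0L
    tot2 <- 2000L
    mitoCount <- as.integer(round(tot2 * qcMaxMito))
    counts[which(mito)[1L], b2] <- mitoCount
    nNon <- tot2 - mitoCount
    fill <- nonMitoIdx[seq_len(min(qcMinGenes + 10L, length(nonMitoIdx)))]
    per <- nNon %/% length(fill)
    counts[fill, b2] <- per
    counts[fill[1L], b2] <- per + nNon %% length(fill)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(ids, sprintf("cell%04d", seq_len(nCells)))
    sce <- makeCountSCE(counts, mito)
    new("FixtureBundle",
        network = new("GeneNetwork", adjacency = new("dgCMatrix")),
        expression = matrix(numeric(0), 0, 0), counts = sce,
        groundTruth = data.frame(cell = colnames(counts),
                                 stringsAsFactors = FALSE),
        seed = as.integer(seed),
        params = list(nGenes = nGenes, nCells = nCells,
                      mitoFractionRange = mitoFractionRange,
                      dropout = dropout, qcMinGenes = qcMinGenes,
                      qcMaxMito = qcMaxMito,
                      boundaryCells = colnames(counts)[c(b1, b2)]))
}
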