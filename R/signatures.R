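#' Per-gene linear-model association with potency (or any response)
#'
#' Ordinary least squares of each gene's normalized expression on a response
#' (continuous potency estimates or a binary group contrast), optionally
#' adjusting for covariates such as cell-cycle scores. With
#' `dropZeros = TRUE` each gene is fitted only on the cells where it is
#' expressed (value strictly above `zero`), the rule used for within-cluster
#' contrasts where dropouts would otherwise confound small differences.
#' P-values are two-sided from the response coefficient's t-statistic;
#' adjusted p-values are Bonferroni over the genes actually tested.
#'
#' @param expr normalized genes x cells matrix or container.
#' @param response numeric vector per cell (or 2-level factor/binary).
#' @param covariates optional numeric matrix/data.frame (cells x q).
#' @param dropZeros restrict each gene's fit to cells expressing it.
#' @param zero baseline value treated as "not expressed" (0 by default; use
#'   `log2(1.1)` for library-normalized matrices).
#' @param minCells minimum usable cells per gene (default 10); genes below it
#'   are reported with NA statistics and excluded from the Bonferroni count.
#' @return data.frame: gene, effect, t, p, p_adj, n_cells_used.
#' @export
deVsPotency <- function(expr, response, covariates = NULL, dropZeros = FALSE,
                        zero = 0, minCells = 10L) {
    X <- getExprMatrix(expr)
    if (is.factor(response) || is.character(response) || is.logical(response)) {
        f <- factor(response)
        if (nlevels(f) != 2L) stop("a categorical response must have 2 levels")
        response <- as.numeric(f) - 1
    }
    response <- as.numeric(response)
    if (length(response) != ncol(X))
        stop("response must have one value per cell")
    if (stats::sd(response) == 0) stop("response is constant")
    Z <- NULL
    if (!is.null(covariates)) {
        Z <- as.matrix(covariates)
        if (nrow(Z) != ncol(X)) stop("covariates must have one row per cell")
    }
    design <- cbind(Intercept = 1, response = response, Z)
    pcol <- 2L
    fitGene <- function(yg, use) {
        nUse <- sum(use)
        if (nUse < minCells) return(c(NA, NA, NA, nUse))
        Xd <- design[use, , drop = FALSE]
        y <- yg[use]
        if (stats::sd(y) == 0 || stats::sd(Xd[, pcol]) == 0)
            return(c(NA, NA, NA, nUse))
        qr. <- qr(Xd)
        if (qr.$rank < ncol(Xd)) return(c(NA, NA, NA, nUse))
        beta <- qr.coef(qr., y)
        res <- y - Xd %*% beta
        df <- nUse - ncol(Xd)
        if (df <= 0) return(c(NA, NA, NA, nUse))
        s2 <- sum(res^2) / df
        if (s2 <= 0) return(c(NA, NA, NA, nUse))
        XtXinv <- chol2inv(qr.R(qr.))
        se <- sqrt(s2 * XtXinv[pcol, pcol])
        t <- beta[pcol] / se
        c(beta[pcol], t, 2 * stats::pt(-abs(t), df), nUse)
    }
    allUse <- rep(TRUE, ncol(X))
    out <- t(vapply(seq_len(nrow(X)), function(g) {
        use <- if (dropZeros) X[g, ] > zero else allUse
        fitGene(X[g, ], use)
    }, numeric(4)))
    tested <- sum(!is.na(out[, 3]))
    data.frame(gene = rownames(X),
               effect = out[, 1], t = out[, 2], p = out[, 3],
               p_adj = pmin(1, out[, 3] * tested),
               n_cells_used = as.integer(out[, 4]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-cycle phase scores
#'
#' Z-scores each signature gene across cells and averages the z-scores of the
#' genes present in the G1/S and G2/M signatures; genes absent from the
#' matrix or with zero variance are dropped (count reported via message).
#'
#' @param expr normalized genes x cells matrix or container.
#' @param g1sGenes,g2mGenes character vectors of phase-signature genes.
#' @return data.frame: cell_id, g1s_score, g2m_score.
#' @export
cellCycleScores <- function(expr, g1sGenes, g2mGenes) {
    X <- getExprMatrix(expr)
    scoreOne <- function(genes, label) {
        present <- intersect(genes, rownames(X))
        sub <- X[present, , drop = FALSE]
        sds <- apply(sub, 1, stats::sd)
        usable <- sds > 0
        dropped <- length(genes) - sum(usable)
        if (dropped > 0)
            message(dropped, " ", label,
                    " gene(s) absent or zero-variance were dropped")
        if (!any(usable))
            stop("no usable ", label, " signature genes in the matrix")
        z <- (sub[usable, , drop = FALSE] -
                  rowMeans(sub[usable, , drop = FALSE])) / sds[usable]
        colMeans(z)
    }
    data.frame(cell_id = colnames(X),
               g1s_score = scoreOne(g1sGenes, "G1/S"),
               g2m_score = scoreOne(g2mGenes, "G2/M"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a signed signature from a differential-expression table
#'
#' Takes the top `nUp` significantly upregulated (largest t) and top `nDn`
#' significantly downregulated (most negative t) genes at the adjusted
#' p-value cutoff; if fewer significant genes exist than requested, all are
#' used with a warning. Ties in t are broken by gene id.
#'
#' @param de data.frame from [deVsPotency()].
#' @param nUp,nDn number of up-/downregulated genes to keep (default 72).
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return a [SignedSignature-class].
#' @export
buildSignedSignature <- function(de, nUp = 72L, nDn = 72L, alpha = 0.05) {
    if (!nrow(de)) stop("empty differential-expression table")
    sig <- de[!is.na(de$t) & !is.na(de$p_adj) & de$p_adj < alpha, , drop = FALSE]
    pickTop <- function(tab, nWant, dir) {
        tab <- tab[order(-dir * tab$t, tab$gene), , drop = FALSE]
        if (nrow(tab) < nWant)
            warning("only ", nrow(tab), " significant ",
                    if (dir > 0) "up" else "down", "regulated genes (",
                    nWant, " requested)")
        utils::head(tab$gene, nWant)
    }
    up <- pickTop(sig[sig$t > 0, , drop = FALSE], nUp, +1)
    dn <- pickTop(sig[sig$t < 0, , drop = FALSE], nDn, -1)
    SignedSignature(gene = c(up, dn), sign = c(rep(1, length(up)),
                                               rep(-1, length(dn))))
}

#' Signed-signature score of an expression profile
#'
#' Pearson correlation between the signature's +1/-1 vector and the profile
#' restricted to the shared genes; +1 on a profile matching the signature,
#' -1 on its negation, invariant under positive affine transforms.
#'
#' @param profile named numeric expression vector (any sample).
#' @param sig a [SignedSignature-class].
#' @return correlation in [-1, 1].
#' @export
signatureScore <- function(profile, sig) {
    stopifnot(is(sig, "SignedSignature"))
    shared <- intersect(sig@gene, names(profile))
    missing <- length(sig@gene) - length(shared)
    if (missing > 0)
        message(missing, " signature gene(s) missing from the profile")
    if (length(shared) < 3L)
        stop("need at least 3 signature genes present in the profile")
    s <- sig@sign[match(shared, sig@gene)]
    x <- as.numeric(profile[shared])
    if (stats::sd(x) == 0) stop("profile is constant on the signature genes")
    if (stats::sd(s) == 0)
        stop("signature needs genes of both signs among those present")
    stats::cor(s, x)
}

#' Rank-based gene-set enrichment with a Monte-Carlo null
#'
#' Classic unweighted running statistic along a ranked gene list: +1/m at the
#' m gene-set hits, -1/(N - m) at misses, so the curve starts and ends at 0.
#' The observed statistic is the maximum of the running sum; the null is the
#' maximum under `nMC` uniformly reshuffled rankings. NES is the observed
#' maximum over the null mean; the p-value is the upper tail of a Gaussian
#' fitted to the null maxima.
#'
#' @param ranking character vector of gene ids, best-ranked first.
#' @param geneSet character vector of gene ids.
#' @param nMC number of Monte-Carlo reshuffles (>= 100; default 1000).
#' @param seed integer seed.
#' @return a [GseaResult-class].
#' @export
gseaMC <- function(ranking, geneSet, nMC = 1000L, seed = 42L) {
    if (nMC < 100L) stop("nMC must be at least 100")
    N <- length(ranking)
    hits <- ranking %in% geneSet
    m <- sum(hits)
    if (m == 0L) stop("gene set does not intersect the ranking")
    if (m == N) stop("gene set covers the whole ranking; no misses to score")
    step <- ifelse(hits, 1 / m, -1 / (N - m))
    curve <- c(0, cumsum(step))
    obs <- max(curve)
    maxESofPositions <- function(pos) {
        # running-max of the curve defined by hit positions (sorted)
        pos <- sort(pos)
        # value just after the i-th hit: i/m - (pos_i - i)/(N - m); the
        # curve only rises at hits, so its max is there (or 0 at the start)
        i <- seq_along(pos)
        max(0, i / m - (pos - i) / (N - m))
    }
    set.seed(as.integer(seed))
    nulls <- vapply(seq_len(nMC), function(b)
        maxESofPositions(sample.int(N, m)), numeric(1))
    mu <- mean(nulls); sdv <- stats::sd(nulls)
    new("GseaResult", esCurve = curve, maxES = obs, nes = obs / mu,
        p = stats::pnorm(obs, mu, sdv, lower.tail = FALSE),
        nMC = as.integer(nMC), nullMean = mu, nullSd = sdv)
}

#' Monte-Carlo mean-difference test for a gene set
#'
#' Compares the mean of a per-gene statistic over a gene set against the
#' means of `nMC` uniformly drawn same-size gene sets; one-tailed p-value
#' `(r + 1) / (nMC + 1)` with `r` the number of null means >= observed.
#'
#' @param stat named numeric vector of per-gene statistics (the universe).
#' @param geneSet character vector, subset of `names(stat)`.
#' @param nMC number of random draws (default 10000).
#' @param seed integer seed.
#' @return list with `observed`, `p`, `nullMean`.
#' @export
mcMeanDiffTest <- function(stat, geneSet, nMC = 10000L, seed = 42L) {
    if (is.null(names(stat))) stop("stat must be named by gene id")
    if (!all(geneSet %in% names(stat)))
        stop("gene set contains genes outside the statistic's universe")
    m <- length(geneSet)
    if (m > length(stat)) stop("gene set larger than the universe")
    obs <- mean(stat[geneSet])
    set.seed(as.integer(seed))
    nulls <- vapply(seq_len(nMC), function(b)
        mean(stat[sample.int(length(stat), m)]), numeric(1))
    r <- sum(nulls >= obs)
    list(observed = obs, p = (r + 1) / (nMC + 1), nullMean = mean(nulls))
}

#' Overlap enrichment of two gene sets
#'
#' 2x2 odds ratio (Haldane 0.5 correction when any cell is zero) and
#' one-tailed hypergeometric p-value for the overlap of two sets within a
#' universe.
#'
#' @param setA,setB character vectors.
#' @param universeSize size of the gene universe (>= |A union B|).
#' @return list with `oddsRatio`, `p`, `table` (a, b, c, d).
#' @export
overlapEnrichment <- function(setA, setB, universeSize) {
    setA <- unique(setA); setB <- unique(setB)
    u <- length(union(setA, setB))
    if (universeSize < u)
        stop("universe (", universeSize, ") smaller than |A union B| (", u, ")")
    a <- length(intersect(setA, setB))
    b <- length(setA) - a
    c <- length(setB) - a
    d <- universeSize - a - b - c
    or <- if (any(c(a, b, c, d) == 0))
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
    p <- stats::phyper(a - 1, length(setB), universeSize - length(setB),
                       length(setA), lower.tail = FALSE)
    list(oddsRatio = or, p = p, table = c(a = a, b = b, c = c, d = d))
}

#' Read gene sets from GMT or one-gene-per-line files
#'
#' @param path a `.gmt` file (name, description, genes per line) or a plain
#'   text file with one gene per line (a single unnamed set).
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
        toks <- strsplit(lines, "\t")
        sets <- lapply(toks, function(t) unique(t[-(1:2)]))
        names(sets) <- vapply(toks, `[`, character(1), 1L)
        sets
    } else {
        list(set1 = unique(trimws(lines)))
    }
}

#' Read a signed signature from a two-column TSV (gene, sign)
#' @param path TSV path; sign column coerced to +1/-1.
#' @return a [SignedSignature-class].
#' @export
readSignedSignature <- function(path) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (tolower(df[1, 1]) %in% c("gene", "id")) df <- df[-1, , drop = FALSE]
    SignedSignature(gene = df[[1]], sign = sign(as.numeric(df[[2]])))
}
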