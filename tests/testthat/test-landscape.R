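# three well-separated gaussian blobs in 2-D
makeBlobs <- function(n = 60, centers = rbind(c(0, 0), c(30, 0), c(0, 30)),
                      sd = 1, seed = 3) {
    set.seed(seed)
    lab <- rep(seq_len(nrow(centers)), each = n)
    coords <- centers[lab, ] + matrix(rnorm(2 * length(lab), 0, sd),
                                      ncol = 2)
    rownames(coords) <- sprintf("c%03d", seq_along(lab))
    list(coords = coords, labels = lab)
}

test_that("t-SNE embedding is deterministic and separates planted blobs", {
    set.seed(3)
    n <- 40; nGenes <- 30
    lab <- rep(1:3, each = n)
    centers <- matrix(rnorm(3 * nGenes, sd = 4), nrow = nGenes)
    X <- centers[, lab] + matrix(rnorm(nGenes * 3 * n, 0, 0.5), nGenes)
    dimnames(X) <- list(paste0("g", 1:nGenes), paste0("c", seq_len(3 * n)))

    co1 <- embedCells(X, initialDims = 10, perplexity = 10, maxIter = 500,
                      seed = 3)
    co2 <- embedCells(X, initialDims = 10, perplexity = 10, maxIter = 500,
                      seed = 3)
    expect_identical(co1[, ], co2[, ])
    expect_equal(dim(co1), c(120L, 2L))
    expect_equal(attr(co1, "params")$perplexity, 10)

    # silhouette of the true labels in the embedding
    D <- as.matrix(dist(co1))
    sil <- vapply(seq_len(nrow(co1)), function(i) {
        a <- mean(D[i, lab == lab[i]][-1])
        b <- min(vapply(setdiff(1:3, lab[i]), function(k)
            mean(D[i, lab == k]), numeric(1)))
        (b - a) / max(a, b)
    }, numeric(1))
    expect_gt(mean(sil), 0.5)

    expect_error(embedCells(X[, 1:20], perplexity = 30), "too few cells")
})

test_that("dbscan clustering: blobs, noise, canonical renumbering", {
    bl <- makeBlobs()
    cl <- clusterEmbedding(bl$coords, eps = 5, minPts = 10)
    expect_equal(max(cl), 3L)
    expect_equal(sum(cl == 0L), 0L)
    # one-to-one with planted labels
    expect_equal(length(unique(paste(cl, bl$labels))), 3L)

    # a far-away singleton is peripheral
    co <- rbind(bl$coords, lone = c(500, 500))
    cl2 <- clusterEmbedding(co, eps = 5, minPts = 10)
    expect_equal(unname(cl2["lone"]), 0L)

    # permutation stability: same partition regardless of input order
    # (label numbers may swap between equal-sized clusters; the partition
    # itself must be identical)
    perm <- sample(nrow(bl$coords))
    cl3 <- clusterEmbedding(bl$coords[perm, ], eps = 5, minPts = 10)
    crossTab <- table(cl, cl3[rownames(bl$coords)])
    expect_true(all(rowSums(crossTab > 0) == 1) &&
                all(colSums(crossTab > 0) == 1))

    # labels ordered by descending cluster size
    bl2 <- makeBlobs(n = 30)
    co4 <- rbind(bl$coords[1:60, ], bl2$coords[61:90, ] + 100)
    cl4 <- clusterEmbedding(co4, eps = 5, minPts = 10)
    sizes <- as.integer(table(cl4[cl4 > 0]))
    expect_true(all(diff(sizes) <= 0))
})

test_that("cell-state table: thresholds, peripherals, marginals", {
    cluster <- rep(c(1L, 2L, 3L), each = 30)
    state <- rep(rep(1:3, each = 10), 3)
    tab <- cellStateTable(cluster, state, minCells = 5L)
    expect_equal(nrow(tab), 9L)
    expect_true(all(tab$qualifies))
    expect_equal(sum(tab$n), 90L)

    # a pair below the threshold is counted but does not qualify
    cluster2 <- c(cluster, rep(1L, 4))
    state2 <- c(state, rep(9L, 4))
    tab2 <- cellStateTable(cluster2, state2, minCells = 5L)
    small <- tab2[tab2$state == 9L & tab2$cluster == 1L, ]
    expect_equal(small$n, 4L)
    expect_false(small$qualifies)

    # peripheral column present, never qualifying
    cluster3 <- c(rep(0L, 10), rep(1L, 10))
    state3 <- rep(1L, 20)
    tab3 <- cellStateTable(cluster3, state3, minCells = 5L)
    periph <- tab3[tab3$cluster == 0L, ]
    expect_equal(periph$n, 10L)
    expect_false(periph$qualifies)

    # marginals match cluster and state sizes
    expect_equal(tapply(tab$n, tab$cluster, sum),
                 tapply(rep(1L, 90), cluster, sum))
    expect_equal(tapply(tab$n, tab$state, sum),
                 tapply(rep(1L, 90), state, sum))

    expect_error(cellStateTable(1:3, 1:4), "equal length")
})

test_that("density surfaces share an extent, normalize, and find blob peaks", {
    bl <- makeBlobs(n = 50, centers = rbind(c(0, 0), c(20, 0)), seed = 8)
    g1 <- densitySurface(bl$coords, bl$labels == 1, gridSize = 80)
    g2 <- densitySurface(bl$coords, bl$labels == 2, gridSize = 80)
    # shared extent over the bounding box of all cells
    expect_equal(g1$x, g2$x); expect_equal(g1$y, g2$y)
    dx <- diff(g1$x[1:2]); dy <- diff(g1$y[1:2])
    expect_equal(sum(g1$z) * dx * dy, 1, tolerance = 1e-3)
    expect_equal(sum(g2$z) * dx * dy, 1, tolerance = 1e-3)
    # each subset's peak sits at its blob center
    pk1 <- which(g1$z == max(g1$z), arr.ind = TRUE)
    expect_lt(abs(g1$x[pk1[1]] - 0), 1)
    expect_lt(abs(g1$y[pk1[2]] - 0), 1)
    pk2 <- which(g2$z == max(g2$z), arr.ind = TRUE)
    expect_lt(abs(g2$x[pk2[1]] - 20), 1)

    # two equal blobs within one subset -> two near-equal local maxima
    co <- rbind(makeBlobs(n = 50, centers = rbind(c(0, 0)), seed = 1)$coords,
                makeBlobs(n = 50, centers = rbind(c(15, 0)), seed = 2)$coords)
    g <- densitySurface(co, gridSize = 60)
    zx <- apply(g$z, 1, max)
    # find local maxima along x
    locmax <- which(diff(sign(diff(zx))) == -2) + 1
    expect_gte(length(locmax), 2)
    top2 <- sort(zx[locmax], decreasing = TRUE)[1:2]
    expect_lt(abs(top2[1] - top2[2]) / top2[1], 0.2)

    expect_error(densitySurface(bl$coords, c(TRUE, rep(FALSE, 99))),
                 "at least 2")
})

test_that("computeLandscape recovers the planted (cluster, state) support", {
    bl <- makeBlobs(n = 40, seed = 12)
    # plant potency states aligned with blobs 1..3
    state <- bl$labels
    l <- computeLandscape(coords = bl$coords, potencyLabels = state,
                          eps = 5, minPts = 10, minCells = 5)
    expect_s4_class(l, "LandscapeResult")
    tab <- l@cellStateTable
    q <- tab[tab$qualifies, ]
    expect_equal(nrow(q), 3L)      # exactly the planted pairs
    expect_equal(sum(tab$n), 120L)
    expect_length(l@densityGrids, 3L)
    expect_equal(sum(l@clusterLabels == 0L), 0L)
})
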