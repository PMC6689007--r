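test_that("potency regression finds a planted linear gene", {
    set.seed(5)
    n <- 500; nG <- 60
    sr <- runif(n, 0.2, 0.95)
    X <- matrix(rnorm(nG * n, 5, 1), nG, n,
                dimnames = list(sprintf("g%02d", 1:nG), paste0("c", 1:n)))
    X["g01", ] <- 2 * sr + rnorm(n, 0, 0.3)
    de <- deVsPotency(X, sr)
    expect_equal(de$gene[which.max(abs(de$t))], "g01")
    expect_lt(de$p_adj[de$gene == "g01"], 0.05)
    expect_gt(de$effect[de$gene == "g01"], 0)
    expect_equal(de$n_cells_used, rep(n, nG))

    # constant gene -> NA statistics, excluded from the Bonferroni count
    X2 <- rbind(X, flat = rep(3, n))
    de2 <- deVsPotency(X2, sr)
    expect_true(is.na(de2$t[de2$gene == "flat"]))
    expect_equal(de2$p_adj, pmin(1, de2$p * (nG)))

    # permuting cells leaves statistics unchanged
    perm <- sample(n)
    de3 <- deVsPotency(X[, perm], sr[perm])
    expect_equal(de3$t, de$t, tolerance = 1e-10)

    expect_error(deVsPotency(X, rep(1, n)), "constant")
})

test_that("planted effect signs are recovered for all spiked genes", {
    set.seed(6)
    n <- 400; nG <- 50
    sr <- runif(n, 0.1, 0.9)
    X <- matrix(rnorm(nG * n, 4, 1), nG, n,
                dimnames = list(sprintf("g%02d", 1:nG), paste0("c", 1:n)))
    eff <- rep(c(1.5, -1.5), each = 10)
    for (i in 1:20) X[i, ] <- X[i, ] + eff[i] * sr
    de <- deVsPotency(X, sr)
    expect_equal(sign(de$effect[1:20]), sign(eff))
    expect_true(all(de$p_adj[1:20] < 0.05))
})

test_that("zero-dropping restricts fits to expressing cells; covariates accepted", {
    set.seed(8)
    n <- 200
    sr <- runif(n)
    g <- ifelse(runif(n) < 0.4, 0, 3 + sr + rnorm(n, 0, 0.2))
    X <- rbind(gene = g, other = rnorm(n, 5))
    colnames(X) <- paste0("c", 1:n)
    de <- deVsPotency(X, sr, dropZeros = TRUE)
    expect_equal(de$n_cells_used[1], sum(g > 0))
    expect_lt(de$p[1], 0.01)
    # with covariates the design gains columns but still fits
    cc <- cbind(g1s = rnorm(n), g2m = rnorm(n))
    dec <- deVsPotency(X, sr, covariates = cc)
    expect_false(any(is.na(dec$t)))
})

test_that("cell-cycle scores are mean-zero z-score averages", {
    set.seed(3)
    X <- matrix(rnorm(40 * 30, 5), 40, 30,
                dimnames = list(sprintf("g%02d", 1:40), paste0("c", 1:30)))
    g1s <- c("g01", "g02", "g03")
    g2m <- c("g10", "g11")
    sc <- cellCycleScores(X, g1s, g2m)
    expect_equal(mean(sc$g1s_score), 0, tolerance = 1e-12)
    expect_equal(mean(sc$g2m_score), 0, tolerance = 1e-12)
    # scale invariance
    sc2 <- cellCycleScores(2 * X, g1s, g2m)
    expect_equal(sc2$g1s_score, sc$g1s_score, tolerance = 1e-12)
    # absent/zero-variance genes dropped with a message
    X4 <- rbind(X, flatg = rep(1, 30))
    expect_message(cellCycleScores(X4, c(g1s, "flatg", "nothere"), g2m),
                   "2 G1/S")
    expect_error(cellCycleScores(X, c("nope"), g2m), "no usable")
})

test_that("signed signature construction: top-t selection, ties, warnings", {
    de <- data.frame(gene = sprintf("g%02d", 1:10),
                     effect = c(3, 2, 1, 0.5, 0.2, -0.2, -0.5, -1, -2, -3),
                     t = c(9, 8, 7, 6, 5, -5, -6, -7, -8, -9),
                     p = rep(1e-6, 10), p_adj = rep(1e-4, 10),
                     n_cells_used = 100L)
    sig <- buildSignedSignature(de, nUp = 2, nDn = 2)
    expect_equal(sig@gene, c("g01", "g02", "g10", "g09"))
    expect_equal(sig@sign, c(1, 1, -1, -1))
    # exactly as many significant positives as requested -> all included
    sig2 <- buildSignedSignature(de, nUp = 5, nDn = 5)
    expect_equal(sum(sig2@sign > 0), 5)
    # too few significant -> warning
    expect_warning(buildSignedSignature(de, nUp = 7, nDn = 2), "only 5")
    # tie in t broken by gene id
    de$t[1:2] <- 9
    sigT <- buildSignedSignature(de, nUp = 1, nDn = 1)
    expect_equal(sigT@gene[1], "g01")
    expect_error(buildSignedSignature(de[0, ]), "empty")
})

test_that("signature scoring: exact +/-1, affine invariance, missing genes", {
    sig <- SignedSignature(gene = c(paste0("u", 1:4), paste0("d", 1:4)),
                           sign = c(rep(1, 4), rep(-1, 4)))
    prof <- c(rep(1, 4), rep(-1, 4))
    names(prof) <- sig@gene
    expect_equal(signatureScore(prof, sig), 1)
    expect_equal(signatureScore(-prof, sig), -1)
    expect_equal(signatureScore(3 * prof + 10, sig), 1, tolerance = 1e-12)
    set.seed(2)
    noisy <- prof + rnorm(8, 0, 0.1)
    expect_equal(signatureScore(2.5 * noisy + 7, sig),
                 signatureScore(noisy, sig), tolerance = 1e-12)
    # missing genes dropped with a message
    expect_message(s <- signatureScore(prof[c(1, 2, 5, 6)], sig), "4 signature")
    expect_equal(s, 1)
    expect_error(signatureScore(prof[1:2], sig), "at least 3")
    expect_error(signatureScore(setNames(rep(1, 8), sig@gene), sig),
                 "constant")
})

test_that("GSEA: top-loaded set gives max ES 1; degenerate set errors", {
    ranking <- sprintf("g%03d", 1:200)
    res <- gseaMC(ranking, ranking[1:15], nMC = 200, seed = 1)
    expect_equal(res@maxES, 1, tolerance = 1e-12)
    expect_lt(res@p, 0.01)
    # running sum starts and ends at 0
    expect_equal(res@esCurve[1], 0)
    expect_equal(res@esCurve[length(res@esCurve)], 0, tolerance = 1e-12)
    expect_error(gseaMC(ranking, "absent"), "intersect")
    expect_error(gseaMC(ranking, ranking), "no misses")
    expect_error(gseaMC(ranking, ranking[1:5], nMC = 10), "at least 100")
})

test_that("GSEA null: NES centers at 1 under random rankings", {
    set.seed(10)
    genes <- sprintf("g%03d", 1:300)
    gs <- sample(genes, 20)
    rankings <- lapply(1:50, function(r) sample(genes))
    nes <- vapply(1:50, function(r) {
        gseaMC(rankings[[r]], gs, nMC = 150, seed = r)@nes
    }, numeric(1))
    expect_equal(mean(nes), 1, tolerance = 0.1)
})

test_that("Monte-Carlo mean-difference test: extremes and the null", {
    set.seed(4)
    stat <- setNames(rnorm(400), sprintf("g%03d", 1:400))
    top <- names(sort(stat, decreasing = TRUE))[1:12]
    r <- mcMeanDiffTest(stat, top, nMC = 999, seed = 2)
    expect_equal(r$p, 1 / 1000)
    expect_equal(r$observed, mean(stat[top]))
    # constant statistic -> p = 1
    flat <- setNames(rep(2, 100), sprintf("f%03d", 1:100))
    expect_equal(mcMeanDiffTest(flat, names(flat)[1:5], nMC = 199,
                                seed = 1)$p, 1)
    expect_error(mcMeanDiffTest(stat, c("zz"), nMC = 199), "outside")

    # p-values are (super-)uniform under the null
    hits <- vapply(1:200, function(r) {
        set.seed(r + 1000)
        gs <- sample(names(stat), 12)
        mcMeanDiffTest(stat, gs, nMC = 199, seed = r)$p < 0.05
    }, logical(1))
    expect_lte(abs(mean(hits) - 0.05), 0.03 + 1e-12)
})

test_that("overlap enrichment: direction, Haldane correction, worked value", {
    # disjoint sets covering the universe -> OR < 1
    a <- sprintf("a%d", 1:50); b <- sprintf("b%d", 1:50)
    expect_lt(overlapEnrichment(a, b, 100)$oddsRatio, 1)
    # identical sets: maximal OR for the table (Haldane kicks in, b = c = 0)
    same <- overlapEnrichment(a, a, 100)
    expect_gt(same$oddsRatio, 1000)
    expect_lt(same$p, 1e-20)
    # hand-computed table (a=10, b=10, c=10, d=970) -> OR = 97
    A <- c(sprintf("s%02d", 1:10), sprintf("x%02d", 1:10))
    B <- c(sprintf("s%02d", 1:10), sprintf("y%02d", 1:10))
    r <- overlapEnrichment(A, B, 1000)
    expect_equal(r$oddsRatio, 97)
    expect_equal(unname(r$table), c(10, 10, 10, 970))
    expect_error(overlapEnrichment(A, B, 25), "smaller")
})

test_that("gene-set and signed-signature readers parse their formats", {
    gmt <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), gmt)
    sets <- readGeneSets(gmt)
    expect_equal(names(sets), c("setA", "setB"))
    expect_equal(sets$setA, c("g1", "g2", "g3"))

    plain <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("g1", "g2"), plain)
    expect_equal(readGeneSets(plain)$set1, c("g1", "g2"))

    sg <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tsign", "u1\t1", "d1\t-1"), sg)
    sig <- readSignedSignature(sg)
    expect_equal(sig@gene, c("u1", "d1"))
    expect_equal(sig@sign, c(1, -1))
})
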