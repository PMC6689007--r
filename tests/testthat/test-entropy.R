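test_that("transition matrix matches the defining formula", {
    p3 <- pathNetwork(3)
    P <- as.matrix(transitionMatrix(c(1, 1, 2), p3))
    expect_equal(unname(P),
                 rbind(c(0, 1, 0), c(1 / 3, 0, 2 / 3), c(0, 1, 0)))

    # uniform expression collapses to the unweighted walk A_ij / deg(i)
    net <- simulateNetwork(25, seed = 3)
    A <- as.matrix(adjacencyMatrix(net))
    Pu <- as.matrix(transitionMatrix(rep(1, 25), net))
    expect_equal(Pu, sweep(A, 1, rowSums(A), "/"))

    # scale invariance and row stochasticity on random inputs
    set.seed(9)
    for (r in 1:5) {
        x <- rexp(25) + 0.05
        P1 <- transitionMatrix(x, net)
        expect_equal(as.matrix(P1), as.matrix(transitionMatrix(10 * x, net)),
                     tolerance = 1e-12)
        expect_equal(Matrix::rowSums(P1), rep(1, 25), ignore_attr = TRUE,
                     tolerance = 1e-12)
        expect_equal(as.matrix(P1), oracleTransition(x, net),
                     tolerance = 1e-12)
    }

    expect_error(transitionMatrix(c(1, 0, 2), p3), "positive")
    expect_error(transitionMatrix(rep(1, 4), p3), "length")
})

test_that("closed-form stationary distribution: left eigenvector, detailed balance", {
    p3 <- pathNetwork(3)
    expect_equal(unname(stationaryDistribution(c(1, 1, 2), p3)),
                 c(1 / 6, 1 / 2, 1 / 3), tolerance = 1e-12)
    expect_equal(unname(stationaryDistribution(rep(1, 3), p3)),
                 c(0.25, 0.5, 0.25), tolerance = 1e-12)

    set.seed(11)
    for (s in 1:5) {
        net <- simulateNetwork(sample(10:50, 1), density = 0.15, seed = s)
        x <- rexp(numNodes(net)) + 0.05
        pi <- stationaryDistribution(x, net)
        P <- transitionMatrix(x, net)
        expect_equal(sum(pi), 1, tolerance = 1e-12)
        # pi P = pi
        expect_lt(max(abs(as.numeric(pi %*% P) - pi)), 1e-10)
        # equals the left Perron eigenvector of dense P
        expect_equal(unname(pi), oracleStationary(P), tolerance = 1e-8)
        # detailed balance, entrywise
        F <- Matrix::Diagonal(x = pi) %*% P
        expect_lt(max(abs(F - Matrix::t(F))), 1e-12)
    }
})

test_that("entropy rate: hand values and brute-force oracle", {
    p3 <- pathNetwork(3)
    expect_equal(entropyRate(rep(1, 3), p3), 0.5 * log(2), tolerance = 1e-12)
    expect_equal(entropyRate(c(1, 1, 2), p3),
                 0.5 * (-(1 / 3) * log(1 / 3) - (2 / 3) * log(2 / 3)),
                 tolerance = 1e-12)
    # star: hub entropy ln 3 visited half the time
    expect_equal(entropyRate(rep(1, 4), starNetwork(3)), 0.5 * log(3),
                 tolerance = 1e-12)

    set.seed(21)
    for (s in 1:5) {
        net <- simulateNetwork(30, density = 0.12, seed = s)
        x <- rexp(30) + 0.05
        sr <- entropyRate(x, net)
        expect_gte(sr, 0)
        expect_equal(sr, oracleEntropyRate(transitionMatrix(x, net),
                                           stationaryDistribution(x, net)),
                     tolerance = 1e-10)
        expect_equal(sr, entropyRate(7 * x, net), tolerance = 1e-12)
    }
})

test_that("normalized SR: worked values, regular graphs, (0, 1] range", {
    p3 <- pathNetwork(3)
    expect_equal(normalizedSR(rep(1, 3), p3), 1, tolerance = 1e-12)
    expect_equal(normalizedSR(c(1, 1, 2), p3), 0.9182958, tolerance = 1e-6)
    expect_equal(normalizedSR(rep(1, 4), pathNetwork(4)), 0.9602801,
                 tolerance = 1e-6)

    # SR = 1 on k-regular graphs with uniform expression
    for (n in c(5, 8)) {
        cyc <- cycleNetwork(n)
        expect_equal(normalizedSR(rep(1, n), cyc), 1, tolerance = 1e-10)
    }

    set.seed(31)
    for (s in 1:5) {
        net <- simulateNetwork(30, density = 0.12, seed = s)
        x <- rexp(30) + 0.05
        srn <- normalizedSR(x, net)
        expect_true(srn > 0 && srn <= 1 + 1e-12)
    }
})

test_that("srProfile: determinism, scale invariance, alignment errors", {
    net <- simulateNetwork(60, seed = 5)
    set.seed(42)
    X <- matrix(rexp(60 * 8) + 0.05, 60, 8,
                dimnames = list(geneIds(net), paste0("c", 1:8)))
    p <- srProfile(X, net)
    expect_s4_class(p, "SRProfile")
    expect_equal(SR(p), setNames(apply(X, 2, normalizedSR, net = net),
                                 colnames(X)), tolerance = 1e-12)

    # identical cells, scaled cells
    X2 <- cbind(X, c9 = X[, 1], c10 = 10 * X[, 1])
    p2 <- srProfile(X2, net)
    expect_equal(unname(SR(p2)["c9"]), unname(SR(p2)["c1"]))
    expect_equal(unname(SR(p2)["c10"]), unname(SR(p2)["c1"]), tolerance = 1e-12)

    # column order must not matter
    p3 <- srProfile(X[, 8:1], net)
    expect_equal(SR(p3)[colnames(X)], SR(p))

    # logit relation and data.frame round trip
    expect_equal(logitSR(p), log2(SR(p) / (1 - SR(p))), tolerance = 1e-12)
    df <- as.data.frame(p)
    expect_equal(df$SR, unname(SR(p)))

    Xbad <- X; Xbad[3, 2] <- 0
    expect_error(srProfile(Xbad, net), "cell 'c2'")
})

test_that("sparse profile agrees with dense per-cell evaluation on larger graphs", {
    net <- simulateNetwork(200, density = 0.05, seed = 8)
    set.seed(1)
    X <- matrix(rexp(200 * 4) + 0.05, 200, 4,
                dimnames = list(geneIds(net), paste0("c", 1:4)))
    p <- srProfile(X, net)
    dense <- vapply(1:4, function(c) {
        P <- oracleTransition(X[, c], net)
        oracleEntropyRate(P, unname(stationaryDistribution(X[, c], net)))
    }, numeric(1)) / maxSR(p)
    expect_equal(unname(SR(p)), dense, tolerance = 1e-10)
})

test_that("logitSR on numerics follows the base-2 formula and rejects 0/1", {
    expect_equal(logitSR(0.5), 0)
    expect_equal(logitSR(0.8), 2, tolerance = 1e-12)
    expect_equal(logitSR(0.2), -2, tolerance = 1e-12)
    expect_error(logitSR(1), "open interval")
    expect_error(logitSR(0), "open interval")
})
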