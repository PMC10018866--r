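test_that("pair fractions apply the minimum-sites rule per end", {
    sim <- sharedSim()
    lp <- sharedPairs()
    pts <- pairFractions(lp, minSites = 3)
    p <- as.data.frame(pairSummary(lp))
    long <- p$pairClass == "CIS_LONG"
    expect_equal(nrow(pts),
                 sum(long & p$gchSites1 >= 3 & p$gchSites2 >= 3))
    i <- pts$pairIdx[1]
    expect_equal(pts$frac1[1], p$gchMeth1[i] / p$gchSites1[i])
    expect_equal(pts$frac2[1], p$gchMeth2[i] / p$gchSites2[i])
    # a stricter cutoff can only shrink the point set
    expect_lte(nrow(pairFractions(lp, minSites = 8)), nrow(pts))
    # WCG mode reads the endogenous-methylation columns
    ptsW <- pairFractions(lp, context = "WCG", minSites = 3)
    expect_equal(nrow(ptsW),
                 sum(long & p$wcgSites1 >= 3 & p$wcgSites2 >= 3))
})

test_that("pearsonR matches collinear expectations and rejects degenerate input", {
    expect_equal(pearsonR(c(0, 0.5, 1), c(0.1, 0.5, 0.9)), 1.0)
    expect_equal(pearsonR(c(0, 0.5, 1), c(1, 0.5, 0)), -1.0)
    expect_error(pearsonR(c(1, 2), c(3, 4)), "3 points")
    expect_error(pearsonR(c(1, 1, 1), c(0, 1, 2)), "zero variance")
})

test_that("phi equals Pearson on the binarized pairs", {
    # build fractions realising the table [[40, 10], [10, 40]]
    f1 <- c(rep(0.8, 40), rep(0.9, 10), rep(0.2, 10), rep(0.1, 40))
    f2 <- c(rep(0.7, 40), rep(0.3, 10), rep(0.6, 10), rep(0.2, 40))
    res <- binarizeAndPhi(f1, f2)
    expect_equal(unname(res$table),
                 matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
    expect_equal(res$phi, (40 * 40 - 10 * 10) / sqrt(50 * 50 * 50 * 50))
    b1 <- as.integer(f1 >= 0.5); b2 <- as.integer(f2 >= 0.5)
    expect_equal(res$phi, cor(b1, b2))
    # a fraction exactly at the cutpoint binarizes to 1
    res2 <- binarizeAndPhi(c(0.5, 0.5, 0), c(1, 1, 0))
    expect_equal(unname(res2$table[1, 1]), 2)
    expect_error(binarizeAndPhi(c(1, 1, 1), c(0, 1, 0)),
                 "degenerate margin")
})

test_that("tetrachoric correlation: independence, cosine form, ML recovery", {
    expect_equal(tetrachoricR(matrix(c(25, 25, 25, 25), 2)), 0,
                 tolerance = 1e-6)
    expect_equal(tetrachoricR(matrix(c(40, 10, 10, 40), 2, byrow = TRUE),
                              method = "cosine"),
                 cospi(1 / 5), tolerance = 1e-12)
    set.seed(42)
    z <- rBinorm(50000, 0.5)
    tab <- table(factor(z[, 1] > 0, c(TRUE, FALSE)),
                 factor(z[, 2] > 0, c(TRUE, FALSE)))
    expect_equal(tetrachoricR(as.matrix(tab)), 0.5, tolerance = 0.03)
    # zero cells are smoothed, zero margins rejected
    expect_equal(tetrachoricR(matrix(c(2, 0, 0, 2), 2)), 1,
                 tolerance = 0.2)
    expect_error(tetrachoricR(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
                 "zero margin")
    expect_error(tetrachoricR(matrix(0, 2, 2)), "empty|zero")
})

test_that("shuffle null permutes end 2 within anchor groups", {
    pts <- data.frame(anchorId = c("a", "a"), pairIdx = 1:2,
                      frac1 = c(1, 0), frac2 = c(0, 1))
    null <- shuffleNull(pts, nShuffles = 50, seed = 3)
    for (rep in null$replicates) {
        expect_true(identical(rep$frac2, c(0, 1)) ||
                    identical(rep$frac2, c(1, 0)))
        expect_equal(mean(rep$frac2), 0.5)
    }
    # same seed reproduces the replicates exactly
    null2 <- shuffleNull(pts, nShuffles = 50, seed = 3)
    expect_identical(null$replicates, null2$replicates)
    # per-anchor multisets of end-2 fractions are preserved exactly
    sim <- sharedSim()
    lp <- sharedPairs()
    big <- pairFractions(lp, assignPairsToAnchorPairs(lp, sim$anchors))
    nb <- shuffleNull(big, nShuffles = 5, seed = 1)
    for (rep in nb$replicates) {
        for (g in split(seq_len(nrow(big)), big$anchorId)) {
            expect_identical(sort(rep$frac2[g]), sort(big$frac2[g]))
        }
    }
})

test_that("Fisher z comparison matches the arctanh formula", {
    expect_equal(fisherZCompare(0.4, 50, 0.4, 80)$z, 0)
    expect_equal(fisherZCompare(0.4, 50, 0.4, 80)$p, 1)
    res <- fisherZCompare(0.5, 103, 0, 103)
    expect_equal(res$z, 3.884, tolerance = 1e-3)
    expect_equal(res$p, 1.03e-4, tolerance = 1e-2)
    # antisymmetric in the group order
    a <- fisherZCompare(0.6, 40, 0.2, 60)
    b <- fisherZCompare(0.2, 60, 0.6, 40)
    expect_equal(a$z, -b$z)
    expect_equal(a$p, b$p)
    expect_error(fisherZCompare(1, 10, 0, 10), "infinite")
    expect_error(fisherZCompare(0.5, 3, 0, 10), "exceed 3")
    # agreement with an independent implementation on random inputs
    set.seed(7)
    for (i in 1:1000) {
        r1 <- runif(1, -0.99, 0.99); r2 <- runif(1, -0.99, 0.99)
        n1 <- sample(4:5000, 1); n2 <- sample(4:5000, 1)
        mine <- fisherZCompare(r1, n1, r2, n2)
        ref <- oracleFisherZ(r1, n1, r2, n2)
        expect_equal(mine$z, ref$z, tolerance = 1e-12)
        expect_equal(mine$p, ref$p, tolerance = 1e-12)
    }
})

test_that("local control selects short same-anchor pairs up to the cap", {
    sim <- sharedSim()
    lp <- sharedPairs()
    pts <- localControlPairs(lp, sim$anchors, seed = 2)
    p <- as.data.frame(pairSummary(lp))
    # every selected pair is short-range and simulated as local material
    expect_true(all(p$separation[pts$pairIdx] <= 1000))
    expect_true(all(grepl("_l", p$qname[pts$pairIdx])))
    # per-anchor sampling cap
    capped <- localControlPairs(lp, sim$anchors, sampleCap = 5, seed = 2)
    expect_true(all(table(capped$anchorId) <= 5))
    expect_true(all(table(pts$anchorId) >
                    table(capped$anchorId)[names(table(pts$anchorId))] |
                    table(pts$anchorId) <= 5))
    # separation beyond the window excludes the pair
    none <- localControlPairs(lp, sim$anchors, maxSeparation = 10,
                              seed = 2)
    expect_equal(nrow(none), 0L)
})

test_that("planted correlation is detected against the shuffle null", {
    sim <- sharedSim()
    lp <- sharedPairs()
    res <- runLongRangeConcordance(lp, sim$anchors, seed = 11)
    expect_gt(res@rObserved, mean(shuffledR(res)) + 0.2)
    expect_lt(res@pFisher, 1e-6)
    expect_equal(length(shuffledR(res)), 100L)
    # local control is at least as concordant as the long-range pairs
    expect_gt(res@local$rObserved, res@rObserved - 0.1)
    # deterministic under the seed
    res2 <- runLongRangeConcordance(lp, sim$anchors, seed = 11)
    expect_identical(shuffledR(res), shuffledR(res2))
    expect_error(runLongRangeConcordance(lp, sim$anchors[0, ]),
                 "insufficient data")
})

test_that("observed r increases with the planted latent correlation", {
    rs <- vapply(c(0, 0.5, 0.9), function(rho) {
        cfg <- simulationConfig(seed = 31, genomeLength = 3e5,
                                nAnchorPairs = 6, nPairsPerAnchor = 150,
                                rhoLatent = rho)
        sim <- simulateLinkedReadPairs(cfg)
        lp <- loadLinkedPairs(sim$records, sim$index)
        res <- runLongRangeConcordance(lp, sim$anchors, seed = 31,
                                       localMaxDist = NULL)
        res@rObserved
    }, numeric(1))
    expect_lt(abs(rs[1]), 0.1)
    expect_gt(rs[2], rs[1] + 0.1)
    expect_gt(rs[3], rs[2] + 0.1)
})
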