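test_that("configuration validates the generative parameters", {
    expect_error(simulationConfig(gcFraction = 1.2), "gcFraction")
    expect_error(simulationConfig(pOpen = 0.2, pClosed = 0.8), "pOpen")
    # rho infeasible for an extreme marginal
    expect_error(simulationConfig(piOpen = 0.95, rhoLatent = -0.9),
                 "infeasible")
    cfg <- simulationConfig(seed = 1)
    expect_s3_class(cfg, "bslinkSimConfig")
    expect_equal(cfg$p11, 0.5^2 + 0.6 * 0.5 * 0.5)
})

test_that("simulated reference has the requested GC content", {
    g <- simulateReference(10000, gcFraction = 0.5, seed = 4)
    freq <- Biostrings::alphabetFrequency(g, collapse = TRUE)
    gc <- sum(freq[c("C", "G")])
    expect_lt(abs(gc - 5000), 3 * sqrt(10000 * 0.25))
    expect_equal(Biostrings::width(g), 10000L)
    # deterministic under the seed
    g2 <- simulateReference(10000, gcFraction = 0.5, seed = 4)
    expect_identical(as.character(g[[1]]), as.character(g2[[1]]))
    expect_error(simulateReference(100, gcFraction = 0), "gcFraction")
    # a GC-richer genome is denser in GCH sites
    d42 <- contextDensity(buildContextIndex(
        simulateReference(50000, 0.42, seed = 6)), "GCH")
    d30 <- contextDensity(buildContextIndex(
        simulateReference(50000, 0.30, seed = 6)), "GCH")
    expect_lt(d42, d30)
})

test_that("anchor pairs are disjoint and separated beyond the threshold", {
    g <- simulateReference(1e6, seed = 2)
    a <- simulateAnchorPairs(g, n = 5, span = 1000,
                             minSeparation = 20001, seed = 2)
    expect_equal(nrow(a), 5L)
    expect_true(all(a$start2 - a$end1 > 20000))
    gr <- c(GenomicRanges::GRanges(a$chrom1,
                IRanges::IRanges(a$start1, a$end1)),
            GenomicRanges::GRanges(a$chrom2,
                IRanges::IRanges(a$start2, a$end2)))
    expect_equal(sum(GenomicRanges::countOverlaps(gr, gr)), length(gr))
    expect_identical(a, simulateAnchorPairs(g, n = 5, span = 1000,
                                            minSeparation = 20001,
                                            seed = 2))
    expect_error(simulateAnchorPairs(g, n = 50, span = 1000,
                                     minSeparation = 20001, seed = 1),
                 "infeasible")
})

test_that("identical configuration and seed give identical bundles", {
    cfg <- simulationConfig(seed = 23, genomeLength = 1e5,
                            nAnchorPairs = 2, nPairsPerAnchor = 10)
    s1 <- simulateLinkedReadPairs(cfg)
    s2 <- simulateLinkedReadPairs(cfg)
    expect_identical(s1$records, s2$records)
    expect_identical(s1$truth, s2$truth)
    expect_identical(as.character(s1$genome[[1]]),
                     as.character(s2$genome[[1]]))
    # every emitted read traces back to a truth molecule
    expect_setequal(unique(s1$records$qname), s1$truth$molecule)
})

test_that("latent states realise the planted correlation and marginal", {
    sim <- sharedSim()
    tr <- sim$truth[sim$truth$kind == "long", ]
    n <- nrow(tr)
    rho <- sim$config$rhoLatent
    expect_lt(abs(cor(tr$S1, tr$S2) - rho), 4 * (1 - rho^2) / sqrt(n))
    expect_lt(abs(mean(tr$S1) - sim$config$piOpen), 4 * 0.5 / sqrt(n))
})

test_that("methylation calls match the truth at the configured noise", {
    # deterministic emission (pOpen=1, pClosed=0): every GCH call error
    # comes from conversion failure or sequencing error
    f <- 0.01; e <- 0.003
    cfg <- simulationConfig(seed = 29, genomeLength = 2e5,
                            nAnchorPairs = 4, nPairsPerAnchor = 120,
                            pOpen = 1, pClosed = 1e-9,
                            conversionFailure = f, sequencingError = e)
    sim <- simulateLinkedReadPairs(cfg)
    lp <- loadLinkedPairs(sim$records, sim$index,
                          conversionFilter = FALSE)
    p <- as.data.frame(pairSummary(lp))
    tr <- sim$truth[match(p$qname, sim$truth$molecule), ]
    calls <- rbind(
        data.frame(meth = p$gchMeth1, tot = p$gchSites1, S = tr$S1),
        data.frame(meth = p$gchMeth2, tot = p$gchSites2, S = tr$S2))
    # open ends: only a sequencing error hitting the C can flip a call
    open <- calls$S == 1
    errOpen <- sum(calls$tot[open] - calls$meth[open])
    nOpen <- sum(calls$tot[open])
    pOpenErr <- e / 3
    expect_lt(abs(errOpen / nOpen - pOpenErr),
              4 * sqrt(pOpenErr / nOpen) + 2e-4)
    # closed ends: conversion failure or an error hitting the T
    errClosed <- sum(calls$meth[!open])
    nClosed <- sum(calls$tot[!open])
    pClosedErr <- f + (1 - f) * e / 3
    expect_lt(abs(errClosed / nClosed - pClosedErr),
              4 * sqrt(pClosedErr / nClosed) + 2e-4)
})

test_that("methylated WCH rate tracks the conversion-failure rate", {
    cfg <- simulationConfig(seed = 37, genomeLength = 2e5,
                            nAnchorPairs = 4, nPairsPerAnchor = 100,
                            conversionFailure = 0.02,
                            sequencingError = 0)
    sim <- simulateLinkedReadPairs(cfg)
    lp <- loadLinkedPairs(sim$records, sim$index,
                          conversionFilter = FALSE)
    calls <- as.data.frame(methylCalls(lp))
    wch <- calls$label == "WCH"
    rate <- mean(calls$methylated[wch])
    expect_lt(abs(rate - 0.02), 3 * sqrt(0.02 * 0.98 / sum(wch)))
})

test_that("conversion filter removes exactly the flagged-unconverted reads", {
    cfg <- simulationConfig(seed = 41, genomeLength = 2e5,
                            nAnchorPairs = 4, nPairsPerAnchor = 80,
                            pFailedMolecule = 0.25)
    sim <- simulateLinkedReadPairs(cfg)
    lpAll <- loadLinkedPairs(sim$records, sim$index,
                             conversionFilter = FALSE)
    lpFlt <- loadLinkedPairs(sim$records, sim$index)
    calls <- as.data.frame(methylCalls(lpAll))
    p <- as.data.frame(pairSummary(lpAll))
    methWch <- calls$label == "WCH" & calls$methylated
    perEnd <- tapply(methWch, list(calls$pairIdx, calls$end), sum)
    flagged <- apply(perEnd >= 3, 1, any, na.rm = TRUE)
    expectKept <- p$qname[!flagged[as.character(seq_len(nrow(p)))]]
    expect_setequal(as.data.frame(pairSummary(lpFlt))$qname, expectKept)
    # failed molecules carry many methylated WCH sites, so all of them
    # are removed at the study's read lengths
    failed <- sim$truth$molecule[sim$truth$failedConversion]
    expect_false(any(failed %in%
                     as.data.frame(pairSummary(lpFlt))$qname))
})

test_that("allelic dataset plants assignable SNPs with labelled groups", {
    fx <- allelicFixture()
    sim <- fx$sim
    expect_equal(nrow(sim$snps), 6L)
    expect_true(all(sim$snps$ref == "A" & sim$snps$alt == "T"))
    # the reference carries the REF allele at each SNP
    chars <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
    expect_true(all(chars[sim$snps$pos] == "A"))
    # end 1 of every pair covers its locus SNP
    rec1 <- sim$records[bitwAnd(sim$records$flag, 64L) > 0L, ]
    locus <- sub("_(REF|ALT).*$", "", rec1$qname)
    snpAt <- sim$snps$pos[match(locus, sim$truth$loci$locus)]
    expect_true(all(rec1$pos <= snpAt &
                    rec1$pos + nchar(rec1$seq) - 1L >= snpAt))
    expect_error(simulateAllelicDataset(simulationConfig(seed = 1,
        nAnchorPairs = 1,
        allelicPlan = data.frame(group = "GROUP1", nLoci = 5))),
        "exceed")
})

test_that("simulation bundles round trip through files", {
    cfg <- simulationConfig(seed = 43, genomeLength = 1e5,
                            nAnchorPairs = 2, nPairsPerAnchor = 15)
    sim <- simulateLinkedReadPairs(cfg)
    dir <- withr::local_tempdir()
    writeSimulation(sim, dir)
    expect_true(all(file.exists(file.path(dir,
        c("reference.fa", "anchors.bedpe", "reads.sam",
          "truth_molecules.tsv")))))
    genome <- readGenome(file.path(dir, "reference.fa"))
    expect_identical(as.character(genome[[1]]),
                     as.character(sim$genome[[1]]))
    lpA <- loadLinkedPairs(file.path(dir, "reads.sam"),
                           buildContextIndex(genome))
    lpB <- loadLinkedPairs(sim$records, sim$index)
    a <- as.data.frame(pairSummary(lpA))
    b <- as.data.frame(pairSummary(lpB))
    a <- a[order(a$qname), ]; b <- b[order(b$qname), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a$gchMeth1, b$gchMeth1)
    expect_equal(a$gchSites2, b$gchSites2)
    expect_equal(a$pairClass, b$pairClass)
})
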