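# shared simulated datasets, built once per test run

.fixtureCache <- new.env(parent = emptyenv())

memoise <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache)) {
        assign(name, builder(), envir = .fixtureCache)
    }
    get(name, envir = .fixtureCache)
}

# medium bundle with planted correlation and local-control pairs
sharedSim <- function() memoise("sharedSim", function() {
    cfg <- simulationConfig(seed = 11, genomeLength = 4e5,
                            nAnchorPairs = 8, nPairsPerAnchor = 60,
                            nLocalPairsPerAnchor = 20)
    simulateLinkedReadPairs(cfg)
})

sharedPairs <- function() memoise("sharedPairs", function() {
    sim <- sharedSim()
    loadLinkedPairs(sim$records, sim$index)
})

# small allelic dataset with strong effects and no sequencing noise
allelicFixture <- function() memoise("allelicFixture", function() {
    plan <- data.frame(group = c("GROUP1", "GROUP2", "NONE"), nLoci = 2,
                       pOpenHigh = 0.95, pOpenLow = 0.05,
                       pairsPerAllele = 12)
    cfg <- simulationConfig(seed = 19, genomeLength = 2e5,
                            nAnchorPairs = 6, allelicPlan = plan,
                            sequencingError = 0, conversionFailure = 0)
    sim <- simulateAllelicDataset(cfg)
    list(sim = sim, lp = loadLinkedPairs(sim$records, sim$index))
})

# 16 bp toy reference with hand-enumerated context sites:
#   fwd C:  pos 4 GCH, pos 8 WCG, pos 13 GCG
#   minus C (at G): pos 3 GCH, pos 9 WCG, pos 12 GCH, pos 14 WCG
toyGenome <- function() {
    g <- Biostrings::DNAStringSet(c(chrT = "AAGCAAACGAAGCGAA"))
    g
}

toyIndex <- function() memoise("toyIndex", function() {
    buildContextIndex(toyGenome())
})

phredChar <- function(q) intToUtf8(q + 33L)
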