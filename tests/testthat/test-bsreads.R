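# toy reference "AAGCAAACGAAGCGAA": forward cytosines at 4 (GCH),
# 8 (WCG), 13 (GCG); minus-strand cytosines at G positions 3 (GCH),
# 9 (WCG), 12 (GCH), 14 (WCG)

test_that("OT reads report forward cytosines as C=meth / T=unmeth", {
    reads <- data.frame(chrom = "chrT", start = 1L,
                        seq = "AAGCAAATGAAGCGAA",
                        qual = strrep("H", 16), conversion = "CT",
                        stringsAsFactors = FALSE)
    calls <- callReadMethylation(reads, toyIndex())
    expect_equal(calls$pos, c(4L, 8L, 13L))
    expect_equal(calls$label, c("GCH", "WCG", "GCG"))
    expect_equal(calls$methylated, c(TRUE, FALSE, TRUE))
    expect_true(all(calls$strand == "+"))
})

test_that("OB reads report minus-strand cytosines as G=meth / A=unmeth", {
    reads <- data.frame(chrom = "chrT", start = 1L,
                        seq = "AAGCAAACAAAGCGAA",
                        qual = strrep("H", 16), conversion = "GA",
                        stringsAsFactors = FALSE)
    calls <- callReadMethylation(reads, toyIndex())
    expect_equal(calls$pos, c(3L, 9L, 12L, 14L))
    expect_equal(calls$label, c("GCH", "WCG", "GCH", "WCG"))
    expect_equal(calls$methylated, c(TRUE, FALSE, TRUE, TRUE))
    expect_true(all(calls$strand == "-"))
})

test_that("calls at or below the base-quality cutoff are dropped", {
    qual <- paste0("AAA", phredChar(4), strrep("H", 12))
    reads <- data.frame(chrom = "chrT", start = 1L,
                        seq = "AAGCAAATGAAGCGAA", qual = qual,
                        conversion = "CT", stringsAsFactors = FALSE)
    calls <- callReadMethylation(reads, toyIndex())
    expect_false(4L %in% calls$pos)
    # quality 5 is excluded (strictly greater required), 6 is kept
    q5 <- paste0("AAA", phredChar(5), strrep("H", 12))
    q6 <- paste0("AAA", phredChar(6), strrep("H", 12))
    reads$qual <- q5
    expect_false(4L %in% callReadMethylation(reads, toyIndex())$pos)
    reads$qual <- q6
    expect_true(4L %in% callReadMethylation(reads, toyIndex())$pos)
    # mismatching bases at a site are skipped, not called
    reads <- data.frame(chrom = "chrT", start = 1L,
                        seq = "AAGAAAATGAAGCGAA",
                        qual = strrep("H", 16), conversion = "CT",
                        stringsAsFactors = FALSE)
    expect_false(4L %in% callReadMethylation(reads, toyIndex())$pos)
    expect_error(callReadMethylation(
        data.frame(chrom = "chrT", start = 10L, seq = strrep("A", 16),
                   qual = strrep("H", 16), conversion = "CT"),
        toyIndex()), "beyond reference")
    expect_error(callReadMethylation(
        data.frame(chrom = "chrT", start = 1L, seq = "ACGT",
                   qual = "HHHH", conversion = "XX"), toyIndex()),
        "conversion strand")
})

test_that("incomplete-conversion flag counts methylated WCH calls", {
    calls <- data.frame(label = rep("WCH", 5),
                        methylated = c(TRUE, TRUE, TRUE, FALSE, FALSE))
    expect_true(isIncompletelyConverted(calls))
    calls$methylated <- FALSE
    expect_false(isIncompletelyConverted(calls))
    expect_false(isIncompletelyConverted(
        data.frame(label = character(), methylated = logical())))
    # threshold is configurable
    calls$methylated <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
    expect_false(isIncompletelyConverted(calls, 3))
    expect_true(isIncompletelyConverted(calls, 2))
})

# crafted alignment records on a simulated two-chromosome reference
mkRecords <- function() {
    g1 <- simulateReference(40000, seed = 21, name = "chrA")
    g2 <- simulateReference(5000, seed = 22, name = "chrB")
    genome <- c(g1, g2)
    idx <- buildContextIndex(genome)
    convRead <- function(chrom, start, conv, raw = FALSE) {
        s <- substr(as.character(genome[[chrom]]), start, start + 99L)
        if (!raw)
            s <- if (conv == "CT") chartr("C", "T", s)
                 else chartr("G", "A", s)
        s
    }
    rec <- function(qn, flag, chrom, start, mapq = 60L, conv = "CT",
                    raw = FALSE)
        data.frame(qname = qn, flag = flag, rname = chrom, pos = start,
                   mapq = mapq, cigar = "100M",
                   seq = convRead(chrom, start, conv, raw),
                   qual = strrep("H", 100), conversion = conv,
                   stringsAsFactors = FALSE)
    records <- rbind(
        rec("long1", 65L, "chrA", 101L), rec("long1", 129L, "chrA", 30101L),
        rec("short1", 65L, "chrA", 101L), rec("short1", 129L, "chrA", 1101L),
        rec("lowmq", 65L, "chrA", 101L),
        rec("lowmq", 129L, "chrA", 30101L, mapq = 10L),
        rec("dup", 65L + 1024L, "chrA", 101L),
        rec("dup", 129L + 1024L, "chrA", 30101L),
        rec("orphan", 65L, "chrA", 101L),
        rec("trans", 65L, "chrA", 101L), rec("trans", 129L, "chrB", 201L),
        rec("unconv", 65L, "chrA", 101L, raw = TRUE),
        rec("unconv", 129L, "chrA", 30101L, raw = TRUE))
    list(records = records, index = idx)
}

test_that("pair filters and classification follow the standard rules", {
    fx <- mkRecords()
    expect_message(
        lp <- loadLinkedPairs(fx$records, fx$index),
        "unmated")
    p <- as.data.frame(pairSummary(lp))
    expect_setequal(p$qname, c("long1", "short1", "trans"))
    expect_equal(p$pairClass[p$qname == "long1"], factor("CIS_LONG",
        levels = c("CIS_LONG", "CIS_SHORT", "TRANS")))
    # outermost span: reads of 100 bp at 101 and 30101 cover 101..30200
    expect_equal(p$separation[p$qname == "long1"], 30099L)
    expect_equal(as.character(p$pairClass[p$qname == "short1"]),
                 "CIS_SHORT")
    expect_equal(as.character(p$pairClass[p$qname == "trans"]), "TRANS")
    expect_true(is.na(p$separation[p$qname == "trans"]))
    st <- filterStats(lp)
    expect_equal(st$nMapqDropped, 1L)
    expect_equal(st$nDupDropped, 1L)
    expect_equal(st$nConversionDropped, 1L)
    expect_equal(st$nUnmated, 1L)
    # the unconverted pair survives when the filter is off
    lpAll <- suppressMessages(loadLinkedPairs(fx$records, fx$index,
                                              conversionFilter = FALSE,
                                              dropDuplicates = FALSE))
    expect_setequal(as.data.frame(pairSummary(lpAll))$qname,
                    c("long1", "short1", "dup", "trans", "unconv"))
    # a long-range threshold is a parameter, not a constant
    lp50 <- suppressMessages(loadLinkedPairs(fx$records, fx$index,
                                             longRange = 50000))
    p50 <- as.data.frame(pairSummary(lp50))
    expect_equal(as.character(p50$pairClass[p50$qname == "long1"]),
                 "CIS_SHORT")
})

test_that("pair classification is symmetric in end order", {
    fx <- mkRecords()
    swapped <- fx$records
    i <- swapped$qname == "long1"
    swapped$flag[i] <- rev(swapped$flag[i])
    a <- suppressMessages(loadLinkedPairs(fx$records, fx$index))
    b <- suppressMessages(loadLinkedPairs(swapped, fx$index))
    pa <- as.data.frame(pairSummary(a)); pb <- as.data.frame(pairSummary(b))
    expect_equal(pa$pairClass[pa$qname == "long1"],
                 pb$pairClass[pb$qname == "long1"])
    expect_equal(pa$separation[pa$qname == "long1"],
                 pb$separation[pb$qname == "long1"])
})

test_that("GCG calls are excluded from GCH and HCG summaries", {
    reads <- data.frame(
        qname = "t1", flag = c(65L, 129L), rname = "chrT", pos = 1L,
        mapq = 60L, cigar = "16M",
        seq = "AAGCAAATGAAGCGAA", qual = strrep("H", 16),
        conversion = "CT", stringsAsFactors = FALSE)
    lp <- loadLinkedPairs(reads, toyIndex())
    p <- as.data.frame(pairSummary(lp))
    # forward sites in the window: GCH at 4 (meth C), WCG at 8 (unmeth T),
    # GCG at 13 (present as a call, counted in neither summary)
    expect_equal(p$gchSites1, 1L)
    expect_equal(p$gchMeth1, 1L)
    expect_equal(p$hcgSites1, 1L)
    expect_equal(p$hcgMeth1, 0L)
    calls <- as.data.frame(methylCalls(lp))
    expect_true("GCG" %in% calls$label)
})

test_that("retained ends respect the mapq and base-quality floors", {
    lp <- sharedPairs()
    expect_true(all(alignedEnds(lp)$mapq > 30))
    expect_true(all(as.data.frame(methylCalls(lp))$baseQuality > 5))
})

test_that("anchor assignment requires one end in each anchor", {
    sim <- sharedSim()
    lp <- sharedPairs()
    asg <- assignPairsToAnchorPairs(lp, sim$anchors)
    p <- as.data.frame(pairSummary(lp))
    # exactly the long-range pairs are assigned, each to its true anchor
    expect_setequal(asg$pairIdx, which(p$pairClass == "CIS_LONG"))
    truthAnchor <- sub("_.*$", "", p$qname[asg$pairIdx])
    expect_equal(asg$anchorId, truthAnchor)
    # local pairs (both ends in one anchor) are never assigned
    expect_false(any(grepl("_l", p$qname[asg$pairIdx])))
})

test_that("BEDPE round trip preserves anchor coordinates", {
    sim <- sharedSim()
    path <- withr::local_tempfile(fileext = ".bedpe")
    writeBedpe(sim$anchors, path)
    back <- readBedpe(path)
    expect_equal(back, sim$anchors)
})
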