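## From aligned bisulfite-converted read pairs to per-read methylation
## calls and classified linked pairs.
##
## A read's conversion strand decides which reference cytosines it can
## report: OT (C->T converted, tag value "CT") reads report forward-strand
## cytosines (read C = methylated, read T = unmethylated); OB ("GA") reads
## report minus-strand cytosines, i.e. forward-strand Gs (read G =
## methylated, read A = unmethylated).

.PAIR_CLASSES <- c("CIS_LONG", "CIS_SHORT", "TRANS")

.phredFromQual <- function(qual) {
    ## vector of phred scores from a phred+33 string
    as.integer(charToRaw(qual)) - 33L
}

#' Call per-read methylation at indexed cytosine sites
#'
#' Computes methylation calls for aligned read ends given their
#' reference-space sequence. Only context sites on the strand matching the
#' read's conversion strand are callable; bases other than C/T (OT) or
#' G/A (OB) at a site are skipped, as are bases at or below the base
#' quality cutoff. GCG-context calls are retained in the output (flagged
#' by their label) but are excluded from GCH and HCG summaries downstream.
#'
#' @param reads A data.frame with one row per read end and columns
#'   `chrom`, `start` (1-based leftmost aligned position), `seq`
#'   (reference-space sequence, i.e. after projecting through the CIGAR),
#'   `qual` (phred+33, same length as `seq`), `conversion` (`"CT"` or
#'   `"GA"`).
#' @param index A [ContextIndex-class] built on the alignment reference.
#' @param minBaseQuality Minimum base quality; only calls with quality
#'   strictly greater are retained (default 5).
#' @return A data.frame with columns `readIdx`, `chrom`, `pos`, `strand`,
#'   `label`, `methylated`, `baseQuality`.
#' @export
callReadMethylation <- function(reads, index, minBaseQuality = 5) {
    stopifnot(is(index, "ContextIndex"))
    need <- c("chrom", "start", "seq", "qual", "conversion")
    miss <- setdiff(need, names(reads))
    if (length(miss))
        stop("reads is missing columns: ", paste(miss, collapse = ", "))
    if (!all(reads$conversion %in% c("CT", "GA")))
        stop("unknown conversion strand; expected 'CT' (OT) or 'GA' (OB)")
    if (nrow(reads) == 0L)
        return(data.frame(readIdx = integer(), chrom = character(),
                          pos = integer(), strand = character(),
                          label = character(), methylated = logical(),
                          baseQuality = integer()))
    width <- nchar(reads$seq)
    sites <- contextSites(index)
    lens <- GenomeInfoDb::seqlengths(sites)
    known <- reads$chrom %in% names(lens)
    if (any(known)) {
        over <- reads$start[known] + width[known] - 1L >
            lens[reads$chrom[known]]
        if (any(over | reads$start[known] < 1L))
            stop("read aligned beyond reference bounds")
    }
    win <- GenomicRanges::GRanges(
        reads$chrom,
        IRanges::IRanges(reads$start, width = width))
    hits <- GenomicRanges::findOverlaps(sites, win, ignore.strand = TRUE)
    si <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    ## strand must match the conversion strand of the read
    wantStrand <- ifelse(reads$conversion[ri] == "CT", "+", "-")
    keep <- as.character(GenomicRanges::strand(sites))[si] == wantStrand
    si <- si[keep]; ri <- ri[keep]
    off <- GenomicRanges::start(sites)[si] - reads$start[ri] + 1L
    base <- substr(reads$seq[ri], off, off)
    bq <- vapply(seq_along(ri), function(k)
        .phredFromQual(substr(reads$qual[ri[k]], off[k], off[k])),
        integer(1))
    isOT <- reads$conversion[ri] == "CT"
    meth <- rep(NA, length(ri))
    meth[isOT & base == "C"] <- TRUE
    meth[isOT & base == "T"] <- FALSE
    meth[!isOT & base == "G"] <- TRUE
    meth[!isOT & base == "A"] <- FALSE
    keep <- !is.na(meth) & bq > minBaseQuality
    data.frame(readIdx = ri[keep],
               chrom = as.character(GenomicRanges::seqnames(sites))[si[keep]],
               pos = GenomicRanges::start(sites)[si[keep]],
               strand = as.character(GenomicRanges::strand(sites))[si[keep]],
               label = as.character(contextLabels(index))[si[keep]],
               methylated = as.logical(meth[keep]),
               baseQuality = bq[keep])
}

#' Flag incompletely bisulfite-converted reads
#'
#' WCH cytosines (W = A/T, H = A/C/T) carry neither GpC footprint nor CpG
#' methylation signal and should be fully converted; a read showing
#' methylation at several WCH sites most likely escaped conversion and is
#' filtered.
#'
#' @param calls A data.frame of calls for one read
#'   (see [callReadMethylation()]).
#' @param maxMethylatedWch Reads with at least this many methylated WCH
#'   calls are flagged (default 3).
#' @return `TRUE` if the read should be filtered.
#' @export
isIncompletelyConverted <- function(calls, maxMethylatedWch = 3) {
    sum(calls$label == "WCH" & calls$methylated) >= maxMethylatedWch
}

.readAlignmentRecords <- function(input, convTag = "XG") {
    if (is.data.frame(input)) {
        need <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                  "seq", "qual", "conversion")
        miss <- setdiff(need, names(input))
        if (length(miss))
            stop("alignment data.frame is missing columns: ",
                 paste(miss, collapse = ", "))
        return(input)
    }
    path <- input
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "seq", "qual"),
        tag = convTag)
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    conv <- b$tag[[convTag]]
    if (is.null(conv)) conv <- rep(NA_character_, length(b$qname))
    data.frame(qname = b$qname, flag = b$flag,
               rname = as.character(b$rname), pos = b$pos, mapq = b$mapq,
               cigar = b$cigar, seq = as.character(b$seq),
               qual = as.character(b$qual), conversion = conv,
               stringsAsFactors = FALSE)
}

.layerToReference <- function(rec) {
    ## project read sequence and qualities into reference space so that
    ## offset i of the string sits at reference position pos + i - 1
    simple <- grepl("^[0-9]+M$", rec$cigar)
    if (all(simple)) return(rec)
    idx <- which(!simple)
    seqs <- GenomicAlignments::sequenceLayer(
        Biostrings::DNAStringSet(rec$seq[idx]), rec$cigar[idx],
        from = "query", to = "reference")
    quals <- GenomicAlignments::sequenceLayer(
        Biostrings::BStringSet(rec$qual[idx]), rec$cigar[idx],
        from = "query", to = "reference",
        D.letter = "!", N.letter = "!")
    rec$seq[idx] <- as.character(seqs)
    rec$qual[idx] <- as.character(quals)
    rec
}

#' Load, filter and classify linked bisulfite read pairs
#'
#' Reads name-grouped alignments (SAM/BAM, or an equivalent data.frame as
#' produced by [simulateLinkedReadPairs()]), applies the standard filters
#' -- both ends uniquely mapped with mapQ above the cutoff, not a PCR
#' duplicate, completely bisulfite converted -- joins mates by name,
#' computes per-read methylation calls and classifies each pair as
#' `CIS_LONG` (same chromosome, separation above `longRange`),
#' `CIS_SHORT` or `TRANS`. Separation is measured between the outermost
#' coordinates of the two ends (the molecule's insertion size).
#'
#' @param input Path to a SAM/BAM file, or a data.frame of alignment
#'   records (`qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`,
#'   `qual`, `conversion`).
#' @param index A [ContextIndex-class] on the alignment reference.
#' @param minMapq Minimum mapping quality, exclusive (default 30).
#' @param minBaseQuality Minimum base quality, exclusive (default 5).
#' @param dropDuplicates Drop pairs with the PCR-duplicate flag set.
#' @param conversionFilter Drop pairs with an incompletely converted end
#'   (see [isIncompletelyConverted()]).
#' @param maxMethylatedWch Methylated-WCH threshold for the conversion
#'   filter (default 3).
#' @param longRange Minimum separation (bp, exclusive) for `CIS_LONG`
#'   (default 20000).
#' @param convTag SAM tag holding the conversion strand (`CT`/`GA`),
#'   default `"XG"`. Records with a missing tag are inferred from their
#'   C/T vs G/A composition relative to the reference context index: a
#'   bisulfite read is depleted of C (OT) or of G (OB).
#' @return A [LinkedPairs-class] object.
#' @export
loadLinkedPairs <- function(input, index, minMapq = 30,
                            minBaseQuality = 5, dropDuplicates = TRUE,
                            conversionFilter = TRUE, maxMethylatedWch = 3,
                            longRange = 20000, convTag = "XG") {
    rec <- .readAlignmentRecords(input, convTag)
    stats <- list(nRecords = nrow(rec))
    ## unique primary mapped records only
    bad <- bitwAnd(rec$flag, 0x4L) > 0L |   # unmapped
           bitwAnd(rec$flag, 0x100L) > 0L | # secondary
           bitwAnd(rec$flag, 0x800L) > 0L   # supplementary
    rec <- rec[!bad, , drop = FALSE]
    if (any(is.na(rec$conversion)))
        rec$conversion[is.na(rec$conversion)] <-
            .inferConversionStrand(rec[is.na(rec$conversion), ], index)
    if (!all(rec$conversion %in% c("CT", "GA")))
        stop("unknown conversion strand value in tag; expected CT or GA")
    ## join mates by name
    cnt <- table(rec$qname)
    paired <- names(cnt)[cnt == 2L]
    stats$nUnmated <- sum(cnt != 2L)
    if (stats$nUnmated > 0L)
        message(stats$nUnmated, " unmated read name(s) skipped")
    rec <- rec[rec$qname %in% paired, , drop = FALSE]
    rec <- rec[order(rec$qname, bitwAnd(rec$flag, 0x80L) > 0L), ,
               drop = FALSE]
    i1 <- seq(1L, nrow(rec), by = 2L)
    i2 <- i1 + 1L
    ## pair-level filters
    dupFail <- dropDuplicates &
        (bitwAnd(rec$flag[i1], 0x400L) > 0L |
         bitwAnd(rec$flag[i2], 0x400L) > 0L)
    mapqFail <- rec$mapq[i1] <= minMapq | rec$mapq[i2] <= minMapq
    stats$nDupDropped <- sum(dupFail & !mapqFail)
    stats$nMapqDropped <- sum(mapqFail)
    keep <- !dupFail & !mapqFail
    i1 <- i1[keep]; i2 <- i2[keep]
    rec <- .layerToReference(rec)
    ends <- rec[c(rbind(i1, i2)), , drop = FALSE]
    ends$endNo <- rep(c(1L, 2L), length(i1))
    ends$pairIdx <- rep(seq_along(i1), each = 2L)
    calls <- callReadMethylation(
        data.frame(chrom = ends$rname, start = ends$pos, seq = ends$seq,
                   qual = ends$qual, conversion = ends$conversion,
                   stringsAsFactors = FALSE),
        index, minBaseQuality = minBaseQuality)
    calls$pairIdx <- ends$pairIdx[calls$readIdx]
    calls$end <- ends$endNo[calls$readIdx]
    ## conversion filter: drop the pair if either end looks unconverted
    methWch <- calls$label == "WCH" & calls$methylated
    wchCount <- tapply(methWch, calls$readIdx, sum)
    failEnd <- rep(FALSE, nrow(ends))
    failEnd[as.integer(names(wchCount))] <- wchCount >= maxMethylatedWch
    convFail <- tapply(failEnd, ends$pairIdx, any)
    stats$nConversionDropped <-
        if (conversionFilter) sum(convFail) else 0L
    keepPair <- if (conversionFilter) !convFail else
        rep(TRUE, length(convFail))
    ## summaries per pair/end
    sumCtx <- function(lab, endNo, what) {
        sel <- calls$label %in% lab & calls$end == endNo
        v <- tapply(if (what == "meth") calls$methylated[sel]
                    else rep(1L, sum(sel)), calls$pairIdx[sel], sum)
        out <- integer(length(i1))
        out[as.integer(names(v))] <- as.integer(v)
        out
    }
    pairs <- S4Vectors::DataFrame(
        qname = rec$qname[i1],
        chrom1 = rec$rname[i1], start1 = rec$pos[i1],
        end1 = rec$pos[i1] + nchar(rec$seq[i1]) - 1L,
        chrom2 = rec$rname[i2], start2 = rec$pos[i2],
        end2 = rec$pos[i2] + nchar(rec$seq[i2]) - 1L,
        conversion = rec$conversion[i1])
    for (ctx in list(c(lab = "GCH", col = "gch"),
                     c(lab = "WCG", col = "wcg"),
                     c(lab = "WCH", col = "wch"))) {
        for (e in 1:2) {
            pairs[[paste0(ctx[["col"]], "Meth", e)]] <-
                sumCtx(ctx[["lab"]], e, "meth")
            pairs[[paste0(ctx[["col"]], "Sites", e)]] <-
                sumCtx(ctx[["lab"]], e, "sites")
        }
    }
    for (e in 1:2) {   # HCG = WCG + CCG; GCG stays excluded
        pairs[[paste0("hcgMeth", e)]] <- sumCtx(c("WCG", "CCG"), e, "meth")
        pairs[[paste0("hcgSites", e)]] <- sumCtx(c("WCG", "CCG"), e,
                                                 "sites")
    }
    sameChrom <- pairs$chrom1 == pairs$chrom2
    sep <- ifelse(sameChrom,
                  pmax(pairs$end1, pairs$end2) -
                  pmin(pairs$start1, pairs$start2), NA_integer_)
    pairs$separation <- as.integer(sep)
    pairs$pairClass <- factor(
        ifelse(!sameChrom, "TRANS",
               ifelse(sep > longRange, "CIS_LONG", "CIS_SHORT")),
        levels = .PAIR_CLASSES)
    ## apply conversion filter last so tallies above refer to all pairs
    keepIdx <- which(keepPair)
    remap <- integer(length(i1)); remap[keepIdx] <- seq_along(keepIdx)
    pairs <- pairs[keepIdx, , drop = FALSE]
    calls <- calls[calls$pairIdx %in% keepIdx, , drop = FALSE]
    calls$pairIdx <- remap[calls$pairIdx]
    reads <- S4Vectors::DataFrame(
        pairIdx = remap[ends$pairIdx], end = ends$endNo,
        chrom = ends$rname, start = ends$pos,
        width = nchar(ends$seq), mapq = ends$mapq,
        conversion = ends$conversion, seq = ends$seq, qual = ends$qual)
    reads <- reads[reads$pairIdx > 0L, , drop = FALSE]
    stats$nPairsRetained <- nrow(pairs)
    new("LinkedPairs", pairs = pairs,
        calls = S4Vectors::DataFrame(
            calls[, c("pairIdx", "end", "chrom", "pos", "strand", "label",
                      "methylated", "baseQuality")]),
        reads = reads, stats = stats)
}

.inferConversionStrand <- function(rec, index) {
    ## a bisulfite-converted read is depleted of C (OT) or of G (OB)
    vapply(seq_len(nrow(rec)), function(i) {
        f <- Biostrings::alphabetFrequency(
            Biostrings::DNAString(rec$seq[i]))
        if (f[["C"]] <= f[["G"]]) "CT" else "GA"
    }, character(1))
}

#' Read chromatin loop anchors from BEDPE
#'
#' BEDPE coordinates are 0-based half-open and are converted to 1-based
#' closed intervals. For cis rows, anchor A is re-ordered to precede
#' anchor B.
#'
#' @param path Path to a BEDPE file (6+ columns, optional 7th name
#'   column).
#' @return A data.frame with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `id`.
#' @export
readBedpe <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stop("BEDPE requires at least 6 columns")
    out <- data.frame(chrom1 = df[[1]], start1 = df[[2]] + 1L,
                      end1 = df[[3]], chrom2 = df[[4]],
                      start2 = df[[5]] + 1L, end2 = df[[6]],
                      id = if (ncol(df) >= 7L) as.character(df[[7]])
                           else paste0("loop", seq_len(nrow(df))),
                      stringsAsFactors = FALSE)
    flip <- out$chrom1 == out$chrom2 & out$start1 > out$start2
    if (any(flip)) {
        tmp <- out[flip, c("start1", "end1")]
        out[flip, c("start1", "end1")] <- out[flip, c("start2", "end2")]
        out[flip, c("start2", "end2")] <- tmp
    }
    out
}

#' Write chromatin loop anchors to BEDPE
#'
#' @param anchors An anchor-pair data.frame (see [readBedpe()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedpe <- function(anchors, path) {
    df <- data.frame(anchors$chrom1, anchors$start1 - 1L, anchors$end1,
                     anchors$chrom2, anchors$start2 - 1L, anchors$end2,
                     anchors$id)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.anchorGRanges <- function(anchors, which = c("A", "B")) {
    which <- match.arg(which)
    if (which == "A")
        GenomicRanges::GRanges(anchors$chrom1,
            IRanges::IRanges(anchors$start1, anchors$end1))
    else
        GenomicRanges::GRanges(anchors$chrom2,
            IRanges::IRanges(anchors$start2, anchors$end2))
}

.endGRanges <- function(pairs, endNo) {
    GenomicRanges::GRanges(
        pairs[[paste0("chrom", endNo)]],
        IRanges::IRanges(pairs[[paste0("start", endNo)]],
                         pairs[[paste0("end", endNo)]]))
}

#' Assign long-range read pairs to anchor pairs
#'
#' A pair is assigned to a BEDPE row when one end overlaps anchor A and
#' the other overlaps anchor B (in either orientation) and the pair is
#' `CIS_LONG`. By default a pair matching several rows is assigned to
#' every matching row.
#'
#' @param x A [LinkedPairs-class] object.
#' @param anchors An anchor-pair data.frame (see [readBedpe()]).
#' @param firstMatchOnly Assign each pair only to its first matching row.
#' @return A data.frame with columns `anchorId` and `pairIdx` (row index
#'   into `pairSummary(x)`).
#' @export
assignPairsToAnchorPairs <- function(x, anchors, firstMatchOnly = FALSE) {
    stopifnot(is(x, "LinkedPairs"))
    pairs <- pairSummary(x)
    grA <- .anchorGRanges(anchors, "A")
    grB <- .anchorGRanges(anchors, "B")
    e1 <- .endGRanges(pairs, 1)
    e2 <- .endGRanges(pairs, 2)
    ovl <- function(ends, anch) {
        h <- GenomicRanges::findOverlaps(ends, anch)
        split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    }
    h1A <- ovl(e1, grA); h2B <- ovl(e2, grB)
    h1B <- ovl(e1, grB); h2A <- ovl(e2, grA)
    isLong <- pairs$pairClass == "CIS_LONG"
    res <- lapply(which(isLong), function(i) {
        k <- as.character(i)
        rows <- union(intersect(h1A[[k]], h2B[[k]]),
                      intersect(h1B[[k]], h2A[[k]]))
        if (length(rows))
            data.frame(anchorId = anchors$id[sort(rows)], pairIdx = i)
        else NULL
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(anchorId = character(), pairIdx = integer())
    if (firstMatchOnly && nrow(out))
        out <- out[!duplicated(out$pairIdx), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write the per-pair summary table
#'
#' TSV with one row per retained pair: coordinates of both ends
#' (0-based starts), pair class, separation and per-end GCH counts.
#'
#' @param x A [LinkedPairs-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePairTable <- function(x, path) {
    p <- as.data.frame(pairSummary(x))
    df <- data.frame(chrom1 = p$chrom1, start1 = p$start1 - 1L,
                     end1 = p$end1, chrom2 = p$chrom2,
                     start2 = p$start2 - 1L, end2 = p$end2,
                     class = p$pairClass, separation = p$separation,
                     GCH_meth1 = p$gchMeth1, GCH_total1 = p$gchSites1,
                     GCH_meth2 = p$gchMeth2, GCH_total2 = p$gchSites2)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write per-site methylation levels (bedGraph-compatible)
#'
#' Aggregates calls over reads per cytosine site and writes `chrom`,
#' `start` (0-based), `end`, `fraction`, `methylated`, `total`, `label`,
#' `strand`.
#'
#' @param x A [LinkedPairs-class] object.
#' @param path Output path.
#' @param labels Context labels to include (default GCH and HCG).
#' @return `path`, invisibly.
#' @export
writeSiteMethylation <- function(x, path, labels = c("GCH", "HCG")) {
    labels <- .expandLabelSet(labels)
    calls <- as.data.frame(methylCalls(x))
    calls <- calls[calls$label %in% labels, , drop = FALSE]
    key <- paste(calls$chrom, calls$pos, calls$strand, calls$label)
    agg <- data.frame(
        key = names(tapply(calls$methylated, key, sum)),
        meth = as.integer(tapply(calls$methylated, key, sum)),
        total = as.integer(tapply(calls$methylated, key, length)))
    parts <- do.call(rbind, strsplit(agg$key, " ", fixed = TRUE))
    df <- data.frame(chrom = parts[, 1],
                     start = as.integer(parts[, 2]) - 1L,
                     end = as.integer(parts[, 2]),
                     fraction = agg$meth / agg$total,
                     methylated = agg$meth, total = agg$total,
                     label = parts[, 4], strand = parts[, 3])
    df <- df[order(df$chrom, df$start, df$strand), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
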