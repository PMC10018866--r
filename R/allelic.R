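## Long-range allele-specific GCH footprint calling.
##
## Linked read pairs with one end overlapping a heterozygous SNP are
## split by allele; pooled GCH methylated/unmethylated counts by allele
## at the SNP-overlapping ends and at the distal mate ends (> 20 kb away)
## form two 2x2 tables per locus, tested with Fisher's exact test and
## BH-corrected. Loci significant at both anchors are GROUP1, only at
## the SNP anchor GROUP2 (distal FDR > 0.95), only at the distal anchor
## GROUP3 (SNP FDR > 0.95).

#' Assign a read end to a SNP allele
#'
#' Matches the read base at a heterozygous SNP to the reference or
#' alternative allele, returning `UNASSIGNABLE` where bisulfite chemistry
#' confounds the call: on OT (`CT`-converted) reads an unmethylated C
#' reads as T, so C/T SNPs cannot be resolved; on OB (`GA`) reads G/A
#' SNPs cannot. Bases matching neither allele and bases at or below the
#' quality cutoff are also unassignable.
#'
#' @param base Read base(s) at the SNP position (reference space).
#' @param baseQuality Phred quality of the base(s).
#' @param conversion Conversion strand of the read(s), `"CT"` or `"GA"`.
#' @param refAllele,altAllele The two alleles (single nucleotides).
#' @param minBaseQuality Quality cutoff, exclusive (default 5).
#' @return Character vector over `REF`, `ALT`, `UNASSIGNABLE`.
#' @export
assignAllele <- function(base, baseQuality, conversion, refAllele,
                         altAllele, minBaseQuality = 5) {
    n <- length(base)
    stopifnot(length(baseQuality) == n, length(conversion) == n)
    if (refAllele == altAllele)
        stop("ref and alt allele must differ")
    alleles <- sort(c(refAllele, altAllele))
    out <- rep("UNASSIGNABLE", n)
    confounded <- (conversion == "CT" &
                       identical(alleles, c("C", "T"))) |
                  (conversion == "GA" &
                       identical(alleles, c("A", "G")))
    ok <- !confounded & baseQuality > minBaseQuality
    out[ok & base == refAllele] <- "REF"
    out[ok & base == altAllele] <- "ALT"
    out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by summing the hypergeometric probabilities of all tables (at
#' the observed margins) no more probable than the observed one, with
#' the conventional `1 + 1e-7` tie tolerance. Vectorised over the
#' hypergeometric support, so cheap enough for exhaustive sweeps.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisherExact2x2 <- function(table) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L)))
        stop("table must be 2x2")
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    m <- sum(table[1, ])           # row-1 margin
    n <- sum(table[2, ])           # row-2 margin
    k <- sum(table[, 1])           # column-1 margin
    if (m + n == 0) return(1)
    supp <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(supp, m, n, k)
    pObs <- stats::dhyper(table[1, 1], m, n, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotone enforcement; input order is
#' preserved. Zero p-values are floored at the smallest representable
#' positive double first.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as `p`.
#' @export
bhFdr <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p <- pmax(p, .Machine$double.xmin)
    stats::p.adjust(p, method = "BH")
}

#' Read heterozygous SNPs from a VCF
#'
#' Keeps biallelic single-nucleotide records; multi-allelic, indel and
#' homozygous-by-GT records are dropped (a record without a GT field is
#' assumed heterozygous, as in a pre-filtered het list).
#'
#' @param path Path to a VCF file.
#' @return A data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @export
readHetSnps <- function(path) {
    v <- readVariantTable(path)
    keep <- v$ref %in% c("A", "C", "G", "T") &
            v$alt %in% c("A", "C", "G", "T") & v$biallelic &
            (is.na(v$genotype) | v$genotype %in% c("0/1", "1/0", "0|1",
                                                   "1|0"))
    data.frame(chrom = v$chrom[keep], pos = v$pos[keep],
               ref = v$ref[keep], alt = v$alt[keep],
               stringsAsFactors = FALSE)
}

#' Build per-SNP allelic 2x2 tables from linked pairs
#'
#' For every heterozygous SNP, read ends covering the SNP are assigned to
#' alleles; pairs whose mate end lies closer than `minDist` (or whose
#' ends lack GCH calls) are excluded. Loci with at least
#' `minCovPerAllele` assigned reads per allele are tested: pooled GCH
#' methylated/unmethylated counts by allele at the SNP-overlapping ends
#' form the SNP-anchor table, the same from the distal mate ends forms
#' the non-SNP-anchor table.
#'
#' @param x A [LinkedPairs-class] object.
#' @param snps Het SNP data.frame (see [readHetSnps()]).
#' @param minDist Minimum SNP-to-mate distance in bp (default 20000,
#'   exclusive); trans mates qualify.
#' @param minCovPerAllele Minimum assigned reads per allele (default 2).
#' @param minGchPerEnd Minimum GCH calls on each end (default 1; allelic
#'   mode keeps sparser reads than the concordance analysis).
#' @param minBaseQuality Base-quality cutoff for the allele-bearing base.
#' @param unit Fisher-table unit: `"calls"` pools GCH calls across reads
#'   (default; accepts the pseudo-replication of sites on one molecule),
#'   `"reads"` counts whole reads dichotomized at fraction 0.5.
#' @return A data.frame with one row per SNP: coordinates, alleles, read
#'   counts per allele, the two tables (as eight count columns `snpRefMeth`
#'   ... `nonAltUnmeth`), `pSnp`, `pNonsnp` and `tested`.
#' @export
buildAllelicTables <- function(x, snps, minDist = 20000,
                               minCovPerAllele = 2, minGchPerEnd = 1,
                               minBaseQuality = 5,
                               unit = c("calls", "reads")) {
    unit <- match.arg(unit)
    stopifnot(is(x, "LinkedPairs"))
    reads <- alignedEnds(x)
    p <- pairSummary(x)
    snpGr <- GenomicRanges::GRanges(snps$chrom,
                                    IRanges::IRanges(snps$pos, snps$pos))
    readGr <- GenomicRanges::GRanges(reads$chrom,
        IRanges::IRanges(reads$start, width = reads$width))
    h <- GenomicRanges::findOverlaps(snpGr, readGr)
    out <- lapply(seq_len(nrow(snps)), function(si) {
        ri <- S4Vectors::subjectHits(h)[S4Vectors::queryHits(h) == si]
        res <- list(chrom = snps$chrom[si], pos = snps$pos[si],
                    ref = snps$ref[si], alt = snps$alt[si],
                    nRefReads = 0L, nAltReads = 0L, tested = FALSE,
                    snpRefMeth = NA_integer_, snpRefUnmeth = NA_integer_,
                    snpAltMeth = NA_integer_, snpAltUnmeth = NA_integer_,
                    nonRefMeth = NA_integer_, nonRefUnmeth = NA_integer_,
                    nonAltMeth = NA_integer_, nonAltUnmeth = NA_integer_,
                    pSnp = NA_real_, pNonsnp = NA_real_)
        if (!length(ri)) return(res)
        pe <- reads[ri, , drop = FALSE]
        pidx <- pe$pairIdx
        snpEnd <- pe$end
        mateEnd <- 3L - snpEnd
        gchS <- cbind(p$gchSites1[pidx], p$gchSites2[pidx])
        okGch <- gchS[cbind(seq_along(pidx), snpEnd)] >= minGchPerEnd &
                 gchS[cbind(seq_along(pidx), mateEnd)] >= minGchPerEnd
        ## distal mate requirement: > minDist from the SNP, or trans
        mateChrom <- ifelse(mateEnd == 1L, p$chrom1[pidx], p$chrom2[pidx])
        mateStart <- ifelse(mateEnd == 1L, p$start1[pidx], p$start2[pidx])
        mateStop <- ifelse(mateEnd == 1L, p$end1[pidx], p$end2[pidx])
        gap <- pmin(abs(mateStart - snps$pos[si]),
                    abs(mateStop - snps$pos[si]))
        okDist <- mateChrom != snps$chrom[si] | gap > minDist
        keep <- okGch & okDist
        if (!any(keep)) return(res)
        pe <- pe[keep, , drop = FALSE]
        pidx <- pidx[keep]; snpEnd <- snpEnd[keep]
        mateEnd <- mateEnd[keep]
        off <- snps$pos[si] - pe$start + 1L
        base <- substr(pe$seq, off, off)
        bq <- vapply(seq_len(nrow(pe)), function(k)
            .phredFromQual(substr(pe$qual[k], off[k], off[k])),
            integer(1))
        allele <- assignAllele(base, bq, pe$conversion, snps$ref[si],
                               snps$alt[si],
                               minBaseQuality = minBaseQuality)
        use <- allele != "UNASSIGNABLE"
        res$nRefReads <- sum(allele == "REF")
        res$nAltReads <- sum(allele == "ALT")
        if (res$nRefReads < minCovPerAllele ||
            res$nAltReads < minCovPerAllele) return(res)
        counts <- function(endSel, alleleName) {
            sel <- use & allele == alleleName
            i <- pidx[sel]
            e <- endSel[sel]
            gm <- ifelse(e == 1L, p$gchMeth1[i], p$gchMeth2[i])
            gs <- ifelse(e == 1L, p$gchSites1[i], p$gchSites2[i])
            if (unit == "calls")
                c(meth = sum(gm), unmeth = sum(gs - gm))
            else {
                open <- gm / gs >= 0.5
                c(meth = sum(open), unmeth = sum(!open))
            }
        }
        sr <- counts(snpEnd, "REF"); sa <- counts(snpEnd, "ALT")
        nr <- counts(mateEnd, "REF"); na <- counts(mateEnd, "ALT")
        res[c("snpRefMeth", "snpRefUnmeth", "snpAltMeth",
              "snpAltUnmeth")] <- as.list(as.integer(c(sr, sa)))
        res[c("nonRefMeth", "nonRefUnmeth", "nonAltMeth",
              "nonAltUnmeth")] <- as.list(as.integer(c(nr, na)))
        res$pSnp <- fisherExact2x2(matrix(c(sr, sa), 2, byrow = TRUE))
        res$pNonsnp <- fisherExact2x2(matrix(c(nr, na), 2, byrow = TRUE))
        res$tested <- TRUE
        res
    })
    do.call(rbind, lapply(out, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Classify allele-specific loci into Groups 1/2/3
#'
#' Applies BH FDR correction across tested loci (separately per anchor
#' class by default) and labels each locus: `GROUP1` when significant at
#' both anchors (`fdr < fdrSig`), `GROUP2` when significant only at the
#' SNP anchor with a clearly null distal anchor (`fdrNonsnp > fdrNull`),
#' `GROUP3` for the reverse pattern, otherwise `NONE`.
#'
#' @param loci Data.frame from [buildAllelicTables()] (needs `pSnp`,
#'   `pNonsnp`, `tested`).
#' @param fdrSig Significance cutoff (default 0.05).
#' @param fdrNull Null cutoff for the insignificant anchor
#'   (default 0.95).
#' @param jointFdr Apply BH jointly over both anchors' p-values instead
#'   of separately per anchor class.
#' @return `loci` with `fdrSnp`, `fdrNonsnp` and `group` columns added;
#'   untested loci keep NA FDRs and group `NONE`.
#' @export
classifyAllelicGroups <- function(loci, fdrSig = 0.05, fdrNull = 0.95,
                                  jointFdr = FALSE) {
    loci$fdrSnp <- NA_real_
    loci$fdrNonsnp <- NA_real_
    t <- which(loci$tested)
    if (length(t)) {
        if (jointFdr) {
            adj <- bhFdr(c(loci$pSnp[t], loci$pNonsnp[t]))
            loci$fdrSnp[t] <- adj[seq_along(t)]
            loci$fdrNonsnp[t] <- adj[length(t) + seq_along(t)]
        } else {
            loci$fdrSnp[t] <- bhFdr(loci$pSnp[t])
            loci$fdrNonsnp[t] <- bhFdr(loci$pNonsnp[t])
        }
    }
    grp <- rep("NONE", nrow(loci))
    sigS <- !is.na(loci$fdrSnp) & loci$fdrSnp < fdrSig
    sigN <- !is.na(loci$fdrNonsnp) & loci$fdrNonsnp < fdrSig
    nulS <- !is.na(loci$fdrSnp) & loci$fdrSnp > fdrNull
    nulN <- !is.na(loci$fdrNonsnp) & loci$fdrNonsnp > fdrNull
    grp[sigS & sigN] <- "GROUP1"
    grp[sigS & nulN] <- "GROUP2"
    grp[sigN & nulS] <- "GROUP3"
    loci$group <- factor(grp, levels = c("GROUP1", "GROUP2", "GROUP3",
                                         "NONE"))
    loci
}

#' Long-range allele-specific footprint analysis
#'
#' Convenience wrapper: [buildAllelicTables()] followed by
#' [classifyAllelicGroups()].
#'
#' @inheritParams buildAllelicTables
#' @inheritParams classifyAllelicGroups
#' @return The classified locus table.
#' @export
runAllelicAnalysis <- function(x, snps, minDist = 20000,
                               minCovPerAllele = 2, minGchPerEnd = 1,
                               minBaseQuality = 5,
                               unit = c("calls", "reads"),
                               fdrSig = 0.05, fdrNull = 0.95,
                               jointFdr = FALSE) {
    loci <- buildAllelicTables(x, snps, minDist = minDist,
                               minCovPerAllele = minCovPerAllele,
                               minGchPerEnd = minGchPerEnd,
                               minBaseQuality = minBaseQuality,
                               unit = unit)
    classifyAllelicGroups(loci, fdrSig = fdrSig, fdrNull = fdrNull,
                          jointFdr = jointFdr)
}
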