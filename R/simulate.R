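## Synthetic bisulfite Hi-C data with known truth.
##
## The generative model: each DNA molecule spans two loop anchors; its
## two ends carry latent open/closed chromatin states drawn from a
## bivariate Bernoulli with marginal piOpen and correlation rhoLatent.
## GCH sites on an open end are methylated by the GpC methyltransferase
## with probability pOpen, on a closed end with pClosed; HCG sites carry
## endogenous methylation at endoHcgMeth. Bisulfite conversion turns
## unmethylated cytosines into T (OT molecules) or, equivalently on the
## opposite strand, G into A (OB molecules); conversion fails per site at
## rate conversionFailure, and whole molecules escape conversion with
## probability pFailedMolecule. Sequencing errors substitute bases
## uniformly at rate sequencingError. Reads are emitted pre-aligned (SAM
## or an equivalent data.frame) with the conversion strand in a tag.

#' Simulation configuration
#'
#' Collects and validates the generator parameters; identical
#' configuration and seed give byte-identical output.
#'
#' @param seed Integer seed driving every random choice.
#' @param genomeLength Reference length in bp.
#' @param gcFraction GC content of the i.i.d. reference, in (0, 1).
#' @param nAnchorPairs Number of loop-anchor pairs.
#' @param anchorSpan Anchor width in bp.
#' @param minAnchorSeparation Minimum gap between the two anchors of a
#'   pair in bp; the default 20001 keeps every anchor-pair read pair
#'   beyond the 20 kb long-range threshold.
#' @param nPairsPerAnchor Read pairs (molecules) per anchor pair.
#' @param readLength Read length in bp.
#' @param rhoLatent Correlation of the two ends' latent open states,
#'   in [-1, 1]; must be feasible for the bivariate Bernoulli given
#'   `piOpen`.
#' @param piOpen Marginal open probability.
#' @param pOpen,pClosed GCH methylation emission probability given an
#'   open / closed end; `pOpen > pClosed`.
#' @param endoHcgMeth Endogenous HCG methylation level.
#' @param conversionFailure Per-site bisulfite conversion failure rate.
#' @param sequencingError Per-base substitution error rate.
#' @param pFailedMolecule Probability a molecule escapes conversion
#'   entirely (detected downstream via methylated WCH).
#' @param nLocalPairsPerAnchor Short-range same-anchor pairs per anchor
#'   pair (local-control material); both ends share one latent state.
#' @param minGchPerRead Minimum GCH sites required in a read window;
#'   placements with fewer are resampled.
#' @param allelicPlan Optional data.frame (`group`, `nLoci`,
#'   `pOpenHigh`, `pOpenLow`, `pairsPerAllele`) for
#'   [simulateAllelicDataset()].
#' @return A validated configuration list of class `bslinkSimConfig`.
#' @export
simulationConfig <- function(seed = 1, genomeLength = 1e6,
                             gcFraction = 0.42, nAnchorPairs = 20,
                             anchorSpan = 1000,
                             minAnchorSeparation = 20001,
                             nPairsPerAnchor = 100, readLength = 150,
                             rhoLatent = 0.6, piOpen = 0.5, pOpen = 0.8,
                             pClosed = 0.2, endoHcgMeth = 0.75,
                             conversionFailure = 0.005,
                             sequencingError = 0.001,
                             pFailedMolecule = 0,
                             nLocalPairsPerAnchor = 0,
                             minGchPerRead = 3, allelicPlan = NULL) {
    if (gcFraction <= 0 || gcFraction >= 1)
        stop("gcFraction must lie in (0, 1)")
    if (pOpen <= pClosed)
        stop("pOpen must exceed pClosed")
    p11 <- piOpen^2 + rhoLatent * piOpen * (1 - piOpen)
    if (p11 < max(0, 2 * piOpen - 1) || p11 > piOpen)
        stop("rhoLatent ", rhoLatent, " infeasible for piOpen ", piOpen)
    cfg <- list(seed = as.integer(seed), genomeLength = genomeLength,
                gcFraction = gcFraction, nAnchorPairs = nAnchorPairs,
                anchorSpan = anchorSpan,
                minAnchorSeparation = minAnchorSeparation,
                nPairsPerAnchor = nPairsPerAnchor,
                readLength = readLength, rhoLatent = rhoLatent,
                piOpen = piOpen, pOpen = pOpen, pClosed = pClosed,
                endoHcgMeth = endoHcgMeth,
                conversionFailure = conversionFailure,
                sequencingError = sequencingError,
                pFailedMolecule = pFailedMolecule,
                nLocalPairsPerAnchor = nLocalPairsPerAnchor,
                minGchPerRead = minGchPerRead, p11 = p11,
                allelicPlan = allelicPlan)
    class(cfg) <- "bslinkSimConfig"
    cfg
}

#' Simulate an i.i.d. reference sequence
#'
#' Bases are drawn independently with `P(G) = P(C) = gcFraction / 2`.
#'
#' @param length Sequence length in bp.
#' @param gcFraction GC content in (0, 1).
#' @param seed Integer seed.
#' @param name Chromosome name (default `"chrSim"`).
#' @return A named [Biostrings::DNAStringSet] with one sequence.
#' @export
simulateReference <- function(length, gcFraction = 0.42, seed = 1,
                              name = "chrSim") {
    if (length <= 0) stop("length must be positive")
    if (gcFraction <= 0 || gcFraction >= 1)
        stop("gcFraction must lie in (0, 1)")
    .withSeed(seed, {
        bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                        prob = c((1 - gcFraction) / 2, gcFraction / 2,
                                 gcFraction / 2, (1 - gcFraction) / 2))
        out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
        names(out) <- name
        out
    })
}

#' Simulate non-overlapping loop-anchor pairs
#'
#' Packs `n` anchor pairs into the genome, one pair per equal slot with
#' seeded jitter; the two anchors of a pair are separated by more than
#' `minSeparation` bp and no intervals overlap.
#'
#' @param genome A [Biostrings::DNAStringSet] (first sequence is used).
#' @param n Number of anchor pairs.
#' @param span Anchor width in bp.
#' @param minSeparation Minimum gap between paired anchors in bp.
#' @param seed Integer seed.
#' @return An anchor-pair data.frame as from [readBedpe()] (1-based
#'   closed coordinates, `id` column).
#' @export
simulateAnchorPairs <- function(genome, n, span = 1000,
                                minSeparation = 20001, seed = 1) {
    chrom <- names(genome)[1]
    L <- Biostrings::width(genome)[1]
    need <- 2 * span + minSeparation + 2
    slot <- L %/% n
    if (slot < need)
        stop("infeasible packing: ", n, " anchor pairs of span ", span,
             " with separation ", minSeparation, " need ", need * n,
             " bp, genome has ", L)
    .withSeed(seed, {
        jitter <- vapply(seq_len(n), function(i)
            sample.int(slot - need + 1L, 1L), integer(1))
        startA <- (seq_len(n) - 1L) * slot + jitter
        startB <- startA + span + minSeparation + 1L
        data.frame(chrom1 = chrom, start1 = startA,
                   end1 = startA + span - 1L, chrom2 = chrom,
                   start2 = startB, end2 = startB + span - 1L,
                   id = paste0("sim", seq_len(n)),
                   stringsAsFactors = FALSE)
    })
}

## per-chromosome emission tables: character vector plus sorted cytosine
## site positions and labels for each conversion strand
.emissionTables <- function(genome, index) {
    sites <- contextSites(index)
    lapply(stats::setNames(names(genome), names(genome)), function(ch) {
        sel <- as.character(GenomicRanges::seqnames(sites)) == ch
        std <- as.character(GenomicRanges::strand(sites))[sel]
        pos <- GenomicRanges::start(sites)[sel]
        lab <- as.character(contextLabels(index))[sel]
        fwd <- std == "+"
        list(chars = strsplit(as.character(genome[[ch]]), "",
                              fixed = TRUE)[[1]],
             posC = as.double(pos[fwd]), labC = lab[fwd],
             posG = as.double(pos[!fwd]), labG = lab[!fwd])
    })
}

## restrict a chromosome emission table to one anchor's footprint so the
## per-read binary searches operate on short vectors
.sliceSites <- function(tbl, lo, hi) {
    iC <- findInterval(c(lo - 1, hi), tbl$posC)
    iG <- findInterval(c(lo - 1, hi), tbl$posG)
    list(chars = tbl$chars,
         posC = tbl$posC[seq_len(iC[2] - iC[1]) + iC[1]],
         labC = tbl$labC[seq_len(iC[2] - iC[1]) + iC[1]],
         posG = tbl$posG[seq_len(iG[2] - iG[1]) + iG[1]],
         labG = tbl$labG[seq_len(iG[2] - iG[1]) + iG[1]])
}

## methylation state for site labels given the end's latent state
.drawMethylation <- function(labels, open, cfg) {
    p <- numeric(length(labels))
    p[labels == "GCH"] <- if (open) cfg$pOpen else cfg$pClosed
    p[labels %in% c("WCG", "CCG", "GCG")] <- cfg$endoHcgMeth
    stats::runif(length(labels)) < p
}

## emit one aligned read end (reference space, pure-match CIGAR)
.emitRead <- function(tbl, start, conv, open, cfg, failedMol = FALSE,
                      alleleBase = NULL, allelePos = NULL) {
    stop_ <- start + cfg$readLength - 1L
    chars <- tbl$chars[start:stop_]
    if (conv == "CT") {
        pos <- tbl$posC; lab <- tbl$labC
        methChar <- "C"; unmethChar <- "T"
    } else {
        pos <- tbl$posG; lab <- tbl$labG
        methChar <- "G"; unmethChar <- "A"
    }
    lo <- findInterval(start - 1L, pos) + 1L
    hi <- findInterval(stop_, pos)
    if (hi >= lo) {
        sIdx <- lo:hi
        meth <- .drawMethylation(lab[sIdx], open, cfg)
        fail <- failedMol |
            stats::runif(length(sIdx)) < cfg$conversionFailure
        out <- ifelse(meth | fail, methChar, unmethChar)
        chars[pos[sIdx] - start + 1L] <- out
    }
    if (cfg$sequencingError > 0) {
        err <- which(stats::runif(length(chars)) < cfg$sequencingError)
        if (length(err))
            chars[err] <- vapply(chars[err], function(b)
                sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1))
    }
    if (!is.null(alleleBase)) {
        off <- allelePos - start + 1L
        if (off >= 1L && off <= length(chars)) chars[off] <- alleleBase
    }
    paste(chars, collapse = "")
}

## choose a read start inside [lo, hi] with at least minGch GCH sites on
## the conversion strand, resampling placement when short
.placeRead <- function(tbl, lo, hi, conv, cfg, tries = 25L) {
    pos <- if (conv == "CT") tbl$posC else tbl$posG
    lab <- if (conv == "CT") tbl$labC else tbl$labG
    for (t in seq_len(tries)) {
        s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        i1 <- findInterval(s - 1L, pos) + 1L
        i2 <- findInterval(s + cfg$readLength - 1L, pos)
        if (i2 >= i1 && sum(lab[i1:i2] == "GCH") >= cfg$minGchPerRead)
            return(s)
    }
    warning("read window with >= ", cfg$minGchPerRead,
            " GCH sites not found after ", tries,
            " placements; keeping last")
    s
}

## pre-allocated column vectors for emitted alignment records; filled
## element-wise (row-wise data.frame assignment is quadratic)
.recAccumulator <- function(n) {
    list(qname = character(n), flag = integer(n), rname = character(n),
         pos = integer(n), mapq = integer(n), cigar = character(n),
         seq = character(n), qual = character(n),
         conversion = character(n))
}

.recToFrame <- function(acc) {
    data.frame(acc, stringsAsFactors = FALSE)
}

#' Simulate linked bisulfite read pairs at loop anchors
#'
#' Draws `nPairsPerAnchor` molecules per anchor pair, each with
#' correlated latent open states at its two ends (see
#' [simulationConfig()]), and emits aligned read records plus the truth
#' tables needed to verify every downstream stage. When
#' `nLocalPairsPerAnchor > 0`, additional short-range pairs with both
#' ends in one anchor (sharing a single latent state) are emitted as
#' local-control material.
#'
#' @param config A [simulationConfig()] list.
#' @param genome,anchors,index Optional pre-built reference, anchor
#'   pairs and context index; generated from `config` when NULL.
#' @return A list with `records` (alignment data.frame accepted by
#'   [loadLinkedPairs()]), `truth` (per-molecule latent states), plus
#'   the `genome`, `anchors`, `index` and `config` used.
#' @export
simulateLinkedReadPairs <- function(config, genome = NULL,
                                    anchors = NULL, index = NULL) {
    stopifnot(inherits(config, "bslinkSimConfig"))
    if (is.null(genome))
        genome <- simulateReference(config$genomeLength,
                                    config$gcFraction, config$seed)
    if (is.null(anchors))
        anchors <- simulateAnchorPairs(genome, config$nAnchorPairs,
                                       config$anchorSpan,
                                       config$minAnchorSeparation,
                                       config$seed + 1L)
    if (is.null(index)) index <- buildContextIndex(genome)
    tbls <- .emissionTables(genome, index)
    .withSeed(config$seed + 2L, {
        nMol <- nrow(anchors) * config$nPairsPerAnchor
        nLoc <- nrow(anchors) * config$nLocalPairsPerAnchor
        nTot <- nMol + nLoc
        rec <- .recAccumulator(2L * nTot)
        tMolecule <- character(nTot); tAnchor <- character(nTot)
        tKind <- character(nTot); tS1 <- integer(nTot)
        tS2 <- integer(nTot); tConv <- character(nTot)
        tFailed <- logical(nTot)
        qualStr <- strrep("H", config$readLength)
        cigarStr <- paste0(config$readLength, "M")
        k <- 0L
        pOpenGiven1 <- if (config$piOpen > 0)
            config$p11 / config$piOpen else 0
        pOpenGiven0 <- if (config$piOpen < 1)
            (config$piOpen - config$p11) / (1 - config$piOpen) else 0
        putEnd <- function(i, qn, flag, chrom, p, seq, conv) {
            rec$qname[i] <<- qn; rec$flag[i] <<- flag
            rec$rname[i] <<- chrom; rec$pos[i] <<- p
            rec$mapq[i] <<- 60L; rec$cigar[i] <<- cigarStr
            rec$seq[i] <<- seq; rec$qual[i] <<- qualStr
            rec$conversion[i] <<- conv
        }
        for (a in seq_len(nrow(anchors))) {
            tbl <- tbls[[anchors$chrom1[a]]]
            loA <- anchors$start1[a]
            hiA <- anchors$end1[a] - config$readLength + 1L
            loB <- anchors$start2[a]
            hiB <- anchors$end2[a] - config$readLength + 1L
            if (hiA < loA || hiB < loB)
                stop("anchor span shorter than read length")
            tblA <- .sliceSites(tbl, loA, anchors$end1[a])
            tblB <- .sliceSites(tbl, loB, anchors$end2[a])
            for (j in seq_len(config$nPairsPerAnchor)) {
                k <- k + 1L
                qn <- paste0(anchors$id[a], "_m", j)
                conv <- sample(c("CT", "GA"), 1L)
                s1 <- stats::rbinom(1L, 1L, config$piOpen)
                s2 <- stats::rbinom(1L, 1L,
                    if (s1 == 1L) pOpenGiven1 else pOpenGiven0)
                failed <- stats::runif(1) < config$pFailedMolecule
                p1 <- .placeRead(tblA, loA, hiA, conv, config)
                p2 <- .placeRead(tblB, loB, hiB, conv, config)
                i <- 2L * k - 1L
                putEnd(i, qn, 65L, anchors$chrom1[a], p1,
                       .emitRead(tblA, p1, conv, s1 == 1L, config,
                                 failed), conv)
                putEnd(i + 1L, qn, 129L, anchors$chrom2[a], p2,
                       .emitRead(tblB, p2, conv, s2 == 1L, config,
                                 failed), conv)
                tMolecule[k] <- qn; tAnchor[k] <- anchors$id[a]
                tKind[k] <- "long"; tS1[k] <- s1; tS2[k] <- s2
                tConv[k] <- conv; tFailed[k] <- failed
            }
            for (j in seq_len(config$nLocalPairsPerAnchor)) {
                k <- k + 1L
                qn <- paste0(anchors$id[a], "_l", j)
                conv <- sample(c("CT", "GA"), 1L)
                s <- stats::rbinom(1L, 1L, config$piOpen)
                failed <- stats::runif(1) < config$pFailedMolecule
                useB <- j %% 2L == 0L
                lo <- if (useB) loB else loA
                hi <- if (useB) hiB else hiA
                tblL <- if (useB) tblB else tblA
                p1 <- .placeRead(tblL, lo, hi, conv, config)
                p2 <- .placeRead(tblL, lo, hi, conv, config)
                i <- 2L * k - 1L
                putEnd(i, qn, 65L, anchors$chrom1[a], p1,
                       .emitRead(tblL, p1, conv, s == 1L, config,
                                 failed), conv)
                putEnd(i + 1L, qn, 129L, anchors$chrom1[a], p2,
                       .emitRead(tblL, p2, conv, s == 1L, config,
                                 failed), conv)
                tMolecule[k] <- qn; tAnchor[k] <- anchors$id[a]
                tKind[k] <- "local"; tS1[k] <- s; tS2[k] <- s
                tConv[k] <- conv; tFailed[k] <- failed
            }
        }
        truth <- data.frame(molecule = tMolecule, anchorId = tAnchor,
                            kind = tKind, S1 = tS1, S2 = tS2,
                            conversion = tConv,
                            failedConversion = tFailed,
                            stringsAsFactors = FALSE)
        list(records = .recToFrame(rec), truth = truth, genome = genome,
             anchors = anchors, index = index, config = config)
    })
}

#' Simulate a dataset with planted allele-specific footprint loci
#'
#' Builds a reference, one anchor pair per planted locus, and a
#' heterozygous A/T SNP (assignable on both conversion strands) at the
#' centre of each SNP anchor. Reads of the two alleles draw their latent
#' open states from allele-dependent open probabilities at the affected
#' anchors (`pOpenHigh` for REF vs `pOpenLow` for ALT) and from the
#' shared background `piOpen` elsewhere: `GROUP1` loci are affected at
#' both anchors, `GROUP2` only at the SNP anchor, `GROUP3` only at the
#' distal anchor, `NONE` at neither. End 1 of every pair covers the SNP.
#'
#' @param config A [simulationConfig()] with a non-NULL `allelicPlan`
#'   (data.frame with columns `group`, `nLoci` and optionally
#'   `pOpenHigh`, `pOpenLow`, `pairsPerAllele`; defaults 0.9, 0.1, 50).
#' @return A list with `records`, `snps` (het SNP table), `truth`
#'   (per-locus group labels and per-molecule states), `genome`,
#'   `anchors`, `index`, `config`.
#' @export
simulateAllelicDataset <- function(config) {
    stopifnot(inherits(config, "bslinkSimConfig"))
    plan <- config$allelicPlan
    if (is.null(plan) || !nrow(plan))
        stop("config$allelicPlan is required")
    if (is.null(plan$pOpenHigh)) plan$pOpenHigh <- 0.9
    if (is.null(plan$pOpenLow)) plan$pOpenLow <- 0.1
    if (is.null(plan$pairsPerAllele)) plan$pairsPerAllele <- 50
    nLoci <- sum(plan$nLoci)
    if (nLoci > config$nAnchorPairs)
        stop("requested ", nLoci, " loci exceed ", config$nAnchorPairs,
             " available anchor pairs")
    genome <- simulateReference(config$genomeLength, config$gcFraction,
                                config$seed)
    anchors <- simulateAnchorPairs(genome, config$nAnchorPairs,
                                   config$anchorSpan,
                                   config$minAnchorSeparation,
                                   config$seed + 1L)
    anchors <- anchors[seq_len(nLoci), , drop = FALSE]
    ## plant the REF allele base at each SNP position, then index
    snpPos <- (anchors$start1 + anchors$end1) %/% 2L
    chars <- strsplit(as.character(genome[[1]]), "", fixed = TRUE)[[1]]
    chars[snpPos] <- "A"
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- anchors$chrom1[1]
    index <- buildContextIndex(genome)
    tbls <- .emissionTables(genome, index)
    snps <- data.frame(chrom = anchors$chrom1, pos = snpPos, ref = "A",
                       alt = "T", stringsAsFactors = FALSE)
    group <- rep(as.character(plan$group), plan$nLoci)
    pHigh <- rep(plan$pOpenHigh, plan$nLoci)
    pLow <- rep(plan$pOpenLow, plan$nLoci)
    nPer <- rep(plan$pairsPerAllele, plan$nLoci)
    .withSeed(config$seed + 2L, {
        nMol <- sum(2L * nPer)
        rec <- .recAccumulator(2L * nMol)
        qualStr <- strrep("H", config$readLength)
        cigarStr <- paste0(config$readLength, "M")
        putEnd <- function(i, qn, flag, chrom, p, seq, conv) {
            rec$qname[i] <<- qn; rec$flag[i] <<- flag
            rec$rname[i] <<- chrom; rec$pos[i] <<- p
            rec$mapq[i] <<- 60L; rec$cigar[i] <<- cigarStr
            rec$seq[i] <<- seq; rec$qual[i] <<- qualStr
            rec$conversion[i] <<- conv
        }
        mols <- vector("list", nLoci)
        k <- 0L
        for (a in seq_len(nLoci)) {
            tbl <- tbls[[anchors$chrom1[a]]]
            affectedA <- group[a] %in% c("GROUP1", "GROUP2")
            affectedB <- group[a] %in% c("GROUP1", "GROUP3")
            loA <- max(anchors$start1[a],
                       snpPos[a] - config$readLength + 2L)
            hiA <- min(anchors$end1[a] - config$readLength + 1L,
                       snpPos[a] - 1L)
            loB <- anchors$start2[a]
            hiB <- anchors$end2[a] - config$readLength + 1L
            tblA <- .sliceSites(tbl, loA, anchors$end1[a])
            tblB <- .sliceSites(tbl, loB, anchors$end2[a])
            loc <- data.frame(
                molecule = character(2L * nPer[a]),
                locus = anchors$id[a],
                allele = rep(c("REF", "ALT"), each = nPer[a]),
                S1 = integer(2L * nPer[a]), S2 = integer(2L * nPer[a]),
                stringsAsFactors = FALSE)
            for (j in seq_len(2L * nPer[a])) {
                k <- k + 1L
                allele <- loc$allele[j]
                qn <- paste0(anchors$id[a], "_", allele, j)
                conv <- sample(c("CT", "GA"), 1L)
                pA <- if (affectedA) {
                    if (allele == "REF") pHigh[a] else pLow[a]
                } else config$piOpen
                pB <- if (affectedB) {
                    if (allele == "REF") pHigh[a] else pLow[a]
                } else config$piOpen
                s1 <- stats::rbinom(1L, 1L, pA)
                s2 <- stats::rbinom(1L, 1L, pB)
                base <- if (allele == "REF") "A" else "T"
                p1 <- loA + sample.int(hiA - loA + 1L, 1L) - 1L
                p2 <- .placeRead(tblB, loB, hiB, conv, config)
                i <- 2L * k - 1L
                putEnd(i, qn, 65L, anchors$chrom1[a], p1,
                       .emitRead(tblA, p1, conv, s1 == 1L, config,
                                 alleleBase = base,
                                 allelePos = snpPos[a]), conv)
                putEnd(i + 1L, qn, 129L, anchors$chrom2[a], p2,
                       .emitRead(tblB, p2, conv, s2 == 1L, config),
                       conv)
                loc$molecule[j] <- qn
                loc$S1[j] <- s1; loc$S2[j] <- s2
            }
            mols[[a]] <- loc
        }
        truth <- list(
            loci = data.frame(locus = anchors$id, chrom = snps$chrom,
                              pos = snps$pos, ref = snps$ref,
                              alt = snps$alt, group = group,
                              stringsAsFactors = FALSE),
            molecules = do.call(rbind, mols))
        list(records = .recToFrame(rec), snps = snps, truth = truth,
             genome = genome, anchors = anchors, index = index,
             config = config)
    })
}

#' Counts-level simulation of allelic loci
#'
#' Draws the pooled 2x2 GCH tables of allelic loci directly from the
#' latent-state model, skipping sequence emission -- the fast path for
#' calibration experiments with many loci. Each read contributes
#' `gchPerEnd` GCH calls; its end is open with the allele- and
#' anchor-specific probability and methylated per site at
#' `pOpen`/`pClosed`.
#'
#' @param nLoci Number of loci.
#' @param pairsPerAllele Read pairs per allele per locus.
#' @param gchPerEnd GCH calls per read end.
#' @param openSnpRef,openSnpAlt Open probabilities at the SNP anchor for
#'   the two alleles.
#' @param openNonRef,openNonAlt Same for the distal anchor.
#' @param pOpen,pClosed Per-site methylation emission probabilities.
#' @param seed Integer seed.
#' @return A data.frame compatible with [classifyAllelicGroups()]:
#'   count columns, `pSnp`, `pNonsnp`, `tested`.
#' @export
simulateAllelicCounts <- function(nLoci, pairsPerAllele = 20,
                                  gchPerEnd = 5, openSnpRef = 0.5,
                                  openSnpAlt = 0.5, openNonRef = 0.5,
                                  openNonAlt = 0.5, pOpen = 0.8,
                                  pClosed = 0.2, seed = 1) {
    .withSeed(seed, {
        cell <- function(openP) {
            open <- stats::rbinom(nLoci * pairsPerAllele, 1L, openP)
            meth <- stats::rbinom(length(open), gchPerEnd,
                                  ifelse(open == 1L, pOpen, pClosed))
            grp <- rep(seq_len(nLoci), each = pairsPerAllele)
            m <- tapply(meth, grp, sum)
            tot <- pairsPerAllele * gchPerEnd
            cbind(meth = as.integer(m), unmeth = tot - as.integer(m))
        }
        sr <- cell(openSnpRef); sa <- cell(openSnpAlt)
        nr <- cell(openNonRef); na <- cell(openNonAlt)
        p2 <- function(r1, r2) vapply(seq_len(nLoci), function(i)
            fisherExact2x2(rbind(r1[i, ], r2[i, ])), numeric(1))
        data.frame(locus = paste0("locus", seq_len(nLoci)),
                   snpRefMeth = sr[, 1], snpRefUnmeth = sr[, 2],
                   snpAltMeth = sa[, 1], snpAltUnmeth = sa[, 2],
                   nonRefMeth = nr[, 1], nonRefUnmeth = nr[, 2],
                   nonAltMeth = na[, 1], nonAltUnmeth = na[, 2],
                   pSnp = p2(sr, sa), pNonsnp = p2(nr, na),
                   tested = TRUE, stringsAsFactors = FALSE)
    })
}

#' Crafted variant table exercising each post-filter rule once
#'
#' Twelve records on one chromosome: one failing each quality rule
#' (LowGQ, HighDepth, StrandBias, HighMQ0, LowGQbyDepth, one SNPCluster
#' pair) and five clean PASS records, with the expected FILTER values.
#'
#' @param seed Integer seed (drives only the allele choices).
#' @return A list with `records` (variant table, see
#'   [readVariantTable()]) and `expected` (character vector of FILTER
#'   values).
#' @export
simulateVariantTable <- function(seed = 1) {
    .withSeed(seed, {
        n <- 12L
        tv <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                   c("A", "C"), c("G", "T"))
        al <- tv[sample.int(length(tv), n, replace = TRUE)]
        rec <- data.frame(
            chrom = "chr1",
            pos = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L, 7000L,
                    7005L, 9000L, 10000L, 11000L, 12000L),
            id = paste0("rs", seq_len(n)),
            ref = vapply(al, `[`, character(1), 1L),
            alt = vapply(al, `[`, character(1), 2L),
            biallelic = TRUE,
            genotype = "0/1",
            GQ = c(60, 20, 350, 60, 60, 30, 60, 60, 60, 60, 60, 60),
            DP = c(45, 15, 300, 45, 50, 40, 45, 45, 45, 45, 45, 45),
            SB = c(-0.5, -0.5, -0.5, -0.01, -0.5, -0.5, -0.5, -0.5,
                   -0.5, -0.5, -0.5, -0.5),
            MQ0F = c(0, 0, 0, 0, 0.2, 0, 0, 0, 0, 0, 0, 0),
            MAF = NA_real_, R2 = NA_real_, filter = ".",
            stringsAsFactors = FALSE)
        expected <- c("PASS", "LowGQ", "HighDepth", "StrandBias",
                      "HighMQ0", "LowGQbyDepth", "SNPCluster",
                      "SNPCluster", "PASS", "PASS", "PASS", "PASS")
        list(records = rec, expected = expected)
    })
}

#' Write alignment records as SAM
#'
#' Emits a valid headered SAM file (unsorted, pure-match CIGARs, the
#' conversion strand in the `XG` tag) readable by [loadLinkedPairs()]
#' and standard tools.
#'
#' @param records Alignment data.frame from the simulator.
#' @param genome The reference [Biostrings::DNAStringSet] (for `@SQ`
#'   lines).
#' @param path Output path (should end in `.sam`).
#' @return `path`, invisibly.
#' @export
writeSamFile <- function(records, genome, path) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", names(genome), "\tLN:",
                    Biostrings::width(genome)))
    ## locate each record's mate by name to fill RNEXT/PNEXT
    first <- bitwAnd(records$flag, 0x40L) > 0L
    mateKey <- paste(records$qname, !first)
    mate <- match(mateKey, paste(records$qname, first))
    rnext <- ifelse(is.na(mate), "*",
                    ifelse(records$rname[mate] == records$rname, "=",
                           records$rname[mate]))
    pnext <- ifelse(is.na(mate), 0L, records$pos[mate])
    body <- paste(records$qname, records$flag, records$rname,
                  records$pos, records$mapq, records$cigar, rnext,
                  pnext, 0L, records$seq, records$qual,
                  paste0("XG:Z:", records$conversion), sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Write a het SNP table as a minimal VCF
#'
#' @param snps Data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHetVcf <- function(snps, path) {
    rec <- data.frame(chrom = snps$chrom, pos = snps$pos,
                      id = ".", ref = snps$ref, alt = snps$alt,
                      biallelic = TRUE, genotype = "0/1", GQ = 99,
                      DP = NA_real_, SB = NA_real_, MQ0F = NA_real_,
                      MAF = NA_real_, R2 = NA_real_, filter = "PASS",
                      stringsAsFactors = FALSE)
    writeVariantVcf(rec, path)
}

#' Write a full simulation bundle to a directory
#'
#' Writes `reference.fa`, `anchors.bedpe`, `reads.sam`, truth TSVs and,
#' for allelic bundles, `hets.vcf`.
#'
#' @param bundle A list from [simulateLinkedReadPairs()] or
#'   [simulateAllelicDataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(bundle, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(bundle$genome,
                                file.path(dir, "reference.fa"))
    writeBedpe(bundle$anchors, file.path(dir, "anchors.bedpe"))
    writeSamFile(bundle$records, bundle$genome,
                 file.path(dir, "reads.sam"))
    tsv <- function(df, name) utils::write.table(df,
        file.path(dir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(bundle$snps)) {
        writeHetVcf(bundle$snps, file.path(dir, "hets.vcf"))
        tsv(bundle$truth$loci, "truth_loci.tsv")
        tsv(bundle$truth$molecules, "truth_molecules.tsv")
    } else {
        tsv(bundle$truth, "truth_molecules.tsv")
    }
    invisible(dir)
}
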