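#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ContextIndex: strand-aware cytosine context index of a genome
#'
#' One entry per cytosine per strand. A forward-strand G harbours a
#' minus-strand cytosine and is reported at the forward coordinate of the G
#' with strand `-` (pileup convention). Labels partition cytosines into
#' GCG, GCH, WCG, CCG, WCH, CCH and UNCLASSIFIED (N-flanked or chromosome
#' edge).
#'
#' @slot sites A [GenomicRanges::GRanges] of width-1 ranges with a `label`
#'   metadata column (factor) and seqlengths set from the source genome.
#'
#' @seealso [buildContextIndex()], [contextDensity()]
#' @export
setClass("ContextIndex", representation(sites = "GRanges"))

setValidity("ContextIndex", function(object) {
    msg <- character()
    if (!"label" %in% names(S4Vectors::mcols(object@sites)))
        msg <- c(msg, "'sites' must carry a 'label' metadata column")
    if (any(GenomicRanges::width(object@sites) != 1))
        msg <- c(msg, "all context sites must have width 1")
    if (length(msg)) msg else TRUE
})

#' LinkedPairs: filtered bisulfite Hi-C read pairs with methylation calls
#'
#' Container for read pairs that passed mapping-quality, duplicate and
#' bisulfite-conversion filters, together with their per-site methylation
#' calls and the aligned (reference-space) read sequences needed for
#' allele assignment at SNPs.
#'
#' @slot pairs A [S4Vectors::DataFrame] with one row per retained pair:
#'   coordinates of both ends, conversion strand, pair class
#'   (`CIS_LONG`/`CIS_SHORT`/`TRANS`), separation, and per-end
#'   methylated/total counts for GCH, WCG, HCG and WCH contexts.
#' @slot calls A [S4Vectors::DataFrame] with one row per retained
#'   methylation call (pair row index, end 1/2, position, strand, label,
#'   methylated, base quality).
#' @slot reads A [S4Vectors::DataFrame] with one row per retained end
#'   holding the reference-space sequence and quality strings.
#' @slot stats Named list of filtering tallies (input records, dropped by
#'   each filter, unmated reads).
#'
#' @seealso [loadLinkedPairs()]
#' @export
setClass("LinkedPairs",
    representation(pairs = "DataFrame", calls = "DataFrame",
                   reads = "DataFrame", stats = "list"))

setValidity("LinkedPairs", function(object) {
    need <- c("qname", "chrom1", "start1", "end1", "chrom2", "start2",
              "end2", "conversion", "pairClass", "separation",
              "gchMeth1", "gchSites1", "gchMeth2", "gchSites2")
    miss <- setdiff(need, colnames(object@pairs))
    if (length(miss))
        paste("pairs is missing columns:", paste(miss, collapse = ", "))
    else TRUE
})

#' ConcordanceResult: observed vs shuffled footprint concordance
#'
#' Result of a long-range single-molecule concordance analysis: observed
#' Pearson/Phi/tetrachoric correlations of per-read methylation fractions
#' across the two ends of linked pairs at loop anchors, the
#' mean-preserving shuffle null, and the Fisher z comparison of observed
#' vs shuffled Pearson r.
#'
#' @slot context Context analysed ("GCH" or "WCG").
#' @slot nPairs Number of qualifying read pairs (points).
#' @slot rObserved,phiObserved,tetrachoricObserved Observed correlations.
#' @slot contingency 2x2 table of binarized fractions
#'   (rows = end 1 in {1,0}, cols = end 2 in {1,0}).
#' @slot rShuffled Per-replicate shuffled Pearson r (length `nShuffles`).
#' @slot zFisher,pFisher Fisher z statistic and two-sided p comparing
#'   observed r with the mean shuffled r.
#' @slot nShuffles,seed Shuffle-null configuration.
#' @slot local A list with the local-control (same-anchor, short-range)
#'   summary, or an empty list when no local control was computed.
#'
#' @seealso [runLongRangeConcordance()]
#' @export
setClass("ConcordanceResult",
    representation(context = "character", nPairs = "integer",
                   rObserved = "numeric", phiObserved = "numeric",
                   tetrachoricObserved = "numeric", contingency = "matrix",
                   rShuffled = "numeric", zFisher = "numeric",
                   pFisher = "numeric", nShuffles = "integer",
                   seed = "integer", local = "list"))

setValidity("ConcordanceResult", function(object) {
    ok <- function(x) !length(x) || all(is.na(x) | abs(x) <= 1 + 1e-12)
    if (!ok(object@rObserved) || !ok(object@rShuffled))
        return("correlations must lie in [-1, 1]")
    TRUE
})

## ---- accessors ----

#' @describeIn ContextIndex The underlying GRanges of context sites.
#' @param x A `ContextIndex`.
#' @export
contextSites <- function(x) {
    stopifnot(is(x, "ContextIndex"))
    x@sites
}

#' @describeIn ContextIndex Factor of context labels, parallel to
#'   `contextSites(x)`.
#' @export
contextLabels <- function(x) S4Vectors::mcols(contextSites(x))$label

#' @describeIn LinkedPairs Per-pair summary table.
#' @param x A `LinkedPairs`.
#' @export
pairSummary <- function(x) {
    stopifnot(is(x, "LinkedPairs"))
    x@pairs
}

#' @describeIn LinkedPairs Per-site methylation calls.
#' @export
methylCalls <- function(x) {
    stopifnot(is(x, "LinkedPairs"))
    x@calls
}

#' @describeIn LinkedPairs Reference-space read sequences of retained ends.
#' @export
alignedEnds <- function(x) {
    stopifnot(is(x, "LinkedPairs"))
    x@reads
}

#' @describeIn LinkedPairs Filtering tallies recorded while loading.
#' @export
filterStats <- function(x) {
    stopifnot(is(x, "LinkedPairs"))
    x@stats
}

#' @describeIn ConcordanceResult Per-replicate shuffled Pearson r.
#' @param x A `ConcordanceResult`.
#' @export
shuffledR <- function(x) {
    stopifnot(is(x, "ConcordanceResult"))
    x@rShuffled
}

#' @describeIn ConcordanceResult One-row data.frame of the headline
#'   statistics (observed r/phi/tetrachoric, mean shuffled r, Fisher z, p).
#' @export
concordanceStats <- function(x) {
    stopifnot(is(x, "ConcordanceResult"))
    data.frame(context = x@context, nPairs = x@nPairs,
               rObserved = x@rObserved, phiObserved = x@phiObserved,
               tetrachoricObserved = x@tetrachoricObserved,
               rShuffledMean = mean(x@rShuffled), zFisher = x@zFisher,
               pFisher = x@pFisher)
}

## ---- show methods ----

setMethod("show", "ContextIndex", function(object) {
    tab <- table(contextLabels(object))
    cat("ContextIndex with", length(object@sites), "cytosine sites on",
        length(GenomeInfoDb::seqlevels(object@sites)), "sequence(s)\n")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("length", "ContextIndex", function(x) length(x@sites))

setMethod("show", "LinkedPairs", function(object) {
    cls <- table(object@pairs$pairClass)
    cat("LinkedPairs with", nrow(object@pairs), "retained read pairs\n")
    cat("  classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
    cat("  methylation calls:", nrow(object@calls), "\n")
})

setMethod("length", "LinkedPairs", function(x) nrow(x@pairs))

setMethod("show", "ConcordanceResult", function(object) {
    cat("ConcordanceResult (", object@context, ", ", object@nPairs,
        " read pairs)\n", sep = "")
    cat(sprintf("  observed:  r=%.4f phi=%.4f tetrachoric=%.4f\n",
                object@rObserved, object@phiObserved,
                object@tetrachoricObserved))
    cat(sprintf("  shuffled:  mean r=%.4f over %d replicates (seed %d)\n",
                mean(object@rShuffled), object@nShuffles, object@seed))
    cat(sprintf("  Fisher z:  z=%.3f, two-sided p=%.3g\n",
                object@zFisher, object@pFisher))
    if (length(object@local))
        cat(sprintf("  local control: r=%.4f (n=%d)\n",
                    object@local$rObserved, object@local$nPairs))
})
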