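## Cytosine-context indexing of a reference genome.
##
## GpC methyltransferase footprinting reads out chromatin accessibility at
## GCH sites (C preceded by G, not followed by G) while endogenous CpG
## methylation is read at HCG sites (C not preceded by G, followed by G),
## partitioned into WCG (W = A/T) and CCG. GCG is ambiguous between the
## exogenous and endogenous signal and is excluded from both summaries;
## WCH residual methylation flags incomplete bisulfite conversion.

.CONTEXT_LEVELS <- c("GCG", "GCH", "WCG", "CCG", "WCH", "CCH",
                     "UNCLASSIFIED")

.complementBase <- function(x) {
    chartr("ACGTN", "TGCAN", x)
}

#' Classify a cytosine by its flanking bases
#'
#' Assigns the trinucleotide context of a cytosine given the bases
#' immediately 5' and 3' of it on the same strand. `H` is A/C/T and `W`
#' is A/T. A cytosine with an `N` flank (including a missing flank at a
#' chromosome edge) is `UNCLASSIFIED`.
#'
#' @param prevBase,nextBase Character vectors of equal length over
#'   `A`, `C`, `G`, `T`, `N`: the base before and after the cytosine.
#' @return A factor with levels `GCG`, `GCH`, `WCG`, `CCG`, `WCH`, `CCH`,
#'   `UNCLASSIFIED`, parallel to the inputs.
#' @examples
#' classifyCytosine(c("A", "G", "G", "C"), c("G", "G", "A", "G"))
#' @export
classifyCytosine <- function(prevBase, nextBase) {
    prevBase <- toupper(prevBase)
    nextBase <- toupper(nextBase)
    if (length(prevBase) != length(nextBase))
        stop("prevBase and nextBase must have equal length")
    bad <- !(prevBase %in% c("A", "C", "G", "T", "N")) |
           !(nextBase %in% c("A", "C", "G", "T", "N"))
    if (any(bad))
        stop("invalid nucleotide symbol(s): ",
             paste(unique(c(prevBase[bad], nextBase[bad])), collapse = ", "))
    out <- rep("UNCLASSIFIED", length(prevBase))
    known <- prevBase != "N" & nextBase != "N"
    cpg <- known & nextBase == "G"
    out[cpg & prevBase == "G"] <- "GCG"
    out[cpg & prevBase %in% c("A", "T")] <- "WCG"
    out[cpg & prevBase == "C"] <- "CCG"
    noncpg <- known & nextBase != "G"
    out[noncpg & prevBase == "G"] <- "GCH"
    out[noncpg & prevBase %in% c("A", "T")] <- "WCH"
    out[noncpg & prevBase == "C"] <- "CCH"
    factor(out, levels = .CONTEXT_LEVELS)
}

#' Load a reference genome from FASTA
#'
#' Reads a (multi-record, line-wrapped) FASTA file into a
#' [Biostrings::DNAStringSet], keeping only the first whitespace-delimited
#' token of each record name. The alphabet must reduce to A/C/G/T/N;
#' lowercase is normalised on load.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
    genome <- Biostrings::readDNAStringSet(path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    .checkGenome(genome)
    genome
}

.checkGenome <- function(genome) {
    if (!is(genome, "DNAStringSet"))
        stop("genome must be a DNAStringSet (see readGenome())")
    if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
        stop("empty genome")
    if (anyDuplicated(names(genome)))
        stop("duplicated chromosome names in genome")
    freq <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
    extra <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
    if (sum(extra) > 0)
        stop("genome alphabet must be restricted to A/C/G/T/N; found: ",
             paste(names(extra)[extra > 0], collapse = ", "))
    invisible(genome)
}

#' Build a strand-aware cytosine context index
#'
#' Indexes every cytosine of the genome on both strands. A forward-strand
#' `C` at position i is classified from `(seq[i-1], seq[i+1])`; a
#' forward-strand `G` carries a minus-strand cytosine and is classified
#' from `(complement(seq[i+1]), complement(seq[i-1]))`, reported at the
#' forward coordinate of the G with strand `-`. Chromosome-edge cytosines
#' are `UNCLASSIFIED`. Coordinates are 1-based as in [GenomicRanges].
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [readGenome()]).
#' @return A [ContextIndex-class] sorted by (chromosome, position, strand).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' buildContextIndex(g)
#' @export
buildContextIndex <- function(genome) {
    .checkGenome(genome)
    perChrom <- lapply(seq_along(genome), function(i) {
        chars <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]]
        n <- length(chars)
        flank <- function(idx) ifelse(idx < 1L | idx > n, "N", chars[
            pmin(pmax(idx, 1L), n)])
        ci <- which(chars == "C")
        gi <- which(chars == "G")
        labC <- classifyCytosine(flank(ci - 1L), flank(ci + 1L))
        labG <- classifyCytosine(.complementBase(flank(gi + 1L)),
                                 .complementBase(flank(gi - 1L)))
        pos <- c(ci, gi)
        std <- c(rep("+", length(ci)), rep("-", length(gi)))
        o <- order(pos, std)
        list(pos = pos[o], strand = std[o],
             label = factor(c(as.character(labC), as.character(labG))[o],
                            levels = .CONTEXT_LEVELS))
    })
    lens <- Biostrings::width(genome)
    gr <- GenomicRanges::GRanges(
        seqnames = rep(names(genome), vapply(perChrom, function(p)
            length(p$pos), integer(1))),
        ranges = IRanges::IRanges(
            start = unlist(lapply(perChrom, `[[`, "pos")), width = 1L),
        strand = unlist(lapply(perChrom, `[[`, "strand")),
        label = factor(unlist(lapply(perChrom, function(p)
            as.character(p$label))), levels = .CONTEXT_LEVELS),
        seqinfo = GenomeInfoDb::Seqinfo(names(genome), lens))
    new("ContextIndex", sites = gr)
}

.expandLabelSet <- function(labels, excludeCCG = FALSE) {
    labels <- unique(unlist(lapply(labels, function(l) {
        switch(l, HCG = c("WCG", "CCG"), HCH = c("WCH", "CCH"), l)
    })))
    bad <- setdiff(labels, .CONTEXT_LEVELS)
    if (length(bad))
        stop("unknown context label(s): ", paste(bad, collapse = ", "))
    if (excludeCCG) labels <- setdiff(labels, "CCG")
    labels
}

#' Genomic density of context sites
#'
#' Returns the number of base pairs per context site, e.g. GCH sites in
#' the human genome occur about once per 13 bp whereas HCGs occur about
#' once per 83 bp. `HCG` expands to `{WCG, CCG}` and `HCH` to
#' `{WCH, CCH}`. By default sites on both strands are counted; set
#' `bothStrands = FALSE` to count the forward strand only.
#'
#' @param index A [ContextIndex-class].
#' @param labels Character vector of context labels (atomic labels or the
#'   unions `HCG`/`HCH`).
#' @param genomeLength Genome size in bp; defaults to the sum of the
#'   seqlengths recorded in the index.
#' @param bothStrands Count sites on both strands (default) or `+` only.
#' @param excludeCCG Drop CCG from an `HCG` request (robustness variant
#'   against residual CpC methyltransferase activity).
#' @return Base pairs per site (a single number).
#' @export
contextDensity <- function(index, labels, genomeLength = NULL,
                           bothStrands = TRUE, excludeCCG = FALSE) {
    stopifnot(is(index, "ContextIndex"))
    labels <- .expandLabelSet(labels, excludeCCG)
    if (is.null(genomeLength))
        genomeLength <- sum(as.numeric(
            GenomeInfoDb::seqlengths(contextSites(index))))
    if (!is.numeric(genomeLength) || genomeLength <= 0)
        stop("genomeLength must be positive")
    keep <- contextLabels(index) %in% labels
    if (!bothStrands)
        keep <- keep & as.character(GenomicRanges::strand(
            contextSites(index))) == "+"
    n <- sum(keep)
    if (n == 0L)
        stop("no sites with label(s) ", paste(labels, collapse = ","),
             ": density undefined")
    genomeLength / n
}

#' In-silico bisulfite conversion of a reference genome
#'
#' Produces the fully converted reference used for bisulfite read
#' alignment: `CT` mode replaces every C with T (original-top-strand
#' reference), `GA` mode replaces every G with A (original-bottom-strand
#' reference). N and sequence lengths are preserved.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param mode `"CT"` or `"GA"`.
#' @return The converted [Biostrings::DNAStringSet].
#' @export
convertReference <- function(genome, mode = c("CT", "GA")) {
    mode <- match.arg(mode)
    .checkGenome(genome)
    if (mode == "CT") Biostrings::chartr("C", "T", genome)
    else Biostrings::chartr("G", "A", genome)
}

#' Orient a compartment eigenvector by GC content
#'
#' The sign of the leading eigenvector of a Hi-C observed/expected
#' correlation matrix is arbitrary; by convention the sign is chosen so
#' that high-GC bins receive positive scores (compartment A). The
#' eigenvector is returned unchanged if its Pearson correlation with the
#' per-bin GC fraction is non-negative, and sign-flipped otherwise.
#' Missing bins are excluded from the correlation but preserved in the
#' output.
#'
#' @param eigenvector Numeric per-bin scores (may contain NA).
#' @param gcPerBin Numeric per-bin GC fractions, same length.
#' @return The oriented eigenvector.
#' @export
orientCompartmentEigenvector <- function(eigenvector, gcPerBin) {
    if (length(eigenvector) != length(gcPerBin))
        stop("eigenvector and gcPerBin must have equal length")
    if (length(eigenvector) < 2L)
        stop("need at least 2 bins")
    ok <- stats::complete.cases(eigenvector, gcPerBin)
    if (sum(ok) < 2L)
        stop("orientation undefined: fewer than 2 complete bins")
    if (stats::sd(gcPerBin[ok]) == 0)
        stop("orientation undefined: constant GC content")
    if (stats::sd(eigenvector[ok]) == 0)
        stop("orientation undefined: constant eigenvector")
    r <- stats::cor(eigenvector[ok], gcPerBin[ok])
    if (r >= 0) eigenvector else -eigenvector
}

#' Export a context index as a BED-like table
#'
#' Writes `chrom`, `start` (0-based), `end`, `label`, `strand`, one row
#' per cytosine site.
#'
#' @param index A [ContextIndex-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeContextTable <- function(index, path) {
    gr <- contextSites(index)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::start(gr),
                     label = as.character(contextLabels(index)),
                     strand = as.character(GenomicRanges::strand(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
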