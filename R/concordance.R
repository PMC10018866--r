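## Single-molecule footprint concordance between loop anchors.
##
## Each linked read pair contributes one point (x, y): the GCH (or WCG)
## methylation fraction of its two ends. Coordination of accessibility
## between spatially proximal anchors shows up as correlation of these
## per-molecule fractions; the null shuffles end-2 summaries among pairs
## of the same anchor group, which preserves every anchor's mean
## footprint exactly while destroying the molecule link.

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        old <- get(".Random.seed", envir = .GlobalEnv)
        on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

#' Per-pair methylation fractions at anchor pairs
#'
#' One point per qualifying read pair: the methylation fraction of each
#' end in the requested context. Pairs with fewer than `minSites` context
#' calls on either end are excluded -- per-read fractions from very few
#' sites are too granular to carry concordance signal.
#'
#' @param x A [LinkedPairs-class] object.
#' @param assignments Optional anchor assignment table from
#'   [assignPairsToAnchorPairs()]; when `NULL`, all `CIS_LONG` pairs are
#'   used as a single group.
#' @param context `"GCH"` (accessibility footprint) or `"WCG"`
#'   (endogenous methylation).
#' @param minSites Minimum context calls per end (default 3).
#' @return A data.frame with columns `anchorId`, `pairIdx`, `frac1`,
#'   `frac2`.
#' @export
pairFractions <- function(x, assignments = NULL,
                          context = c("GCH", "WCG"), minSites = 3) {
    context <- match.arg(context)
    stopifnot(is(x, "LinkedPairs"))
    p <- pairSummary(x)
    col <- tolower(context)
    if (is.null(assignments)) {
        idx <- which(p$pairClass == "CIS_LONG")
        assignments <- data.frame(anchorId = rep("all", length(idx)),
                                  pairIdx = idx)
    }
    i <- assignments$pairIdx
    s1 <- p[[paste0(col, "Sites1")]][i]
    s2 <- p[[paste0(col, "Sites2")]][i]
    keep <- s1 >= minSites & s2 >= minSites
    data.frame(anchorId = assignments$anchorId[keep],
               pairIdx = i[keep],
               frac1 = p[[paste0(col, "Meth1")]][i][keep] / s1[keep],
               frac2 = p[[paste0(col, "Meth2")]][i][keep] / s2[keep])
}

#' Pearson correlation of paired fractions
#'
#' Product-moment correlation with explicit degenerate-input errors:
#' fewer than 3 points or zero variance on either axis is reported as an
#' undefined correlation rather than NA.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 points")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: zero variance")
    stats::cor(x, y)
}

#' Binarize fractions and compute the Phi coefficient
#'
#' Methylation fractions are largely bimodal, so they are dichotomized at
#' `cutpoint` (values at the cutpoint map to 1) and the Phi coefficient
#' -- Pearson correlation of the 0/1 pairs -- is computed together with
#' the 2x2 contingency table.
#'
#' @param frac1,frac2 Numeric fractions in `[0, 1]`, equal length.
#' @param cutpoint Dichotomization threshold (default 0.5; `>=` maps
#'   to 1).
#' @return A list with `phi` and `table` (matrix
#'   `[[n11, n10], [n01, n00]]`; rows index end 1 in {1, 0}).
#' @export
binarizeAndPhi <- function(frac1, frac2, cutpoint = 0.5) {
    if (length(frac1) != length(frac2))
        stop("frac1 and frac2 must have equal length")
    if (length(frac1) < 3L) stop("need at least 3 points")
    b1 <- as.integer(frac1 >= cutpoint)
    b2 <- as.integer(frac2 >= cutpoint)
    tab <- matrix(c(sum(b1 == 1 & b2 == 1), sum(b1 == 1 & b2 == 0),
                    sum(b1 == 0 & b2 == 1), sum(b1 == 0 & b2 == 0)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(end1 = c("1", "0"), end2 = c("1", "0")))
    if (stats::sd(b1) == 0 || stats::sd(b2) == 0)
        stop("undefined phi: degenerate margin")
    list(phi = stats::cor(b1, b2), table = tab)
}

.binormUpper <- function(a, b, rho) {
    ## P(Z1 > a, Z2 > b) under a standard bivariate normal with cor rho
    mvtnorm::pmvnorm(lower = c(a, b), upper = c(Inf, Inf),
                     corr = matrix(c(1, rho, rho, 1), 2),
                     algorithm = mvtnorm::TVPACK())[1]
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood estimate of the correlation of a latent bivariate
#' normal dichotomized at the thresholds implied by the table margins:
#' with the thresholds fixed at the observed margins, the ML estimate is
#' the `rho` that reproduces the observed `n11` cell probability, found
#' by root solving. Tables with a zero cell are smoothed by adding 0.5 to
#' every cell. A closed-form cosine approximation
#' `cos(pi / (1 + sqrt(ad/bc)))` is available via `method = "cosine"`.
#'
#' @param table 2x2 matrix of non-negative counts
#'   (`[[n11, n10], [n01, n00]]`).
#' @param method `"ml"` (default) or `"cosine"`.
#' @return The estimated latent correlation.
#' @export
tetrachoricR <- function(table, method = c("ml", "cosine")) {
    method <- match.arg(method)
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L)))
        stop("table must be 2x2")
    if (any(table < 0)) stop("counts must be non-negative")
    if (sum(table) < 1) stop("empty table")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("undefined tetrachoric correlation: zero margin")
    if (any(table == 0)) table <- table + 0.5
    if (method == "cosine") {
        ad <- table[1, 1] * table[2, 2]
        bc <- table[1, 2] * table[2, 1]
        return(cospi(1 / (1 + sqrt(ad / bc))))
    }
    n <- sum(table)
    p1 <- sum(table[1, ]) / n   # P(end1 = 1)
    p2 <- sum(table[, 1]) / n   # P(end2 = 1)
    a <- stats::qnorm(1 - p1)
    b <- stats::qnorm(1 - p2)
    target <- table[1, 1] / n
    f <- function(rho) .binormUpper(a, b, rho) - target
    lim <- 0.999999
    if (f(-lim) >= 0) return(-1)
    if (f(lim) <= 0) return(1)
    stats::uniroot(f, c(-lim, lim), tol = 1e-10)$root
}

#' Mean-preserving shuffle null for paired fractions
#'
#' Permutes the end-2 fractions among the read pairs of each anchor
#' group, leaving end-1 fixed. Per-anchor mean fractions are therefore
#' preserved exactly in every replicate while the within-molecule link is
#' destroyed. Groups of size 1 contribute their original pair.
#'
#' @param points A data.frame from [pairFractions()] (columns `anchorId`,
#'   `frac1`, `frac2`).
#' @param nShuffles Number of replicates (default 100).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return A list with `replicates` (list of data.frames, each a shuffled
#'   copy of `points`) and `r` (per-replicate pooled Pearson correlation,
#'   NA where degenerate).
#' @export
shuffleNull <- function(points, nShuffles = 100, seed = 1) {
    grp <- split(seq_len(nrow(points)), points$anchorId)
    .withSeed(seed, {
        replicates <- vector("list", nShuffles)
        r <- rep(NA_real_, nShuffles)
        for (k in seq_len(nShuffles)) {
            f2 <- points$frac2
            for (g in grp)
                f2[g] <- points$frac2[g][sample.int(length(g))]
            rep_k <- points
            rep_k$frac2 <- f2
            replicates[[k]] <- rep_k
            if (stats::sd(points$frac1) > 0 && stats::sd(f2) > 0)
                r[k] <- stats::cor(points$frac1, f2)
        }
        list(replicates = replicates, r = r)
    })
}

#' Fisher's z comparison of two independent correlations
#'
#' Tests the difference of two correlation coefficients observed in
#' independent groups via the variance-stabilizing arctanh transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p from the standard normal.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Group sizes (each > 3).
#' @return A list with `z` and `p`.
#' @export
fisherZCompare <- function(r1, n1, r2, n2) {
    if (any(abs(c(r1, r2)) >= 1))
        stop("|r| = 1: arctanh transform is infinite")
    if (n1 <= 3 || n2 <= 3) stop("group sizes must exceed 3")
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Short-range local-control pairs within single anchors
#'
#' Selects read pairs whose two ends overlap the same single anchor
#' interval and lie within `maxSeparation` of each other; within each
#' anchor at most `sampleCap` pairs are drawn uniformly. These local
#' pairs provide the reference concordance level that long-range pairs
#' are compared against.
#'
#' @param x A [LinkedPairs-class] object.
#' @param anchors An anchor-pair data.frame (see [readBedpe()]); the
#'   anchor universe is the union of all A and B intervals.
#' @param maxSeparation Maximum pair separation in bp (default 1000).
#' @param sampleCap Maximum pairs sampled per anchor (default 100).
#' @param seed Integer seed for the per-anchor sampling.
#' @param context,minSites Passed to the fraction computation as in
#'   [pairFractions()].
#' @return A data.frame with columns `anchorId`, `pairIdx`, `frac1`,
#'   `frac2`.
#' @export
localControlPairs <- function(x, anchors, maxSeparation = 1000,
                              sampleCap = 100, seed = 1,
                              context = c("GCH", "WCG"), minSites = 3) {
    context <- match.arg(context)
    stopifnot(is(x, "LinkedPairs"))
    p <- pairSummary(x)
    uni <- unique(rbind(
        data.frame(chrom = anchors$chrom1, start = anchors$start1,
                   end = anchors$end1),
        data.frame(chrom = anchors$chrom2, start = anchors$start2,
                   end = anchors$end2)))
    uni$id <- paste0(uni$chrom, ":", uni$start, "-", uni$end)
    gr <- GenomicRanges::GRanges(uni$chrom,
                                 IRanges::IRanges(uni$start, uni$end))
    cand <- which(p$chrom1 == p$chrom2 &
                  !is.na(p$separation) & p$separation <= maxSeparation)
    h1 <- GenomicRanges::findOverlaps(.endGRanges(p, 1)[cand], gr)
    h2 <- GenomicRanges::findOverlaps(.endGRanges(p, 2)[cand], gr)
    k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
    k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
    both <- intersect(k1, k2)
    if (!length(both))
        return(data.frame(anchorId = character(), pairIdx = integer(),
                          frac1 = numeric(), frac2 = numeric()))
    m <- do.call(rbind, strsplit(both, " ", fixed = TRUE))
    asg <- data.frame(anchorId = uni$id[as.integer(m[, 2])],
                      pairIdx = cand[as.integer(m[, 1])])
    .withSeed(seed, {
        kept <- unlist(lapply(split(seq_len(nrow(asg)), asg$anchorId),
            function(idx) {
                if (length(idx) > sampleCap)
                    idx[sample.int(length(idx), sampleCap)]
                else idx
            }), use.names = FALSE)
        asg <- asg[sort(kept), , drop = FALSE]
    })
    pairFractions(x, assignments = asg, context = context,
                  minSites = minSites)
}

.corSummaries <- function(points) {
    r <- tryCatch(pearsonR(points$frac1, points$frac2),
                  error = function(e) NA_real_)
    pt <- tryCatch(binarizeAndPhi(points$frac1, points$frac2),
                   error = function(e) NULL)
    phi <- if (is.null(pt)) NA_real_ else pt$phi
    tab <- if (is.null(pt))
        matrix(NA_real_, 2, 2)
    else pt$table
    tet <- if (is.null(pt)) NA_real_ else
        tryCatch(tetrachoricR(pt$table), error = function(e) NA_real_)
    list(r = r, phi = phi, tetra = tet, table = tab)
}

#' Long-range footprint concordance against the shuffle null
#'
#' End-to-end analysis at a set of loop-anchor pairs: pools one point per
#' qualifying `CIS_LONG` read pair across all anchor pairs, computes
#' observed Pearson/Phi/tetrachoric correlations, builds the
#' mean-preserving shuffle null (end-2 permuted within anchor groups,
#' `nShuffles` replicates), compares observed vs mean shuffled Pearson r
#' with Fisher's z, and computes the matched short-range local control.
#'
#' @param x A [LinkedPairs-class] object.
#' @param anchors An anchor-pair data.frame (see [readBedpe()]).
#' @param context `"GCH"` or `"WCG"`.
#' @param minSites Minimum context calls per end (default 3).
#' @param nShuffles Shuffle replicates (default 100).
#' @param seed Integer seed for shuffling and local-control sampling.
#' @param shuffleWithin Shuffle grouping: `"anchorPair"` (default, the
#'   tightest null preserving per-anchor means) or `"anchor"` (pairs
#'   grouped by the interval their end 2 falls in).
#' @param nullN Effective n for the shuffled group in the Fisher z test:
#'   `"matched"` (n2 = n1, default) or `"pooled"`
#'   (n2 = n1 * nShuffles).
#' @param localMaxDist,localCap Local-control parameters
#'   (see [localControlPairs()]); set `localMaxDist = NULL` to skip the
#'   local control.
#' @param firstMatchOnly Passed to [assignPairsToAnchorPairs()].
#' @return A [ConcordanceResult-class] object.
#' @export
runLongRangeConcordance <- function(x, anchors, context = c("GCH", "WCG"),
                                    minSites = 3, nShuffles = 100,
                                    seed = 1,
                                    shuffleWithin = c("anchorPair",
                                                      "anchor"),
                                    nullN = c("matched", "pooled"),
                                    localMaxDist = 1000, localCap = 100,
                                    firstMatchOnly = FALSE) {
    context <- match.arg(context)
    shuffleWithin <- match.arg(shuffleWithin)
    nullN <- match.arg(nullN)
    asg <- assignPairsToAnchorPairs(x, anchors,
                                    firstMatchOnly = firstMatchOnly)
    points <- pairFractions(x, asg, context = context,
                            minSites = minSites)
    if (nrow(points) < 3L)
        stop("insufficient data: fewer than 3 qualifying read pairs")
    if (shuffleWithin == "anchor")
        points$anchorId <- .end2AnchorKey(x, anchors, points)
    obs <- .corSummaries(points)
    null <- shuffleNull(points, nShuffles = nShuffles, seed = seed)
    rShufMean <- mean(null$r, na.rm = TRUE)
    n1 <- nrow(points)
    n2 <- if (nullN == "matched") n1 else n1 * nShuffles
    fz <- fisherZCompare(obs$r, n1, rShufMean, n2)
    local <- list()
    if (!is.null(localMaxDist)) {
        lp <- localControlPairs(x, anchors, maxSeparation = localMaxDist,
                                sampleCap = localCap, seed = seed,
                                context = context, minSites = minSites)
        if (nrow(lp) >= 3L) {
            ls <- .corSummaries(lp)
            local <- list(nPairs = nrow(lp), rObserved = ls$r,
                          phiObserved = ls$phi,
                          tetrachoricObserved = ls$tetra)
        }
    }
    new("ConcordanceResult", context = context, nPairs = n1,
        rObserved = obs$r, phiObserved = obs$phi,
        tetrachoricObserved = obs$tetra, contingency = obs$table,
        rShuffled = null$r, zFisher = fz$z, pFisher = fz$p,
        nShuffles = as.integer(nShuffles), seed = as.integer(seed),
        local = local)
}

.end2AnchorKey <- function(x, anchors, points) {
    ## group key for the whole-anchor shuffle variant: the anchor
    ## interval containing end 2 of each pair
    p <- pairSummary(x)
    uni <- unique(rbind(
        data.frame(chrom = anchors$chrom1, start = anchors$start1,
                   end = anchors$end1),
        data.frame(chrom = anchors$chrom2, start = anchors$start2,
                   end = anchors$end2)))
    gr <- GenomicRanges::GRanges(uni$chrom,
                                 IRanges::IRanges(uni$start, uni$end))
    e2 <- .endGRanges(p[points$pairIdx, , drop = FALSE], 2)
    h <- GenomicRanges::findOverlaps(e2, gr, select = "first")
    key <- ifelse(is.na(h), points$anchorId,
                  paste0(uni$chrom[h], ":", uni$start[h], "-",
                         uni$end[h]))
    key
}
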