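# independent oracles: deliberately written against the definitions, not
# against the package's implementation paths

# two-sided Fisher exact p by full enumeration with binomial coefficients
oracleFisher2x2 <- function(tab) {
    a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ])
    k <- sum(tab[, 1])
    if (m + n == 0) return(1)
    supp <- max(0, k - n):min(k, m)
    probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
    pObs <- probs[match(a, supp)]
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# step-up BH by explicit sort / cummin from the definition
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- Inf
    for (i in m:1) {
        prev <- min(prev, m * p[o[i]] / i, 1)
        adj[o[i]] <- prev
    }
    adj
}

# textbook Fisher z for two independent correlations
oracleFisherZ <- function(r1, n1, r2, n2) {
    fz <- function(r) 0.5 * log((1 + r) / (1 - r))
    z <- (fz(r1) - fz(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    list(z = z, p = 2 * pnorm(-abs(z)))  # lower tail: stable for large z
}

# correlated standard binormal sample
rBinorm <- function(n, rho) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(z1, z2)
}

# counts-level Monte-Carlo oracle for the long-range concordance r:
# redraws latent states and binomial methylation counts directly from the
# generative model on the same genome/anchors, bypassing sequence
# emission, SAM parsing and the calling machinery entirely
concordanceOracle <- function(sim, nPairs = 2e5) {
    cfg <- sim$config
    anchors <- sim$anchors
    sites <- contextSites(sim$index)
    lab <- as.character(contextLabels(sim$index))
    std <- as.character(GenomicRanges::strand(sites))
    pos <- GenomicRanges::start(sites)
    gchP <- sort(pos[lab == "GCH" & std == "+"])
    gchM <- sort(pos[lab == "GCH" & std == "-"])
    perA <- ceiling(nPairs / nrow(anchors))
    p11 <- cfg$p11
    pg1 <- p11 / cfg$piOpen
    pg0 <- (cfg$piOpen - p11) / (1 - cfg$piOpen)
    countIn <- function(gch, starts)
        findInterval(starts + cfg$readLength - 1L, gch) -
            findInterval(starts - 1L, gch)
    emitP <- function(s) {
        p <- ifelse(s == 1, cfg$pOpen, cfg$pClosed)
        p + (1 - p) * cfg$conversionFailure
    }
    xs <- ys <- numeric(0)
    for (a in seq_len(nrow(anchors))) {
        s1 <- rbinom(perA, 1, cfg$piOpen)
        s2 <- rbinom(perA, 1, ifelse(s1 == 1, pg1, pg0))
        conv <- sample(c("CT", "GA"), perA, replace = TRUE)
        st1 <- sample(anchors$start1[a]:
                      (anchors$end1[a] - cfg$readLength + 1L), perA,
                      replace = TRUE)
        st2 <- sample(anchors$start2[a]:
                      (anchors$end2[a] - cfg$readLength + 1L), perA,
                      replace = TRUE)
        k1 <- ifelse(conv == "CT", countIn(gchP, st1), countIn(gchM, st1))
        k2 <- ifelse(conv == "CT", countIn(gchP, st2), countIn(gchM, st2))
        m1 <- rbinom(perA, k1, emitP(s1))
        m2 <- rbinom(perA, k2, emitP(s2))
        ok <- k1 >= 3 & k2 >= 3
        xs <- c(xs, m1[ok] / k1[ok])
        ys <- c(ys, m2[ok] / k2[ok])
    }
    cor(xs, ys)
}
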