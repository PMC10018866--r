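## Post-processing of bisulfite genotype calls.
##
## Raw bisulfite genotypes are noisy in specific, recognisable ways:
## collapsed repeats (extreme depth), strand-biased support, reads with
## mapping quality 0, calls whose genotype quality is low relative to
## their depth, and clustered SNPs from misalignment. Each record is
## annotated with every rule it fails; PASS means none.

.FILTER_RULES <- c("LowGQ", "HighDepth", "StrandBias", "HighMQ0",
                   "LowGQbyDepth", "SNPCluster")

#' Read a VCF into a flat variant table
#'
#' Extracts the fields the bisulfite post-filters consume: coordinates,
#' alleles, genotype, genotype quality (GQ), depth (DP), the caller's
#' signed strand-bias score (INFO key `SB`, more negative = less biased),
#' the fraction of mapping-quality-0 reads (INFO `MQ0F`), and the
#' imputation annotations minor allele frequency (INFO `MAF`) and
#' imputation `R2`. Missing fields become NA.
#'
#' @param path Path to a VCF 4.x file.
#' @param sbKey,mq0Key,mafKey,r2Key INFO keys to read the strand-bias
#'   score, MQ0 fraction, minor allele frequency and imputation R2 from.
#' @return A data.frame with one row per record: `chrom`, `pos`, `id`,
#'   `ref`, `alt` (comma-joined for multi-allelic records), `biallelic`,
#'   `genotype`, `GQ`, `DP`, `SB`, `MQ0F`, `MAF`, `R2`, `filter`.
#' @export
readVariantTable <- function(path, sbKey = "SB", mq0Key = "MQ0F",
                             mafKey = "MAF", r2Key = "R2") {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("readVariantTable() requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    alt <- VariantAnnotation::alt(v)
    altChar <- vapply(as.list(alt), function(a)
        paste(as.character(a), collapse = ","), character(1))
    info <- VariantAnnotation::info(v)
    getInfo <- function(key) {
        if (key %in% colnames(info)) {
            val <- info[[key]]
            if (is(val, "List") || is.list(val))
                val <- vapply(as.list(val), function(z)
                    if (length(z)) as.numeric(z[[1]]) else NA_real_,
                    numeric(1))
            as.numeric(val)
        } else rep(NA_real_, nrow(info))
    }
    g <- VariantAnnotation::geno(v)
    getGeno <- function(key, as = as.numeric) {
        if (key %in% names(g)) as(g[[key]][, 1]) else
            rep(as(NA), length(rr))
    }
    dp <- getInfo("DP")
    if (all(is.na(dp))) dp <- getGeno("DP")
    data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        id = names(rr),
        ref = as.character(VariantAnnotation::ref(v)),
        alt = altChar,
        biallelic = lengths(alt) == 1L & !grepl(",", altChar),
        genotype = getGeno("GT", as.character),
        GQ = getGeno("GQ"),
        DP = dp,
        SB = getInfo(sbKey),
        MQ0F = getInfo(mq0Key),
        MAF = getInfo(mafKey),
        R2 = getInfo(r2Key),
        filter = as.character(VariantAnnotation::fixed(v)$FILTER),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Post-filter raw bisulfite genotype calls
#'
#' Annotates each record with every quality rule it fails:
#' \describe{
#'   \item{LowGQ}{genotype quality at or below `gqMin` (default 20);}
#'   \item{HighDepth}{depth above `maxDepth` (250x, collapsed repeats);}
#'   \item{StrandBias}{strand-bias score above `sbMax` (-0.02; the
#'     caller's convention is more negative = less biased);}
#'   \item{HighMQ0}{depth above `mq0Depth` (40x) with more than
#'     `mq0Frac` (10%) of reads at mapping quality 0;}
#'   \item{LowGQbyDepth}{genotype quality divided by depth below
#'     `gqOverDepthMin` (1);}
#'   \item{SNPCluster}{another SNP within `window` bp (+-10); all
#'     records of a cluster fail.}
#' }
#' Records failing no rule get FILTER `PASS`. A record missing the
#' annotation a rule needs skips that rule; skipped-rule counts are
#' returned in the `"skipped"` attribute.
#'
#' @param records Variant table (see [readVariantTable()]), sorted by
#'   chromosome then position.
#' @param window Cluster window in bp (default 10).
#' @param maxDepth,sbMax,mq0Depth,mq0Frac,gqOverDepthMin,gqMin Rule
#'   thresholds (defaults 250, -0.02, 40, 0.1, 1, 20).
#' @return `records` with the `filter` column rewritten
#'   (`PASS` or `;`-joined failed rule names).
#' @export
postprocessFilters <- function(records, window = 10, maxDepth = 250,
                               sbMax = -0.02, mq0Depth = 40,
                               mq0Frac = 0.1, gqOverDepthMin = 1,
                               gqMin = 20) {
    o <- order(records$chrom, records$pos)
    if (!identical(o, seq_len(nrow(records))))
        stop("records must be sorted by chromosome, position")
    n <- nrow(records)
    fails <- matrix(FALSE, n, length(.FILTER_RULES),
                    dimnames = list(NULL, .FILTER_RULES))
    skipped <- integer(0)
    rule <- function(name, value) {
        miss <- is.na(value)
        if (any(miss)) {
            warning(sum(miss), " record(s) missing annotation for rule ",
                    name, "; rule skipped there")
            skipped[name] <<- sum(miss)
        }
        fails[!miss, name] <<- value[!miss]
    }
    rule("LowGQ", records$GQ <= gqMin)
    rule("HighDepth", records$DP > maxDepth)
    rule("StrandBias", records$SB > sbMax)
    rule("HighMQ0", records$DP > mq0Depth & records$MQ0F > mq0Frac)
    rule("LowGQbyDepth", records$GQ / records$DP < gqOverDepthMin)
    if (n > 1L) {
        sameChromPrev <- c(FALSE,
            records$chrom[-1] == records$chrom[-n])
        nearPrev <- sameChromPrev &
            c(FALSE, diff(records$pos) <= window)
        fails[, "SNPCluster"] <- nearPrev | c(nearPrev[-1], FALSE)
    }
    records$filter <- apply(fails, 1, function(f)
        if (any(f)) paste(.FILTER_RULES[f], collapse = ";") else "PASS")
    attr(records, "skipped") <- skipped
    records
}

#' Post-imputation quality filter
#'
#' Keeps biallelic SNPs with minor allele frequency above `mafMin` and
#' imputation R2 above `r2Min`. Records missing MAF or R2 are dropped;
#' their count is returned in the `"droppedMissing"` attribute.
#'
#' @param records Variant table (see [readVariantTable()]).
#' @param mafMin Minimum minor allele frequency, exclusive
#'   (default 0.01).
#' @param r2Min Minimum imputation R2, exclusive (default 0.3).
#' @param biallelicOnly Require biallelic records (default TRUE).
#' @return The retained records.
#' @export
imputationQcFilter <- function(records, mafMin = 0.01, r2Min = 0.3,
                               biallelicOnly = TRUE) {
    miss <- is.na(records$MAF) | is.na(records$R2)
    keep <- !miss & records$MAF > mafMin & records$R2 > r2Min
    if (biallelicOnly) keep <- keep & records$biallelic
    out <- records[keep, , drop = FALSE]
    attr(out, "droppedMissing") <- sum(miss)
    out
}

.isTransition <- function(ref, alt) {
    (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Transition/transversion ratio
#'
#' Ratio of transitions (A<->G, C<->T) to transversions over biallelic
#' SNV records; a standard genotype-quality heuristic (genome-wide truth
#' sits near 2, random errors push it toward 0.5).
#'
#' @param records Variant table; non-SNV and multi-allelic records are
#'   excluded.
#' @return The Ti/Tv ratio.
#' @export
titvRatio <- function(records) {
    snv <- records$biallelic & records$ref %in% c("A", "C", "G", "T") &
           records$alt %in% c("A", "C", "G", "T")
    ref <- records$ref[snv]; alt <- records$alt[snv]
    ti <- sum(.isTransition(ref, alt))
    tv <- sum(snv) - ti
    if (tv == 0)
        stop("undefined Ti/Tv ratio: no transversions")
    ti / tv
}

.normGT <- function(gt) {
    ## unphased, allele-sorted genotype string
    vapply(strsplit(gt, "[/|]"), function(a)
        paste(sort(a), collapse = "/"), character(1))
}

#' Genotype concordance between a test and a truth call set
#'
#' Joins the two sets by (chromosome, position, ref, alt) -- an allele
#' mismatch at a shared position counts as discordant -- and reports the
#' genotype concordance fraction over shared sites, sensitivity (truth
#' sites recovered with matching genotype over all truth sites) and
#' precision (test sites with matching truth genotype over all test
#' sites), plus a genotype-by-genotype confusion table.
#'
#' @param test,truth Variant tables (see [readVariantTable()]).
#' @param mask Optional confident-region mask: a data.frame with
#'   `chrom`, `start`, `end` (1-based, closed); both sets are restricted
#'   to it.
#' @return A list with `nSitesCompared`, `genotypeConcordance`,
#'   `sensitivity`, `precision`, `confusion` and `undefined` (TRUE when
#'   the comparison is empty).
#' @export
genotypeConcordance <- function(test, truth, mask = NULL) {
    restrict <- function(df) {
        if (is.null(mask)) return(df)
        gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(df$pos, df$pos))
        mgr <- GenomicRanges::GRanges(mask$chrom,
            IRanges::IRanges(mask$start, mask$end))
        df[IRanges::overlapsAny(gr, mgr), , drop = FALSE]
    }
    test <- restrict(test); truth <- restrict(truth)
    if (nrow(test) == 0L || nrow(truth) == 0L)
        return(list(nSitesCompared = 0L, genotypeConcordance = NA_real_,
                    sensitivity = NA_real_, precision = NA_real_,
                    confusion = table(character(), character()),
                    undefined = TRUE))
    keyPos <- function(df) paste(df$chrom, df$pos)
    keyFull <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    shared <- intersect(keyPos(test), keyPos(truth))
    ti <- match(shared, keyPos(test))
    ui <- match(shared, keyPos(truth))
    alleleMatch <- keyFull(test)[ti] == keyFull(truth)[ui]
    gtT <- .normGT(test$genotype[ti])
    gtU <- .normGT(truth$genotype[ui])
    concord <- alleleMatch & gtT == gtU
    list(nSitesCompared = length(shared),
         genotypeConcordance = if (length(shared)) mean(concord)
                               else NA_real_,
         sensitivity = sum(concord) / nrow(truth),
         precision = sum(concord) / nrow(test),
         confusion = table(truth = gtU, test = ifelse(alleleMatch, gtT,
                                                      "allele_mismatch")),
         undefined = length(shared) == 0L)
}

#' Write a variant table as VCF
#'
#' Emits a minimal single-sample VCF 4.2 with the table's `filter`
#' column in FILTER and the consumed annotations in INFO/FORMAT.
#'
#' @param records Variant table (see [readVariantTable()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(records, path) {
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias score\">",
        "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of MQ0 reads\">",
        "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
        "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
        paste0("##FILTER=<ID=", .FILTER_RULES,
               ",Description=\"Failed ", .FILTER_RULES, " rule\">"),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
    fmtNum <- function(x) ifelse(is.na(x), NA, sub("\\.?0+$", "",
        formatC(x, format = "f", digits = 4)))
    info <- vapply(seq_len(nrow(records)), function(i) {
        kv <- c(DP = as.character(records$DP[i]),
                SB = fmtNum(records$SB[i]),
                MQ0F = fmtNum(records$MQ0F[i]),
                MAF = fmtNum(records$MAF[i]),
                R2 = fmtNum(records$R2[i]))
        kv <- kv[!is.na(kv)]
        if (length(kv)) paste(names(kv), kv, sep = "=", collapse = ";")
        else "."
    }, character(1))
    gt <- ifelse(is.na(records$genotype), "./.", records$genotype)
    gq <- ifelse(is.na(records$GQ), ".", as.character(records$GQ))
    filt <- if ("filter" %in% names(records))
        ifelse(is.na(records$filter) | records$filter == "",
               ".", records$filter)
    else rep(".", nrow(records))
    id <- if ("id" %in% names(records) && !all(is.na(records$id)))
        ifelse(is.na(records$id), ".", records$id)
    else rep(".", nrow(records))
    body <- paste(records$chrom, records$pos, id, records$ref,
                  records$alt, ".", filt, info, "GT:GQ",
                  paste(gt, gq, sep = ":"), sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}
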