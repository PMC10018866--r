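# bslink

Linked bisulfite read-pair analysis of GpC methyltransferase footprints.

Bisulfite-converted Hi-C libraries treated with the GpC methyltransferase
*M.CviPI* read out four signals from the same DNA molecule: spatial
proximity (the two ends of a read pair), chromatin accessibility (GCH
methylation laid down by the enzyme on open chromatin), endogenous CpG
methylation (HCG/WCG sites), and genetic variants. `bslink` implements
the downstream computational core for such data:

- **Context indexing** — strand-aware classification of every reference
  cytosine into GCG / GCH / WCG / CCG / WCH / CCH. GCH reports the
  accessibility footprint, WCG+CCG (= HCG) endogenous methylation, GCG
  is ambiguous and excluded, and residual WCH methylation flags
  incomplete bisulfite conversion. In-silico C→T / G→A reference
  conversion and GC-content utilities (compartment-eigenvector
  orientation) are included.
- **Read-pair extraction** — per-read methylation calls from SAM/BAM with
  the standard filters (mapQ > 30 on both ends, base quality > 5, PCR
  duplicates removed, incompletely converted reads dropped at ≥ 3
  methylated WCH), and classification of pairs as long-range cis
  (separation > 20 kb), short cis, or trans.
- **Long-range concordance** — for read pairs linking two chromatin loop
  anchors, each molecule contributes one point: the GCH (or WCG)
  methylation fraction of its two ends (≥ 3 sites per end). Coordination
  is measured by the Pearson *r* of these points, by the Phi coefficient
  after binarizing at 0.5, and by the tetrachoric correlation
  (maximum-likelihood latent binormal). The null shuffles end-2 summaries
  among pairs of the same anchor group — preserving every anchor's mean
  footprint exactly — 100 times, and observed vs shuffled *r* are
  compared with Fisher's (1925) *z*:
  `z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))`.
  A matched short-range local control (same anchor, ≤ 1 kb, ≤ 100
  sampled pairs per anchor) gives the reference concordance level.
- **Allele-specific footprints** — read pairs with one end on a
  heterozygous SNP are split by allele (respecting bisulfite
  confounding: C/T SNPs are unreadable on OT reads, G/A on OB reads);
  pooled GCH methylated/unmethylated counts by allele at the SNP end and
  at the distal mate end (> 20 kb) form two 2×2 tables per locus, tested
  with Fisher's exact test and BH-corrected. Loci are classed GROUP1
  (allelic at both anchors, FDR < 0.05), GROUP2 (SNP anchor only, distal
  FDR > 0.95) or GROUP3 (distal anchor only).
- **Bisulfite genotype post-filtering** — the quality rules for raw
  bisulfite genotypes (GQ ≤ 20; depth > 250×; strand bias > −0.02;
  depth > 40× with > 10% MQ0 reads; GQ/depth < 1; SNP cluster within
  ±10 bp), post-imputation QC (biallelic, MAF > 1%, R² > 0.3), Ti/Tv and
  genotype-concordance summaries.
- **Simulator** — seeded generation of references, loop anchors, aligned
  read pairs whose two ends carry correlated latent open/closed states
  (bivariate Bernoulli: marginal `piOpen`, correlation `rhoLatent`;
  emission `pOpen`/`pClosed` per GCH site), planted allele-specific
  loci, and crafted variant tables. Every stage of the pipeline is
  testable at desk scale against this known truth.

## Worked example

Simulate a dataset with planted footprint coordination
(`rhoLatent = 0.6`) at 20 loop-anchor pairs, extract filtered linked
pairs, and test long-range concordance against the mean-preserving
shuffle null:

```r
library(bslink)

cfg <- simulationConfig(seed = 7, genomeLength = 1e6, nAnchorPairs = 20,
                        nPairsPerAnchor = 100, nLocalPairsPerAnchor = 30)
sim <- simulateLinkedReadPairs(cfg)
pairs <- loadLinkedPairs(sim$records, sim$index)
pairs
#> LinkedPairs with 2600 retained read pairs
#>   classes: CIS_LONG=2000 CIS_SHORT=600 TRANS=0
#>   methylation calls: 164841

res <- runLongRangeConcordance(pairs, sim$anchors, seed = 7)
res
#> ConcordanceResult (GCH, 2000 read pairs)
#>   observed:  r=0.4452 phi=0.4684 tetrachoric=0.6717
#>   shuffled:  mean r=0.0036 over 100 replicates (seed 7)
#>   Fisher z:  z=15.015, two-sided p=5.89e-51
#>   local control: r=0.7242 (n=600)

round(contextDensity(sim$index, "GCH"), 1)
#> [1] 14.4
```

Reading: the 2000 long-range molecules show strongly coordinated
footprints between their two anchors (r = 0.45, approaching the local
same-anchor control of 0.72), while shuffling molecule links — with
every anchor's mean footprint held fixed — abolishes the correlation
(mean shuffled r = 0.004); Fisher's z rejects equality at p ≈ 6e−51.
The planted latent correlation (0.6) exceeds the observed r because
per-site emission noise attenuates the per-read fractions. One GCH site
per ~14 bp on this reference is what makes the per-read fraction
informative.

A command-line front end wrapping the same functions is installed at
`inst/cli/bslink.R` (subcommands `contexts-index`, `contexts-density`,
`calls`, `concordance`, `allelic`, `variants-filter`, `variants-titv`,
`variants-concordance`, `simulate`).

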