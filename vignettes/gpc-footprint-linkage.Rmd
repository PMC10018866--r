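---
title: "Long-range GpC footprint linkage: models and methods"
author: "bslink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-range GpC footprint linkage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bslink` analyses bisulfite-converted Hi-C read pairs from GpC
methyltransferase (*M.CviPI*) treated nuclei. Because the enzyme
methylates GpC cytosines only where chromatin is accessible, and the two
ends of a Hi-C pair come from one DNA molecule, the joint methylation
state of the two ends carries single-molecule information about the
coordination of regulatory activity at loci far apart in sequence but
close in space. This vignette documents the models, the parameter
choices, the numerical decisions, and the calibration analyses behind
the package; it is the design record a maintainer should read first.

## Cytosine contexts

Bisulfite sequencing reads cytosine methylation; in GpC-footprinted
libraries a cytosine's trinucleotide context decides which signal it
carries:

* **GCH** (preceded by G, not followed by G; H = A/C/T): exogenous
  GpC methyltransferase footprint, i.e. accessibility.
* **HCG**, partitioned into **WCG** (W = A/T) and **CCG**: endogenous
  CpG methylation. CCG can carry residual CpC methyltransferase
  activity, so `contextDensity()` and the extraction layer expose an
  `excludeCCG` switch; the default keeps CCG inside HCG.
* **GCG**: ambiguous between the two enzymes — indexed and called, but
  excluded from both GCH and HCG summaries.
* **WCH**: carries neither signal; because it should always convert,
  residual WCH methylation flags incomplete conversion (see below).

Both strands are indexed: a forward-strand G is a minus-strand cytosine
and is reported at the G's forward coordinate with strand `-`, the
pileup convention. Cytosines with an N flank or at a chromosome edge
are `UNCLASSIFIED` and never counted. Internally all coordinates are
1-based closed, the GRanges/IRanges convention; 0-based half-open
appears only at the BED/BEDPE boundary. On an i.i.d. simulated
reference GCH and HCG densities coincide by symmetry (both are
`P(G)·P(C)·P(H)` patterns); the large GCH/HCG density gap of real
mammalian genomes comes from CpG depletion, which the simulator does
not emulate.

## From alignments to linked pairs

`loadLinkedPairs()` trusts the aligner and upstream duplicate marking
and applies the standard filter stack: primary alignments only, mapQ
strictly above 30 on both ends, duplicate pairs dropped, base quality
strictly above 5 per call. The conversion strand is read from a SAM tag
(default `XG`, values `CT`/`GA`); if absent it is inferred from the
read's C vs G depletion. OT (`CT`) reads report forward-strand
cytosines (C = methylated, T = unmethylated), OB (`GA`) reads report
minus-strand cytosines (G/A). A read with three or more methylated WCH
calls is treated as incompletely converted and its pair is removed; the
threshold is a count, not a fraction, chosen to tolerate sporadic
conversion failure (at the default 0.5% per-site failure rate a 150 bp
read carries ~25 WCH sites, so P(≥3 failures) is negligible) while
rejecting unconverted molecules outright (which methylate essentially
every WCH). Pair separation is the outermost span of the two ends — the
molecule's insertion size — and pairs above 20 kb are `CIS_LONG`, the
unit of all long-range analyses.

## Long-range concordance

Each qualifying `CIS_LONG` pair at a loop-anchor pair contributes one
point `(x, y)`: the GCH methylation fractions of its two ends, each
from at least `minSites = 3` calls (fractions from fewer sites are too
granular). Points are pooled across anchor pairs — each dot is one
molecule, not one anchor — and summarised three ways:

* Pearson *r* of the fractions;
* the **Phi coefficient**: Pearson on the fractions dichotomized at
  0.5 (values exactly 0.5 map to 1), with the 2×2 table returned;
* the **tetrachoric correlation**: the latent-binormal correlation
  maximising the likelihood of that table. With thresholds fixed at the
  observed margins this reduces to solving `P(Z1>a, Z2>b; rho) = n11/n`,
  done by `uniroot` on the bivariate normal tail (`mvtnorm::pmvnorm`
  with the deterministic TVPACK algorithm, tolerance 1e-10). Tables
  with a zero cell get 0.5 added to every cell; zero margins are an
  error. The closed-form cosine approximation
  `cos(pi/(1+sqrt(ad/bc)))` is available via `method = "cosine"`.

**The shuffle null.** To show that concordance reflects the molecule
link rather than anchors having similar mean accessibility, end-2
summaries are permuted among the pairs of each anchor-pair group, 100
times, seeded. Because a permutation only reorders the same multiset,
every anchor's mean footprint is preserved *exactly* in every
replicate — the test suite asserts multiset identity, not numerical
closeness. Grouping by anchor pair is the default (the tightest null);
grouping by the anchor containing end 2 is available via
`shuffleWithin = "anchor"`.

**Fisher's z and the effective null n.** Observed and mean-shuffled *r*
are compared with the independent-groups z statistic. What n to assign
the shuffled group is genuinely open; both options are exposed:

* `nullN = "matched"` (default): `n2 = n1`. The statistic then assumes
  variance `2/(n-3)` for the difference, while the true variance is
  close to `1/(n-3)` — the mean over 100 replicates is nearly
  noise-free — so the p-value is conservative by roughly a factor
  `sqrt(2)` on the z scale. This is the safe choice for headline
  significance claims.
* `nullN = "pooled"`: `n2 = n1 × nShuffles`, whose assumed variance
  `1/(n1-3) + 1/(100·n1-3)` matches the truth; under a null simulation
  the resulting p-values are uniform. The acceptance suite verifies
  calibration in this mode and the `|r_obs − r_shuffled|` bound in the
  default mode.

**Local control.** Pairs with both ends in one anchor and separation
≤ 1 kb, sampled to at most 100 per anchor (seeded), give the
short-range reference level that long-range concordance is read
against. Degenerate statistics (zero variance, degenerate margins)
return explicit errors at the operation level and become `NA` fields,
never silent zeros, in `ConcordanceResult`.

## Allele-specific footprints

Pairs with one end covering a heterozygous SNP are split by allele.
Bisulfite chemistry confounds some assignments: on an OT read an
unmethylated C reads as T, so a C/T SNP is unreadable (and G/A on OB
reads); those reads are `UNASSIGNABLE`, never guessed. For each SNP
with ≥ 2 assigned reads per allele and mate ends beyond 20 kb, pooled
GCH methylated/unmethylated counts by allele form one 2×2 table at the
SNP ends and one at the distal ends; each is tested with a two-sided
Fisher exact test (`dhyper`-based, the conventional `1+1e-7` tie
tolerance; `stats::fisher.test` serves as an independent cross-check in
the tests, and a brute-force enumeration oracle covers all tables with
total ≤ 40). BH correction is applied separately per anchor class
across tested loci (jointly via `jointFdr = TRUE`), and loci are
labelled GROUP1/2/3 by the FDR < 0.05 / FDR > 0.95 rule. In allelic
mode a single GCH call per end suffices (`minGchPerEnd = 1`), unlike
the 3-site rule of the concordance analysis.

**Pseudo-replication, and what the FDR rules can and cannot deliver.**
The default Fisher unit is the pooled GCH *call*. Calls on one read are
not independent — the read's latent open/closed state is shared — so
pooled counts are overdispersed relative to the hypergeometric model
(variance factor ~2.4 at the simulator defaults) and null-anchor
p-values are anti-conservative. A per-read unit (`unit = "reads"`,
reads dichotomized at fraction 0.5) restores validity and is the right
choice for calibration-sensitive work; the pooled unit is kept as the
default for continuity with field practice. Two structural consequences
are worth recording. First, the GROUP2/GROUP3 definition requires
BH-adjusted FDR > 0.95 at the null anchor; for continuous-ish null
p-values embedded in a vector with many tiny p-values, adjusted values
above 0.95 are rare (the adjusted value of a null locus is
`min_j m·p_(j)/j` over larger ranks, which concentrates near but below
1), so with well-powered loci most truly-GROUP2/3 loci are labelled
NONE. The rule effectively selects loci whose null-anchor p is at or
near exactly 1 — which happens frequently only at very low coverage,
where Fisher's p is strongly discrete. Second, under the pooled-call
unit some GROUP2/3 loci leak into GROUP1 through the anti-conservative
null-anchor p. The test suite therefore asserts what the design can
deliver — near-perfect GROUP1 recovery and zero GROUP2↔GROUP3
swaps — and records the full-recovery shortfall openly. The type-I
calibration test runs in the i.i.d.-call regime (`pOpen = pClosed`),
where the exact test's assumptions hold.

## Variant post-filtering

Raw bisulfite genotypes are annotated with every failed rule: GQ ≤ 20,
depth > 250×, strand-bias score > −0.02 (the upstream caller's signed
score is consumed, not recomputed; more negative = less biased),
depth > 40× with MQ0 fraction > 0.1, GQ/depth < 1, and a second SNP
within ±10 bp (all members of a cluster fail, symmetric by
construction). Records missing an annotation skip that rule with a
counted warning. Post-imputation QC keeps biallelic SNPs with
MAF > 1% and R² > 0.3. Ti/Tv (transitions A↔G, C↔T over the rest) and
genotype concordance (join by chromosome, position and alleles; allele
mismatches are discordant; optional confident-region mask) summarise
call quality.

## The simulator

The generator is the package's fixture source and defines the study
conditions; its defaults were chosen once, on first principles:

| parameter | default | rationale |
|---|---|---|
| `gcFraction` | 0.42 | human-like GC content |
| `readLength` | 150 | paired-end 150 sequencing |
| `anchorSpan` / `minAnchorSeparation` | 1000 / 20001 bp | loop-anchor scale; every anchor pair beyond the 20 kb long-range cut |
| `piOpen` | 0.5 | maximally informative marginal; no feasibility constraint on rho |
| `pOpen` / `pClosed` | 0.8 / 0.2 | strong but noisy footprint emission |
| `rhoLatent` | 0.6 | clearly detectable coordination at desk scale |
| `endoHcgMeth` | 0.75 | typical bulk CpG methylation |
| `conversionFailure` | 0.005 | typical non-conversion rate |
| `sequencingError` | 0.001 | Illumina-scale substitution rate |

Each molecule draws latent end states from a bivariate Bernoulli
(`p11 = pi^2 + rho·pi(1−pi)`, feasibility checked), emits per-site
methylation, converts (unmethylated C→T, or G→A on OB molecules;
failures stay unconverted; whole molecules escape conversion with
`pFailedMolecule`), applies substitution errors, and is emitted as two
pre-aligned pure-match SAM records tagged with the conversion strand.
Read placements are resampled until the window holds ≥ 3 GCH sites.
Allelic datasets plant an A/T SNP (assignable on both conversion
strands) at each SNP-anchor centre, write the REF base into the
reference, and draw per-allele open probabilities (0.9 vs 0.1 at
affected anchors, background `piOpen` elsewhere). Identical config and
seed give identical bundles; the RNG state of the caller is restored
afterwards.

What the simulator does **not** emulate — and hence what green tests do
not certify on real data: CpG-island structure and CpG depletion,
indels and soft-clipping (the caller handles arbitrary CIGARs via
reference-space projection, but fixtures are pure-match), mappability
and duplicate structure (flags are planted, not arisen), chromatin
domains beyond the two-state open/closed model, and linked phasing of
nearby SNPs.

## Problem sizes and runtime

The test and acceptance runs use 1 Mb genomes, 20 anchor pairs × 100
molecules (2000 long-range pairs) for concordance, 20 seeds for null
calibration, 90 planted loci × 50 pairs per allele for allelic
recovery, 500 counts-level loci for type-I calibration, and the
exhaustive Fisher sweep over all 135,751 tables with total ≤ 40 —
sizes at which every check completes in seconds to a few minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The concordance observed/shuffled comparison treats the mean shuffled
  r as a fixed quantity in the default mode; see the effective-n
  discussion above.
* Allelic analysis pools all qualifying distal mates of a SNP into one
  table; a per-partner-region mode would be needed to resolve multiple
  distinct distal partners of the same SNP.
* The strand-bias and MQ0 annotations are consumed from the upstream
  caller; their definitions travel with it.
* No imputation, phasing, loop calling or RNA quantification — those
  stages live upstream or downstream of this package.
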