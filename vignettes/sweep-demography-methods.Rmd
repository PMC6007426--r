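---
title: "Methods: sweep scanning and SFS demography in SweepDemes"
author: "SweepDemes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning and SFS demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SweepDemes implements the post-variant-calling half of a population-genomic
study of animal domestication: variant QC, sliding-window diversity and
differentiation scans with joint outlier calling, discovery of
phenotype-diagnostic fixed variants, folded joint site-frequency-spectrum
(SFS) demographic inference across competing domestication scenarios, and a
structured-coalescent generator that supplies synthetic cohorts with ground
truth for every stage. This vignette records the models, conventions and
numerical choices behind each component. It states no empirical result; all
quantitative claims about the implementation are exercised by the test
suite and by `scripts/acceptance.R`.

## Data model

A cohort is a `VariantCohort` (an extension of `RangedSummarizedExperiment`):
a `GRanges` of biallelic sites carrying REF/ALT alleles, the variant class
(SNP or 1–50 bp INDEL), and the standard site QC annotations (QUAL, QD, FS,
MQ, MQRankSum, ReadPosRankSum, DP); a genotype assay coded as alternate
allele dosage 0/1/2 with `NA` for missing; optional per-sample depth
assays; and per-sample population and group labels in `colData`.
Coordinates are 1-based inclusive at the VCF interface and 0-based
half-open for window arithmetic; `makeWindows()` is the single point of
conversion. Multiallelic records are split into one biallelic record per
alternate allele with genotypes recoded as dosage of that allele — every
downstream statistic is defined for biallelic sites, and splitting (rather
than dropping) retains information; this is a package choice, documented
rather than asserted as the originating pipeline's. Half-calls such as
`0/.` are treated as fully missing, the simplest defensible convention.

## Variant QC

Hard filters apply the stringent GATK-style thresholds: SNPs must satisfy
QUAL > 30, QD > 5, FS < 60, MQ > 40, MQRankSum > −12.5 and
ReadPosRankSum > −8; INDELs must satisfy QUAL > 30, QD > 5, FS < 200 and
ReadPosRankSum > −20. All inequalities are strict; a record missing an
annotation passes that criterion by default (with a warning), because
synthetic fixtures may omit annotations the calling pipeline guarantees —
a switch drops them instead.

The cluster rule removes every SNP belonging to a set of more than three
SNPs spanning at most 10 consecutive bases, evaluated over sliding (not
disjoint) windows: a SNP is removed if any 10-bp interval containing it
holds four or more SNPs. The allele-depth rule removes a variant when its
summed alternate-read depth over genotype-carrying samples is less than
half the summed site depth over the same carriers, with the boundary kept
at equality; whether the original rule was per sample or per site is
ambiguous, so the per-sample variant is available behind a switch
(`perSample = TRUE`) and the aggregate form is the default. The
population-structure site filter keeps SNPs with minor allele frequency
strictly above 0.1 and call rate strictly above 90%.

## Windowed statistics

Windows are 10 kb with a 5-kb shift (defaults), placed wholly within
scaffolds strictly longer than 10 kb. Per-site nucleotide diversity is
π = 2j(n−j)/(n(n−1)) over called haplotypes; windowed π sums sites and
divides by the full window length — the convention of VCFtools'
`--window-pi`, chosen because the denominator question (window length vs
callable sites) is not settled by the source pipeline; it is isolated in
one function. Missing genotypes reduce the per-site n; nothing is imputed.

Differentiation is Weir & Cockerham's (1984) θ̂ from the a, b, c variance
components, windowed as the ratio of sums Σa / Σ(a+b+c) — not the mean of
per-site ratios, which is a different (and worse) estimator; a regression
test pins this choice. Negative θ̂ is retained so the genome-wide Z
distribution matches the estimator's support; windows with an undefined
denominator are excluded from quantiles and Z-standardization. Z(FST)
standardizes by the empirical mean and (sample) standard deviation of the
defined window values, both reported.

## Sweep scan

The scan contrasts a wild group with a domesticated group: windows in the
upper q tail of both Z(FST) and log2(π_wild/π_domestic) are selected
(q = 0.05 or 0.01). Thresholds are nearest-rank order statistics over
defined windows, with selection inclusive at the threshold so ties widen
the set — deterministic and conservative toward inclusion. Selected
windows that overlap or are book-ended merge into sweep regions, keeping
peak statistics; genes are assigned by ≥ 1 bp overlap (not midpoint). Both
merged-region and raw-window gene counting are available, since which one
produced the published gene count is not stated. Diagnostic variants
require every called sample of one phenotype group homozygous for one
allele and every called sample of the other group homozygous for the other
— "absent" is interpreted as fixed-for-the-alternative-state — with a
`minCalled` floor per group because synthetic cohorts, unlike the original
complete panel, contain missing genotypes.

## Folded joint SFS

Projection to m haplotypes is the hypergeometric expectation over
subsamples (`dhyper`), accommodating missing data; sites with fewer called
haplotypes than the projection in any population are skipped and counted.
The joint spectrum is folded on the global minor allele across the pooled
populations; cells at exactly 50% global frequency receive half mass in
each mirrored cell — the convention of the diffusion-method ecosystem,
pinned by an executable fixture. The projection search maximizes total
segregating mass over even haplotype counts from 4 to the full sample
size (diploid samples), with ties broken toward the larger projection; the
objective decomposes per site into corner-cell weights, so the search
never builds full spectra. Thinning to a fraction (default 1%, to
alleviate linkage between markers) is seeded uniform sampling without
replacement; a systematic every-k-th mode exists because the original
choice between the two is unstated. Noncoding-region restriction is a
BED-mask intersection (`subsetByMask`), not annotation parsing.

## Demographic inference

Four domestication scenarios are parameterized in diffusion-style scaled
units (sizes ν relative to the ancestral reference N_ref; times in 2N_ref
generations; migration M = 2N_ref·m): (1) simultaneous domestication of
both breeds; (2) one domestication founding an ancestral domesticated
population that later splits into the meat and egg/dual-purpose breeds;
(3) and (4) two independent domestications with either breed first. All
share a deep ancestral size change and continuous migration from each
breed into the wild population while that breed exists; during model 2's
short shared-domestic epoch no migration is modeled (the epoch spans ~100
years; the two reported migration parameters are tied to the breeds).
Ordering guards reject inconsistent event times (e.g. a breed split older
than domestication).

The expected folded joint SFS is computed by Monte-Carlo structured
coalescent rather than a diffusion PDE solver: for each of n_reps
independent genealogies, every lineage's lifetime accrues to the joint
frequency class of its descendant counts (the branch-length form of the
expected SFS, which is the Rao-Blackwellized version of dropping mutations
and has far lower variance). The per-epoch engine (splits as backwards
merges, piecewise-constant sizes, backwards migration jumps) is compiled
C++ for speed. A fixed seed per optimization gives common random numbers:
the objective is deterministic and smooth in the parameters, so
derivative-free optimization behaves.

Fitting maximizes the Poisson composite log-likelihood
Σ[o·ln μ − μ − ln o!] over unmasked cells, with the overall scale θ̂
profiled analytically as Σo/Σe per evaluation; k in AIC = 2k − 2logL
counts the explicitly optimized parameters (θ̂ being profiled). Multi-
parameter fits use Nelder-Mead on log-transformed parameters with
independent restarts (10 by default, mirroring repeated independent
starts; convergence is flagged when the best two agree, and flagged — not
raised — otherwise); single-parameter fits use Brent/golden-section.
Real-unit conversion uses N_ref = θ̂/(4μL) with μ = 1.191 × 10⁻⁹ per bp
per generation and a 1-year generation: sizes ν·N_ref individuals, times
T·2N_ref years, migration M·ν_recipient/2 migrants per generation (the
recipient of both migration parameters is the wild population; the
convention is pinned by a fixture). Uncertainty comes from a
scaffold-block percentile bootstrap with refits — chosen over an
information-matrix approach because it needs no analytic score and its
coverage is testable.

One reported value is knowingly not reconcilable: published AIC and
log-likelihood values for this kind of analysis cannot be made consistent
with an integer parameter count, so the package reports its own AIC
arithmetic and does not attempt to reproduce that pair.

## The synthetic-data generator

The generator emulates the study design: nine populations (two wild
mallard, three meat, three egg, one dual-purpose; 8 diploids each, 14 for
the second wild population) sampled from three demes, under a default
demography with a large wild population (N_e 88,842), an ancestral size
change (663,439 at 249,944 years), a domestication bottleneck (N_e 320 at
2,228 years) followed ~100 years later by the breed split (2,126 years),
expansion to current breed sizes (5,597 and 12,988), and gene flow of 1.12
and 3.92 migrants per generation from the breeds into the wild
population. The reference size N_ref = 100,000 (the pre-size-change
ancestral size) is the generator's own choice — the scaled analysis
determines only ratios, so some anchor must be fixed — and all other
values follow from it.

Windows (10 kb by default) are genealogically independent, with complete
linkage within a window: sufficient for SFS and window statistics while
avoiding ancestral-recombination-graph machinery. This is the key
simplification relative to real data — real linkage decays continuously,
so real window statistics are more autocorrelated along scaffolds than
simulated ones, and passing tests say nothing about intra-window
recombination effects. Sweeps are emulated by dividing the domestic demes'
coalescent sizes by a factor f ≥ 1 inside the swept span — one
interpretable parameter producing the diversity-reduction and
differentiation-elevation signature the scan targets — rather than by
explicit selection trajectories; hard-sweep haplotype structure is not
reproduced. Mutations are infinite-sites with θ = 4·N_ref·μ·L per window;
REF/ALT alleles are synthesized, with a configurable fraction of INDELs
whose geometric length distribution makes 1-bp INDELs predominant
(qualitatively matching resequencing data; the exact fraction is a
real-data quantity and not matched). QC annotations are drawn from passing
ranges so the hard filters are exercisable, with a switch to inject
failing values; synthesized het allele depths give the alternate allele at
least half the reads so the depth rule passes by construction. Diagnostic
loci are injected as variants fixed homozygous in one plumage group and
absent in the other, shifting to the next free position on collision.
Everything derives from one mandatory seed through a single RNG stream
(the C++ engine draws from R's RNG), so equal seeds give byte-identical
VCFs.

## Problem sizes used in the checks

The test suite and acceptance script keep the simulations at desk scale,
as the package's own study design: estimator-oracle equivalence uses 1,000
random sites; neutral calibration uses hundreds of independent loci;
sweep recovery uses a 5-Mb genome (500 simulation windows, 78 diploids,
three 30-kb sweeps at f = 10); model selection uses 20 replicate spectra
of 1e5 SNPs fit under all four scenarios; parameter recovery profiles one
parameter at a time on a 1e5-SNP spectrum at projections (16, 16, 16),
with 1e5 genealogies per likelihood evaluation (8e5 for the wild size and
migration parameters, whose likelihoods are nearly flat). Monte-Carlo
noise in the expected spectrum is the main accuracy limit for those two
flat parameters; the chosen replicate counts put it well inside the
published confidence intervals while keeping the full run in minutes.

## Known limitations

No intra-window recombination and no haplotype-based statistics (iHS,
XP-EHH); no phasing; structural variants beyond 50-bp INDELs are out of
scope; ancestry/admixture estimation and likelihood-based trees are not
implemented (the tree module is distance-based neighbor joining only — the
original description conflates neighbor joining with maximum likelihood,
and NJ is what the distance matrix supports); the composite likelihood
treats SFS cells as independent Poisson counts, so its likelihood-ratio
scale is not calibrated for hypothesis tests — it is used only for point
estimation and AIC ranking, with uncertainty from the block bootstrap.
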