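---
title: "Local-ancestry-aware methylation analysis: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-ancestry-aware methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

DNA methylation differs systematically between ancestral populations, and
in admixed groups such as African Americans the ancestry of any one
genomic segment varies from person to person and from locus to locus.
Self-reported race and even genome-wide (global) ancestry are blunt
summaries of this variation. `admixmeth` implements an analysis chain
that works at the resolution of *local ancestry* (LA): the ancestral
origin (African or European) of each haplotype segment, summarized at
every CpG site, used first as the exposure of an epigenome-wide
association scan (EWAS) and then as the backbone of a cis-meQTL model in
which a SNP's effect on methylation may differ depending on which
ancestral background carries the allele.

## Ancestry features

Per-SNP local ancestry calls (two per individual, one per haplotype) are
summarized at a CpG as a weighted average of African-haplotype dosages
over SNPs in a flanking window:

$$ LA_{ij} = \sum_{k \in W(j)} w_k \frac{d_{ik}}{2}, \qquad
   w_k \propto \frac{1}{\max(|pos_k - pos_j|, 1)}, \; \sum_k w_k = 1, $$

where $d_{ik} \in \{0,1,2\}$ counts African-origin haplotypes of
individual $i$ at SNP $k$. The window argument is the *total* span: the
default 1 Mb means ±500 kb around the CpG, closed at both ends. Weights
use physical (bp) distance; a SNP at the exact CpG coordinate is given a
1 bp distance so weights stay finite. LA is kept on the proportion scale
in $[0,1]$; effects "per 25% increase in local African ancestry" are the
regression coefficient times 0.25. Global ancestry (GA) is the unweighted
genome-wide mean of local African dosage, which tracks the individual's
true admixture proportion almost perfectly once tens of Morgans of genome
are averaged (the package's acceptance checks require $r > 0.99$ on a
35-Morgan simulated genome).

Hard ancestry calls are assumed. If posterior probabilities are supplied
instead, they pass through the same arithmetic as fractional dosages.

## Two-stage EWAS

For each ancestry variable (self-reported race on all samples; GA and LA
on the admixed subset only, LA additionally adjusted for GA) the scan is
ordinary least squares per CpG on the methylation M-value,
$M = \log_2 \beta/(1-\beta)$, which is approximately homoscedastic where
the beta-value is not:

* stage 1 regresses every CpG on all covariates *except* the tested
  ancestry variable (age, smoking, alcohol, adherence, viral load,
  white-cell count, six cell-type proportions, and the first 30
  principal components of control-probe intensities) and takes the top 5
  principal components of the stacked residuals;
* stage 2 adds those residual PCs to the design and tests the ancestry
  coefficient with a two-sided t test.

Genomic inflation is summarized as
$\lambda = \mathrm{median}(\chi^2_{obs}) / \chi^2_{1}(0.5)$ on the
ancestry p-values only. PC signs are fixed (largest-magnitude loading
positive) so repeated runs are bit-identical. Listwise deletion is used
per CpG; no imputation of covariates or dosages.

A caution that matters at small scale: the residual-PC stage assumes
ancestry-associated CpGs are a negligible fraction of the array. In
simulations where 3–10% of CpGs carry a strong LA effect, the residual
PCs themselves pick up the shared ancestry factor and the race/GA scans
become conservative (the LA scan is less affected because its exposure
varies CpG by CpG). This is a property of the two-stage design, not a
bug; the package's simulated analyses therefore read the LA scan as the
primary one.

Thresholds are never hard-coded: the discovery cutoff is a configured
constant (default 1.16e-7, the conventional epigenome-wide level for a
~437k-probe array; desk-scale analyses pass `0.05 / n_cpgs` instead), and
every replication cutoff is `alpha / m` with `m` recomputed from the
count of discovery hits. Replication additionally requires a concordant
direction of effect, and untestable probes stay in the denominator of the
replication percentage by default.

## Ancestry-decomposed meQTL models

For each CpG–SNP pair with the SNP inside the CpG's window, three nested
least-squares models share a covariate block that always includes the
CpG's LA (to control confounding by ancestry background):

| model | genetic terms |
|---|---|
| null | none |
| conventional | $b_{SNP} \cdot SNP$ |
| ancestry | $b_{AFR} \cdot SNP_{AFR} + b_{EUR} \cdot SNP_{EUR}$ |

$SNP_{AFR}$ and $SNP_{EUR}$ are alternate-allele counts on African- and
European-origin haplotypes; they sum to the ordinary dosage, exactly, and
that identity is asserted on every fit. The ancestry model is identical
to the reparameterization
$b_{average} \cdot SNP + b_{diff} \cdot (SNP_{AFR}-SNP_{EUR})/2$ with
$b_{average}=(b_{AFR}+b_{EUR})/2$ and $b_{diff}=b_{AFR}-b_{EUR}$ — same
fitted values and residual sum of squares to numerical precision, which
the test suite checks at 1e-10. Inference is by nested F tests from the
recorded RSS and df: conventional vs null (1 df) for the conventional
meQTL p-value, ancestry vs null (2 df) for the ancestry meQTL p-value,
ancestry vs conventional (1 df) for the ancestry-difference test, whose p
equals the squared-t test of $b_{diff}$.

Count-derived thresholds again: the meQTL cutoff is `alpha` over the
number of pairs tested; the $b_{diff}$ cutoff is `alpha` over the number
of ancestry-model-significant meQTLs. Where different printed constants
could be derived for the same quantity, this package always recomputes
`alpha / count` from the counts it actually observed, so the constants
generalize to any input size.

Significant meQTLs are labelled by the pattern of their per-ancestry
effects: `comparable` when the difference test is not significant;
otherwise `opposite`, `same_direction_diff_magnitude`, `african_only` or
`european_only` according to the per-coefficient t tests at
$\alpha = 0.05$ (a deliberate, documented choice — nothing in the model
itself dictates the per-ancestry significance level) and the signs. A
SNP whose alternate allele was never observed on one ancestral background
makes the decomposed design collinear; the pair is flagged `inestimable`
for the ancestry model while the conventional model still fits.
Decomposed columns with fewer than 3 carriers are flagged low-confidence
rather than dropped.

## Clumping

Significant meQTLs for a CpG are collapsed into loci by PLINK-style
greedy seeding: the lowest-p unassigned SNP seeds a clump and captures
all unassigned SNPs with dosage $r^2 \ge 0.01$ to it (composite-genotype
LD, i.e. squared Pearson correlation of unphased dosages in the analysis
cohort itself — no reference panel). Clumps with fewer than 10 SNPs, or
whose boundary lies within 250 kb of another clump's boundary, are
merged into the nearest clump (smallest boundary gap; ties broken by
lower lead p), iterated to a fixed point; the least-significant flagged
clump merges first so the procedure is deterministic. The lead SNP is the
lowest-p member, re-identified after every merge. Clumping is per-CpG by
default with a pooled global mode available.

## Enrichment

Positional enrichment compares annotation coverage of the significant
CpG set against the universe of tested CpGs over 11 categories (3'UTR,
Body, 1st exon, 5'UTR, TSS200, TSS1500, CpG island, N/S shore, N/S
shelf). The fold change is the ratio of coverages; the p-value is
hypergeometric in the tail matching the fold-change direction (upper for
enrichment, lower for depletion), adjusted by Benjamini–Hochberg across
the 11 categories. Probes missing an annotation are excluded from both
numerator and denominator for that category; probes with several
annotations count in each. Trait enrichment takes a user-supplied
trait-to-CpG catalog (no remote lookups), tests the 2×2 overlap table per
trait with a plain Fisher exact test — a deliberately unweighted variant,
labelled as such — and Bonferroni-corrects at `alpha` over the number of
traits with nonzero overlap.

## Variant QC

SNPs enter the analysis only if MAF ≥ 0.01, call rate ≥ 95%, imputation
r² ≥ 0.8 (skipped when absent), and exact Hardy–Weinberg p ≥ 1e-6, with
indels removed by an allele-length test. The HWE test is the
Levene–Haldane exact test (heterozygote-count distribution conditional on
allele counts) rather than the chi-square approximation, because a 1e-6
cutoff lives in the tail where the approximation misbehaves for rare
alleles. Missing genotypes are excluded pairwise from frequency and HWE
computations, and samples missing a genotype are dropped from that SNP's
meQTL fit — no dosage imputation, keeping the ancestry decomposition
exact.

## The simulator

`simulate_cohort()` generates everything downstream of the (out of
scope) genotyping, phasing, and ancestry-inference steps:

* **Tracts.** Each individual draws a global African proportion
  $\theta_i \sim \mathrm{Beta}(2, 0.5)$ — mean 0.8 with an effective
  0.15–1 range, matching the wide admixture spread reported for
  self-identified African-American cohorts. Along each haplotype,
  breakpoints arrive as a Poisson process at rate $g = 7$ per Morgan
  (generations since admixture) and each tract is African independently
  with probability $\theta_i$ (a Pool–Nielsen-style model; real cohorts
  were used in the source studies, so the generative model is this
  package's own choice). The genetic map is uniform unless supplied.
* **Genotypes.** Haplotype alleles are Bernoulli with the allele
  frequency of the tract's population; default frequencies come from a
  Balding–Nichols draw with $F_{st} = 0.15$, clamped to [0.01, 0.99].
* **Covariates.** Age ~ N(49.4, 7.2²), 61% smokers, log10 alcohol
  biomarker ~ N(1.6, 2.3²), 78% adherent, log10 viral load ~ N(2.7,
  1.2²), white-cell count ~ N(5.2, 1.9²) truncated at 0.5, and six
  cell-type proportions from a 7-component Dirichlet (six named types
  plus remainder) so they are nonnegative and sum below 1. Covariates
  are independent of ancestry by default; `confound_theta_age` adds a
  $\theta$–age correlation to exercise adjustment.
* **Methylation.** Causal CpGs follow
  $M = \sum_i b_i x_i + b_{LA} LA + b_{AFR} SNP_{AFR} + b_{EUR} SNP_{EUR}
  + \varepsilon$ with Gaussian noise ($\sigma_\varepsilon = 1$ by
  default); non-causal CpGs get covariates and noise only. The default
  effect registry makes 10% of CpGs causal with $b_{LA} = 3$ per unit LA
  (0.75 per 25%, the scale of strong reported LA–methylation signals)
  and SNP-effect pairs cycling through the canonical patterns
  (0.5, 0.5), (0.5, −0.5), (0.5, 0), (0, 0.5), (0.3, 0.8). Ground truth
  is recorded and round-trips through JSON for recovery tests.
* **Control probes and batch.** Samples alternate between batches;
  control probes load on the batch factor with SD 1, methylation with SD
  0.2, so control-probe PCs have genuine confounding to absorb.

One global seed fans out to fixed per-component substreams, so any stage
can be regenerated in isolation and a full run is byte-reproducible.

What the simulator does *not* emulate: array probe chemistry and
normalization artefacts, cell-type deconvolution error, LD within
ancestral populations (SNPs are independent given ancestry), selection
or demographic detail, three-way or more admixture. Passing tests
therefore demonstrate the statistical machinery under the stated model,
not robustness to every artefact of real arrays.

## Numerical choices and degenerate inputs

Least squares is solved by Cholesky on the normal equations; designs here
are small and well-conditioned, and a factorization failure is reported
as a collinearity error naming the offending columns. F statistics are
clamped at zero against roundoff; monomorphic SNPs get HWE p = 1; an
empty cis window or an all-missing LA window yields a flagged missing
value, never a silent zero; a constant dosage vector has undefined LD and
is treated as r² = 0 with a warning. Beta-values are clipped to
[eps, 1−eps] (eps = 1e-6) before the M transform; eps = 0 turns clipping
off and out-of-range input errors.

## Problem sizes

The bundled analyses and checks run at desk scale, chosen so the full
suite completes in minutes on one core: cohorts of 80–527 individuals,
1–2 simulated chromosomes with a few hundred SNPs, 12–300 CpGs; the
tract-process and GA–LA checks use a 35-Morgan, 17,600-SNP genome with
500 haplotypes; calibration of the ancestry-difference test uses 2,000
simulated pairs of 400 samples, and parameter recovery 200 replicates of
600. Sampling-noise tolerances (3 binomial standard errors for rejection
rates, 2 standard errors for means) follow from those sizes.

## Limitations

Two-way admixture only; autosomes only; hard ancestry calls; fixed-width
cis windows; no trans-meQTL scan, no conditional secondary-signal
analysis, no mixed-model relatedness control, and no SNP-based
heritability estimation (externally computed estimates can be joined to
the output tables). The trait catalog must be supplied locally.
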