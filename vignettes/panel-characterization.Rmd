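---
title: "Characterizing a structured diversity panel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a structured diversity panel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

panelforge takes a collection of inbred crop accessions — the motivating
case is a panel of traditional rice varieties spanning the deeply diverged
*indica* and *japonica* subspecies — from raw marker tables to an
association-ready panel: marker QC, genetic distances and trees,
core-collection selection, model-based population structure, pairwise
differentiation, linkage-disequilibrium decay and mixed-model association
mapping. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open.

## Haploid coding

Everything in the package assumes highly homozygous inbred lines. Each
accession carries a single allele per biallelic locus, stored as 0
(reference), 1 (alternate) or `NA`. Heterozygote codes in input files are
set to missing with a warning; diploid heterozygosity is out of model. This
keeps every downstream statistic simple: allele frequencies are column
means, genotypic r² equals haplotype r², and the admixture likelihood is a
Bernoulli mixture.

## The synthetic panel generator

`simulate_genotypes()` builds panels with known ground truth. Its defaults
describe the study conditions the package is calibrated against: a
182-accession panel with two subspecies pools split into 6 + 4 nested
populations (114 + 62 pure accessions, 6 admixed), 12 chromosomes with one
marker per ~17 kb, and about 10% missing data.

The model has three layers:

1. **Frequencies.** Ancestral allele frequencies are Uniform(`maf_floor`,
   1 − `maf_floor`); each pool drifts from them by a Balding–Nichols Beta
   draw with parameter `pools_fst`, and each population drifts from its
   pool with its own `pop_fst`. For two populations with drift F the
   expected pairwise FST is approximately F, which is how the defaults were
   chosen: per-population drifts of 0.25–0.5 (indica-like pool) and
   0.45–0.6 (japonica-like pool) reproduce the asymmetry of a real
   two-subspecies panel in which the japonica compartment is the more
   strongly differentiated. Founder sampling (below) adds roughly
   (1 − F)/`founder_haplotypes_per_pop` of extra realized drift on top.

2. **Haplotypes.** Each population has a small set of founder haplotypes
   sampled site-wise from its frequencies; each accession copies founders
   along the chromosome, switching to a random founder with per-bp
   probability `switch_rate` (geometric segment lengths, a Li–Stephens-
   style mosaic). This produces within-population LD that decays on a
   physical scale controlled by `switch_rate`. Admixed accessions copy
   from two random populations with a Uniform(0.25, 0.75) mixture weight,
   which is recorded in the returned truth.

3. **Missingness.** Per-marker missing rates are Beta(0.5, ·) distributed
   with mean `missing_rate`, and cells are masked at random within marker.
   GBS missingness is strongly marker-heterogeneous in practice, and the
   structure-subset rule (markers with < 2.5% missing) presumes such
   heterogeneity — under a uniform per-cell rate of 10% essentially no
   marker would qualify.

Planted flowering-time QTLs are restricted to markers that are common
overall (MAF > 0.10) *and* variable within populations (mean within-
population heterozygosity > 0.08). A locus differentially fixed between
populations is collinear with structure, so its effect is unidentifiable
under a structure-corrected association model; planting such a locus would
make any power statement meaningless rather than conservative.
`simulate_phenotype()` rescales components so the realized variance
fractions match the request exactly: the QTL share equals `qtl_variance`
and the population effect has realized standard deviation `pop_effect_sd`
days around a grand mean of 110 days. A waxy endosperm locus (iodine-test
color) and pool-typical grain dimensions are emitted alongside.

What the generator does *not* emulate: coalescent genealogies, selection,
mutation, genotyping error correlated with allele frequency, and linked
(rather than site-wise independent) founder haplotypes across populations.
Tests passing on these panels demonstrate that the estimators recover the
parameters of this generative model; conclusions about real data rest on
the model being an adequate caricature of a structured inbred panel, not on
these tests.

## Marker quality control

For dominant (DArT-style) presence/absence markers the cascade is:
polymorphism, then reproducibility (mismatch rate over replicated samples,
missing comparisons excluded) and the cluster-variance quality index P
(between-cluster over total variance of hybridization intensity, the
one-way ANOVA SS ratio), then call rate. Defaults: P ≥ 0.8,
reproducibility ≥ 0.99, and strictly more than 10% missing data fails.
Identical call vectors — including the missing mask — are collapsed to one
representative per group; matching on shared calls only is available but
not the default, because strict equality is deterministic and never merges
markers that could be distinguished.

For SNP markers the filter drops markers without a mapped position and
markers with strictly more than 20% missing data. Marker diversity is
summarized as PIC = 1 − Σp², the expected-heterozygosity form whose maximum
for a biallelic locus is 0.5; the Botstein variant (max 0.375) is not used,
because observed marker panels of this kind are summarized on the 0–0.5
scale. MAF and PIC are computed on non-missing calls only.

## Distances, trees and core selection

Two dissimilarities are provided: the Sokal–Michener index u/(m+u) for
dominant markers and the shared-allele mismatch proportion for haploid SNPs,
both computed over pairwise-complete loci (support counts are retained).
Trees are classical Saitou–Nei neighbor joining (via ape); negative branch
lengths are clipped to zero with the clipped total recorded, so that
tree-length accounting in the core-selection step stays well defined.

Core selection follows the maximum-length-subtree idea: repeatedly remove
the accession whose loss costs the least total tree length, until the
requested size remains. The default mode prunes the current tree (the loss
is the pendant branch length, ties broken by label order); a slower mode
re-estimates the NJ tree from the distance submatrix for every candidate
removal. The procedure this mirrors is described only verbally in the
literature ("prunes the tree of its most redundant units"), so both
variants are provided; on redundancy-dominated inputs they agree, and exact
duplicates are always removed first at zero loss.

## Population structure

`fit_admixture()` maximizes the haploid admixture likelihood
L = Σ_il log Σ_k q_ik f_kl^x (1 − f_kl)^(1−x) by EM, with missing genotypes
marginalized by omission and frequencies clamped to [1e-6, 1 − 1e-6]. This
is a deliberate methodological substitution: the classical Bayesian MCMC
treatment of the same admixture model is replaced by deterministic
maximum likelihood, with random restarts playing the role of replicate
runs. That preserves the Evanno ΔK workflow — ΔK(K) =
|L(K+1) − 2L(K) + L(K−1)| / sd(L(K)) over replicate log-likelihoods —
because what ΔK needs is a mean and replicate spread of L at each K.
Replicate spread here comes from restart-to-restart differences in the
reached optimum and stopping point; near the true K the restarts agree
closely, sd collapses, and ΔK peaks, which is the same mechanism that
drives ΔK with MCMC replicates. EM stops when the per-iteration
log-likelihood gain drops below `tol` (default 1e-3, at most 2000
iterations); runs hitting the iteration cap are flagged non-converged and
excluded from ΔK, mirroring the discard-non-converged-runs convention.
ΔK is undefined (NA) where the replicate sd is exactly zero.

Markers enter the structure analysis through `subset_markers()`: eligible
markers (< 2.5% missing, strict) are visited in seeded random order and
greedily accepted when ≥ 100 kb from every already-accepted marker on the
chromosome. Accessions are discretely assigned to a population only when
its admixture proportion strictly exceeds 0.75; everything else is
"admixed". DAPC (PCA, then k-means, then LDA on the retained PCs) is
provided as the likelihood-free cross-check; PCs with near-zero
within-group variance are dropped before the LDA to keep the within-group
covariance invertible.

Comparisons of estimated to true Q matrices are made after the best column
permutation (exhaustive at the small K used here), since mixture components
are identified only up to relabeling.

## Pairwise FST and permutation tests

The estimator is the Weir–Cockerham-style ratio of sums adapted to haploid
data: per locus, between- and within-population mean squares give
components a and b, and θ = Σa / Σ(a+b) over loci polymorphic in the pair.
Small negative estimates are valid sampling outcomes and are only truncated
for display. Significance comes from permuting accessions between the two
populations of a pair (sizes preserved, each pair permuted independently)
with p = (1 + #{FST_perm ≥ FST_obs})/(n_perm + 1), so 1000 permutations
floor at p = 1/1001 ≈ 0.001.

## LD decay

r² is the squared Pearson correlation of allele vectors over accessions
non-missing at both markers, within chromosomes, for markers with MAF
strictly above 0.10. Pairs are averaged in half-open 25-kb distance classes
(a pair at exactly 25,000 bp falls in the second class), a power law
y = a·x^k is fitted by OLS of log mean r² on log class midpoint (bins with
zero mean excluded; the abscissa of class 0 is 12.5 kb — the midpoint
choice is a documented convention, as is the unweighted fit), and the
distance at a target r² is the inversion x = (y/a)^(1/k). Because a study
average can be formed two ways, `decay_report()` emits both the mean of
per-chromosome inversions and the inversion of a pooled fit.

For calibration tests the generator permits an analytically tractable
special case: with exactly two founder haplotypes per population, every
segregating marker pair has founder-level |r| = 1, and the accession-level
r²(d) is exp(−2cd) for per-bp switch rate c. The "planted decay scale" of
the recovery tests is defined through the analysis's own lens: c is chosen
(by root-finding) so that a power law fitted to the theoretical binned
curve — including the (1−r²)²/n finite-sample uplift — inverts to 100 kb
at r² = 0.2. The pipeline estimate is then required to land within one
bin width (25 kb) of that scale.

## Imputation, kinship and the Q+K mixed model

Missing calls are filled by a nearest-haplotype vote: for each missing
cell, candidate donors observed at the site are ranked by agreement with
the target over a window of 20 markers on each side (roughly the
within-population LD scale at the default density). A donor matching the
window perfectly is decisive — its allele is copied — otherwise the three
best-agreeing donors vote; exact ties fall back to an allele-frequency
draw. Observed
calls are never altered, and the imputer returns a provenance mask. This
is a stand-in for full haplotype-cluster HMM imputation, chosen because it
is auditable and its accuracy is directly measurable by masking
(`impute_accuracy()`); on the default panel about 91% of masked calls are
recovered. Accuracy will degrade on panels with weaker LD, rarer
haplotypes, or donors absent from the panel.

Kinship is the centered, standardized cross-product K = ZZᵀ/m with marker
columns scaled by √(p(1−p)); IBS similarity is available as an
alternative. If the smallest eigenvalue is negative the matrix is bent by
adding |λ_min| + 1e-8 to the diagonal, recorded in an attribute.

The association model is y = Xβ + u + e with var(u) = σ²_g K, solved by
spectral decomposition: with K = UDUᵀ, REML profiles the single variance
ratio δ = σ²_e/σ²_g on the rotated data. By default every marker is tested
by a GLS Wald t-test reusing the null-model δ (the population-parameters-
are-previously-determined shortcut); exact per-marker re-profiling is
available behind a flag and agrees closely on well-behaved panels. With an
identity K the whole machinery collapses to ordinary least squares, which
is the package's strongest correctness anchor (agreement to 1e-6 is
enforced in tests). Structure covariates are admixture proportions with one
column dropped against the intercept. Significance uses the fixed
threshold p < 5e-4 (strict), matching the convention of comparing hit
counts across panels at a common raw threshold rather than adjusting for
multiplicity.

## Phenotype classes and characterization

Maturity classes from days to flowering: E ≤ 85 < M ≤ 105 < L ≤ 135 < VL.
Grain shape from the length/width ratio: A > 3.0, 2.5 < B ≤ 3.0, C ≤ 2.5.
Iodine staining: dark blue = glutinous (G), brown = non-glutinous (NG).
All boundaries are closed/open exactly as written, and the boundary
semantics are property-tested. `characterize_populations()` cross-tabulates
these classes (and passport region/ecosystem) against population
assignments, with admixed accessions as their own column and missing
metadata under "na". The finer grain-length and grain-width categories
sometimes reported alongside have no standard thresholds and are left
configurable rather than defaulted.

## Numerical choices and problem sizes

Tolerances and scales used by the test-suite and the acceptance script, all
chosen once for desk-scale realism: panels of 90–182 accessions and
320–2000 markers; EM tolerance 1e-3 on the log-likelihood gain with at most
2000 iterations; frequency clamp 1e-6; REML search for log δ on
[log 1e-5, log 1e5]; FST recovery judged at ±0.05 against the drift
parameter; LD-scale recovery at ±25 kb (one bin); Q recovery at RMSE < 0.10
after column permutation; imputation at ≥ 90% masked-call recovery with 5%
masking. The pipeline's single master seed is expanded into named
substreams per stage, so partial reruns are reproducible and every CLI
entry point accepts `--seed`.

## Known limitations

* The admixture fit is maximum likelihood, not Bayesian: no credible
  intervals on Q, and ΔK's replicate spread reflects restart variability
  rather than posterior uncertainty.
* The imputer has no notion of phase or recombination rate; it is a local
  haplotype matcher and should not be used at missing rates far above the
  defaults without re-measuring masked accuracy.
* The Weir–Cockerham adaptation treats populations as independent samples;
  hierarchical (pool/population) variance partitioning is not implemented.
* max_length_subtree is greedy; it attains the exhaustive optimum under
  strong redundancy (tested) but carries no general optimality guarantee.
* Tree rendering, bootstrap support, D' statistics and haplotype blocks
  are out of scope; the package emits data for plotting instead.
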