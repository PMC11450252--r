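---
title: "Invasion genomics with genoffset: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion genomics with genoffset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoffset)
```

## The scientific problem

Widespread invaders pose a puzzle: founder events should strip introduced
populations of genetic variation, yet many establish and spread. Two
evolutionary mechanisms can soften the paradox. First, long-term history in
the native range — divergence in glacial refugia followed by post-glacial
admixture — structures the *source* pool of diversity, so an introduced
population's diversity reflects its source more than its founding. Second,
adaptation to native-range climates may pre-adapt some genotypes to similar
non-native environments ("prior adaptation").

`genoffset` implements the analysis chain used to examine both mechanisms
in a range-wide SNP survey of an invasive freshwater fish (the tench,
*Tinca tinca*, sampled across native, introduced and farmed populations):

1. genotype filtering from a VCF;
2. admixture ancestry estimation (two refugial clusters at broad scale) and
   genotype PCA;
3. pairwise and population-specific Fst, with neighbour-joining and MDS
   summaries;
4. per-population diversity (Ho, He, Pi, private alleles) modelled on
   population status plus an ancestry polynomial;
5. genotype–environment association in the native range: a latent-factor
   scan plus partial RDA with variance partitioning, outlier calling and
   candidate combination;
6. extrapolation of a genotype–environment index over climate rasters and a
   genetic offset for each introduced population relative to its
   Fst-nearest native source.

Every stage is driven either by user data or by the package's synthetic
generator, which reproduces the statistical structure the analysis assumes
and carries ground truth for parameter-recovery tests.

## The synthetic data generator

`simulate_dataset()` emulates the study system:

* **Two ancestral clusters with an admixture cline.** Each locus draws an
  ancestral frequency $p_0 \sim U(0.05, 0.95)$ and two cluster frequencies
  from a Balding–Nichols distribution,
  $p_E, p_W \sim \mathrm{Beta}\!\big(p_0\tfrac{1-F}{F},\,(1-p_0)\tfrac{1-F}{F}\big)$,
  whose divergence is controlled by a single Fst-like parameter $F$.
  A native population with Western ancestry
  $q_W$ has frequency $q_W p_W + (1-q_W) p_E$; the default cline runs
  evenly from $q_W = 0$ to $q_W = 1$ across 36 native populations arranged
  west to east. Balding–Nichols is the simplest generator with a tunable
  differentiation analogue; the study implies deep divergence but no
  generative model, so this is a package design choice.
* **Environment-correlated adaptive loci.** A configurable number of loci
  receive a logit-scale frequency shift equal to `env_effect` times the
  standardized annual-mean-temperature at the population's location
  (default slope 1.0). The raster layers are smooth gradients (linear plus
  sinusoids) over a 50x50 unit square; the focal variable varies both along
  the cline axis and across it, which deliberately reproduces the partial
  confounding of climate with demographic structure that the variance
  partitioning stage exists to expose.
* **Founder-effect introductions.** Each of the 40 introduced populations
  (default) is founded by `2 * founder_size` gene copies drawn binomially
  from a named native source (default 10 diploid founders, the classical
  threshold at which $1 - 1/(2N) = 95\%$ of source heterozygosity is
  retained in expectation), after which residents are binomial draws from
  the founder frequencies.
* **Defaults as study conditions.** 36 native / 40 introduced / 19 farmed
  populations, 7 samples per population (633 genotyped individuals over 95
  populations in the study, i.e. about 6.7 per population), 7958 loci, and
  a uniform 6.42% genotype missingness match the filtered data set of the
  study system. `fst_divergence = 0.15` is the package's choice for two
  refugial lineages of a freshwater fish: deep enough that pure Eastern and
  pure Western populations are strongly differentiated, shallow enough that
  the admixture cline stays continuous.

One seed drives the run. Internally it is split (via one `sample.int`
draw) into four recorded stage seeds — coordinates, frequencies, genotypes,
missingness — so stages can be re-simulated independently; the seeds are
returned in the truth object.

What the generator does *not* emulate: linkage disequilibrium (loci are
exchangeable and independent), coalescent noise around the cline,
isolation-by-distance within clusters, and non-climatic selection. Passing
tests therefore demonstrate correctness of the estimators under the model's
assumptions, not robustness to violations a real RAD data set may show.

## Filtering

`apply_filters()` fixes the order of the four standard filters: minor
allele count, per-site missingness, per-individual missingness (computed
after the site filters, mirroring sequential VCFtools calls), then one SNP
per RAD locus (the first position of each locus tag). Site statistics are
computed on the matrix as passed in, so a re-run after individuals were
removed can in principle prune further sites; with the individual filter
inactive the operation is exactly idempotent. Depth-based genotype filters
(minimum depth, mean depth) belong upstream: the package starts from called
genotypes.

## Ancestry estimation

`estimate_ancestry()` maximises the binomial admixture likelihood
$\ell = \sum_{i,l} d_{il}\log \pi_{il} + (2 - d_{il})\log(1 - \pi_{il})$
with $\pi = QF$ by EM block ascent, the same likelihood the standard
admixture tools optimise with quasi-Newton steps. EM guarantees a
monotone likelihood but converges slowly near the optimum, so results are
comparable only within a run; masked-entry cross-validation
(`cross_validate_K()`) therefore reports the full error curve and leaves
elbow-reading to the analyst (the study itself reports the absence of a
clear minimum on real data). Missing dosages are excluded from the
likelihood, not imputed. Defaults: `max_iter = 500`, `tol = 1e-3` on the
absolute log-likelihood improvement; on data sets of a few hundred samples
the cline correlation with truth exceeds 0.95 well before the iteration
cap, so non-convergence warnings at the cap are informational.

Cluster labels are arbitrary; `match_clusters()` aligns solutions by
exhaustive permutation search (fine for the K of interest here).

## Differentiation

Pairwise Fst uses the Weir–Cockerham (1984) variance components as a
multi-locus ratio of sums over loci polymorphic within the pair;
population-specific Fst uses the Weir–Goudet allele-matching estimator
$\beta_i = (M_i - M_B)/(1 - M_B)$ with the matching proportions averaged
over loci before the ratio. The study names functions (snpgdsFst, betas)
rather than formulas; these are the estimators those functions implement.
Raw Fst (not linearized) feeds `nj_tree()` and `classical_mds()` by
default, matching the study's use of the raw matrix; `linearize = TRUE`
switches to $F_{ST}/(1-F_{ST})$. Negative NJ branch lengths are clamped to
zero with the deficit logged.

A caveat worth stating: on a fine admixture cline, neighbouring native
populations can be less differentiated than the Fst estimation noise, in
which case the "Fst-nearest native source" of an introduced population is
not identifiable from the data. The package's recovery tests therefore use
scenarios with well-separated natives and near-clonal introductions; with
10-founder drift and 36 cline-adjacent natives, exact argmin recovery is
not a meaningful target.

## Diversity and its models

Diversity metrics follow the per-variant-site convention of the STACKS
populations module: Ho is the fraction of heterozygotes among genotyped
samples, He $= 2p(1-p)$, Pi is the sample-size-corrected heterozygosity
$\frac{n}{n-1} 2p(1-p)$ with $n$ the number of non-missing allele copies,
all averaged over variant sites only (hence comparable between runs of this
package, not to genome-wide nucleotide diversity). Private alleles are
counted at loci where an allele seen in the focal population is absent from
every other population with data.

`fit_diversity_models()` fits `metric ~ status + q_west + q_west^2` — the
quadratic captures the diversity peak at intermediate admixture — by OLS
for Ho/He/Pi and by Poisson GLM for the private-allele count. Terms are
tested by likelihood-ratio comparisons of nested models (F tests for the
linear models, deviance chi-square for the Poisson; the ancestry pair of
terms and the status contrasts are each dropped jointly). Published
analyses of this design print negative "F" statistics for the Poisson
model, which cannot be F statistics; this package reports the standard
deviance chi-square instead. Per-status fitted means carry Wald 95%
intervals computed on the link scale (via emmeans), a pragmatic choice
matching common practice for GLM interval plots.

## Genotype–environment association

Five bioclimatic variables are the default predictor set (annual mean
temperature, minimum temperature of the coldest month, maximum temperature
of the warmest month, temperature seasonality, annual precipitation); the
list is configurable. Predictors are centred and scaled over the native
range, and pairwise correlations at or above 0.7 trigger a warning.

`lfmm_scan()` is a least-squares latent factor mixed model operating on
individual dosages: latent factors come from the rank-k SVD of the centred
genotype matrix after a ridge-regularised projection off the environmental
design (penalty `1e-5`; k = 2 by default, matching the two-cluster
structure), each locus is then regressed on environment plus factors, and
z-scores are recalibrated by genomic-inflation rescaling before
Benjamini–Hochberg correction per variable. With `n_latent = 0` the scan
reduces exactly to per-locus OLS — a tested identity. This is a documented
reimplementation of the standard ridge-LFMM approach; exact candidate
counts from any specific tool are not a target.

`prda()` (population allele frequencies as response) residualises response
and predictors on the conditioning design — geographic coordinates plus
the Western-cluster ancestry proportion; one column suffices because the
K = 2 proportions are collinear — and eigen-decomposes the fitted values,
via `vegan::rda()`. Tests verify the construction against a from-scratch
fitted-value eigenproblem. The model p-value uses reduced-model permutation
(999 by default, seeded). Variance partitioning runs the full model plus
the three single-block conditioned models and derives the confounded
component as full minus the sum of unique components and the unexplained
component as total minus full; the proportions column sums to one by
construction. Published decompositions of this form are not always
internally consistent (a printed confounded inertia can disagree with the
bookkeeping identity); `partition_from_inertias()` always derives it.

Outliers are loci whose axis-1 loading lies more than 2.5 standard
deviations from the mean loading (about 1.24% of loci under a Gaussian
null). The latent-factor and ordination candidate sets are combined as a
union by default — the reported combined counts in this literature follow
inclusion–exclusion, `|union| = |scan| + |rda| - |shared|` — with an
intersection mode available, since methodological texts sometimes say
"detected by both". Ties in the per-locus strongest-variable assignment
break to the first variable in canonical order.

## The genotype–environment index and genetic offset

The adaptively enriched RDA (candidates only, unconditioned) yields
environmental-variable scores on its first axis. The index at a raster
pixel is $\sum_j s_j (e_j - \mu_j)/\sigma_j$, with standardization taken
from the native-range table the ordination was fit on — this keeps index
maps comparable between native and introduced ranges. The genetic offset of
an introduced population is the absolute index difference between its pixel
and the pixel of its Fst-nearest native source; the signed difference is
retained in a separate column. Offsets are classified Low/Medium/High by
empirical tertiles by default (values at a breakpoint fall to the lower
class; fixed breaks are available), because the published Low/Medium/High
labelling of this table type is not reproducible from value tertiles alone
and the package declines to guess the exact rule.

The axis orientation of any ordination is arbitrary; the absolute
difference makes offsets invariant to it (a tested reflection identity).

## Numerical choices and degenerate inputs

* Dosage probabilities in the EM are clipped to $[10^{-9}, 1-10^{-9}]$;
  adaptive-locus logits are computed on frequencies clamped to
  $[10^{-3}, 1-10^{-3}]$.
* Loci with no data are dropped (PCA) or excluded per pair/fold (Fst,
  cross-validation) with messages, never silently.
* A population with fewer than two genotyped allele copies everywhere gets
  `NA` for Pi; empty populations are an error.
* All-equal offset vectors classify as Low with a warning; an all-zero
  constrained ordination yields an empty loading table rather than an
  error, so self-conditioning checks are expressible.
* Every stochastic routine takes an explicit integer seed; pipeline and
  simulation manifests record them.

## Problem sizes used by the test-suite and acceptance script

The test suite and `scripts/acceptance.R` run the estimators at reduced
problem sizes chosen so each property is measured where it is identifiable:
1,500–2,000 loci for ancestry-cline and null-calibration checks, 300–500
loci for per-stage property tests, 60 populations x 15 samples for the
latent-factor power simulation (10–50 replicates), 200 replicate founder
events for the retention check, and near-clonal introductions among six
well-separated natives for source recovery. The vignette states these as
the package's own analysis choices; the generator's *defaults* remain the
full study layout.

## Known limitations

* The latent-factor scan is a least-squares reimplementation; its exact
  ridge path differs from any specific released tool, so candidate counts
  are comparable in distribution, not locus by locus.
* The offset maps a single ordination axis; adaptation structured on later
  axes is invisible to it.
* Source matching uses a single argmin native population even for admixed
  introductions.
* Rasters use a plain-text grid format with one shared geotransform;
  reprojection and multi-resolution stacks are out of scope.
* Allelic-richness rarefaction, LD pruning, Bayesian GEA and gene
  annotation of candidates are out of scope.
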