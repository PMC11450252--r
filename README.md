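# genoffset

Invasion population genomics in R: from a filtered SNP matrix to a
per-population **genetic offset** that quantifies how well an introduced
population's source genotype matches the climate where it was introduced.

## The problem

Introduced populations are founded by few individuals, which should erode
genetic variation and adaptive potential — yet widespread invaders exist.
Two mechanisms complicate the simple founder-effect story:

* **Native-range history.** When the native range was recolonised from two
  glacial refugia, diversity peaks where the refugial lineages admix. An
  introduced population's diversity then reflects *which* source it came
  from at least as much as the introduction bottleneck. The classical drift
  expectation says a founder group of *N* diploids retains
  `1 − 1/(2N)` of source heterozygosity (95% for *N* = 10).
* **Prior adaptation.** If allele frequencies track climate in the native
  range, a source genotype may be pre-adapted (or mismatched) to the
  climate at the introduction site.

`genoffset` implements the full analysis chain for testing both ideas in a
range-wide SNP survey (native + introduced + farmed populations), and a
synthetic-data generator with ground truth so every stage is verifiable.

## The method chain

| Stage | Function(s) | Core statistic |
|---|---|---|
| Filtering | `read_vcf()`, `apply_filters()` | MAC, site/individual missingness, one SNP per RAD locus |
| Ancestry | `estimate_ancestry()`, `cross_validate_K()`, `pca_genotypes()` | binomial admixture likelihood `π = QF`, EM block ascent; masked-entry CV |
| Differentiation | `pairwise_fst()`, `population_specific_fst()`, `nj_tree()`, `classical_mds()` | Weir–Cockerham Fst; Weir–Goudet `β = (M_i − M_B)/(1 − M_B)` |
| Diversity | `diversity_metrics()`, `fit_diversity_models()` | Ho, He, Pi, private alleles; `metric ~ status + q_W + q_W²` with LRTs |
| GEA | `lfmm_scan()`, `prda()`, `variance_partition()`, `rda_outliers()`, `combine_candidates()` | ridge-LFMM z-scores with genomic-inflation calibration + BH; partial RDA; ±2.5 SD loadings |
| Offset | `enriched_rda()`, `adaptive_index()`, `nearest_native_source()`, `genetic_offset()`, `classify_offsets()` | index = Σⱼ scoreⱼ · standardized envⱼ; offset = \|index(intro) − index(source)\| |

The genotype–environment index of a raster pixel projects its standardized
climate onto the environmental-variable scores of the first axis of an RDA
fit on candidate adaptive loci; the genetic offset of an introduced
population is the absolute index difference between its pixel and the pixel
of its Fst-nearest native source. Large offsets mean adaptive mismatch.

## Worked example

Simulate a small system (12 native populations on an admixture cline, 6
founder-effect introductions, 3 farms, 600 SNPs of which 30 track annual
mean temperature) and run the whole pipeline:

```r
library(genoffset)

res <- run_pipeline(list(
  simulate = list(n_native_pops = 12, n_introduced_pops = 6,
                  n_farmed_pops = 3, samples_per_pop = 8,
                  n_loci = 600, n_adaptive_loci = 30),
  gea = list(permutations = 199)
), seed = 42)

res$ancestry
#> <ancestry_fit> K = 2 , n = 168 , loglik = -92732.26 , NOT converged in 500 iterations

glance(res$models)
#> # A tibble: 4 × 5
#>   response statistic_name     statistic  p_ancestry  p_status
#>   <chr>    <chr>                  <dbl>       <dbl>     <dbl>
#> 1 Ho       r_squared      0.843         0.0000159   0.000196
#> 2 He       r_squared      0.884         0.000000326 0.0000368
#> 3 Pi       r_squared      0.884         0.000000308 0.0000363
#> 4 Pa       deviance       0.00000000161 0.167       1.000
```

Diversity tracks ancestry strongly (R² ≈ 0.84–0.88 with a quadratic peak at
intermediate admixture). The status term is detectable here because the
simulated introductions were founded by 10 diploids; private-allele counts
are nearly all zero at this small scale, so the Poisson fit is degenerate
and its tests are uninformative (expected at 600 loci).

```r
dplyr::select(as.data.frame(res$partition), component, inertia, r_squared)
#>     component    inertia  r_squared
#> 1        full  9.4285189 0.83461423
#> 2     climate  3.4433053 0.30480202
#> 3   geography  1.2355426 0.10937046
#> 4  demography  0.5974349 0.05288505
#> 5  confounded  4.1522361 0.36755670
#> 6 unexplained  1.8683397 0.16538577
#> 7       total 11.2968586 1.00000000

glance(res$candidates)
#> # A tibble: 1 × 4
#>   n_lfmm n_rda n_shared n_combined
#>    <int> <int>    <int>      <int>
#> 1      4    15        3         16

head(dplyr::select(res$offsets, population_id, source_population_id,
                   offset, relative_difference), 5)
#> # A tibble: 5 × 4
#>   population_id source_population_id offset relative_difference
#>   <chr>         <chr>                 <dbl> <fct>
#> 1 INT01         NAT09                 0.868 Low
#> 2 INT02         NAT10                 3.77  High
#> 3 INT03         NAT01                 2.43  High
#> 4 INT04         NAT07                 1.65  Medium
#> 5 INT05         NAT04                 0.194 Low
```

A large confounded fraction between climate, geography and demography is
the expected signature of adaptation along an expansion cline — the
variance partitioning makes it explicit rather than hiding it. Each
introduced population gets its Fst-nearest native source, an index
difference, and a tertile label.

The package also ships the published offset table for the 40 introduced
tench populations it models:

```r
count_below(tench_offsets()$offset, 2.83)
#> [1] 27
```

Plots: `plot_diversity()` (metric vs ancestry with the fitted curve),
`plot_rda()` (candidate-locus biplot with environment arrows),
`plot_index()` (index map); `autoplot()` methods dispatch to these.

## Method and design notes

See the vignette (`vignettes/invasion-genomics.Rmd`) for the generative
model behind the synthetic data, estimator choices and their rationale,
numerical edge cases, the problem sizes used by the tests, and known
limitations.
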