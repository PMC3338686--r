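# trflpdyn

Community dynamics and environmental correlates from T-RFLP fingerprints.

Terminal restriction fragment length polymorphism (T-RFLP) is a community
fingerprinting technique: a fluorescently labeled marker-gene amplicon (here
the ammonia monooxygenase gene *amoA* of ammonia-oxidizing bacteria) is cut
with a restriction enzyme (TaqI, recognizing `TCGA`), and the length of the
labeled terminal fragment (T-RF) identifies a community member, while its
peak area measures relative abundance. Monitoring a wastewater treatment
plant this way yields, per sampling date, a profile of relative abundances
over T-RF bins — and the question of which operational variables (dissolved
oxygen, ammonia, BOD, temperature, ...) drive the community's temporal
dynamics.

`trflpdyn` implements the full analysis chain for such time series, for
microbial ecologists and environmental engineers:

- **Preprocessing** — peak tables to aligned relative-abundance profiles:
  50–500 bp size window, single-linkage T-RF binning, per-sample area
  ratios, and exclusion of background noise below the 2 % relative-abundance
  floor.
- **Moving-window change analysis** — for consecutive sampling dates *x* −
  Δ and *x*, the change value is 100 − *r*(x−Δ, x)·100 with *r* the Pearson
  correlation of the two profiles; the series is summarized as
  Δt = mean ± sd of the change values, optionally excluding a start-up
  phase.
- **Canonical correspondence analysis (CCA)**, written from first
  principles: the chi-square standardized table
  Q<sub>ij</sub> = (p<sub>ij</sub> − r<sub>i</sub>c<sub>j</sub>) / √(r<sub>i</sub>c<sub>j</sub>)
  is projected by weighted least squares onto the span of the environmental
  covariates; the SVD of the projection gives canonical eigenvalues
  (constrained + residual inertia = total inertia exactly), species/site
  scores and biplot arrows. Significance by Monte-Carlo permutation (499
  permutations, P = (1+b)/(1+n)), greedy forward selection of covariates by
  pseudo-F with reduced-model residual permutation.
- **Mantel tests** — r<sub>M</sub> between the community distance matrix
  (Bray-Curtis or 1 − Pearson) and per-variable distance matrices, with
  sampled or exhaustive permutation nulls, one row per covariate.
- **In-silico clone digestion** — orient clone sequences by the labeled
  *amoA* primer (IUPAC-aware, ≤1 mismatch), locate the first TaqI site,
  predict the terminal fragment length, and assign clones to observed T-RF
  bins (±3 bp).
- **Synthetic-study generator** — AR(1) covariates with physical bounds,
  Gaussian (unimodal) taxon responses to a planted driver, optional
  Dirichlet compositional noise, and peak-table rendering with sizing jitter
  and sub-floor noise peaks, so every stage can be validated against a known
  ground truth.

## Worked example

A synthetic monitoring study (24 samples, 15-day interval, dissolved oxygen
as the planted driver):

```r
library(trflpdyn)

scenario <- scenario_planted_driver(seed = 42)
env   <- simulate_env_series(scenario)
peaks <- render_peak_tables(simulate_profile_series(scenario, env), scenario)
pre   <- preprocess_peaks(peaks, env)
pre$series
#> profile series: 24 samples (day 0-345), 3 T-RF bins (219, 354, 491 bp)

moving_window(pre$series, exclude_before_day = 60)
#> moving-window change series: 23 consecutive pairs (19 used)
#>   pairs ending on or before day 60 excluded
#>   delta-t = 10.0% +/- 15.2%

X <- as.matrix(env[, c("DO", "temperature", "SVI", "MLSS", "SRT", "effluent_NO3")])
fit_cca(pre$series$matrix, X, n_perm = 499, seed = 1)
#> Canonical correspondence analysis
#>   inertia: total 0.1235 = constrained 0.1131 + residual 0.0104
#>   species variance explained: 91.6%
#>   canonical eigenvalues: 0.1109, 0.0022
#>   species-environment relation shown by first 2 axes: 100.0%
#>   permutation P (first axis): 0.002; (all axes): 0.002 [499 perms]

forward_select(pre$series$matrix, X, n_perm = 499, seed = 1)
#> forward selection (alpha = 0.05, 499 permutations)
#>   included: DO
#>  round variable extra_inertia  pseudo_F p_value included
#>      1       DO  0.1101124957 181.05423   0.002     TRUE
#>      2      SRT  0.0008363346   1.40017   0.266    FALSE

mantel_table(pre$series, env, variables = colnames(X), n_perm = 999, seed = 1)
#>       variable      r_m p_value n_used
#> 1           DO  0.89906   0.001     24
#> 2  temperature -0.03605   0.660     24
#> ...
```

Reading the output: the three retained T-RFs (219, 354, 491 bp) change at an
average rate of 10 % per 15 days once the start-up phase is excluded — a
moderately dynamic community despite stable operation. The CCA ordination
explains 92 % of the species (T-RF) variance, its two canonical axes show
100 % of the species–environment relation, and both global permutation tests
are significant at the smallest attainable P (0.002 with 499 permutations).
Forward selection includes only the true driver (DO); the per-variable
Mantel screen agrees (r_M = 0.90, P = 0.001, decoys non-significant).

`run_pipeline()` chains all stages, writes every stage output plus a
manifest with checksums, and is byte-identical across reruns of one
configuration; `inst/cli/trflp-pipeline.R` is a thin command-line wrapper
over it.

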