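---
title: "Methods: fingerprint preprocessing, moving-window dynamics, constrained ordination and Mantel screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint preprocessing, moving-window dynamics, constrained ordination and Mantel screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflpdyn)
```

This vignette is the package's own account of the statistical machinery it
implements, of the assumptions behind each stage, and of the design choices
made where the methodology was genuinely open. The running application is
the monitoring of ammonia-oxidizing bacteria (AOB) in activated sludge by
*amoA* T-RFLP, but every stage is generic for fragment-fingerprint time
series.

## 1. From peak tables to community profiles

A capillary fragment analysis yields, per sample, peaks with a fragment
length (bp) and a fluorescence area. Preprocessing applies four rules, in
order:

1. **Size window.** Fragments shorter than 50 bp or longer than 500 bp are
   excluded: short fragments are confounded with primers and both extremes
   sit outside the reliable range of the size standard. The boundaries
   themselves are retained — the exclusion rule names strict violations
   only.
2. **Binning.** Sizing error scatters the same terminal fragment across
   samples by fractions of a base pair, so lengths from all samples are
   clustered by single linkage in one dimension: sorted lengths chain
   together while the gap to the next length is strictly below the
   tolerance (default 1 bp, typical capillary sizing precision). The strict
   inequality makes re-binning already-binned integer labels a no-op, so
   the preprocessing pipeline is idempotent. Each cluster is labelled with
   its rounded area-weighted mean length; no published binning rule exists
   for this kind of data beyond the integer labels it produces, so the rule
   is the package's own and is deliberately simple.
3. **Relative abundance.** Within a sample, a bin's abundance is its area
   divided by the sample's total area — profiles are compositions.
4. **Noise floor.** Bins with relative abundance *strictly* below 2 % are
   treated as background noise and removed. By default the retained bins
   are renormalized to sum to 1, because the downstream Pearson and
   chi-square machinery treats profiles as compositions; renormalization
   can be disabled to keep raw ratios for reporting (whether published
   analyses renormalize after the floor is typically unstated, so both
   behaviours are supported and the default is documented here). The
   removed mass is reported per sample and, on realistic data, should stay
   within a few percent.

Degenerate inputs fail loudly by design: a sample with zero total area, a
profile left empty by the noise floor, or a covariate table with negative
concentrations are errors naming the offending sample or variable, never
silent repairs.

## 2. Moving-window community change

For profiles at consecutive dates the similarity is the Pearson
product-moment correlation over the union of their bins (absent bins count
as zero), times 100; the **change value** is `100 − similarity`. The
summary statistic

\[
\Delta_t = \text{mean} \pm \text{sd of the change values}
\]

uses the arithmetic mean and the sample (n−1) standard deviation — the
population/sample choice is rarely stated in applications; the sample sd is
the package's choice. Pairs ending on or before an optional
`exclude_before_day` (e.g. a reactor start-up phase) are dropped from the
summary but still reported. Two further conventions matter:

- *Consecutive* means adjacent in the time-sorted series even when the
  actual gap differs from the nominal interval; the realized gap is
  recorded per pair.
- A negative correlation gives a change value above 100 %. Values are not
  clamped — the defining formula is applied literally — but a warning is
  attached, since the change-percentage framing presumes non-negative
  correlation.

The analytic oracle for this stage is `fixed_similarity_series()`: profiles
are constructed on a sphere in the centered simplex so that every
consecutive pair has Pearson correlation exactly equal to a target (each
step rotates the previous centered profile by `acos(target_r)` in a random
orthogonal direction; correlation is the cosine between centered profiles,
and the construction keeps every profile a strictly positive composition).
A target of 0.90 forces every change value to 10 %, a target of 0.75 forces
25 %, with zero variance — which is how the moving-window code is tested
without circularity.

## 3. Canonical correspondence analysis

CCA is the constrained form of correspondence analysis, appropriate when
taxa respond unimodally to gradients (the common ecological case, and the
reason it is preferred over redundancy analysis for abundance data). The
engine is implemented from first principles:

1. With \(P = Y / y_{++}\), row masses \(r\), column masses \(c\), form the
   chi-square standardized residuals
   \(Q_{ij} = (p_{ij} - r_i c_j) / \sqrt{r_i c_j}\). The total inertia is
   \(\sum Q_{ij}^2\).
2. Covariates are centered and scaled with weights \(r\) and the rows
   multiplied by \(\sqrt{r}\), so ordinary least squares on the transformed
   design equals weighted least squares on the original. \(Q\) is projected
   onto the span of the transformed design; by Pythagoras the constrained
   and residual inertias add to the total exactly (asserted to 1e-9 in the
   tests for every fit).
3. The SVD of the projected matrix gives canonical eigenvalues (squared
   singular values, each in \([0, 1)\)), species and site scores, and
   biplot arrow scores (the weighted correlation of each covariate with
   each canonical axis).

**Scaling.** Ordination "focusing on inter-species distances" is the
species-focused biplot scaling: species scores are scaled by the singular
values, site scores left as standard coordinates; a site-focused mode does
the reverse. **Sign convention:** each axis is oriented so its
largest-magnitude species score is positive, making runs comparable.
**Collinearity** is screened by variance inflation before fitting (exactly
aliased columns first, then greedy removal while any VIF exceeds 20 — the
threshold conventionally reported alongside CCA biplots), with a warning
naming the dropped columns rather than a silent failure. With full-rank
constraints the canonical eigenvalues equal the unconstrained CA
eigenvalues of \(Y\), which provides an exact oracle for the engine; the
test suite also cross-checks eigenvalues and inertias against an
independent established implementation to 1e-8.

**Permutation inference.** The global tests permute the rows of the
covariate matrix ("under the full model"), recompute either the first
canonical eigenvalue or the trace of all canonical eigenvalues, and report
\(P = (1 + b) / (1 + n_{perm})\) with \(b\) the count of permutation
statistics at or above the observed one — P is never zero and its minimum
with the conventional 499 permutations is 0.002. Type-I error is verified
by simulation: with covariates independent of the community, the rejection
rate at \(\alpha = 0.05\) over 1000 null replicates must sit inside the 95 %
binomial band around 0.05 (it does; the estimator's discrete support makes
the nominal level exact under exchangeability).

**Forward selection** is greedy: each round scores every excluded covariate
by the extra constrained inertia it adds given the included set, summarized
as a pseudo-F (extra inertia over the post-inclusion residual inertia per
residual degree of freedom; which pseudo-statistic commercial packages use
is unstated, so pseudo-F is the default and raw extra inertia is available
via an argument). Only the best candidate is tested by permutation, and
selection stops at its first failure. The first round permutes the
candidate outright; later rounds permute the candidate's residuals after
projection on the included covariates (reduced-model residual permutation),
which conditions the test on what is already in the model. Residual
permutation is exact only when the residual variation is exchangeable —
which is why the validation preset adds compositional measurement noise
(section 6).

## 4. Mantel screening

The Mantel statistic \(r_M\) is the Pearson correlation between the
corresponding upper-triangle entries of two distance matrices; the null
distribution jointly permutes rows and columns of one matrix. For \(n \le
7\) an exhaustive mode enumerates all \(n!\) relabelings and returns the
exact permutation P (the identity relabeling keeps P strictly positive);
the sampled mode uses \((1+b)/(1+n_{perm})\) with 999 permutations by
default. Choices the literature usually leaves unstated, made explicit
here:

- community metric: Bray-Curtis by default (ecological convention);
  1 − Pearson available for consistency with the moving-window statistic;
- per-variable distances: \(|z_i - z_j|\) on the optionally z-scored
  covariate (z-scoring cannot change \(r_M\) — Mantel correlation is
  invariant to linear rescaling of one matrix — but keeps distances
  comparable across variables);
- tail: one-sided (greater) by default, since the screening question is
  positive association; two-sided available. Negative \(r_M\) values with
  P near 0.5–0.75 are the expected signature of the one-sided test on
  unrelated variables;
- missing covariate values: complete-case per variable, with both matrices
  reduced to the same samples and the dropped ids logged.

## 5. In-silico clone digestion

Clone T-RFLP is emulated sequence-side. Each clone is oriented by locating
the labeled forward primer on either strand (IUPAC-aware matching, one
mismatch tolerated for PCR/cloning errors; found on both strands is an
ambiguity error), the amplicon is read 5'→3' from the primer's first base
and trimmed at the reverse primer's binding site when present. The
predicted terminal fragment is the 0-based index of the first exact
occurrence of the recognition site plus the cut offset (TaqI cuts T^CGA, so
offset 1); the labeled primer counts toward the length, and a site-free
amplicon yields the full amplicon length with `cut_found = FALSE`. This
convention reproduces the canonical 219-bp (cut) and 491-bp (uncut) *amoA*
fragment geometry. A window that is only compatible with the site through
degenerate codes is counted conservatively — only if every expansion
contains the site, i.e. never for a truly degenerate window — with a
warning when such a window precedes the first certain site. Predictions are
matched to observed bins within ±3 bp, the midpoint of the 1–7 bp
discrepancy range commonly reported between sequence-predicted and
electrophoretically measured fragment lengths; exact ties break toward the
smaller bin with a warning. Electrophoretic mobility shifts of the dye
label are *not* modelled: predictions are sequence-exact by definition.

## 6. The synthetic-study generator

The generator provides ground truth for every downstream stage. Its
defaults emulate a one-year monitoring campaign of a stably nitrifying
pilot-scale plant: 24 samples at 15-day intervals; three true T-RF bins
(219, 354, 491 bp); twelve operational covariates as stationary Gaussian
AR(1) series \(x_t = \mu + \rho(x_{t-1} - \mu) + \varepsilon_t\) with
innovation sd \(\sigma\sqrt{1-\rho^2}\) (so the stationary sd is exactly
\(\sigma\)), clamped to physical bounds (concentrations at 0, removal
efficiency at 100 %); Gaussian (unimodal) taxon responses
\(a_{kt} = h_k \exp(-(x_t - u_k)^2 / 2t_k^2)\) to a named driver, row-
normalized to compositions. Rendering turns profiles into peak tables with
areas proportional to abundance, Gaussian sizing jitter (sd 0.3 bp), and
three noise peaks per sample at random lengths away from the true bins,
each strictly below the 2 % floor — so the filtering rules recover the true
profiles by construction. One master seed drives every draw, and all
outputs are bit-reproducible from it.

Parameter choices worth recording:

- Covariate means and spreads follow typical operating ranges of such a
  plant (DO near 1.9 mg/L, seasonal temperature around 21 °C, MLSS 4.5–6
  g/L, SRT 7–10 d, effluent ammonia mostly below 2 mg/L). Slowly varying
  controlled quantities carry strong autocorrelation (DO \(\rho = 0.9\),
  temperature 0.8): at a 15-day sampling interval this keeps consecutive
  community changes in the moderate (\(\Delta_t\) near 10 %) regime that
  stably operated plants show, rather than the erratic regime a weakly
  autocorrelated driver would produce.
- The planted-driver preset (`scenario_planted_driver()`) makes dissolved
  oxygen the only true driver (optima of the two abundant taxa at ±1.2
  driver sd, niche tolerance ≈1.4 driver sd, so the response is strong but
  close to monotone over the sampled gradient) and resamples each rendered
  profile as Dirichlet with concentration 150 (per-bin sd ≈4 % at even
  abundance), emulating run-to-run area noise of capillary fingerprints.
  The noise matters statistically: with perfectly deterministic profiles
  the forward-selection residuals are smooth functions of the driver, and
  an autocorrelated decoy covariate then passes the residual-permutation
  test far above its nominal rate. With measurement noise the residuals
  are exchangeable and decoy inclusion sits at its nominal level. Under
  this frozen preset, forward selection includes the driver with P ≤ 0.01
  in 100/100 seeds, includes each decoy in well under 10 % of seeds, and
  the driver's Mantel \(r_M\) ranks first in 100/100 seeds.
- The noise-free preset (`scenario_noise_free()`) removes jitter, noise
  peaks and resampling and keeps every taxon above the floor at all times,
  so `preprocess(render(series))` returns the true series to 1e-6 per
  cell — the pipeline-inversion test.
- A "dirty" preset allows noise peaks above the 2 % floor for negative
  tests of the filtering rules.

What the generator deliberately does **not** emulate: electropherogram
traces and peak calling, pull-up/stutter artifacts, PCR amplification bias,
multi-dye chemistry, and dye-dependent mobility shifts. Passing tests
therefore validate the statistical chain downstream of peak calling, not
the instrument-side signal processing.

## 7. Numerical conventions and problem sizes

- Permutation P-values use the add-one estimator everywhere; seeds are
  explicit arguments and one master seed derives per-stage streams.
- Inertia conservation is asserted at 1e-9; the CA-reduction oracle at
  1e-8; profile compositions at 1e-12; the fixed-similarity construction at
  1e-9.
- Eigenvalues below 1e-10 are treated as numerically zero rank.
- Exhaustive Mantel enumeration is limited to \(n \le 7\) (5040
  relabelings).
- The validation suite uses 200 random 6×4 tables for the conservation and
  CA-reduction checks, 1000 null replicates at n = 24 for permutation
  calibration, and 100 seeds of the planted-driver preset for recovery
  rates — sizes chosen so each property is measured with useful precision
  while the whole suite stays interactive.

## 8. Known limitations

- Binning is one-dimensional single linkage; profile alignment across runs
  with systematic sizing drift (requiring size-standard recalibration) is
  out of scope.
- The unrestricted permutation schemes assume exchangeable samples; under
  strong temporal autocorrelation of *both* community and covariate they
  are anti-conservative, as for any unrestricted permutation test on time
  series. Restricted (e.g. cyclic-shift) permutations are not implemented.
- The change statistic inherits the limitations of Pearson correlation on
  compositions with few parts; with three bins it is dominated by the two
  abundant ones.
- Forward selection is greedy and, like all stepwise procedures, can be
  order-unstable when covariates are strongly collinear; the VIF screen
  mitigates but does not eliminate this.
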