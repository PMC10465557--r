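---
title: "Methods: assemblage-level mitochondrial diversity, its environmental correlates, and the synthetic worlds used to test them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assemblage-level mitochondrial diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`macrogd` implements a class III macrogenetic workflow: it aggregates
intraspecific mitochondrial variation from large georeferenced DNA-barcode
collections into per-grid-cell summaries, tests their spatial and
environmental correlates with autocorrelation-aware statistics, and predicts
them into unsampled environments with a Bayesian spatial regression. This
vignette explains the models and the design decisions; the README shows the
workflow itself.

## The two diversity summaries

The unit of observation is an OTU-in-a-cell: all sequences of one barcode
cluster (OTU/BIN) sampled inside one equal-area grid cell. For each such
alignment the package computes nucleotide diversity, the mean over all
unordered sequence pairs of the per-pair mismatch fraction. Sites enter a
pair's comparison only when both sequences carry an unambiguous base
(pairwise deletion); each pair is normalised by its own comparable-site
count because trimmed barcode fragments differ in coverage. OTUs with fewer
than three copies in a cell are excluded: below that, the estimator is
pure noise, while coalescent theory says a handful of copies already
estimates diversity about as well as hundreds.

Two summaries are taken over the OTUs of a cell:

* **GDM** (genetic diversity mean): the arithmetic mean of per-OTU
  diversities. Its cell-level distribution is strongly right-skewed, so a
  square-root transform is applied for every statistic and model; the raw
  mean is always retained in outputs.
* **GDE** (genetic diversity evenness): the first-order Hill number of the
  per-OTU diversity distribution divided by OTU richness \(N\). Writing
  \(p_i = \pi_i / \sum_j \pi_j\),
  \[
  \mathrm{GDE} = \frac{\exp\left(-\sum_i p_i \ln p_i\right)}{N} \in
  \left[\tfrac{1}{N},\, 1\right],
  \]
  equal to 1 exactly when all OTUs with nonzero diversity are equally
  diverse and none are invariant.

**Normalisation choice.** The evenness formula is sometimes written with the
entropy applied to the raw \(\pi_i\) themselves. Raw diversities do not sum
to one, so that form is not bounded by the richness correction and is not an
evenness; the Hill-number framework the metric comes from requires
proportions. `macrogd` therefore normalises by default and exposes the
literal unnormalised variant behind `gde(..., normalize = FALSE)` (and the
pipeline flag `gde_literal`) for comparison only. A cell whose OTUs are all
invariant has undefined evenness and is reported as missing, never as zero.

## Filtering and gridding

Record-level filters mirror standard barcode-survey practice: end gaps are
trimmed; sequences longer than 800 bp (gap-riddled alignments) or shorter
than 400 bp (fragments that bias diversity downward) are removed, with the
boundary values retained since the removal inequalities are strict;
ungeoreferenced records are dropped; user-listed invasive taxa are removed
only when the data actually show them on two or more continents. Rules are
conjunctive, so the retained set is order-independent; the per-rule
attribution in the report follows a fixed documented order.

Cells come from a cylindrical equal-area (Behrmann, standard parallel
30°) projection of the authalic sphere, tiled with square cells of
96.5, 193 or 385.9 km side. Since neither the original grid origin nor its
edge convention is recoverable, the package fixes both: origin at the
projected equator/prime-meridian intersection and half-open lower-left-closed
cells. Results for records lying near cell boundaries can therefore differ
from any particular archived gridding.

## Spatially corrected statistics

Grid-cell summaries are spatially autocorrelated, which invalidates the
nominal degrees of freedom of ordinary correlation tests. Two corrections
are provided:

* **Modified t-test** (Dutilleul's effective-sample-size correction). The
  spatial covariance of each variable is estimated over distance classes
  (13 equal-count classes by default; the class count is configurable since
  the appropriate number is data-dependent), and the effective sample size
  \(\hat M\) replaces \(n\) in the F-statistic
  \((\hat M - 2) r^2 / (1 - r^2)\) with fractional degrees of freedom
  \(\hat M - 2\). With no autocorrelation \(\hat M \to n\); the estimate is
  clamped to \((2, n]\). Simulation checks in the test suite verify nominal
  size under an iid null and controlled size under strongly autocorrelated
  independent fields where the naive test rejects several times too often.
* **Moran's I** with a one-sided (greater) permutation null, row-standardised
  k-nearest-neighbour weights (k = 8 by default; inverse-distance available),
  used for residual autocorrelation checks.

The latitudinal analysis runs the modified test of a response against
absolute and squared latitude; a subtropical peak shows up as a negative
quadratic correlation provided the sampled latitude range extends well past
the peak on both sides.

## The spatial regression

The environmental model is a Gaussian spatial GLMM:
\[
y_i = \alpha + x_i^\top \beta + w(s_i) + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma^2),
\]
fitted to sqrt-GDM and to GDE (optionally logit-transformed, since GDE is a
proportion-like quantity in \((0,1]\); the identity link is the default as
the observation family of the original analyses is not recoverable). The
spatial effect \(w\) is a knot-based predictive-process random field with
exponential covariance and a heavy-tail scale mixture: given
\(\lambda \sim \mathrm{Inv\text{-}Gamma}(\nu/2, \nu/2)\) the knot values are
Gaussian with covariance \(\sigma_w^2 \lambda K\), so marginally the field
is multivariate-t with \(\nu\) degrees of freedom (default 10), which lets
isolated cells deviate without inflating the global field variance.

Priors: slopes \(N(0, 0.1)\) on standardised predictors — read as variance
0.1 (sd ≈ 0.316). The notation is ambiguous, and the sd-0.1 reading is
rejected on identifiability grounds: a genuine standardised effect of
moderate size (±0.3–0.5) would sit several prior standard deviations from
zero and incur shrinkage bias of about two posterior standard deviations at
any realistic noise level, so credible intervals could never cover such
effects. The variance reading regularises without that pathology. Residual
and field scales get half-N(0,1) priors; the intercept N(0, 5). All priors
are overridable via `priors`.

Everything in this model is conditionally conjugate, so posterior draws come
from a blocked Gibbs sampler written for exactly this structure:
\((\alpha, \beta, u)\) jointly Gaussian given the scales (one Cholesky solve
per sweep), slice-sampling updates on the log residual and field scales, and
a closed-form inverse-gamma update for the t-mixture variable. Defaults are
4 chains of 1000 warmup + 1000 kept sweeps; convergence is summarised by
split R-hat and effective sample size, and a fit with any R-hat above 1.05
is flagged and warns on downstream use. Per-draw Bayesian
\(R^2 = \mathrm{var}(\eta) / (\mathrm{var}(\eta) + \sigma^2)\) uses the
linear predictor plus field. Prior–posterior overlap (integrated minimum of
the two densities) summarises identifiability per parameter.

**Knots.** The config default is 25 knots, placed by k-means on the cell
coordinates, with the covariance range defaulting to a quarter of the
maximum inter-cell distance. A guideline from the package's own calibration
experiments: when the residual field is believed to have structure at scales
near the inter-cell spacing, use knot counts nearer n/4 — an
under-resolved field leaks into the slope estimates and degrades interval
coverage for null effects.

**Variable selection.** Predictors are first pruned for collinearity
(greedy removal above |r| = 0.75, keeping the higher-priority member of
each pair), then optionally screened by a forward search that ranks
candidates by K-fold cross-validated expected log predictive density under a
ridge-penalised Gaussian linear model whose penalty matches the slope prior.
This screening is deliberately non-spatial and fast; the spatial field
enters at the final fit. It replaces reference-model projection, which needs
a machinery this package does not carry; the two approaches agree on the
dominant predictors but can order weak ones differently.

**Train/test protocol.** Cells are split 75/25 stratified by continent
(majority continent of a cell's records), rounding half-up per continent,
single-cell continents to training. Test-set calibration is summarised by
the regression of observed on predicted (slope, intercept, \(R^2\), RMSE) —
the same bias/precision criterion used to choose the minimum-OTU threshold
in `threshold_sweep()`.

**Extrapolation masking.** Global predictions are masked where the
multivariate environmental similarity surface (MESS) is negative, i.e. where
at least one predictor falls outside its training range. The similarity
score uses the strictly-below percentile convention (ties-as-half available
as an option, since reference implementations differ) and is exact on the
formula's interior branches; because it is an empirical-percentile formula
it steps by 200/n as a value crosses a reference point, which matters only
for tiny reference sets.

## The synthetic worlds

`generate_world()` produces the full input set — BOLD-schema table, per-OTU
alignments, environment table, truth record — from one master seed, with all
stage seeds derived deterministically. It emulates: per-OTU coalescent
sequence variation (Hudson's single-population algorithm with finite-sites
Jukes–Cantor mutation, so diversity is computed from mismatches exactly as
on real data); spatially autocorrelated environments (Gaussian fields with
exponential covariance, 800 km range by default — a CHELSA-like smoothness,
not a reproduction of any raster); and a planted linear
environment→diversity relationship on the sqrt-GDM scale
(baseline 0.12, i.e. raw diversity ≈ 0.014, typical of insect COI
assemblages; default planted effects of +0.02 per sd of maximum temperature
of the warmest month and −0.012 per sd of precipitation seasonality — small
relative to baseline, as real environmental effects are). Per-OTU scaled
mutation rates are gamma-distributed around the cell mean (shape 3), which
produces the L-shaped within-cell diversity distributions real assemblages
show, and the per-cell residual field (sd 0.01) plus iid noise (sd 0.008)
keep planted effects recoverable at desk scale without being trivial.

What the generator does **not** emulate: alignment error and chimeras,
geographic range structure within OTUs (each OTU is confined to one cell
unless multi-cell OTUs are explicitly planted), taxon-biased sampling
effort, sequencing error, selection, recombination, migration, and
endosymbiont-linked distortions. Passing tests on these worlds therefore
demonstrate the pipeline's internal correctness and statistical calibration,
not robustness to those real-data pathologies.

`inject_pathologies()` adds labelled violations of each filter (over/under
length, end-gap-padded fragments, missing coordinates, a two-continent
invasive species, under-sampled OTUs) so that filter reports can be asserted
against exact expected counts.

`simulate_cell_data()` skips sequences entirely and plants the regression
structure directly at cell level (default 200–250 cells over a
5000 km square, unit-variance predictor fields, field sd 0.2, noise sd 0.1)
— the configuration used for the parameter-recovery and calibration tests.

## The duplicate-allele experiment

Barcode repositories may omit duplicate alleles from submissions, so
collection data can contain only unique haplotypes. The experiment
quantifies the resulting bias by simulating coalescent samples and computing
diversity on all copies versus unique haplotypes only (exact string
equality; a replicate that collapses to a single haplotype records zero for
the unique-only value). Its default design — 10 copies, 600 bp, mutation
rate 2e-4 per site per generation, 300 replicates per Ne in
{1e3, 1e4, 1e5, 1e6} — is a *designed regime*, not a biological estimate:
the grid must start at or past the bias peak (θL of order 1–10) for the
decline with Ne to be monotone, and must end where every copy is a unique
haplotype (θL far above the squared sample size) for the bias to vanish. At
a realistic COI mutation rate the same grid would start below the peak and
the bias would first rise with Ne.

On average the bias is positive — deduplication discards the zero-distance
pairs created by recent coalescences — and decreases toward zero as Ne
grows. It is *not* positive in every single replicate: when the duplicated
haplotype sits on a long branch, duplication also up-weights that
haplotype's long-distance pairs, and removing the copy lowers the mean.
This arises in roughly 1–3% of replicates in duplicate-rich regimes and is
a property of the statistic, not a simulation artefact.

## Numerical choices and degenerate inputs

* Sequence pairs with no comparable sites are excluded from the pair count
  (logged); an alignment with no comparable pair is an error.
* All-zero-diversity cells: GDE missing, flagged, dropped from downstream
  statistics with a logged count.
* Effective sample size in the modified t-test clamped to \((2, n]\); a
  non-positive trace denominator falls back to no correction.
* Slice sampling operates on log scales, so scale parameters never touch
  zero; the knot covariance carries a 1e-8 diagonal jitter.
* Degenerate MESS references (constant predictor) score 0 at the constant
  and negative elsewhere.
* Ties in cell assignment cannot occur (half-open intervals); points exactly
  on an edge belong to the +x/+y cell.
* The problem sizes in the test suite and acceptance script (worlds of
  6–24 cells with 12–40 OTUs each, 250-cell regression worlds, 300–2000
  simulation replicates, 2 chains × 1000 sweeps) are the package's chosen
  desk-scale study conditions: large enough for the statistical checks to
  have power, small enough to iterate on.

## Known limitations

* The sampler is exact for the implemented conjugate model but does not
  estimate the field range; a badly misspecified range shows up as residual
  autocorrelation (check `morans_i()` on `residuals(fit)`).
* Predictive-process prediction uses the conditional mean of the field at
  new locations; the field's conditional variance beyond the knots is not
  added, so intervals at locations far from all knots are modestly narrow.
* The forward-ELPD screen is greedy and non-spatial; strongly collinear
  predictor sets should be pruned first (the pipeline does).
* Single-locus mitochondrial diversity is one draw of the coalescent per
  OTU and is shaped by selection and mutation-rate variation as well as
  demography; the package quantifies and maps it without claiming it proxies
  genome-wide diversity.
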