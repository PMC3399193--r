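---
title: "Methods: dispersal-constrained range projection under climate change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersal-constrained range projection under climate change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

nichecast projects species' geographic ranges under climate change with
presence-background species distribution models (SDMs), a multi-model climate
ensemble, and explicit dispersal constraints. This vignette explains the
models and procedures, the tunable parameters, the synthetic study system the
package ships with, and the numerical and design choices a user should know
about before trusting (or extending) the results.

## The problem

Given (i) monthly temperature and precipitation grids for a baseline period
and for an ensemble of future climate realisations, (ii) presence-only
occurrence records per species, (iii) a mosaic of biogeographic subregions,
and (iv) per-species dispersal metadata, the pipeline estimates for each
species a current range, projects its climatically suitable area per future
decade, constrains the projection by what the species can plausibly reach,
and aggregates species into range-change and richness summaries.

## Bioclimatic covariates

Six bioclim covariates are derived cell-wise from twelve monthly values:
annual mean temperature (`mat`, C), temperature seasonality (`ts`, the
population standard deviation of monthly means as a percentage of the annual
mean), maximum temperature of the warmest month (`twp`, C), annual
precipitation (`ap`, mm), precipitation seasonality (`ps`, percent), and
precipitation of the driest month (`pdp`, mm). Two conventions exist for
`ts`; the default is percent-of-mean, with `ts_convention = "sd_x100"`
switching to the plain scaled standard deviation. Percent-of-mean is
undefined where the annual mean is at or below 0 C; such cells become nodata
with a warning rather than receiving an invented value. "Period" here is the
calendar month: the inputs are monthly surfaces, and inventing weekly values
by interpolation would add structure the data do not contain.

Decade labels are represented by climatologies: `window_average()` takes the
month-wise mean of yearly series in a closed symmetric window (default
half-width 10 years, i.e. 21 series). A symmetric window is the only
self-consistent reading when a decade label must be centred on its year; the
half-width is a parameter for users who prefer a different smoothing span.

## The maximum-entropy model

For each species the package fits a Gibbs distribution over background cells,
\(q_\lambda(x) \propto \exp(\lambda \cdot f(x))\), choosing \(\lambda\) to
maximise the L1-penalised presence log-likelihood

\[
\ell(\lambda) = \frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i)
  - \log Z(\lambda) - \sum_j \beta_j |\lambda_j| ,
\]

with \(Z(\lambda) = \sum_{b \in \text{background}} e^{\lambda\cdot f(b)}\).
This is the presence-background maximum-entropy estimator: among all
distributions whose feature expectations match the presence sample (up to the
\(\beta\)-slack), it selects the one of maximum entropy.

Features are the linear, quadratic and pairwise-product transforms of the six
covariates (27 features), min-max normalised to [0, 1] on the background and
clamped to that range at prediction time. Hinge and threshold features of the
original Maxent software are deliberately out of scope; the quadratic family
already represents Gaussian-like (unimodal, elliptical) niches exactly on the
log scale, which is the behaviour the method's character depends on.

Presences are deduplicated to one per cell before fitting, and presence cells
are added to the background sum (the standard presence-background
construction; both behaviours are arguments). The default penalties are
\(\beta_j = \beta_{\text{mult}}\, s_j/\sqrt{m}\) where \(s_j\) is the feature
standard deviation over the *presence sample*, floored at 5% of the
background standard deviation, and \(\beta_{\text{mult}} = 1\). Scaling by
the presence spread follows the classic error-bound argument (the penalty
absorbs the sampling error of the presence feature means) and matches the
original algorithm's default; scaling by the background spread
(`beta_scale = "background"`) is available but over-regularises species whose
niches are narrow relative to the landscape — in recovery experiments it
roughly doubled the spread of the fitted distribution, inflating
entropy-based range estimates by a factor of about two.

The objective is concave; `fit_maxent()` uses accelerated proximal gradient
(FISTA) with backtracking line search, monotone restarts, and soft
thresholding for the L1 part. The convergence contract is the KKT condition:
the minimal-norm subgradient must fall to `1e-6` (or the objective change to
`1e-9`); hitting the iteration cap raises an error reporting the final
gradient norm rather than returning a silently unconverged model.

### Outputs, evaluation, thresholding

The *raw* output is \(q_\lambda\), a probability distribution over background
cells (its conservation to 1 is asserted in the test suite). The reported
suitability index is the logistic transform
\(e^{H} q / (1 + e^{H} q)\), where \(H\) is the entropy of the fitted raw
distribution; it is strictly inside (0, 1) and equals 0.5 where a cell's raw
score equals the typical presence score \(e^{-H}\).

Models are evaluated by training AUC in the Mann-Whitney formulation (ties
count one half) against the background sample; no train/test split is applied
because none is part of the procedure being reproduced. Models with AUC below
0.7 are excluded from species-level summaries but retained for richness
stacking, where individual weak models matter little.

Binary ranges use the entropy-equating threshold: retain the \(k\) most
suitable landscape cells where \(k = \mathrm{round}(e^{H})\), clipped to
\([1, N]\) — the cell count whose uniform-distribution entropy is closest to
\(H\). The threshold is computed once on the baseline landscape and reused
for every future projection, giving each species a single species-specific
threshold. This rule is known to be liberal for peaked distributions: for a
Gaussian suitability profile the retained area exceeds the area above any
moderate suitability quantile (the analysis below quantifies this for the
synthetic scenario).

## Ensemble projection

Each fitted model is projected onto every (circulation model, realization,
decade) climate stack. Per decade the ensemble is summarised by the
*realization-weighted* mean: cell-wise mean over realizations within each
circulation model, then the unweighted mean across models — equivalent to
weighting each realization by \(1/(n_{\text{models}}\, n_r(g))\), so models
contributing many realizations do not dominate. With the published ensemble
structure of eight models carrying (1, 3, 3, 4, 1, 1, 9, 8) realizations this
yields exactly 30 surfaces per decade and 300 per species over ten decades.
Extremes are the unweighted cell-wise minimum and maximum (weighting-invariant
by construction) and feed sensitivity outputs only.

Binarisation happens on the ensemble-mean map, not per realization; whether
to threshold before or after averaging is genuinely open, and mean-then-
threshold is the reading consistent with thresholding "the" projection of a
species. Climate-change maps contrast the two-stage future mean with the
baseline: absolute differences for temperature variables, ratios for rainfall
variables (nodata where the baseline is zero).

## Dispersal scenarios

The current *potential* range (thresholded baseline suitability) is clipped
to subregions with at least one occurrence record, giving the current
*realized* range — subregions never reporting the species are treated as
unsuitable for reasons beyond climate. Three future scenarios apply:

* **full** — the future potential range, unclipped;
* **rate-limited** — intersection with a decade-indexed mask: all cells whose
  centre lies within \(r \times 10 \times d\) km of the current realized
  range (Euclidean distance between cell centres, exact distance transform),
  with default rate \(r = 3\) km/yr giving radii 30, 60, ..., 300 km over ten
  decades;
* **none** — intersection with the current realized range (cell-level by
  default; `none_level = "region"` relaxes this to occupied subregions, since
  the constraint "confined to currently occupied subregions" admits both
  readings).

Masks are anchored on the current range, not grown iteratively from each
decade's occupied area; an iterative mode would be a different (and
path-dependent) model and is intentionally not provided. Masks are therefore
nested across decades and always contain the current range, which forces the
scenario nesting none ⊆ rate-limited ⊆ full, cell-wise, everywhere — one of
the package's tested invariants.

The **realistic** scenario is pure selection: each species' metadata assigns
it one of the three categories (from movement ecology and habitat
specificity, supplied as input, never computed), and the matching output is
taken per species.

## Range and assemblage summaries

`class_stats()` reimplements per-class landscape statistics from first
principles: patch count by connected-component labelling (queen connectivity
by default, rook available; the choice is configurable because no universal
convention exists), areas from uniform cell areas on km grids, proportion of
the non-nodata landscape, and edge length as the count of presence-absence
or presence-border rook edges times the cell side.

Proportional change is future area over current realized area, with the
direction classified on the ratio rounded to two decimals (so 1.004 is "No
change", matching how such tables are conventionally printed and read).
Assemblage summaries count and average increasers and decreasers; group
contrasts across movement classes or biogeographic groups use one-way
fixed-effects ANOVA (via `aov`) with per-group quartiles for boxplots. No
multiple-testing correction is applied to the two ANOVAs, mirroring the
reporting convention of raw F and P. Richness maps are cell-wise sums of
binary ranges over *all* species, and richness change is their difference
between decades.

## The synthetic study system

Real inputs (atlas records, interpolated climate surfaces, a biogeographic
regionalisation) are deliberately not required. The `synthetic_data`
generators produce a landscape with the statistical structure the analysis
assumes, plus known truth for validation:

* **Grid**: 80 x 60 cells of 5 km (a 400 x 300 km domain), Euclidean
  coordinates in km. Working in km keeps all buffering logic exact; degree
  rasters should be converted via a mean cell size.
* **Baseline climate**: temperature = 25 C at mid-domain with a
  -10 C / 1000 km meridional gradient (cooler "poleward" = +y), a 4 C
  seasonal cosine cycle peaking in January, and independent cell-month noise
  (sd 0.2 C). Precipitation distributes 1000 mm/yr with 85% in a four-month
  wet season, a +1.5 / 1000 km fractional meridional gradient, and 3%
  multiplicative noise. The gradient is steeper than continental reality so
  that a desk-scale domain spans a meaningful climatic range.
* **Futures**: four circulation models with (1, 2, 3, 2) realizations, per-
  decade warming trends 0.12-0.32 C (ensemble mean ~0.22 C/decade, i.e. ~2 C
  by 2080, mid-range-scenario scale) and precipitation factors 0.98-1.01,
  plus small per-realization offsets. Precipitation is clamped at zero.
* **Subregions**: a Voronoi mosaic of 12 contiguous regions around uniformly
  drawn seed cells.
* **Virtual species**: Gaussian niches over the six covariates,
  \(s(x) = \exp(-\tfrac12 \sum_v ((x_v - c_v)/w_v)^2)\), centres stratified
  along the climatic gradient (lower 70% of the domain, leaving room to
  document poleward shifts before ranges exit the grid). Widths are 0.35
  landscape standard deviations for `mat`, `twp`, `ap`, `pdp` and 4 standard
  deviations for the two seasonality indices: in this landscape the spatial
  variation of `ts` and `ps` is dominated by sampling noise of the monthly
  values, and a narrow tolerance there would make the "true range" a
  microclimate lottery that no climate-surface model could recover — not a
  property of real species ranges. The true range is suitability at or above
  0.10 of the peak (prevalence ~15-20% of the landscape, typical of the
  widespread species such analyses target).
* **Occurrences**: 400 presence draws per species with probability
  proportional to suitability times a mild longitudinal accessibility bias
  (0.5-1.5), snapped to cell centres, duplicates allowed (atlas-like);
  fitting uses the first 200 unique cells.

What the generator does *not* emulate: real spatial autocorrelation structure
of interpolated climate, survey-effort bias correlated with the climatic
gradient, non-Gaussian or multimodal niches, interannual variability (the
baseline is a single climatology), and land-use constraints. Passing the
recovery tests therefore demonstrates that the estimation machinery is
correct and well-calibrated under its own assumptions — not that any real
dataset would meet those assumptions.

### What recovery looks like under these conditions

With the defaults above, each of the twelve virtual species is recovered with
training AUC above 0.9 and Jaccard overlap above 0.6 between the
entropy-thresholded predicted range and the true range, and all twelve
recovered ranges shift poleward by 2080 under the imposed warming (the
acceptance script recomputes these numbers from scratch). The ~1.3x
liberality of the entropy-equating rule for peaked suitability profiles is
visible in the Jaccard ceiling: the predicted range is systematically
somewhat larger than the true range, which is the documented behaviour of the
threshold rule, not an estimation error.

## Numerical choices and degenerate inputs

* Ties in Voronoi assignment go to the lowest region id; ties in AUC scores
  count one half; the k-th largest logistic value is taken after a
  descending sort with nodata dropped.
* A cell is inside a dispersal buffer if its centre is within the radius;
  distances are exact centre-to-centre Euclidean values, so buffer tests can
  be (and are) verified against brute-force distance computations.
* Empty current ranges produce empty masks with a warning; a species whose
  realized range is empty is excluded from change records with a warning.
  Degenerate fitted distributions (point mass) threshold to the single top
  cell. Zero-variance group comparisons define F = 0, p = 1.
* All generators draw from seeds derived deterministically from one master
  seed per run, so any keyed subset (a single species, one realization) is
  reproducible in isolation and two runs of the same configuration are
  bit-identical.
* Problem sizes in the bundled scenario (80 x 60 grid, 12 species, 8
  realizations, 10 decades) were chosen so a full run takes well under a
  minute on one core while every stage still exercises its full code path;
  the record counts of continental atlas datasets are orders of magnitude
  larger and are intentionally not emulated.

## Limitations

The maxent implementation covers the default feature family and a single
regularisation multiplier, not hinge/threshold features or cross-validated
tuning. AUC is training AUC. Emission scenarios beyond a single labelled
pathway, circulation-model skill weighting, mechanistic dispersal kernels,
landscape resistance, and habitat-mediated colonisation lags are out of
scope. Raster I/O uses a self-describing plain-text format (one file per
layer) rather than GeoTIFF; the containers are small matrix-backed objects,
and users with real rasters should bring their own import step onto a km
grid.
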