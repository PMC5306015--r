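---
title: "Modelling farmland bird richness from landscape composition and heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling farmland bird richness from landscape composition and heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Farmland conservation can act on *what* a landscape is made of
(composition: the identity and amount of land-cover types) or on *how
diverse and how arranged* those covers are (compositional heterogeneity:
richness, diversity and evenness of cover types; configurational
heterogeneity: patch sizes, shapes and edge density). `farmscape`
implements a complete, testable pipeline for separating these influences
on bird species richness in agricultural mosaics: species richness per
transect is modelled against 24 landscape variables measured in a 250-m
buffer, organised into six a priori variable sets — composition,
compositional heterogeneity and configurational heterogeneity of the
*natural* component (woodlands, open woodlands, shrublands, streams,
water bodies) and of the *production* component (arable land with
scattered trees, annual dry crops, permanent pastures, annual irrigated
crops, permanent crops).

The pipeline runs three analysis modes per species group: spatial
variation within each of two survey periods (T0, T1; Poisson GLM with log
link on richness counts) and temporal variation (Gaussian GLM with
identity link on richness differences T1 − T0). Species groups are
`all`, `woodland`, `farmland` and `steppe` (steppe birds being
open-grassland farmland specialists, by default counted as a subset of
farmland).

## Landscape metrics

Metrics are computed directly on categorical rasters (integer codes; 0 =
outside buffer), re-implementing the standard FRAGSTATS-style
definitions:

* **Composition** — percent cover of each category relative to buffer
  area; covers sum to 100.
* **Compositional heterogeneity**, per component — cover richness (count
  of categories present), Shannon diversity $H=-\sum p_i\ln p_i$, and
  Pielou evenness $H/\ln S$. Proportions $p_i$ are taken relative to the
  *component's own* area, not the whole buffer, so the diversity of a
  thin natural component is comparable with that of a dominant
  production component. Evenness is defined as 0 when $S \le 1$ (field
  data summaries show minima of exactly 0, which would be impossible if
  undefined values were dropped). Absent components score 0 on all
  metrics.
* **Configurational heterogeneity**, per component — largest patch index
  (largest patch as % of buffer area), mean patch size (ha), edge
  density (m/ha) and mean shape index. Patches are maximal 8-connected
  same-category regions (4-connectivity available). The shape index uses
  the raster form $0.25\,P/\sqrt{A}$ in cell units, so a square patch
  scores exactly 1. Edge density counts each internal edge between two
  in-buffer cells of different categories once (for each component
  touching it); the buffer boundary and grid border contribute to patch
  *perimeter* but are excluded from edge density, which avoids artefacts
  of buffer shape.

Every metric implementation is checked exactly against brute-force
oracles (recursive flood fill, exhaustive edge enumeration) on hundreds
of random mosaics, and against invariances: category-code permutation,
rotation and mirroring leave heterogeneity metrics unchanged.

The 24 variable columns use component-prefixed snake_case names
(`nat_edge_density`, `prod_cover_diversity`, ...) because the field's
conventional display names duplicate across components and cannot serve
as CSV headers.

## Transforms and the analysis matrix

Proportional variables (the ten covers, LPI rescaled to [0, 1],
evenness) receive the angular transform $\arcsin\sqrt p$; continuous and
count variables (diversity, cover richness, patch size, edge density,
shape) receive $\ln(x+1)$. The +1 offset is a package choice — landscape
metrics are frequently exactly 0 — and is configurable. In temporal mode
the package differences *transformed* predictors by default
(`delta_on = "transformed"`, more stable across the very different
scales of the variables); raw-scale differencing is one switch away, and
raw differences are always used for the richness response. Paired
t-tests (`paired_t()`) describe the temporal change of each variable.

## Two-stage multimodel inference

**Stage 1 — set screen.** All $2^6-1 = 63$ non-empty combinations of the
six variable sets are fitted; each set appears in exactly 32 candidates
and every variable appears together with every other variable in some
model. Model support is measured by Akaike weights
$w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)$ from AICc
$= -2\ell + 2k + 2k(k+1)/(n-k-1)$, where $k$ counts the intercept, the
slopes, and the Gaussian residual variance (taken from the exact model
log-likelihood). A set's importance is the summed weight $w_{i+}$ of the
models containing it; sets with $w_{i+} > 0.5$ are carried forward.

**Stage 2 — variable-level averaging.** All subsets of the retained
variables (including the intercept-only model, which calibrates the
weights) are fitted. Within each model, every variable's unstandardized
coefficient is multiplied by its *partial standard deviation*

$$s^*_j = s_j \sqrt{1/\mathrm{VIF}_j}\,\sqrt{(n-1)/(n-p)},$$

which discounts the sample SD by the variable's variance inflation
factor in that model, acknowledging that intercorrelated predictors
carry overlapping information. $p$ counts the mean-structure
coefficients including the intercept (the convention is exposed as an
argument, since usage varies). Relative importance within a model is the
ratio of the absolute standardized coefficient to the largest absolute
standardized coefficient in that model — the dominant variable of every
model scores exactly 1, and exact ties share the 1. Both the
standardized coefficients and the importances are averaged *across the
models containing the variable*, with Akaike weights renormalized over
those models (conditional averaging, matching the per-model definition
of the ratio; zero-filled full averaging would conflate absence with
smallness). Standardized coefficients are invariant to affine rescaling
of any predictor, which the tests verify numerically.

For Gaussian (temporal) models the standardized coefficients are
additionally divided by the response sample SD (toggleable), so
coefficients remain comparable across response groups with different
variances. The deviance-based pseudo-$R^2$ of the global model,
$1 - D_{model}/D_{null}$, summarises explanatory power.

When no set passes the 0.5 screen, stage 2 is skipped and the run report
says so; diagnostics then fall back to the intercept-only model.

## Spatial autocorrelation diagnostics

Residual spatial structure would bias both the screen and the averaged
coefficients, so the package estimates nonparametric spline
correlograms: values are centred and scaled, all pairwise products
$z_i z_j$ are regressed on pairwise distance with a cubic smoothing
spline (default equivalent degrees of freedom $\min(10, \sqrt n)$), and
a 95% pointwise envelope comes from $B$ bootstrap resamples of sites
(1,000 by default; resamples are re-standardised, self-pairs excluded).
The evaluation grid runs to half the maximum pairwise distance by
default, avoiding the sparse far tail. Correlograms are computed for the
raw response and for model residuals (deviance residuals for Poisson
models; Pearson via a flag), and autocorrelation counts as removed when
the residual envelope contains zero over at least 95% of the grid — the
reference methodology gives no numeric rule, so this operational
definition is a package constant, configurable.

## The synthetic-landscape generator

Because the pipeline's claims must be verifiable without field data, the
package ships a generator whose defaults emulate the target study
design: 73 sites × 2 periods; a circular buffer mask inscribed in a
45 × 45 grid of 50-m cells; 5 natural + 5 production categories. Each
category enters a buffer independently (presence probability 0.3 for
natural, 0.33 for production categories, at least one production
category always present), reproducing the sparse cover richness of real
farmland buffers (natural cover richness ranging 0–5 around a mean near
1.5, production 1–5 around 2.3); shares within a component are
Dirichlet-distributed, and the natural component's total share is
Beta-distributed around 15%. Composition is realised *exactly* by
multi-seed region growing — each category receives about one seed per
`aggregation` (default 60) cells of target and claims unclaimed frontier
cells, largest deficit first, re-seeding when a region is walled in — so
realised covers differ from drawn proportions only by integer rounding.
A threshold-on-noise generator was rejected because it cannot hit
composition targets exactly, which the generator tolerance tests
require.

Responses are drawn from the assumed model itself:
$\eta = \beta_0 + X\beta$ on unit-variance transformed predictors (so
$\beta$ entries are effect sizes per predictor SD), Poisson counts
$\mathrm{Pois}(e^\eta)$ for spatial modes, Gaussian for temporal deltas,
with an optional exponential-covariance Gaussian field (Cholesky
factorisation; adequate at these small $n$) added to $\eta$ for spatial
autocorrelation experiments. The documented strong-effect default is
$|\beta| = 0.3$ on the five production-composition covers with
$\beta_0 = \ln 10$, giving richness counts in a realistic range
(roughly 0–40) and high but unsaturated single-run power for the set
screen. Survey records are then emitted so that pooled distinct-species
counts reproduce the richness targets exactly across the three survey
years of each period, with duplicate records sprinkled in (pooling must
be invariant to them).

What the generator does *not* emulate: detection error, observer
effects, species-level community assembly, within-period land-cover
change, and real parcel geometry. Passing tests therefore demonstrate
the correctness and statistical behaviour of the pipeline under its own
assumptions, not ecological conclusions about any real landscape.

## Problem sizes and numerical choices

The shipped test-and-demonstration sizes are package choices balancing
Monte-Carlo resolution against desk-scale runtimes: recovery experiments
use 73 sites with 40–100 response replicates over fixed landscapes
(regenerating landscapes per replicate adds nothing, as the response is
the only stochastic stage under test); correlogram calibration uses
50–60 sites with 99–199 bootstrap resamples (the pointwise envelope
needs only percentile resolution; the 1,000-resample default remains for
analyses); the demo pipeline runs all 12 group × mode analyses at full
size. Further numerical conventions: Akaike weights are computed after
subtracting the minimum AICc (shift-invariant, overflow-safe); VIFs come
from the inverse correlation matrix, with near-singular matrices
(diagonal beyond 1e12) treated as perfect collinearity and refused;
rank-deficient candidate designs are refused naming the collinear
column; stage-2 enumeration refuses more than 20 variables (2^20
models) unless the cap is raised explicitly; correlogram estimates are
clamped to [−1, 1].

## Known limitations

* Raster IO is limited to the ESRI ASCII grid dialect (with stable
  header order, so round trips are byte-identical).
* The stage-2 candidate space grows as $2^v$; with all six sets retained
  (24 variables) the enumeration exceeds the default cap and must be
  raised deliberately.
* The correlogram envelope is pointwise, not simultaneous; the 95%
  coverage rule is calibrated accordingly.
* Overdispersion is reported (Pearson $\chi^2/(n-p)$) but not corrected;
  quasi-likelihood or negative-binomial refits are out of scope.
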