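# farmscape

Does farmland bird diversity respond to what a landscape is made of, or
to how heterogeneous it is? `farmscape` is an R package for separating
the effects of **landscape composition** (the identity and amount of
land-cover types) from those of **compositional heterogeneity**
(richness, diversity, evenness of cover types) and **configurational
heterogeneity** (patch sizes, shapes, edge density) on bird species
richness in agricultural mosaics. It is aimed at landscape ecologists
analysing transect-based bird surveys with categorical land-cover maps,
and at methodologists who need a fully testable reference implementation
of the two-stage information-theoretic workflow.

The pipeline:

1. **Landscape metrics** — FRAGSTATS-style composition and heterogeneity
   variables computed on categorical rasters within survey buffers, for
   the *natural* and *production* components separately (24 variables in
   six a priori sets).
2. **Design matrices** — angular transforms for proportions
   (arcsin sqrt(p)), log(x+1) for continuous metrics, temporal deltas,
   paired t-tests of change.
3. **Two-stage multimodel inference** — stage 1 fits all 2^6 − 1 = 63
   combinations of the six variable sets and screens them by summed
   Akaike weights, w_i+ > 0.5, from AICc
   (−2LL + 2k + 2k(k+1)/(n−k−1)); stage 2 enumerates all subsets of the
   retained variables and averages **partial standardized coefficients**
   b_j · s_j · sqrt(1/VIF_j) · sqrt((n−1)/(n−p)) and per-model relative
   importances (|coef| / max |coef| within each model) with
   conditionally renormalized Akaike weights.
4. **Spatial diagnostics** — nonparametric spline correlograms with
   bootstrap 95% pointwise envelopes, applied to raw responses and model
   residuals to verify that the landscape models removed spatial
   autocorrelation.
5. **Synthetic data** — a region-growing landscape generator plus
   Poisson/Gaussian response and survey-record simulators with known
   ground truth, so every stage is verifiable end to end without field
   data.

## Worked example

Simulate 73 sites whose richness is driven by the production-composition
variables, then run the full two-stage inference:

```r
library(farmscape)

sc   <- sim_config(seed = 11)             # 73 sites, strong-effect defaults
land <- simulate_landscape_set(sc)
met  <- metric_table(land$mosaics)

resp <- simulate_response(met[met$period == "T0", ], sc, seed = 21)
rt   <- data.frame(site_id = resp$site_id, period = "T0", group = "all",
                   richness = pmax(0L, as.integer(round(resp$response))))
mat  <- build_matrix(met, rt, mode = "spatial_T0", group = "all")

(s1 <- stage1_screen(mat))
#>               set w_plus retained
#> 1        nat_comp 0.0108    FALSE
#> 2       prod_comp 1.0000     TRUE
#> 3  nat_compos_het 0.1585    FALSE
#> 4  nat_config_het 0.2064    FALSE
#> 5 prod_compos_het 0.0627    FALSE
#> 6 prod_config_het 0.2953    FALSE
```

The generating set (`prod_comp`) gets essentially all the summed Akaike
weight and is the only set passing the 0.5 screen. Stage 2 then averages
partial standardized coefficients over all 2^5 = 32 subsets of its five
variables:

```r
stage2_average(mat, variable_sets()[s1$set[s1$retained]])
#> averaged_model over 32 candidates (pseudo-R2 of global model: 0.830)
#>                variable avg_coef importance w_plus
#>  arable_scattered_trees   0.1024      0.359  0.991
#>        annual_dry_crops   0.0578      0.250  0.644
#>      permanent_pastures  -0.3074      0.903  1.000
#>  annual_irrigated_crops  -0.2394      0.747  1.000
#>         permanent_crops  -0.3021      0.944  1.000
```

`avg_coef` is the model-averaged partial standardized coefficient
(effect per partial SD of the predictor), `importance` the averaged
within-model ratio to the dominant coefficient (1 = dominant in every
model), and `w_plus` the variable-level summed Akaike weight. A
correlogram of the response checks for residual spatial structure:

```r
spline_correlogram(land$sites[, c("x", "y")], mat$response,
                   B = 199, seed = 99)
#> spline_correlogram: n = 73 sites, B = 199 resamples, df = 8.54
#>   e0 = 0.039, x-intercept = 691.1 m, grid 0..12746.5 m
```

`run_pipeline(default_config(seed = 1), out_dir = "run")` performs the
whole analysis (4 species groups × 3 modes, correlogram diagnostics,
CSV outputs, markdown report, JSON manifest) in one reproducible call.

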