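# kelpCSP

Carbon export, decomposition and sequestration potential of *Laminaria*
kelp forests.

Kelp forests shed most of their production as eroding lamina detritus.
Whether that carbon counts towards blue carbon sequestration depends on how
fast the detritus is remineralized — and in the Northeast Atlantic the three
forest-forming *Laminaria* species differ sharply: the warm-temperate
*L. ochroleuca* exports as much carbon per plant as *L. hyperborea* but its
detritus decomposes much faster. As ocean warming shifts forest composition
towards the warm-temperate species, the ecosystem's carbon sequestration
potential (CSP) can fall even while total export stays stable. kelpCSP is
for quantitative ecologists who want that full carbon-flux chain —
measurement reduction, budget, decay model, climate projection — as tested,
reproducible code.

## What it computes

At its core is the linear CSP decay model

```
CSP(t) = N · CE · max(0, 1 − t·D)
```

with N the zone-weighted sporophyte density (plants m⁻²), CE the per-plant
carbon export (g C plant⁻¹ yr⁻¹) and D the decomposition rate (day⁻¹); the
95% CI uses Goodman's variance of a product of independent means,
`z·√(SE_N²SE_CE² + SE_N²CE² + SE_CE²N²)`, and the pool empties at
t = 1/D (SE by the delta method). Around it:

- **Erosion → export**: hole-punch reductions (G = H_F − H_I,
  E_L = L_I + G − L_F, E_M = E_L·ML_R/Δt), carbon conversion, monthly →
  seasonal/annual aggregation with variance-sum SEs, areal export.
- **Decomposition & biochemistry**: litterbag rates D = (M₀−M₁)/(M₀Δt),
  grazing-scar proportions, phloroglucinol standard curves, detrital-age
  trends (linear and log-linear OLS).
- **Respirometry**: blank-corrected NPP/R/GPP from paired light/dark
  incubations, photoinhibition screening (≥ 971 µmol photons m⁻² s⁻¹),
  carbon assimilation CA = NPP·10⁻⁶·12.0107/M_R.
- **Range projection**: LOESS-smoothed SST series, threshold-linear density
  models for cold- (August SST vs T_U) and warm-temperate (February SST vs
  T_L = 9.53 °C) species, forest CE_T and CSP_T through time.
- **Detrital assimilation**: tanh photosynthesis–irradiance curve,
  exponential light attenuation, cumulative carbon assimilation along a
  sinking trajectory.
- **Synthetic data**: generators reproducing the field designs (10
  plants/month, 43 litterbags, 42 incubation pairs, 27 biochemistry records
  per species) so everything runs without external data.

## Worked example

```r
library(kelpCSP)

m <- csp_model(N = 1.7, CE = 75, D = 0.0154,
               se_N = 0.2, se_CE = 9, se_D = 0.0023,
               species = "ochroleuca")
m
#> Linear CSP decay model [ochroleuca]
#>   CSP(t) = N * CE * (1 - t * D),  annual
#>   N  = 1.700 plants m^-2 (SE 0.200)
#>   CE = 75.00 g C plant^-1 (SE 9.00)
#>   D  = 0.0154 day^-1 (SE 0.0023)
#>   CSP(0) = 127.5 g C m^-2; reaches zero at 65 days (SE 9.7)
```

127.5 g C m⁻² yr⁻¹ of exported carbon is available at the moment of export;
at 1.54% mass loss per day the detrital pool is fully remineralized after
65 days. `predict(m, t = 0:65)` gives the curve with its CI band.

The full pipeline on a synthetic data set:

```r
set.seed(1)
res <- run_kelp_pipeline(T_U = 23, seed = 1)   # T_U: cold-species thermal limit
res$summary
#>               species areal_CE_gC_m2_yr D_pct_day t_zero_days CA_net_mg_g_h
#> digitata     digitata              87.1     1.250          80         0.991
#> hyperborea hyperborea             203.8     0.501         200         0.761
#> ochroleuca ochroleuca             137.5     1.629          61        -0.142
#>            cumulative_CA_gC_m2
#> digitata                 104.0
#> hyperborea               183.5
#> ochroleuca                74.4
```

Areal export is highest for *L. hyperborea* and the time to zero CSP is
shortest for *L. ochroleuca* (61 d here, estimated from noisy synthetic
litterbags) — the warm-temperate species contributes carbon that disappears
fastest, and its detritus is a net carbon emitter on average
(negative CA). `res$decline_rates` gives the geometric-mean annual CSP
decline per temperature scenario, steepest under RCP8.5.

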