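# ballastr

Ballast water — seawater carried for vessel trim and discharged when cargo
is loaded — is a primary pathway for marine bioinvasion. `ballastr` is an R
package for quantifying that transport risk over a shipping network. It is
written for quantitative ecologists and biosecurity analysts who have (or
must simulate) three tabular inputs: a voyage history, a ballast tank
census, and a port/ecoregion gazetteer.

The pipeline:

1. **Vessel geometry.** Deadweight tonnage from vessel length via the
   ship-design cube-root relation
   `DWT = L^3 * rho * C_B * C_D / ((L/B)^2 * (B/H))`
   (defaults C_D = 0.8, C_B = 0.75, L/B = 6.5, B/H = 2.2, rho = 1.025);
   ballast capacity as 30% of DWT; curation of records with length
   outside (0, 345] m or discharge above 120% of calculated DWT.
2. **Discharge models.** For tankers/containers/other: OLS on calculated
   ballast capacity and destination-port purpose, with candidate predictor
   sets ranked by BIC. For bulkers: a K-component mixture of linear
   regressions, `y ~ beta1_j + beta2_j * x + N(0, sigma_j^2)` with weights
   `p_j`, fitted by EM (compiled inner loop, random-responsibility
   restarts, degeneracy detection) and K in 1–5 chosen by AIC / AIC3 /
   MDL / BIC; repeated random-sampling cross-validation.
3. **Hindcast.** Expected discharge and predictive variance for every
   voyage in the history, with exactly conserved aggregates by year, port,
   ecoregion and route, plus volume-weighted provenance-consistency
   statistics (uptake vs source, discharge vs arrival).
4. **Routing.** Great-circle distances (1 nm = 1 arc-minute) on an
   over-water visibility graph built from shoreline polygons; shortest
   paths via Dijkstra; durations at 15 knots.
5. **Risk.** Propagule pressure per voyage as
   `volume * D(0) * r * exp(-lambda * T)` with
   `lambda = mu1 * p + mu2 * (1 - p)` under mid-ocean ballast-water
   exchange (defaults D(0) = 2113.489 organisms/m3, lambda = 0.161/day,
   p = 0.5, r = 1); route and ecoregion rankings and a lambda sensitivity
   analysis over [0.01, 0.50].

A synthetic world generator (`gen_world()`, `gen_fleet()`,
`gen_voyages()`, `gen_ballast_census()`) with known ground truth stands in
for the confidential shipping and census data and drives all tests.

## Worked example

```r
library(ballastr)

man <- run_pipeline(pipeline_config(
  fleet = fleet_config(n_vessels = 800),
  traffic = traffic_config(years = 1999:2008, base_intensity = 3),
  K_range = 1:5, n_restarts = 3, cv_repeats = 5,
  lambda_grid = seq(0.01, 0.5, length.out = 10), seed = 42),
  out_dir = "ballastr_out")
man
#> <run_manifest> seed 42, 2863 voyages, 5735 ballast events, K* = 4
#>   config 018361d3e1d28f2ed051daab97411c6d; 19 output files in ballastr_out

tidy(man$results$models$bulker)
#> # A tibble: 4 x 5
#>   component weight intercept  slope sigma
#>       <int>  <dbl>     <dbl>  <dbl> <dbl>
#> 1         1  0.232      391. 0.0499  255.
#> 2         2  0.336     1355. 0.297  1230.
#> 3         3  0.286     1185. 0.593  1713.
#> 4         4  0.146     1509. 0.948  2079.
```

The four components are the discharge regimes of the bulker fleet, from
minimal (slope ~0.05 m3 discharged per m3 of capacity) to heavy ballast
(~0.95); the generator's true slopes are 0.05/0.30/0.60/0.95 with weights
0.25/0.30/0.30/0.15, so the EM fit has recovered the regimes from 1,430
curated bulker voyages, and MDL selected the true component count. The
manifest's digests make the run reproducible: the same config and seed
give byte-identical output files.

Downstream, `man$results$by_year` holds the annual hindcast totals,
`top_routes(man$results$risk, "propagules", 20)` the dominant routes with
their share of total propagule pressure, and
`autoplot(man$results$sensitivity)` the ecoregion rank trajectories as the
decay rate varies — near sources climb in importance as decay strengthens,
high-volume distant sources stay dominant at low decay.

See the vignette (`vignettes/ballast-risk-methods.Rmd`) for the models,
their assumptions, and the design decisions.

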