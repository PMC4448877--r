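---
title: "Modelling ballast-water discharge and propagule pressure with ballastr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ballast-water discharge and propagule pressure with ballastr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballastr)
library(dplyr)
```

## The problem

Commercial vessels carry ballast water for trim and stability and discharge
it — along with whatever coastal organisms it contains — when they load
cargo. Ranking shipping routes and marine ecoregions by the number of
viable organisms they deliver (propagule pressure) requires three model
components that ballastr implements end to end:

1. a **per-voyage discharge model** built on vessel geometry and
   destination-port purpose, fitted to a ballast census and hindcast over a
   much longer voyage history;
2. an **over-water routing model** giving voyage durations between ports;
3. a **survival model** converting discharge volume and voyage duration
   into surviving propagules, with mid-ocean ballast-water exchange (BWE).

Because real ballast censuses are confidential government data, the package
ships a synthetic-data generator (`gen_world()`, `gen_fleet()`,
`gen_voyages()`, `gen_ballast_census()`) whose ground-truth parameters are
known, so every stage is testable offline. All tabular inputs and outputs
are tibbles, and results chain with the pipe.

## Vessel geometry and curation

Deadweight tonnage (DWT) is derived from vessel length by inverting the
ship-design "cube root" relation,

$$\mathrm{DWT} = \frac{L^3\,\rho\,C_B\,C_D}{(L/B)^2\,(B/H)},$$

with defaults $C_D = 0.8$, $C_B = 0.75$, $L/B = 6.5$, $B/H = 2.2$ and
seawater density $\rho = 1.025$ — mid-range design-guideline values for the
cargo fleet. The printed form of this relation is typographically ambiguous;
we adopt the rearrangement above because it is the only one that makes DWT a
linear function of $L^3$ with realistic magnitudes (a 225 m Panamax comes
out near 75 kt). Ballast capacity is taken as 30% of calculated DWT. The
tonnes-to-m³ distinction (factor $\rho$) is at most 2.5% and is not applied
by default; `calc_ballast_capacity(..., convert_to_m3 = TRUE)` applies it.

`calc_block_coefficient()` implements the speed–length relation
$C_B = 1.23 - 0.395\,V/\sqrt{L}$ for completeness; the pipeline fixes
$C_B = 0.75$.

Curation (`curate_ballast()`) removes records with length ≤ 0 m or
> 345 m, and records whose discharge exceeds 120% of calculated DWT.
Length rules are applied before the feasibility rule, so a record failing
both is counted once under the length rule; records with missing fields are
counted separately as `"missing"`. Curation is idempotent.

## Discharge models

**Tankers, container vessels, other.** Per-voyage total discharge is
modelled by OLS on calculated ballast capacity plus destination-purpose
offsets (one-hot, reference level first alphabetically). Candidate
predictor sets are ranked by BIC ($-2\ell + k\ln n$, $k$ counting
coefficients plus one for $\sigma$); ties favour fewer parameters, and
candidates whose design is rank-deficient are recorded as non-competing.

**Bulkers.** Bulker discharge is multi-regime: a vessel may discharge a
minimal, partial, typical or heavy-ballast volume. `em_fit_mixture()` fits
a $K$-component mixture of linear regressions,
$y_i \sim \beta_{1j} + \beta_{2j} x_i + N(0, \sigma_j^2)$ with mixing
weights $p_j$, by EM:

* E-step responsibilities from the current component densities; M-step
  per-component weighted least squares; the observed-data log-likelihood is
  non-decreasing and this is asserted at every iteration.
* Initialisation by random responsibilities; the best of `n_restarts`
  runs by final log-likelihood is kept (defaults: tol $10^{-8}$ relative,
  1000 iterations, variance floor $(10^{-6}\,\mathrm{sd}(y))^2$).
* A run is degenerate when a weight falls below $1/n$ or a variance sits at
  its floor for 10 consecutive iterations; convergence is never declared
  while a variance is pinned at the floor, so exactly-collinear data
  degenerate rather than "converge". If every restart degenerates the fit
  errors.
* $K = 1$ bypasses EM and returns the exact OLS solution. Components are
  sorted by slope for identifiability.

The inner loop is compiled (Rcpp) so that replicated selection studies run
in seconds per fit.

**Order selection.** With $k = 4K - 1$ free parameters
(intercept/slope/σ per component plus $K-1$ weights):
AIC $=-2\ell+2k$, AIC3 $=-2\ell+3k$, BIC $=-2\ell+k\ln n$, and
MDL $=-\ell+\tfrac{k}{2}\ln n$ (the common mixtures usage; the source
literature does not restate the formula, so we adopt the BIC/2 form).
`select_mixture_components()` tabulates all four over $K \in \{1..5\}$.

A caution from our own simulations (100 replicates at $n = 5000$ under the
generator's ground truth): MDL and BIC select the true $K = 4$ in ~99% of
replicates and AIC3 in ~90%, but plain AIC overselects $K = 5$ in roughly a
quarter of replicates. This is the well-known behaviour of AIC for mixture
order selection — the spurious likelihood gain of an extra component
exceeds AIC's penalty of 4 with non-vanishing probability — and is a
property of the criterion, not of the fitter. For this reason
`run_pipeline()` adopts MDL's choice as its default component count; the
full per-criterion table is always reported alongside.

**Prediction.** `predict_discharge()` returns the mixture mean
$\sum_j p_j(\beta_{1j}+\beta_{2j}x)$ with variance from the law of total
variance (or a component-then-noise draw in sample mode), truncated to
$[0,\ 1.2\,\mathrm{DWT}]$ — the curation feasibility bound. Linear models
predict the linear predictor; unseen factor levels fall back to the
frequency-weighted marginal offset with a warning.

**Cross-validation.** `cross_validate()` implements repeated
random-sampling CV (default 80% train), reporting held-out $R^2$ and the
total-discharge prediction error per repeat. One structural point is worth
stating plainly: when mixing weights do not depend on capacity — which is
exactly the generative contract of the synthetic census — the mixture's
predictive mean is itself an affine function of capacity, so its held-out
accuracy cannot systematically beat a correctly-specified single line; in
our simulations the two win equally often (~50%). On real data, where
regime membership correlates with vessel size and port purpose, the
mixture's advantage re-emerges. Passing CV tests on synthetic data
therefore demonstrate correctness of the machinery, not superiority of the
mixture under these conditions.

## Hindcasting

`hindcast_voyages()` applies the per-type fitted models to the full voyage
table: length → DWT → capacity → expected discharge and predictive
variance per voyage. Voyages whose vessel fails the geometry rules are
excluded and counted; vessels outside the fitted covariate range are
extrapolated linearly. Tank events are summed to voyage totals before any
modelling (`census_voyage_totals()`), since the models are per-journey.
`aggregate_discharge()` produces grouped totals whose sums are exactly
conserved over any complete partition (year, port, ecoregion, route);
per-voyage variances add under an independence assumption — the simplest
defensible contract, since no aggregation method is stated for the
uncertainty bars we emulate.

`provenance_consistency()` quantifies the volume-weighted agreement of
recorded ballast uptake (discharge) locations with voyage source (arrival)
ports, at port, ecoregion, or grouped-ecoregion resolution; grouping merges
named ecoregion sets (e.g. the South China Sea group and the Japan/Korea
group of `ecoregion_supergroups()`) before comparison. Coarsening can only
convert mismatches into matches, so consistency is monotone in resolution.

## Over-water routing

Distances are great-circle on a sphere whose radius is fixed by the
definition of the nautical mile (1 nm = 1 arc-minute; no ellipsoid — the
error is far below model uncertainty). `build_water_graph()` forms the
visibility graph on ports plus shoreline vertices; shoreline vertices are
nudged 0.01° offshore along the outward radial so that navigation nodes
never lie exactly on a boundary. Longitudes are normalised to (−180°, 180°]
and polygons crossing the antimeridian must be pre-split.

Two land tests are provided. The default (`land_test = "crossing"`) is
exact in the lon/lat plane: an edge is blocked iff its segment properly
crosses a polygon side or its midpoint lies inside a polygon. The
alternative `"sampled"` test checks points spaced at most `sampling_step`
nm apart (counts of the form $2^k+1$, so refining the step only ever
blocks more edges — a monotone-conservative refinement). We made the exact
test the default after observing that grazing contacts near offset
shoreline corners produce inside chords of ~0.05 nm, which no affordable
sampling step detects; the sampled test remains for very large shorelines
where the exact test's cost per polygon side matters. Shortest paths on
the graph are Dijkstra via igraph; `voyage_duration_days()` converts
distance at a fixed 15-knot service speed (360 nm/day).

## Propagule survival and risk

Organism density decays exponentially, $D(t) = D(0)e^{-\lambda t}$, with
defaults $D(0) = 2113.489$ organisms/m³ and $\lambda = 0.161$/day (coastal
zooplankton survey values). With BWE a proportion $p$ through the voyage,
survival fraction $r$, and pre-/post-exchange rates $\mu_1,\mu_2$:

$$D(T) = D(0)\,r\,e^{-\mu_1 p T} e^{-\mu_2 (1-p) T}
       = D(0)\,r\,e^{-\lambda T},\quad \lambda = \mu_1 p + \mu_2(1-p).$$

$p$ defaults to 0.5 (exchange concentrates near mid-voyage; the generator
draws the timing from Beta(8, 8), mode 0.5) and $r$ to 1. $D(0)$ and $r$
are pure scale factors: every ranking is invariant to them.

`propagule_pressure()` multiplies each voyage's expected discharge by the
surviving density at its route duration and sums per route and per
source/arrival ecoregion. `sensitivity_rank()` re-ranks ecoregions over a
λ grid (default 50 evenly spaced values on [0.01, 0.50]; λ = 0 is allowed
as the no-decay baseline, under which the ranking equals the pure-volume
ranking). For equal-volume sources the nearer one's share
is provably non-decreasing in λ ($e^{-\lambda(T_1-T_2)}$ is monotone), and
the rank trajectories make that visible (`autoplot()` on the result).
Ranking ties break by larger volume, then alphabetical source id.

## The synthetic world

The generator emulates the study conditions: four vessel classes with
truncated-normal lengths (bulkers 225 ± 40 m, tankers 220 ± 45 m,
containers 250 ± 50 m, other 120 ± 50 m, all in (30, 345]); an
11-category port-purpose scheme with mining purposes over-represented and
bulkers preferentially routed to mining ports; voyage counts that are
negative-binomial per route (mean-1 gamma multipliers, shape 0.6) growing
6%/yr over 1999–2012, which doubles annual counts over the period; a
bulker census drawn from the 4-component mixture (weights .25/.30/.30/.15,
slopes .05/.30/.60/.95, σ 250/1200/1800/2200 m³); linear-plus-noise
discharge for the other classes; a 20% uptake-provenance mismatch rate
with half of mismatches drawn within the source ecoregion (reproducing the
pattern that port-level source consistency is markedly lower than
ecoregion-level); and a configurable record-corruption rate (default 5%)
injected after clean generation and flagged, so curation counts can be
asserted exactly. Negative discharge draws are truncated to zero.

What the generator does **not** emulate: realistic coastline geometry,
seasonal traffic, economic structure in trade flows, capacity-dependent
regime membership for bulkers (see the CV note above), or behavioural
change after ballast-treatment regulation. Tests passing on this world
validate the machinery and the statistical contracts, not claims about any
real fleet.

## Numerical choices and problem sizes

* EM: tol $10^{-8}$ relative, ≤1000 iterations, 3–10 restarts depending on
  context; selection studies use 3 restarts, which recovers the global
  optimum reliably on well-separated components.
* Routing tests compare against a brute-force planar segment-intersection
  oracle on archipelagos of ≤50 nodes, with exhaustive simple-path
  enumeration (branch-and-bound) on the ≤20-node worlds.
* The packaged simulation studies run at the study scale where it matters
  (mixture recovery and order selection at $n = 5000$, 100 replicates in
  the test suite; the acceptance script reports a 30-replicate version) and
  at reduced scale elsewhere; each script states its sizes.
* All randomness flows from one root seed, split deterministically per
  stage; identical configurations produce byte-identical output files
  (verified by MD5 digests in the run manifest).

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
man <- run_pipeline(cfg, out_dir = "ballastr_out")
man$results$mixture_selection   # per-K criteria table
man$results$by_year             # annual hindcast discharge
top_routes(man$results$risk, "propagules", 20)
autoplot(man$results$sensitivity)
```

## Known limitations

* The DWT relation is a fleet-average design formula; per-vessel registry
  DWT would be better where available.
* Predictive variances assume independence across voyages; shared vessel-
  or port-level effects would inflate true uncertainty.
* The exact land test works in the lon/lat plane; near the poles or across
  very long edges the great-circle path deviates from the plane segment.
  At the mid-latitude scales generated here the discrepancy is negligible
  relative to the 15-knot duration model.
* Establishment and spread of introduced organisms are out of scope: the
  package quantifies transport risk only.
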