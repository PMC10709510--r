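# vegsucc

Grid-based simulation of herbaceous vegetation succession driven by
ecological indicator values.

## What it is for

Managers of semi-natural landscapes — national parks, protected grasslands,
post-disturbance sites — need to anticipate how plant communities respond
to changed management or site conditions: what happens to a fertilized hay
meadow when fertilization stops, or which communities assemble on a mosaic
of contrasting soils. `vegsucc` is a simulator for such questions at the
local scale. It represents the landscape as a raster of 10 m x 10 m cells,
each carrying one percent-cover compartment per herbaceous species, and
drives growth with the empirical backbone of Central European vegetation
science: ordinal 1–9 **ecological indicator values** (Ellenberg-type values
for light L, temperature T, moisture M, soil reaction R and nutrients N;
Briemle-type tolerances for cutting C, grazing G and trampling TR). The
indicator values are used *inversely*: instead of inferring site conditions
from the species present, the cell's site values predict which species can
grow.

## The model in brief

Per species and cell, each time step (weekly or daily):

* mortality frees space: `c <- c * (1 - 2/n_steps)` (200 % per year);
* each environmental factor yields a control value — land use
  `f = (1 - EIV/9)(100 - I)/100 + EIV/9`, site conditions
  `f = exp(-slope (SV - EIV)^2 / 9)` (reduced curve
  `opt_red * exp(-slope_red (SV - 5)^2 / 9)` for indifferent species);
* the eight control values combine as a weighted mean
  `f_total = sum(W f) / sum(W)` with `W = (2 - f)^w`;
* the growth rate `g = g_max (F_S - c)/F_S * f_total` (floored at 0) gives
  the step's potential growth `g c / n_steps`; the self-regulation factor
  `F_S` caps a species' own expansion and stands in for microsite
  heterogeneity;
* with probability `c/100` a cover fraction `u ~ U(0,1)` of the potential
  growth is redirected into one of the eight neighbouring cells (delivered
  one step later) — vegetative spread;
* all potentials compete for the free space by lottery: under scarcity each
  species realises `potential * available / sum(potentials)`.

An ordered decision tree aggregates each cell's cover vector into a
vegetation type twice a year for mapping and evaluation. The two free
species parameters (`g_max`, `F_S`) are fitted by the calibration module so
that observed equilibrium communities are reproduced; everything else comes
from literature indicator values and mapped site data.

## Worked example

The packaged lowland-meadow scenario carries a calibrated 17-species
hay-meadow community (dominated by *Arrhenatherum elatius*) on a
homogeneous 10 x 10 grid, in a fertilized (site N = 8) and an unfertilized
(site N = 5) form:

```r
library(vegsucc)

sc   <- make_test2("fertilized")
grid <- scenario_grid(sc)
grid
#> <veg_grid> 10x10 cells (100 modeled), 17 species
#>   steps/year: 365, mean total cover (modeled): 100.08 %

run <- run_simulation(grid, years = 30, seed = 1, record_every = 365)
lm  <- landscape_mean_cover(run)
eq  <- sort(colMeans(lm[lm$year > 25, -(1:2)]), decreasing = TRUE)
round(eq[eq > 0.5], 1)
#> arrhenatherum_elatius  alopecurus_pratensis heracleum_sphondylium
#>                  57.1                   9.9                   5.1
#>  taraxacum_officinale anthriscus_sylvestris  tragopogon_pratensis
#>                   5.1                   5.1                   4.9
#>     festuca_pratensis        galium_mollugo      ranunculus_acris
#>                   4.4                   3.8                   2.9
#>        holcus_lanatus
#>                   0.7
```

The community is a dynamic equilibrium: the dominant grass holds a
landscape mean near 60 % while individual cells fluctuate around it,

```r
cells <- cell_cover_series(run, "arrhenatherum_elatius", years = c(5, 30))
round(range(cells), 1)
#> [1] 52.0 67.0
```

and species that belong to the unfertilized form only (initialised at
0.01 % for general availability) die out within a few years. Starting from
the fertilized covers under the impoverished site
(`make_test2("transition")`) converts the community into its unfertilized
counterpart — 30 % *A. elatius*, more forbs — over roughly two decades.

The second packaged landscape, `make_test1()`, is a patchy 10 x 20 mosaic
of ten habitat patches in a grassland matrix; `check_dominance()` verifies
that each patch becomes dominated by its habitat's indicator species.

Scenario directories for the command-line interface are produced with
`materialize_scenario()` or the bundled script:

```sh
inst/cli/vegsucc init-demo --scenario test2-fertilized --outdir demo
inst/cli/vegsucc run --config demo/run_config.yaml --seed 7
```

Rule tables for vegetation typing are delimited text with columns
`order`, `expression`, `type_id`, where expressions follow a small
grammar: `species cmp threshold` conditions (`<`, `>`, `<=`, `>=`,
thresholds in percent cover) combined with `AND` / `OR` and parentheses,
e.g. `arrhenatherum_elatius > 50 AND climbers < 5`. Rules are evaluated in
order, first match wins, and a default type catches the rest.

## Package layout

* `R/` — model core (growth, dispersal, scheduling), classification,
  site-indicator tools, calibration, IO (delimited tables, ESRI ASCII
  grids, YAML run configs), scenario generators, CLI.
* `vignettes/vegetation-succession-model.Rmd` — the methods vignette:
  model description, assumptions, numerical choices, calibration of the
  packaged scenarios, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
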