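---
title: "Modelling herbaceous succession with ecological indicator values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling herbaceous succession with ecological indicator values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegsucc)
```

## The model

`vegsucc` simulates the development of herbaceous vegetation on a raster
landscape. Each grid cell (default 10 m x 10 m) carries one cover
compartment per species, expressed in percent of the cell area; the
community in a cell can never exceed 100 %. Species differ in two kinds of
parameters:

* **Ecological indicator values (EIVs)** — ordinal 1–9 preferences along
  five site gradients (light L, temperature T, moisture M, soil reaction R,
  nutrients N, in the Ellenberg tradition) and three land-use tolerances
  (cutting C, grazing G, trampling TR, in the Briemle tradition). These are
  literature values describing the *realized* niche: where a species is
  found under competition, not its physiological optimum. A species may be
  *indifferent* ("x") for a site gradient, never for a land-use tolerance.
* **Two calibrated growth parameters** — a maximum growth rate $g_{max}$
  (per year, bounded by 10) and a self-regulation factor $F_S$ (percent
  cover units, bounded by 15 000). $F_S$ caps a species' effective growth
  as its own cover rises, standing in for the fine-scale microsite
  heterogeneity that homogeneous cell compartments cannot represent; it is
  what allows inferior competitors to persist.

The environment of a cell is described on the same scales: five site
indicator values $SV_X \in [1,9]$ and three land-use intensities
$I_X \in [0,100]$. Scenarios are expressed as spatially explicit changes of
these cell values.

### Growth, competition and mortality

Every time step (52 or 365 per year), each modeled cell is updated in
row-major order (upper-left to lower-right):

1. **Mortality.** A fixed background mortality of 200 % of cover per year,
   divided evenly over the steps, frees space:
   $c \leftarrow c\,(1 - 2/n_{steps})$. Without it a saturated cell could
   never change composition — plants cannot push each other out, they
   compete only through regrowth into uncovered area.
2. **Control functions.** For each land-use factor,
   $f(X) = (1 - EIV_X/9)\,(100 - I_X)/100 + EIV_X/9$, a linear sensitivity
   bounded on $[1/9, 1]$. For each site factor, a Gaussian tolerance curve
   $f(X) = \exp(-slope_X (SV_X - EIV_X)^2/9)$, equal to 1 at the optimum;
   for indifferent species a broader, lower curve
   $f(X) = Opt_{red}\exp(-slope_{red}(SV_X - 5)^2/9)$ centred on the scale
   midpoint is used, so the factor stays positive everywhere.
3. **Total environmental dependency.** The eight control values are
   combined as a weighted mean,
   $f_{total} = \sum W_X f(X) / \sum W_X$ with $W_X = (2 - f(X))^{w_X}$,
   so suboptimal factors gain influence. A plain product would collapse
   with many factors ($0.7^8 < 0.1$); the weighted mean always lies
   between the worst and the best factor. The per-factor weights $w_X \in
   [1, 20]$ express which gradients drive the landscape under study.
4. **Growth.** $g = g_{max}\,\frac{F_S - c}{F_S}\,f_{total}$, floored at 0
   (several parameterisations place $F_S$ below 100, so the floor matters);
   the per-step potential growth is $\Delta c_{pot} = g\,c/n_{steps}$.
5. **Vegetative dispersal.** If a species' cover exceeds the 1 % threshold,
   an event fires with probability $c/100$; a direction is drawn uniformly
   among the eight virtual Moore positions and a uniform fraction
   $u \sim U(0,1)$ of $\Delta c_{pot}$ is redirected to that neighbour. A
   draw pointing across the closed boundary transfers nothing (no flux:
   the growth stays local); a draw into an unmodeled cell (roads and other
   structural elements) is created and then discarded. Transferred
   potential is delivered with a one-step delay and competes in the target
   cell like resident growth — this is how species immigrate into cells.
6. **Lottery competition.** All potentials (local plus delivered ingrowth)
   compete for the available space $AS$: if their sum exceeds $AS$, each
   species realises $\Delta c_{pot} \cdot AS / \sum \Delta c_{pot}$ —
   space is divided proportionally to potential growth.

Vegetation types are assigned twice a year (first and mid-year step) by an
ordered decision tree over the cover vector: the first satisfied rule wins,
comparators are exactly as written, and a default type catches everything
else.

### Assumptions worth keeping in mind

* The herbaceous layer in a cell is homogeneous; all within-cell structure
  is delegated to $F_S$.
* Mortality is species-independent and constant; there is no seasonality
  and no seed dispersal beyond the eight-cell neighbourhood.
* Environmental conditions are constant within a run; scenarios change
  them instantaneously at initialisation.
* EIVs are ordinal scales used in arithmetic — standard practice in
  indicator-value work, but an approximation.

## Parameters

| Parameter | Unit / range | Default | Meaning |
|---|---|---|---|
| `slope` (per site factor) | [0, 2] | 1 | width of the site tolerance curve |
| `slope_red`, `opt_red` | [0, 1] | 0.3, 0.6 | reduced curve for indifferent species |
| `weights` $w_X$ | [1, 20] | 1 | ecological relevance of each factor |
| `steps_per_year` | 52 or 365 | 52 | time resolution |
| `dispersal_threshold_pct` | % cover | 1 | minimum cover for vegetative spread |
| `annual_mortality` | per year | 2 (= 200 %) | background turnover |
| `cell_area` | m² | 100 | informational; cover is in percent |
| `g_max` (per species) | [0, 10] a⁻¹ | calibrated | maximum growth rate |
| `f_s` (per species) | (0, 15000] | calibrated | self-regulation factor |

## Numerical choices

* All state is double precision; covers below $10^{-6}$ % are truncated to
  0 (extinction threshold against denormal drift).
* The growth rate is clamped at 0 rather than allowed to go negative;
  decline is driven by mortality and competition only.
* Area conservation ($\sum c + AS = 100$) holds by construction after every
  step and is asserted in the test suite to $10^{-6}$.
* One global RNG stream, seeded once per run, is consumed in deterministic
  (row-major cell, species-table) order; identical seeds give bit-identical
  runs.
* **Step size is part of the scenario definition.** The per-step linear
  splits of mortality and growth compound differently at 52 vs 365 steps:
  equilibrium states agree to well under 2 %, but exponential transients
  can differ by ~10 % per year, and the variance of the stochastic
  dispersal exchange is about seven times smaller at daily resolution.
  Equilibrium-focused analyses are therefore robust to the choice, but
  per-cell variability and transient timing are not, which is why each
  packaged scenario fixes its resolution explicitly.
* The discrete single-species equilibrium is
  $c^* = F_S\,(1 - M/((1-m)\,g_{max} f_{total}))/(1-m)$ with
  $m = M/n_{steps}$; the continuous-limit form drops the $(1-m)$ factors.
  The independent oracle in the test suite uses the exact discrete form.

## The demonstration landscapes

Two fully parameterised landscapes ship with the package. They are stylised
by design: simple enough that the expected outcome follows from reasoning
alone, so they probe the model mechanics rather than reproduce a mapped
site.

### Patchy landscape (`make_test1()`)

A 10 x 20 grid holding ten 2 x 2 patches with contrasting site conditions
(dry/wet, acidic/calcareous, nutrient-poor/rich, open/woodland) inside a
surrounding grassland matrix of intermediate character. Eleven species —
one indicator per patch type plus a generalist for the matrix — start
everywhere at 1 % cover with identical growth parameters
($g_{max} = 3.5$, $F_S = 10{,}000$), so only environmental tolerance
differentiates them. Land use is off (all intensities 0; the land-use
tolerance columns are filled with the neutral midpoint 5, which is inert at
zero intensity). The expectation, which the acceptance suite checks across
seeds, is that each patch ends up dominated by its indicator species and
the matrix by the generalist, accompanied by the calcareous-grassland
species.

Two globals had to be chosen for this landscape because the source
description prints none for its test runs. With all weights at 1 the
environmental signal is too dilute: patch cells receive a continuous
ingrowth subsidy from the matrix (every patch cell borders at least two,
in fact five, matrix cells) and three patches remain dominated by the
matrix generalist indefinitely. Equal weights of 7 — equal weighting, only
more emphatic — make the sorting decisive. Secondly, most woodland
indicator species in the set are temperature-indifferent; with the
illustrative reduced optimum of 0.6 they pay a constant ~0.4 penalty on one
of eight factors, which at high weights is crippling in their own patches,
so the packaged landscape uses `opt_red = 0.75`. Both values are ordinary
pre-configuration choices within the documented ranges.

### Lowland meadow under soil impoverishment (`make_test2()`)

A homogeneous 10 x 10 grid carrying a 17-species hay-meadow community
(dominant *Arrhenatherum elatius*) in two forms: fertilized (site N = 8,
total initial cover 100.08 %) and unfertilized (site N = 5, 100.03 %),
with hay-meadow land use (cutting 75, grazing 1, trampling 1) and site
L = 8, T = 5, M = 5, R = 6. Species absent from a form are initialised at
0.01 % to mimic general availability. The `"transition"` form starts from
the fertilized covers under the impoverished site — the instantaneous
N 8 → 5 experiment.

The published parameter table concatenates the $g_{max}$ and $F_S$ columns
ambiguously; the packaged `"printed"` reading takes $g_{max}$ with one
decimal unless that pushes $F_S$ beyond its bound of 15 000 (then two
decimals: *A. elatius* 5.33/6201, *Festuca pratensis* 4.25/5105). Under the
default globals this reading is not a coexistence equilibrium — at its 60 %
target the dominant grass still out-grows every other species'
best-attainable growth level, and the simulated community collapses to an
*A. elatius* monoculture. Since the source prints neither the globals nor a
resolution of the column ambiguity, the package treats the two community
forms as what they are in the described workflow: *calibration targets*.

The default `"calibrated"` parameterisation was produced with the packaged
calibration machinery, holding all EIVs, initial covers, site values and
global defaults (slope 1, slope_red 0.3, opt_red 0.6, all weights 1)
fixed:

1. At a coexistence equilibrium every persisting species shares one growth
   level $g^*_s$ per scenario, so
   $c_{i,s} = F_{S,i}(1 - g^*_s/(g_{max,i} f_{i,s}))$. With two scenarios
   and two free parameters per species this solves in closed form for
   species present in both forms; species confined to one form get the
   remaining freedom in $F_S$ assigned from the start-value categories and
   are required to decay in the other form.
2. The analytic solution is then refined against simulations (the realized
   growth levels sit slightly above the analytic ones for strongly
   dispersing species, which pay a small stochasticity tax), including a
   final two-parameter Newton step for the dominant grass.

A few species (*Festuca pratensis*, *Tragopogon pratensis*,
*Galium mollugo*, *Ranunculus acris*) cannot satisfy both
equilibria exactly under any admissible parameters — their environmental
ratios run against the direction of their tabulated cover change — and
carry strongly self-limited compromise values; their equilibria sit within
about 1.5 cover points of the targets. The scenario runs at daily steps
(365/year): at weekly resolution the dispersal noise is large enough that
the per-cell cover of the dominant grass cannot stay inside its documented
55–65 % band for any admissible parameterisation, while daily resolution
reproduces it. Verified behaviour of the packaged scenario (five seeds):
landscape-mean *A. elatius* 57 % fertilized / 30.5 % unfertilized over the
final five years, per-cell range ≈ 52–67 %, and a fertilized-to-
unfertilized transition crossing 10 % of its initial community distance at
year 23.

## Calibration machinery

`calibrate()` automates the manual pre-configuration workflow: a coordinate
search over $(g_{max}, F_S)$ per species with multiplicative steps that
shrink when a sweep yields no improvement. The objective is the maximum
over calibration scenarios of the mean absolute error between simulated
landscape-mean covers (averaged over the last 5 years of each run, length
configurable) and the target covers — because every candidate is evaluated
against *all* scenarios, previously satisfied scenarios are re-checked
automatically (the workflow's backward check). `start_values()` supplies
the documented start categories ($F_S$ 1000/500/100 by dominance, $g_{max}$
5.0/4.5/3.5 by abundance). The default convergence tolerance is a 2 %
absolute cover error; the source workflow is visual and states no
quantitative criterion, so this is the package's own choice, matching the
parameter-recovery test. No global-optimality claim is made.

## Site indicator tools

`mean_site_eiv()` aggregates a relevé (median, mean, or cover-weighted
mean) into a site value, skipping indifferent species. `soil_to_site_eiv()`
encodes the published decision rules from German (NRW BK50-style) soil-map
attributes; where the source aggregates scale points into a class the
printed proxy is returned with the range attached, and combinations the
rules cannot resolve without field information (covered sites for L,
exceptionally warm sites for T, fine-textured shallow profiles for N)
return `NA` flagged as undetermined rather than a guess. One typographic
note: the altitude classes align 650–450 m with T = 5 and 450–300 m with
T = 6. `scenario_intensities()` carries the published land-use scenario
catalogue (hay-meadow 75–1–1, intensive pasture 0–50–50, fallow 0–1–1, …).

## What the packaged scenarios do and do not show

The synthetic landscapes exercise every mechanism — growth control,
weighting, lottery competition, stochastic spread, classification,
calibration — under conditions where the expected outcome is known. They do
not contain measurement noise, mapping error, within-type compositional
variation, temporal forcing, or any woody dynamics; passing them
demonstrates internal consistency and the intended qualitative behaviour,
not predictive skill on a real landscape, which requires the full
pre-configuration workflow against local relevé data.

Problem sizes in the test suite are kept deliberately small (single cells
to 10 x 20 grids, horizons of 1–50 years, three-species calibration
recovery); they are chosen as the smallest sizes at which each property is
informative.

## Known limitations

* Indicator values are scarce outside Europe; the approach inherits their
  geographic scope.
* Transient dynamics are not calibrated and may contain artifacts (initial
  spikes of released species; slow final approach of weak colonisers).
* Only instantaneous environmental change is supported.
* The model relies on continuous competition; rare or pioneer species that
  persist through other mechanisms are outside its scope.
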