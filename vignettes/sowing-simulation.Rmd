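---
title: "Simulating single-seed precision sowing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating single-seed precision sowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sowsim)
```

## The problem

Single-seed precision sowing places exactly one maize seed per planting
position. Unlike traditional multi-seed holes, a seed that fails to emerge
leaves a permanent gap: no thinning, no replacement. With a field
seedling-emergence rate $\rho < 1$ the realized stand is both thinner and
spatially ragged, and the practical question is how to sow. sowsim
implements a stochastic field model to compare two policies:

* **Method 1** — sow at the optimum density $D^{*}$; the expected stand is
  $\rho D^{*}$.
* **Method 2** — sow at $D^{*}/\rho$; the expected stand is $D^{*}$.

and to characterize the *seedling-missing spots* (connected gaps) that
single-seed sowing produces.

## The yield–density model

Yield responds to planting density as a downward parabola, written in
vertex form

$$Y(D) = A\,(D - D_m)^2 + Y_m, \qquad A < 0,$$

with $D$ in plants/m², $Y$ in t/hm², maximum yield $Y_m$ at the optimum
density $D_m$. Its derivative $dY/dD = 2A(D - D_m)$ equals $\pm 2A$ one
plant/m² on either side of the optimum. We parameterize the curvature by
the **density sensitivity** $\theta$: the angle between those two unit-offset
tangents,

$$A = -\tfrac{1}{2}\tan(\theta/2),$$

so that $\theta \in \{16, 48, 80, 112\}$ degrees spans tolerant to highly
density-sensitive varieties, monotone in $|A|$. Units are fixed throughout:
model densities in plants/m², field densities in plants/hm² (factor
$10^4$), yields in t/hm², per-plant yields in tonnes; all conversions live
in the yield-model functions.

```{r}
m <- yield_model(Dm = 6, Ym = 7.5, theta = 112)
m
yield_derivative(m, c(5, 7))   # +/- 2|A|
```

## Emergence grids

A field is a rectangular lattice (`field_layout()`): rows `row_spacing` m
apart (0.6 m by default, fixed by machinery), plants `plant_spacing` m
apart within rows, so planting density is $10^4/(0.6\,s_p)$ plants/hm² and
density is adjusted through $s_p$. Emergence is i.i.d. Bernoulli: each
position carries a plant with probability $\rho$, independently
(`simulate_emergence()`). This is the model's central simplification — real
emergence failure is spatially correlated through soil moisture, crusting
and sowing depth, and such clustering would enlarge gaps relative to the
i.i.d. model. Passing tests therefore validate the stochastic machinery,
not the spatial realism of any particular field.

Randomness is reproducible by construction: every replicate draws from a
seed derived deterministically from `(base_seed, replicate)`, so sweeps and
factorials are bit-stable under a fixed base seed.

## Missing-seedling spots

A *seedling-missing spot* is a maximal connected component of zeros
(`label_spots()`). The package defaults to 8-connectivity (diagonal contact
joins a spot). The choice matters and was made on quantitative grounds: for
an i.i.d. zero-field with density $q$, the expected component count is
approximated by the Euler characteristic
$V - E + T$ (zero cells, adjacent zero pairs including diagonals, zero
3-cliques), which on the 60×120 reference lattice at $q = 0.05$ gives
$\approx 293$ — matching the published reference value 293.3, while the
4-connected count ($\approx 324$) does not. 4-connectivity remains
selectable for sensitivity analysis.

The reference experiment (`spot_rate_sweep()`) runs 1000 replicates per
rate on the 60×120 lattice, rates 0.95 down to 0.7, and summarizes: mean
missing count, mean spot count, *hundred-dot spots* (spots per 100
positions) and *spot missing seedlings* (missing count per spot). The last
is a **ratio of means**, not a mean of ratios — it reproduces the reference
table and stays defined when a replicate has no spot. Two fitted laws
summarize the sweep (`fit_quadratic()`, `fit_exponential()`): hundred-dot
spots follow a parabola in $\rho$ peaking near $\rho = 0.81$, and spot
missing seedlings decay roughly as $\alpha e^{\beta\rho}$. The exponential
is fit on logs by default; a nonlinear refinement (`method = "nonlinear"`)
re-optimizes on the original scale starting from the log-linear solution.
The quadratic law is robustly reproducible; the exponential's printed
coefficients depend on exactly which points enter the fit, so we treat its
exponent as approximate.

```{r}
ref <- reference_spot_table()
fit_quadratic(ref$rate, ref$hundred_dot_spot)
```

## Voronoi yield compensation

Plants bordering a gap exploit the vacated soil, light and air. The
package's compensation channel is purely geometric: each emerged plant
receives its **nutrition area** — its Voronoi cell clipped to the field
rectangle (`voronoi_cell_areas()`) — and produces
$\max\{0, Y(1/a)\}\,a/10^4$ tonnes, the field parabola evaluated at its
personal equivalent density $d = 1/a$. A full stand is scored by the
planting density directly (the tessellation then tiles the field into
spacing rectangles exactly, so the two rules agree). Summing plants and
normalizing by field area gives the compensated field yield
(`compensated_field_yield()`).

Numerical choices:

* Cells are bounded by clipping the field rectangle itself with
  perpendicular-bisector half-planes, which is mathematically identical to
  tessellating with mirror plants reflected across the four field edges and
  keeping the original cells. Areas then partition the field exactly
  (conservation to ~1e-12 relative in practice) and a full grid yields
  per-cell areas exact to double precision.
* The neighbor search expands anisotropic lattice boxes, clips
  nearest-first, and stops once no plant outside the searched box can be
  closer than twice the clipped polygon's maximal vertex distance — a
  rigorous cut-off, so results equal the all-pairs construction
  (`voronoi_polygons()`) to rounding error at a fraction of the cost.
* Per-plant yield is clamped at zero for very large areas; the raw parabola
  is left unclamped elsewhere. No upper cap is applied to per-plant yield
  for large areas beyond the clamp's implicit one.

One property worth stating precisely: compensation does *not* always beat a
rigid accounting that gives every survivor its nominal full-stand share.
Per-plant yield $g(a) = a\,Y(1/a)/10^4$ is concave and increases with area
only while $a \le \sqrt{-A/(A D_m^2 + Y_m)}$; when $A D_m^2 + Y_m < 0$
(steep sensitivity, e.g. $\theta = 112$ at $D_m = 6$, $Y_m = 7.5$) a plant
that absorbs a whole missing rectangle contributes *less* than its
full-stand share, and total compensated yield can fall below the rigid sum.
When $A D_m^2 + Y_m \ge 0$, $g$ is increasing everywhere and compensation
dominates; the test suite asserts the bound in that regime. Compensation is
always partial: a gapped stand never recovers the full-stand yield.

## The policy experiments

`run_method_comparison()` crosses optimum densities
$\{4.5, 6, 7.5, 9, 10.5, 12\}$ plants/m², maximum yields
$\{5.25, 7.5, 9.75, 12, 14.25\}$ t/hm², sensitivities
$\{16, 48, 80, 112\}$° and emergence rates $\{0.75, 0.85, 0.9, 0.95\}$,
both methods, 200 replicates per cell by default. Since $(Y_m, \theta)$
only rescale the parabola, grids and tessellations are shared across those
20 combinations, and the factorial costs what the 6×4×2 density×rate×method
grid costs.

The simulated field defaults to 36 m × 36 m (60 rows at 0.6 m spacing;
2000–21000 positions depending on density). Yields are normalized per hm²,
so field size is purely a Monte-Carlo convergence knob; at this size the
per-cell standard error of the mean yield is an order of magnitude below
the policy differences the experiments measure, and the full factorial runs
in a few minutes on one core. `layout_from_density()` keeps a 100 m × 100 m
(1 hm²) default for stand-alone use.

The headline result — inflated sowing (method 2) matches or beats
optimum-density sowing (method 1) cell by cell, with smaller yield
variance — holds across most of the grid, and the advantage widens with
the yield level. It does **not** hold everywhere, and the exception is
structural, not Monte-Carlo noise: method 2 deliberately sows at
$D^{*}/\rho$, so its interior plants (those with no missing neighbor) live
at equivalent density $D^{*}/\rho > D_m$. When that density approaches the
parabola's positive root $D_m + \sqrt{Y_m/|A|}$ — steep sensitivity
combined with high optimum density, low maximum yield and low emergence —
those plants earn almost nothing, while method 1's interior plants sit
exactly at the optimum, and method 2 can lose by more than 1 t/hm² (e.g.
$\theta = 112$, $D_m = 12$, $Y_m = 5.25$, $\rho = 0.85$). This is a direct
consequence of keeping the curvature $A$ independent of the yield level
$Y_m$; biologically, high-yield varieties are reported to be the more
density-sensitive ones, which would keep the positive window
$\sqrt{Y_m/|A|}$ from collapsing, but no quantitative form of that
coupling is established, so the package does not impose one. Interpret
method-2 dominance as conditional on the sown density staying well inside
the parabola's positive window.

Downstream analyses mirror the two regression summaries of such
experiments: `yield_reduction_regression()` regresses yield reduction
($Y_m$ minus simulated mean) on $\rho$ per density and method — slopes are
negative, and method 2's are flatter in magnitude; and
`sensitivity_rate_regression()` regresses reduction on $\theta$ and
$\theta\times\rho$ — positive sensitivity main effects, negative
interactions. Their coefficient *magnitudes* depend on unstated details of
the original experiments (replicate counts, field dimensions), so signs,
orderings and correlations are the reproducible contract, not the decimals.

```{r, eval = FALSE}
res <- run_method_comparison(seed = 1)        # full factorial, ~5 min
yield_reduction_regression(res, sensitivity = 112)
sensitivity_rate_regression(res)
```

## Reproducibility surface

Every experiment is also reachable through a serializable configuration
(`run_config()`, `run_from_config()`) and a thin command-line wrapper
(`inst/cli/sowsim.R`) with subcommands `spot-sweep`, `compare-methods`,
`table1`, `table2`, `fit` and `render-grid`; each run writes its outputs
plus a JSON manifest naming the config, seed and package version, and a
saved YAML config reproduces a run byte-for-byte.

## Known limitations

* Emergence is spatially independent; soil patchiness is out of scope.
* Compensation is instantaneous geometry — no competition kinetics, light
  interception or temporal growth.
* The yield parabola is the only density response considered; asymptotic
  yield–density forms are not implemented.
* Grid granularity: layouts floor the row/column counts that fit the field,
  so very small fields realize densities with a one-row/column bias.
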