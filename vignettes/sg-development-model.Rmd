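---
title: "Modelling sebaceous-gland development: methods and design notes"
author: "sgdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sebaceous-gland development: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(sgdyn)
```

## The model

Postnatal sebaceous glands (SGs) grow from a small pool of basal
progenitors attached to the basement membrane. Dividing progenitors either
stay basal (self-renewal) or detach inward and differentiate into
suprabasal sebocytes. `sgdyn` describes this with two coupled compartments,
basal `P` and suprabasal `D`:

$$\frac{dP}{dt} = (2 f_P - 1)\, u_P\, P, \qquad
  \frac{dD}{dt} = (1 - f_P)\, u_P\, P,$$

where `f_P` is the per-division self-renewal probability and `u_P` the
per-cell division rate. The division rate is modulated by two opposing
influences:

$$u_P(t) = c \left(1 + \frac{D}{P}\right)^{k} e^{-t^2 / s}.$$

The feedback term `(1 + D/P)^k` captures the mechanical demand that an
expanding suprabasal mass places on the basal layer: differentiating
sebocytes swell the gland, the covering basement membrane area grows, and
basal cells must divide to keep the layer intact. The Gaussian factor
damps growth over developmental time so that gland size plateaus — a
developmental window rather than unbounded growth. Time `t` is measured in
days since developmental onset, so growth is maximal at onset and decays
thereafter.

Default initial conditions and horizons follow the biology of mouse skin:
development starts at about postnatal day 2 (P2) from roughly 11
progenitors and no suprabasal cells; back-skin glands stop growing around
P7, tail-skin glands around P9. The model works in continuous cell counts
(deterministic ODE semantics); rounding is left to presentation.

### Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `c` | growth-rate amplitude; also the Gaussian decay scale `s` unless overridden | 1/day (scale: day²) | fitted |
| `k` | feedback exponent on `D/P` | — | fitted |
| `f_p` | self-renewal probability | — | fitted |
| `p0`, `d0` | initial counts | cells | 11, 0 |
| `t_onset`, `t_end` | development window | postnatal day | 2, 9 |
| `decay_scale` | optional independent `s` | day² | `NULL` (= `c`) |

The printed form of the Gaussian ties its scale to the amplitude, leaving
the model with exactly two growth constants (`c`, `k`); that shared-scale
reading is the default here. Because the shared scale cannot express a
duration change without an amplitude change, `decay_scale` optionally
decouples the two — this is also how the shorter back-skin and longer
tail-skin development windows can be represented with a common amplitude,
and it subsumes the alternative algebraic reading
$e^{-c t^2}$ via `decay_scale = 1/c`.

```{r}
wt <- sg_params(c = 1.5, k = 2, f_p = 0.8)
traj <- simulate_sg(wt)
endpoint(traj)
plot(traj)
```

## Numerical choices

* **Integrator.** `deSolve::ode` with `lsodar`, relative tolerance 1e-8,
  absolute 1e-10, output on a fine uniform grid containing every whole
  postnatal day. The system is non-stiff in the biological regime; the
  tight tolerances make oracle comparisons (fixed-step Euler at 1e-4 day,
  closed-form Gaussian limits) meaningful.
* **Domain guards by root-finding.** For `f_p < 0.5` and `k >= 1` the true
  solution exhausts the basal layer in finite time with unbounded slope,
  and the `D/P` feedback leaves its domain. Integration therefore
  terminates — by root-finding, which keeps the solver from collapsing its
  step size against the singularity — when `P` drops below 1e-3 cells
  ("no dividing cells left") or when the population exceeds 1e6 cells
  (runaway growth at extreme parameter combinations; real glands hold a
  few hundred cells). After either event the state is held constant.
  Conservation identities are unaffected because all rates freeze
  simultaneously.
* **Division bookkeeping.** The identity
  $P + D - P_0 - D_0 = f_P \int u_P P\,dt$ is checked by accumulating the
  integral as an auxiliary solver state, so the comparison carries the
  integrator tolerance rather than a grid-quadrature error.

## Calibration

`sg_fit()` estimates `(c, k, f_p)` from observed counts by minimising a
weighted sum of squared *relative* errors between simulated and observed
quantities (`P`, `D` and/or totals, per postnatal day). Relative errors
keep basal counts (tens of cells) and suprabasal counts (hundreds)
commensurate.

The optimiser is bounded quasi-Newton (`optim`, L-BFGS-B) restarted from
32 Latin-hypercube points in the box `c` in (0, 50], `k` in [0, 6],
`f_p` in [0, 1], followed by a deterministic polish of the incumbent with
a tighter finite-difference step. Two design points matter:

* `c` is searched on the **log scale**. It is a positive scale parameter
  spanning nearly two decades of its box; uniform sampling would place
  almost no starts below `c = 3`, where biologically plausible optima
  live, and log-stepping conditions the quasi-Newton updates.
* A quasi-Newton method was preferred over a derivative-free simplex
  because box bounds are native to L-BFGS-B and the loss is smooth at the
  integrator tolerances used, so it converges in far fewer ODE solves —
  which is what keeps a 32-start fit in the seconds-to-a-minute range.

Failed integrations inside a line search (rare, since exhaustion and
runaway growth terminate cleanly) score as a large finite penalty rather
than aborting the start. Everything is deterministic given
`(obs, bounds, n_starts, seed)`.

### Identifiability — what count data can and cannot pin down

A fit is flagged `underdetermined` when there are fewer observations than
free parameters, or when several converged starts reach losses within
1e-6 of the best with parameter spread above 1e-2 — the flat-valley
signature. A single endpoint observation always triggers it.

Total-count time series deserve a stronger warning, which the package's
own simulation study (the test suite and `scripts/acceptance.R` recompute
it) makes precise. With noiseless daily totals the global optimum is the
generating truth and the fit recovers all three parameters to better than
1%. Add even mild noise (lognormal, 5% CV, 20 replicates averaged — about
1.1% effective) and the loss surface reveals a sloppy, multi-modal valley:
parameter sets as far apart as `(c, k, f_p) = (1.5, 2.0, 0.80)` and
`(3.4, 0.7, 0.44)` reproduce almost the same total-count curve, and the
global minimum under a given noise draw routinely sits tens of percent —
sometimes > 100% — away from the truth in `c` and `k`, at a loss *below*
the truth's. This is a property of the data type, not of the optimiser:
polishing from the truth itself slides along the valley at equal loss.
What noisy totals *do* pin down is the trajectory — fitted total curves
track the truth to better than 1% — and scenario classifications built on
endpoints inherit that robustness. Compartment-resolved counts (`P` and
`D` separately) narrow the valley but do not eliminate it. Parameter
*values* from totals-only calibrations should therefore be read as one
representative of a data-equivalent family.

## Perturbation scenarios

`classify_perturbation()` compares endpoint compartment sizes between a
base and a perturbed parameter set (shared development window) and labels
the change `P_EXPANSION`, `D_EXPANSION`, `COMBINED` or `NONE`, with a 5%
relative tolerance separating genuine expansion from integrator noise.
`sweep_perturbations()` maps these labels over a grid of the two factors
that govern gland composition: the detachment/differentiation probability
(`1 - f_p`) and the feedback strength (`k`).

The packaged wild-type/knockout illustration (`wt_ko_fixtures()`) keeps
everything fixed except a drop of `f_p` from 0.80 to 0.65 — a knockout
whose phenotype is faster detachment of basal progenitors into the
differentiating compartment. Simulated, it yields a larger suprabasal
endpoint (9.3 to 18.4 cells) and a 2.9-fold higher `D/P` ratio with no
basal accumulation, classifying as `D_EXPANSION`. These fixture values are
illustrative choices of this package, selected once for showing the
signature cleanly; they are not fitted estimates.

```{r}
fx <- wt_ko_fixtures()
classify_perturbation(fx$wt, fx$ko)
```

## Morphometry to cell counts

`estimate_counts()` converts wholemount measurements into compartment
sizes by modelling a gland as a prolate spheroid: semi-axes
`a = max_length/2` and `b = c = max_width/2` (measured lengths are full
extents, so they are halved; length >= width is enforced). The surface is
tiled by basal cells, the volume filled by suprabasal cells:

* volume $V = \frac{4}{3}\pi a b c$;
* surface by the Thomsen power-mean approximation
  $A \approx 4\pi \big( ((ab)^p + (ac)^p + (bc)^p)/3 \big)^{1/p}$ with
  `p = 1.6` — exact for spheres, within ~1.2% of the true surface
  integral across aspect ratios up to 5 (checked against a quadrature
  oracle in the tests);
* basal-cell footprint `(1 / basal_nuclear_density)^2`. The nuclear
  density is a **linear** density (nuclei per µm along the basal layer),
  so its inverse is the internuclear spacing and the square a cell's
  surface footprint — the only reading with correct units, and a
  documented assumption;
* suprabasal cell volume `suprabasal_cell_size^3`.

Counts are left unrounded.

```{r}
m <- sg_measurements("demo", max_length = 70, max_width = 45,
                     basal_nuclear_density = 0.14,
                     suprabasal_cell_size = 14)
estimate_counts(m)
```

## The marker screen

`filter_by_go()` restricts a per-compartment marker table to genes
carrying at least one configured Gene Ontology term — by default the two
adhesion terms used to hunt for niche-interaction candidates, cell-cell
adhesion mediator activity (GO:0098632) and cell-matrix adhesion
(GO:0007160) — and `rank_markers()` orders each compartment by descending
fold change, ties broken alphabetically (no ties policy exists upstream,
so the deterministic lexicographic rule is documented here). Matching is
by exact GO identifier against the supplied annotation map; no
ontology-graph descendant expansion is attempted, since the screen names
specific terms. The "non-integrin membrane protein" style of sub-listing
is supported as a user-supplied gene subset, because no computable
membrane/integrin criterion is available. Ranking is invariant under any
monotone transform of fold change, so whether upstream fold changes are
linear- or log-scale does not affect the ordering (linear is assumed for
display).

## Synthetic data

All generators are deterministic per seed (R's default Mersenne-Twister;
draw order fixed by the documented implementation) and use **lognormal**
noise for every positive quantity — morphometry, counts, fold changes —
since multiplicative error with guaranteed positivity is the standard
model for such measurements, parameterised so the arithmetic mean equals
the configured target. Morphometry defaults (length 70 µm, width 45 µm,
density 0.14/µm, cell size 14 µm, CVs 10-15%) were chosen once as
realistic adult-mouse tail-gland magnitudes: they give glands of a few
hundred suprabasal and tens of basal cells, the regime the count model is
calibrated to. `synth_marker_table()` plants enriched genes with known
fold-change multipliers and annotates a fixed, known fraction of genes,
so filter and ranking outputs are exactly predictable.

What the generators deliberately do not emulate: spatial gland shape,
cell-size growth during differentiation, measurement correlations between
length and width, dropout or batch structure in expression data. Tests
passing on these synthetics therefore validate the pipeline's mechanics
and its statistical contracts, not its fidelity to any particular real
data set.

## Problem sizes and runtimes

The test suite and the acceptance script run fits with 32 multistart
points on 8-day observation series, Euler-oracle panels of 10 parameter
sets at a 1e-4-day step, 100-table ranking oracle comparisons, and
20-draw geometry panels; these sizes were chosen so each stage completes
in seconds to about a minute while still exercising the full machinery.

## Known limitations

* The two-compartment simplification has no lineage depth (no
  transit-amplifying chain) and no stochasticity; it cannot describe
  clone-size distributions, only mean counts.
* Parameter values fitted from totals-only data are one representative of
  a data-equivalent family (see identifiability above).
* The geometry estimators assume a prolate spheroid and uniform cell
  packing; irregular or lobulated glands violate both.
* GO filtering is only as good as the annotation map supplied; genes
  absent from the map are treated as unannotated and dropped.
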