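# sgdyn

Quantitative tools for postnatal sebaceous-gland (SG) development in mouse
skin, built for researchers studying how basal progenitors balance
self-renewal against detachment and differentiation — for example when a
knockout (such as loss of the sebocyte receptor embigin) shifts that
balance and changes gland size.

The package covers four connected analyses:

1. **Compartment model.** Basal progenitors `P` and suprabasal
   differentiating sebocytes `D` evolve as

   dP/dt = (2·f_P − 1)·u_P·P,  dD/dt = (1 − f_P)·u_P·P,

   with per-cell division rate u_P = c·(1 + D/P)^k·exp(−t²/s): growth is
   amplified by the suprabasal-to-basal ratio (the expanding gland forces
   the basal layer to keep up) and shut down by a Gaussian decay over the
   developmental window (onset ~P2, end ~P7 back skin / ~P9 tail skin,
   starting from ~11 progenitors).
2. **Calibration and scenarios.** `sg_fit()` estimates `(c, k, f_p)` from
   observed cell counts by seeded Latin-hypercube multistart L-BFGS-B on a
   squared-relative-error loss, with an identifiability flag;
   `classify_perturbation()` and `sweep_perturbations()` label parameter
   changes as progenitor-driven (`P_EXPANSION`), differentiation-driven
   (`D_EXPANSION`), `COMBINED` or `NONE` gland expansion.
3. **Morphometry.** `estimate_counts()` turns wholemount gland
   length/width, basal nuclear density and suprabasal cell size into
   basal/suprabasal cell numbers via prolate-spheroid geometry (exact
   volume; Thomsen p = 1.6 surface approximation).
4. **Marker screen.** `filter_by_go()` + `rank_markers()` reproduce the
   discovery screen that ranks compartment marker genes by fold change
   after filtering for adhesion GO terms (GO:0098632, GO:0007160).

Synthetic-data generators (`synth_*`) emulate every input with known
ground truth, so the full pipeline is testable without any external data.

## Worked example

```r
library(sgdyn)

## simulate a wild-type-like gland and its knockout counterpart
fx <- wt_ko_fixtures()          # identical except f_p: 0.80 (WT) vs 0.65 (KO)
endpoint(simulate_sg(fx$wt))
#>     p_end     d_end     total
#> 38.964491  9.321497 48.285987
endpoint(simulate_sg(fx$ko))
#>    p_end    d_end    total
#> 26.73539 18.35796 45.09335
classify_perturbation(fx$wt, fx$ko)
#> D_EXPANSION (rel_tol 0.05): P 38.96 -> 26.74, D 9.32 -> 18.36
```

Lowering only the self-renewal probability doubles the differentiated
compartment (9.3 → 18.4 cells) and nearly triples the D/P ratio without
any basal accumulation — the model's reading of a knockout that
accelerates progenitor detachment, labelled `D_EXPANSION`.

```r
## recover parameters from synthetic observations
truth <- sg_params(c = 1.5, k = 2, f_p = 0.8)
obs <- synth_count_observations(truth, obs_days = 2:9, count_noise_cv = 0,
                                seed = 1)
fit <- sg_fit(obs, n_starts = 32, seed = 1)
coef(fit)
#>         c         k       f_p
#> 1.4999971 2.0000237 0.7999998

## gland morphometry to cell counts
est <- estimate_counts(sg_measurements("g1", max_length = 20, max_width = 20,
                                       basal_nuclear_density = 0.1,
                                       suprabasal_cell_size = 15))
round(c(P = est$p_est, D = est$d_est), 3)
#>      P      D
#> 12.566  1.241
```

For a spherical 20 µm gland at 0.1 nuclei/µm the surface holds ~12.6
basal-cell footprints and the volume ~1.2 suprabasal-cell volumes.

Note that parameter values fitted from noisy totals-only data are one
representative of a near-equivalent family (the totals constrain the
trajectory much more tightly than the individual parameters); see the
vignette's identifiability section.

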