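# spindlescale

Quantitative analysis of mitotic spindle scaling during neural
differentiation of embryonic stem cells (ESCs), for cell biologists and
image analysts who work with per-cell morphometry rather than raw image
volumes.

When mouse ESCs differentiate towards the neural lineage their mitotic
cells shrink (mean volume 2,719 → 1,942 µm³) and their spindles shrink
with them — but not proportionally: at matched cell volume, spindles in
early-differentiated cells (DIF) are up to ~24% smaller than in
undifferentiated ESCs, while microtubule growth speed (~0.26 µm s⁻¹) and
turnover (FRAP half-time ~11 s) stay unchanged. What changes instead is
the cytoplasm itself: its mass density drops ~10% (140 → 125 mg ml⁻¹),
lowering the free tubulin concentration, which liberates the centrosomal
regulator CPAP from its inhibitory tubulin complex, enlarges the
pericentriolar material (~1.4-fold higher centrosome occupancy), and
redistributes microtubules from the spindle bulk to the asters.

The package implements that full analysis chain plus its theoretical core,
a limiting-component model of astral microtubule number:

- free tubulin from the cellular mass balance,
  `c_free = (c_tot·V_cell − ρ_poly·V_spindle) / V_cell`;
- CPAP liberation by single-site inhibition, `f_free = K_d / (K_d + c_free)`;
- a saturating (Michaelis–Menten) astral count,

  ```
  N(V) = N_sat · V / (K_V + V),   N_sat = α · CPAP_tot · f_free
  ```

  so diluted cytoplasm (lower `c_free`, higher `f_free`) predicts a higher
  astral plateau `N_sat` in differentiating cells — with constant total
  microtubule number per cell volume.

Because the underlying imaging data live in an external repository, the
package ships a seeded synthetic-data generator (`generate_*` functions)
that reproduces the published population statistics, so every analysis
stage is testable and reproducible without any download. Analysis
functions take plain tibbles (CSV schemas documented per function), so the
same code runs on real per-cell exports.

## What is in the box

| Stage | Functions |
| --- | --- |
| Synthetic data | `state_params()`, `generate_cell_population()`, `generate_frap_traces()`, `generate_comet_tracks()`, `generate_half_spindle_profiles()`, `generate_blot_dataset()`, `generate_lineages()` |
| Scaling statistics | `bin_by_cell_volume()`, `summarise_bins()`, `subscaling_profile()`, `compare_groups()` (Welch t + Cohen's d), `spearman_rho()`, `occupancy()`, `fold_change_vs_control()`, `intermitotic_times()` |
| FRAP turnover | `preprocess_trace()`, `fit_recovery()`, `fit_frap_traces()` |
| EB1 comets | `track_filter_rules()`, `filter_tracks()`, `mean_growth_speed()`, `pole_signal_fraction()`, `comet_partition()` |
| Mass density & blots | `mass_density_from_ri()`, `ri_from_mass_density()`, `average_masked_ri()`, `fit_calibration()`, `quantify_tubulin_fraction()` |
| CPAP–tubulin model | `model_params()`, `free_tubulin_concentration()`, `cpap_free_fraction()`, `predict_astral_count()`, `estimate_astral_counts()`, `fit_saturation_curve()`, `astral_saturation_analysis()` |
| Orchestration | `default_run_config()`, `read_run_config()`, `run_pipeline()`, `write_report()`, `ingest_records()` |

Fitted objects (`frap_fit`, `saturation_fit`, `blot_calibration`) carry
broom-style `tidy()`/`glance()` methods and `autoplot()` diagnostics.

## Worked example

```r
library(spindlescale)
library(dplyr)

esc <- generate_cell_population(state_params("ESC"), n = 1084, seed = 1)
dif <- generate_cell_population(state_params("DIF"), n = 2920, seed = 2)

spearman_rho(bind_rows(esc, dif)$V_cell_um3,
             bind_rows(esc, dif)$V_spindle_um3)
#> [1] 0.797

compare_groups(esc$V_cell_um3, dif$V_cell_um3)
#>   t_statistic df_welch p_two_sided cohens_d   n_a   n_b
#> 1        40.9    1568.   1.03e-249     1.65  1084  2920

edges <- seq(1000, 3500, 500)
subscaling_profile(summarise_bins(esc, edges), summarise_bins(dif, edges))
#> <subscaling_profile> max median deficit 27.4% over 5 bins
#>   bin         bin_low bin_high n_ref n_test deficit_pct flagged
#> 1 [1000,1500)    1000     1500    16    405        27.4 FALSE
#> 2 [1500,2000)    1500     2000    90   1176        25.8 FALSE
#> 3 [2000,2500)    2000     2500   270   1016        23.1 FALSE
#> 4 [2500,3000)    2500     3000   371    270        23.6 FALSE
#> 5 [3000,3500)    3000     3500   233     23        23.1 FALSE

fits <- fit_frap_traces(generate_frap_traces(state_params("ESC"), 31, seed = 3))
mean(fits$t_half[fits$qc_pass])
#> [1] 10.84

astral_saturation_analysis(bind_rows(
  generate_cell_population(state_params("ESC"), 2000, seed = 4),
  generate_cell_population(state_params("DIF"), 2000, seed = 5)))
#>   state N_sat   K_V n_bins
#> 1 DIF    66.5 1046.     6
#> 2 ESC    61.4 1061.     7
```

Reading the numbers: the pooled rank correlation (0.797) says spindle
volume tracks cell volume; the Welch comparison (d = 1.65) is the 29%
volume drop upon differentiation; the per-bin deficits (~23–27%) are the
spindle subscaling at matched cell volume; the mean FRAP half-time
(10.8 s for this draw, parent mean 11.1 s) shows turnover unchanged; and
the fitted saturation plateaus (`N_sat` 66.5 vs 61.4) reproduce the
model's prediction that diluted cytoplasm supports more astral
microtubules.

A single call runs everything end to end:

```r
report <- run_pipeline(default_run_config(seed = 1))
report$density$summary   # per-state mass densities via the RI conversion
report$model$fits        # per-state (N_sat, K_V)
```

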