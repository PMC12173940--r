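---
title: "Methods: spindle subscaling, cytoplasmic dilution and the CPAP-tubulin model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spindle subscaling, cytoplasmic dilution and the CPAP-tubulin model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical procedures applied to per-cell morphometry, FRAP traces,
EB1 comet tracks, refractive-index tomography and quantitative
immunoblots; the limiting-component model of astral microtubule number;
the synthetic-data generator that stands in for the deposited imaging
data; and the numerical choices that matter. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The biological question and the model

During neural differentiation, mitotic cells shrink and their spindles
shrink disproportionately: at matched cell volume, spindle volume in
early-differentiated cells (DIF) sits below the undifferentiated (ESC)
scaling line, while microtubule growth speed and turnover are unchanged.
The package's core model explains this through the physical state of the
cytoplasm:

1. **Mass balance.** Total tubulin is a fixed share (~1.5%) of protein
   mass, so its concentration follows the cellular mass density
   $\rho$: $c_{tot} = 0.015\,\rho$ (1 mg ml$^{-1}$ $\equiv$ 1 fg
   µm$^{-3}$, so all mass balance is done in fg and µm³ without
   conversion constants). The spindle locks away polymer at density
   $\rho_{poly}$ per spindle volume:
   $$c_{free} = \frac{c_{tot} V_{cell} - \rho_{poly} V_{spindle}}{V_{cell}}.$$
   The mixing volume is the whole cell — the simplest defensible choice;
   subtracting the spindle volume from the denominator changes
   $c_{free}$ by ~10% and none of the qualitative behaviour.

2. **CPAP liberation.** Soluble tubulin inhibits the centrosomal
   regulator CPAP by single-site binding with tubulin in excess, so the
   free fraction is $f_{free} = K_d/(K_d + c_{free})$.

3. **Saturating astral count.** The astral microtubule number follows a
   Michaelis–Menten dependence on cell volume, proportional to free CPAP:
   $$N(V) = N_{sat}\frac{V}{K_V + V},\qquad
     N_{sat} = \alpha\,\mathrm{CPAP}_{tot}\,f_{free}.$$
   Because a state's spindle fraction and density are roughly constant
   across its cells, $f_{free}$ is nearly volume-independent within a
   state, and the mechanistic chain composes to an exact Michaelis–Menten
   curve (the test suite verifies < 5% RMS deviation; under the default
   noiseless chain it is identically zero). Cytoplasmic dilution (DIF,
   hypo-osmotic, or CCB02-mimicked CPAP liberation) raises $f_{free}$ and
   with it the plateau.

The exact printed form of the model equation lives in
supplementary material that is not reproduced here; the implementation
follows the main-text characterization above and isolates it behind
`predict_astral_count()`. "Proportional to free CPAP" is read as
proportional to the per-cell free amount ($\mathrm{CPAP}_{tot} f_{free}$,
scaled by $\alpha$); reading it as a concentration would fold an extra
$1/V$ into $\alpha$ and rescale $K_V$, not change the fitted plateaus'
ordering.

## 2. Parameters: published values, derived values, calibration values

Three tiers of constants appear in `state_params()` and `model_params()`.

**Published population statistics** (used verbatim as generator
defaults): cell volume 2,719 ± 567 µm³ (ESC) / 1,942 ± 424 µm³ (DIF);
mass density 140 ± 12 / 125 ± 11 mg ml$^{-1}$ (and 118 ± 10 / 112 ± 9
for the iso/hypo-osmotic arms); FRAP half-time 11.1 ± 4.6 / 9.7 ± 5.8 s;
comet growth speed 0.26 ± 0.034 / 0.26 ± 0.031 µm s$^{-1}$; a 24%
multiplicative spindle-volume deficit for DIF; tubulin at 1.5% of
protein mass; blot standards of 25/50/100 ng against lanes of 4/2/1 µg;
the 3 + 35 frame FRAP layout at 1 s per frame with a 1-s bleach; 0.4-s
comet frames; track retention by duration 2–4 s, median quality 200–600
and endpoints within frames 0–30; centrosome occupancy 1.4-fold higher
in DIF; saturation of ESC centrosomes and astral counts above
~3,000 µm³; the refractive-index conversion
$\rho = ((\mathrm{RI}_{raw}/10^4 - \mathrm{RI}_{medium})\cdot 1000)/0.19$.

**Derived defaults**: $c_{tot}$ = 0.015 × the state's density (2.1
mg ml$^{-1}$ for ESC) — derived, not measured directly.

**Calibration values** (quantities without published values; chosen once,
with the calibration target stated, and not revisited):

| Constant | Default | Calibration target / rationale |
| --- | --- | --- |
| `spindle_fraction` | 0.10 | spindle occupies ~10% of cell volume at reference; typical for mammalian metaphase |
| `scaling_noise_sd` | 0.225 | log-scale spindle noise such that the pooled ESC+DIF Spearman correlation of (V_cell, V_spindle) is 0.80 on 2×10⁵ draws. The published 0.8 describes the pooled dataset; with this value the within-ESC correlation is ~0.68 |
| `centrosome_fraction` | 0.002 (ESC) | summed centrosome volume ~5.4 µm³ at the ESC mean volume |
| DIF `centrosome_fraction` | 0.002726 | median occupancy fold of 1.4 relative to the soft-capped ESC reference (10⁵ draws) |
| `centrosome_cap` | 6 µm³, scale 0.5 | smooth soft-minimum; the data show an upper limit above ~3,000 µm³, not a kink |
| `pole_fraction_mean` | 0.55 (ESC) / 0.62 (DIF) | pole-ward shift of EB1 signal upon differentiation; printed only as significance, not values |
| `astral_prob` | 0.13 / 0.23 | astral:bulk comet odds ~0.15 vs ~0.30 |
| `K_d` | 0.3 mg ml$^{-1}$ | half-inhibition well below $c_{free}$ so the dilution channel is sensitive |
| `rho_poly` | 2 mg ml$^{-1}$ | kept small: a large polymer term would cancel the dilution effect, because DIF's smaller spindle releases tubulin exactly where its cytoplasm is diluted |
| `cpap_total`·`alpha` | 440 | mechanistic ESC plateau ≈ 60 astral microtubules |
| `n_V` | 0.05 µm$^{-3}$ | ~136 comets per ESC-sized cell; constant across states |
| `lambda_bulk` | 0.330 µm$^{-3}$ | morphometric astral estimator unbiased against the forward model at ESC defaults (2×10⁵ draws) |
| `K_V` | 1,000 µm³ | the curve reaches 75% of its plateau at the ~3,000 µm³ volume where astral counts level off; larger values make the curve indistinguishable from a line over the observed volumes and the plateau unidentifiable |

## 3. The synthetic-data generator

`generate_cell_population()` draws cell volume from a normal truncated at
`max(0, mean − 3·sd)` (matches the printed moments without heavy tails),
spindle volume from a linear-through-origin law with log-normal noise and
the state's multiplicative subscaling factor, centrosome volume as a
soft-capped fraction of cell volume, density from its normal law, and a
ground-truth astral count from the mechanistic chain (using each cell's
own density) with Poisson noise. FRAP traces follow the published frame
layout with per-trace half-times from a truncated normal, a shared slow
mono-exponential acquisition-photobleaching decay on both ROIs, and
additive Gaussian noise (default SD 0.02 on the normalized scale). Comet
tracks are straight lines at truncated-normal speeds with uniform
durations spanning the retention window and its rejects. Half-spindle
profiles come from a power-law family, $y = (1-x)^p$ (pole-peaked) or
$x^p$ (equator-weighted), whose pole share $1 - 0.5^{p+1}$ (resp.
$0.5^{p+1}$) has a closed-form inverse — this matters because min–max
normalization annihilates any affine offset, so only the shape can carry
the target share. Blots are linear in loaded mass with multiplicative
log-normal noise.

What the generator deliberately does **not** emulate: 3D image volumes or
segmentation, comet catastrophes or curved trajectories, photophysics
beyond mono-exponential bleaching, per-experiment nesting (the measurements
pools experiments), or the right skew of the real differentiating-cell
volume distribution (the printed mean ± SD is all we have; the real
per-bin counts suggest heavier upper tails). Passing tests therefore
certify the analysis chain against data with the published first and
second moments — not against raw-image artefacts, detection noise or
between-replicate variance.

Two consequences of these modelling choices are worth stating plainly.
First, with a *uniform* 24% subscaling factor, the binned
ratio-of-medians deficit does not read exactly 24% in every bin: within a
500-µm³ bin the two states' volume distributions differ (ESC probability
mass sits higher in each bin), which pushes per-bin deficits to ~25–27%,
and taking the maximum over five bins with sparse edge bins adds ~2
points more; the maximum deficit statistic on synthetic data therefore
reads ~27–30%, systematically above the factor itself. Second, the
truncation of half-time and volume laws at zero shifts their means
slightly above the printed values (e.g. +0.1 s for the ESC half-time);
both effects are small against the reported dispersions.

## 4. Estimators and numerical choices

**Binning** is left-closed, right-open (`[edge, edge)`), with an explicit
`"unbinned"` bucket so no record is dropped silently. The scaling
comparison uses 500-µm³ bins spanning 1,000–3,500 µm³. Per-bin deficits
with fewer than 5 cells in either group (the smallest published bin
count) are flagged and excluded from the reported maximum.

**Group comparisons** use Welch's t-test (Satterthwaite df, two-sided)
and Cohen's d with the (n−1)-weighted pooled SD. No multiple-testing
correction is applied across bins, matching the per-bin reporting of the
source figures. Spearman correlations use average ranks for ties and
signal constant inputs.

**FRAP.** Bleach-ROI signals are divided by the control ROI rescaled to
its pre-bleach mean (the standard ratio reading of "corrected using a
control ROI"), then min–max normalized over the full trace (a switch
restricts normalization to post-bleach frames). Fits use only post-bleach
frames with time re-zeroed at the first post-bleach frame. The recovery
$A(1-e^{-t/\tau})+C$ is fitted by Levenberg–Marquardt, parameterized by
its plateau $P = A + C$ with the physical bound $P \le 1.05$ on the
normalized scale — the recovery cannot exceed the pre-bleach level.
Without that bound, traces whose recovery outlasts the 35-s window drift
up a $(P, \tau)$ ridge and the condition mean is biased upward by as much
as +1 s. Fits with $\tau$ beyond the window are flagged
(`tau_exceeds_window`) and excluded from condition means; fits with
$\tau$ beyond 10× the window are refused outright. Initialization:
$C_0$ = first value, $P_0$ = late-frame plateau, $\tau_0$ = time to
half-plateau. Accuracy has a statistical floor: with 35 one-second
frames, the median half-time error is < 5% at noise SD 0.02 for
half-times within the window, but no estimator reaches 5% at noise SD
0.05 or for $\tau \approx 30$ s — the tests encode exactly that.

**EB1.** Per-track speed is path length over duration (comets are
ballistic here, so path length and end-to-end displacement coincide);
per-cell speed is the mean over kept tracks. Compartment labels are
consumed from the generator (or an explicit column in real exports) —
geometric re-classification would require the segmentation that is out of
scope. Comet counts average three sample frames (default 1, 15, 30,
inside the default track window; the published videos are longer than the
0–30-frame filter window, an unresolved inconsistency we expose as
parameters). Pole fractions integrate trapezoidally over normalized
distance 0–0.5 versus 0–1, interpolating at 0.5 when needed.

**Blots.** The calibration line is ordinary least squares through the
standards; lane tubulin is back-calculated as (signal − intercept)/slope;
the Coomassie correction divides each lane by its expected signal at
nominal load, with the signal-per-µg pooled across lanes (the published
normalization algebra is not fully specified; this convention makes the
quantification invariant to a common detector gain, which the tests
check). Lanes are averaged unweighted, as three technical replicates.

**Saturation fits** are weighted nonlinear least squares of
$N_{sat}V/(K_V+V)$ with five jittered multistarts. Two choices remove
systematic bias found during development: each bin enters at its **mean
cell volume**, not its geometric center (cells are not uniform within a
bin; centers bias $K_V$ low by ~10%), and bin means are weighted by
their standard errors ($sd/\sqrt{n}$), not raw SDs, so sparse edge bins
inform the plateau without dominating it. The default fit range covers
the full observed volume span (500–5,000 µm³ in 500-µm³ bins, bins with
≥ 5 cells): restricting to the 1,000–3,500 µm³ display window leaves the
plateau unidentified. Flat count profiles are returned with a
`K_V_non_identifiable` flag rather than an error. The per-state analysis
fits the generator's forward-model counts; the morphometric estimator
`estimate_astral_counts()` ($n_V V_{cell} - \lambda_{bulk} V_{spindle}$)
is validated separately for population-level unbiasedness — its per-cell
values are noisy (the spindle-volume noise enters multiplied by
$\lambda_{bulk}$) and occasionally negative, which is flagged and floored.

**Reproducibility.** Every generator takes an explicit seed; the
pipeline fans one master seed out per stage through a fixed affine rule
(`split_seed()`), and runs with identical config and seed are identical
up to the provenance timestamp.

## 5. Problem sizes

All checks run at desk scale: populations at the published sample sizes
(1,084 / 2,920 cells; 188 / 182 for occupancy; 60–107 for densities), 31
FRAP traces per condition, 92 comet cells at 60 tracks each, and
2,000 cells per state (five replicates) for the model-recovery checks.
The full test suite and the acceptance script each run in well under five
minutes on a single core.

## 6. Known limitations

- The supplementary derivation of the model equation was not available;
  the mechanistic-to-Michaelis–Menten reduction here is the package's
  reconstruction, isolated behind `predict_astral_count()`.
- $K_d$, $\mathrm{CPAP}_{tot}$, $\alpha$, $n_V$, $\lambda_{bulk}$ and
  $K_V$ are calibration constants, not measured values; absolute astral
  counts are on an arbitrary but self-consistent scale.
- The subscaling maximum-deficit statistic is biased a few points above
  the generating factor by bin-composition effects (Section 3); comparing
  it directly against the printed 24% conflates the factor with the
  statistic.
- CCB02 is represented only as a state with a larger effective free-CPAP
  fraction; there is no pharmacodynamic model.
- The FRAP model is a single-exponential recovery; reaction–diffusion
  kinetics and explicit mobile-fraction decomposition are out of scope.
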