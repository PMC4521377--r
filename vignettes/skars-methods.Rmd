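---
title: "Models and methods behind skars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind skars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skars)
```

This vignette documents the scientific and numerical choices in the
package: the shuttling model and its assumptions, the defaults and why they
were chosen, what the synthetic-data generator does and does not emulate,
and the conventions adopted where the underlying procedures are genuinely
underdetermined.

## The shuttling model

A kinase activity relocation sensor shuttles between nucleus and cytoplasm.
Four species are tracked as *amounts*: unphosphorylated and phosphorylated
sensor in the nucleus ($U_n$, $P_n$; volume 1) and in the cytoplasm ($U_c$,
$P_c$; volume $V$, the cytoplasm-to-nucleus volume ratio). With activity
$A(t) \in [0,1]$ the fraction of the kinase pool in the active state:

$$
\begin{aligned}
\dot U_n &= -k_{phos} A\, U_n + k_{dephos} P_n + k_{imp} u_c + k_{diff}(u_c - u_n) \\
\dot P_n &= \phantom{-} k_{phos} A\, U_n - k_{dephos} P_n + k_{diff}(p_c - p_n) \\
\dot U_c &= -k_{phos} A\, U_c + k_{dephos} P_c - k_{imp} u_c - k_{diff}(u_c - u_n) \\
\dot P_c &= \phantom{-} k_{phos} A\, U_c - k_{dephos} P_c - k_{diff}(p_c - p_n)
\end{aligned}
$$

where lower-case letters are concentrations ($u_c = U_c/V$, $u_n = U_n$,
etc.). The model's assumptions:

* both compartments are well mixed (no spatial gradients);
* phosphorylation and dephosphorylation have the same rate constants in
  both compartments; the phosphatase is constitutive;
* passive exchange moves both phospho-forms down the concentration
  gradient with flux $k_{diff}(c_n - c_c)$ per unit of concentration
  difference;
* only the unphosphorylated sensor is actively imported, with flux
  $k_{imp} u_c$;
* no synthesis or degradation: the total amount is conserved exactly by
  construction (every flux appears twice with opposite signs).

Two consequences anchor the model. At $A = 0$ everything is
unphosphorylated, the import–diffusion balance gives
$u_n/u_c = 1 + k_{imp}/k_{diff}$ exactly, and with the default
$k_{imp}/k_{diff} = 2$ the basal nuclear enrichment is exactly 3-fold.
With $k_{imp} = 0$ diffusion equalizes concentrations and the ratio is 1
at any activity. In between, the steady-state ratio decreases
monotonically (close to linearly) with activity, which is what makes the
readout quantitative.

A useful closed form exists in the limit of fast phospho-turnover
(both $k_{phos}$ and $k_{dephos}$ large relative to exchange): each
compartment then carries the same unphosphorylated fraction
$f_u = k_{dephos}/(k_{phos}A + k_{dephos})$ and the ratio tends to
$1 + (k_{imp}/k_{diff}) f_u$. Note the direction of the limit: with fast
*exchange* instead, the volume-weighted mixing of the phosphorylated pool
leaves a finite deviation from this formula (about 5% at the default
geometry), so the closed form is used as an asymptotic test, not as the
implementation. The implementation solves the linear steady-state system
directly (the fixed point is unique), and the test suite checks it against
long-horizon numerical integration on a parameter lattice.

## Default parameters

Rate values for this class of sensor are not tabulated anywhere usable, so
the defaults are *calibration-constrained*, chosen once to reproduce three
observed features of the biology and then frozen:

| parameter | default | unit | constraint it encodes |
|---|---|---|---|
| `k_imp`   | 1.0 | min⁻¹ | basal 3-fold enrichment (with `k_diff`) |
| `k_diff`  | 0.5 | min⁻¹ | basal 3-fold enrichment; minutes-scale exit |
| `k_phos`  | 2.0 | min⁻¹ | relocation within a few minutes of stimulation |
| `k_dephos`| 0.5 | min⁻¹ | ~7 min return to basal after kinase inhibition |
| `vol_ratio` | 7 | – | typical yeast cytoplasm:nucleus geometry |
| `total_sensor` | 100 | a.u. | arbitrary; results depend only on ratios |

With these values the 90% recovery time after switching activity from 1 to
0 is about 7 minutes, matching the observed return of the sensor after
acute kinase inhibition, and inside the 2–15 min band the calibration
demands.

## Activity profiles and fitting

Measured activity time courses are represented by a deliberately small
parametric family: baseline $A_0$ until the onset $t_{on}$, then an
exponential relaxation to the plateau $A_{max}$ with timescale
$\tau_{rise}$, optionally multiplied by $e^{-(t-t_{on})/\tau_{decay}}$ for
transient responses. This is the simplest family that can express sustained
steps, delayed rises and transient pulses, the three shapes the responder
classes require.

`fit_activity_timecourse()` minimizes the sum of squared differences
between simulated and measured ratios with `L-BFGS-B` under box
constraints ($A_0, A_{max} \in [0,1]$; $\tau$ on a log scale in
[0.1, 60] min). Three fixed starting points (fast, intermediate and slow
response) guard against local minima while keeping the fit fully
deterministic. The objective integrates the ODE at a relaxed tolerance
(`rtol = 1e-6`); the returned trajectory is recomputed at `1e-8`. The
right-hand side is compiled C (through `deSolve`), with an R
implementation kept as a cross-checked second engine.

One identifiability caveat: single-cell traces are normalized by their own
basal level, and in normalized space different baselines produce nearly
the same shape, so $A_0$ is only weakly identified. The pipeline therefore
pins $A_0$ (default 0.2, the unstimulated activity obtained by
steady-state dose-response inversion) when fitting normalized population
medians; absolute-scale fits leave it free.

Inferred activities outside $[0,1]$ arise from measurement noise; the
inversion clips them to the range with a warning rather than failing.

## The synthetic-data generator

The generator is the package's ground truth and encodes the study
conditions:

* **Classes.** Cells are responding / slow / non-responding with default
  fractions 0.72 / 0.11 / 0.17, the composition reported for pheromone
  stimulation. Responding cells rise fast ($\tau_{rise} = 1$ min from
  $A_0 = 0.2$ to $A_{max} = 0.9$), slow cells rise with
  $\tau_{rise} = 8$ min, and non-responders get a transient pulse
  ($A_{max} = 0.45$, $\tau_{decay} = 3$ min) that returns to baseline —
  emulating the early sensor exit and return observed in refractory cells.
* **Basal heterogeneity.** Basal ratios are log-normal with median 3 and
  log-sd 0.4 (interquartile range ≈ 2.3–4), representing the large
  cell-to-cell variability in intrinsic import capacity. Traces are the
  model output rescaled to the cell's basal ratio: the heterogeneity is
  treated as import capacity, not as activity differences.
* **Kinetic jitter.** Per-cell $\tau_{rise}$ carries multiplicative
  log-normal jitter (log-sd 0.15), *clamped at ±2 sd* so that every cell's
  noise-free kinetics still satisfy its own class definition (responders
  stay below the 1.5× slow boundary, slow cells above it). Without the
  clamp a planted "responding" label could be false by construction.
* **Markers.** The cell-cycle marker is nuclear with class-dependent
  probability (0.55 / 0.5 / 0.2), qualitatively reproducing the enrichment
  of G1-like cells among responders; these probabilities are illustrative,
  not fitted.
* **Noise.** Additive Gaussian noise on the ratio (sd 0.05) plus per-cell
  intensity scaling; rendered images add per-pixel Gaussian noise. There is
  no point-spread function (cells are large relative to pixels at a
  40×-like scale), no photobleaching, no focus drift, and no growth or
  division during the movie.

Consequently, passing tests show that the *pipeline* is correct under these
conditions; they do not show robustness to crowded fields, segmentation
errors from out-of-focus cells, bleaching trends, or division events —
real-data effects the generator deliberately omits.

## Image quantification conventions

* Nuclei: Otsu threshold (fixed-value override available) on the
  nuclear-marker channel, connected components as labelled by EBImage,
  area-filtered to [20, 2000] px.
* Cells: seeded region growing (`EBImage::propagate`) from the nuclei over
  a thresholded cell-body channel. The original brightfield-based contour
  detection of the source platform is not described anywhere reusable; the
  contract that matters downstream — exactly one cell region per nucleus,
  regions disjoint, nucleus contained — is what is implemented and tested.
  A nucleus with no surrounding body signal falls back to a dilated disk
  and is logged.
* Cytoplasm: the cell minus its own nucleus dilated by a *digital disk of
  radius 2 px* (the structuring element is $x^2+y^2 \le r^2$; "expanded by
  two pixels" is read as radius-2 dilation). Cells whose ring comes out
  empty are flagged and excluded from ratios.
* Tracking: greedy nearest-centroid linking with a 10 px displacement
  gate; ties break by lower label id; unmatched nuclei start new tracks;
  only tracks spanning the whole movie survive QC.

## Trace statistics conventions

Where the procedures are underdetermined, the package fixes and documents
a convention:

* The initial-response window is the three points inside 3–5 min
  post-stimulus, or the three nearest points when sampling is coarser.
  Note that at ≥3 min sampling the window necessarily includes a point
  ~1 min after the stimulus, which dilutes IR and can push borderline
  responders over the 1.5× slow boundary; the 1-min default sampling of
  the generator avoids this.
* The final response uses the last three frames regardless of spacing.
* Boundary conventions: $FR = \theta$ classifies as responding;
  $FR = 1.5 \cdot IR$ classifies as responding; marker enrichment must
  exceed its threshold strictly to count as nuclear.
* The control-derived threshold is the 95th percentile of control final
  responses (≥20 control cells required), giving a designed false-positive
  rate of 5%; the fixed threshold 0.2 is provided for cell-wall-stress
  style analyses. The percentile rule is a documented choice — the
  underlying study does not state its rule.
* QC bounds default to a coefficient of variation of 0.2 on nucleus area,
  cell area, nuclear-marker fluorescence and whole-cell sensor
  fluorescence ("low variability" made concrete).
* Population percentiles interpolate linearly between order statistics
  (`quantile` type 7).

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: 300-cell
cohorts for classification recovery, 2000 control cells for the threshold,
50-cell/8–15-frame rendered movies at 512×512 for segmentation fidelity,
20-seed Monte-Carlo for noisy parameter recovery. These sizes put the
multinomial and noise tolerances well inside their 3σ bands while keeping
a full run in minutes. Every stochastic step derives from one integer
seed; `generate_cohort`, trace simulation and rendering use fixed offsets
of the spec seed and restore the caller's RNG state, so identical
(config, seed) pairs give byte-identical outputs.

## Known limitations

* The four phosphorylation sites of the real sensor are lumped into one
  phospho-state; site-resolved kinetics are not representable.
* The activity family cannot express oscillations or multi-phasic
  responses; the fit reports its residual so such misfits are visible.
* Rate constants are fixed inputs; the package does not estimate them from
  data, by design.
* The renderer's flat-disk cells make segmentation easier than real
  brightfield data; fidelity numbers on synthetic movies are upper bounds.
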