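# skars

Quantification of synthetic kinase activity relocation sensors (SKARS) in
single cells.

## The problem

SKARS are engineered MAP-kinase substrates built from three modules: a
docking site that gives specificity for one kinase, a nuclear localization
sequence (NLS) flanked by phosphorylatable serines, and a fluorescent
protein. When the kinase is active it phosphorylates the NLS, nuclear
import weakens, and the sensor redistributes from the nucleus to the
cytoplasm. Following the nuclear-to-cytoplasmic fluorescence ratio of
individual cells through a time-lapse movie therefore gives a dynamic,
single-cell readout of kinase activity — in budding yeast, of the mating
MAPKs Fus3/Kss1 or the cell-wall-integrity MAPK Mpk1.

This package implements the full analysis chain for such experiments, for
microscopists and modellers who want to go from multi-channel image stacks
(or per-cell trace tables) to kinase activities and responder statistics:

* **Kinetic model.** A two-compartment reaction model links the activity
  *A* ∈ [0, 1] (fraction of the kinase pool in the active state) to the
  sensor ratio. The sensor is phosphorylated at rate *k*<sub>phos</sub>·*A*
  and dephosphorylated constitutively at *k*<sub>dephos</sub> in both
  compartments; both phospho-forms exchange passively down the
  concentration gradient at *k*<sub>diff</sub>, and only the
  unphosphorylated form is actively imported at *k*<sub>imp</sub>. At zero
  activity the nuclear:cytoplasmic ratio is exactly
  1 + *k*<sub>imp</sub>/*k*<sub>diff</sub> (3-fold with the defaults), and
  the steady-state ratio decreases monotonically — close to linearly — with
  activity, which is what makes the sensor quantitative. The model is
  forward-simulated (compiled ODE right-hand side via deSolve), calibrated
  at steady state, inverted to infer activity from measured ratios, and fit
  by bounded multi-start least squares to estimate activity time courses.
* **Synthetic data.** A ground-truthed generator plants responder classes
  (responding / slow / non-responding), log-normal basal enrichment,
  minute-scale kinetics, cell-cycle marker states and measurement noise in
  single-cell traces, and renders multi-channel TIFF movies with label
  masks — so every downstream stage is testable without external data.
* **Image quantification.** Nucleus segmentation by thresholding the
  nuclear-marker channel, seeded expansion to cell regions, cytoplasm rings
  (cell minus the nucleus dilated by 2 px), nearest-centroid tracking, and
  per-object intensity extraction.
* **Trace statistics.** Quality control (full-length tracks, low
  coefficient of variation of areas and fluorescence), basal level *B*
  (mean of the first three ratio points), normalized trace *R*(*t*)/*B*,
  final response FR = 1 − mean of the last three normalized points, initial
  response IR = 1 − mean of three normalized points 3–5 min post-stimulus,
  responder classification (FR below a threshold → non-responding; FR more
  than 1.5× IR → slow), control-derived thresholds, population
  median/quartile summaries, heat-map ordering, and cell-cycle-marker
  quadrant analysis.
* **Pipeline.** `run_pipeline()` chains the stages deterministically from a
  single seed and writes every intermediate as CSV/TIFF/JSON.

## Worked example

```r
library(skars)

p <- sensor_params()                       # calibration-constrained defaults
steady_state_ratio(p, c(0, 0.5, 1))
#> [1] 3.000000 1.637363 1.385650

cal <- build_calibration(p)                # ratio -> activity
infer_activity_steady(c(3.0, 2.1, 1.5), cal)
#> [1] 0.0000000 0.1873601 0.7097013

cfg <- pipeline_config(synthetic = cohort_spec(n_cells = 300, seed = 1),
                       theta = 0.2, out_dir = "skars_run")
rep <- run_pipeline(cfg)
unlist(rep$class_counts)
#>     responding           slow non_responding
#>            222             32             46
```

The steady-state ratios say that an idle kinase leaves the sensor 3-fold
enriched in the nucleus and a fully active one pulls it down to ~1.39; the
inversion turns measured ratios back into activities (a ratio of 3.0 means
no activity, 1.5 means ~0.71). The pipeline run simulates a 300-cell
cohort, applies QC, and classifies 74% of cells as responding, 11% as
slow-responding and 15% as non-responding with the fixed final-response
threshold of 0.2 — recovering the planted population structure
(72/11/17%). `skars_run/` then contains `traces.csv`, `features.csv`
(per-cell basal level, IR, FR, class, marker enrichment), `summary.csv`
(population median and quartiles), `activity.csv` (fitted activity time
course) and `report.json`.

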