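# icsim

Spatially resolved interacting-cell-system (ICS) modeling of tumor–immune
microenvironments in R.

Multiplexed imaging (IMC, CyCIF) gives one pretreatment snapshot of a
melanoma biopsy: the positions and phenotypes of every cell in a
~1 × 1 mm tissue core, paired with the patient's later binary response to
immune checkpoint inhibitors. `icsim` turns that snapshot into a
mechanistic, stochastic simulation of the tumor microenvironment and asks
which interactions — in particular the exhaustion of activated CD8+
T cells by melanoma cells and by tumor-associated macrophages (TAMs) —
explain the recorded outcomes.

## What the package does

* **Data model and I/O** — tidy per-cell coordinate tables
  (`read_cell_table()`), cohorts with response manifests
  (`read_cohort()`), lossless trajectory CSVs.
* **Microscale spatial statistics** — per-slide densities and an annulus
  pair-correlation statistic `C(r)` (local target density around reference
  cells, minus the slide density, normalized by the cohort-mean target
  count), with exact geometric edge correction and Welch/permutation group
  comparisons between responders and nonresponders.
* **The ICS simulator** — the slide is rasterized onto 10 µm chambers with
  a hard occupancy cap and evolved by kinetic Monte Carlo. Events:
  melanoma proliferation; lysis of melanoma at rate *l* per contact pair
  with activated T cells; exhaustion of activated T at rate *bC* per
  melanoma contact pair and *bM* per same-chamber TAM pair; activated-T
  proliferation and recruitment boosted by the number of melanoma cells
  lysed in the previous feedback window; exhausted-T death; diffusive
  hops. The engine is compiled (Rcpp) with Fenwick-tree event sampling and
  is distribution-checked against a naive reference implementation.
* **Calibration** — a simulated slide predicts "responder" when the
  melanoma fold change over a 333 h therapy cycle is below 1; per-slide
  prediction success frequencies `f_i` enter the score
  `score(θ) = ∏ᵢ [(1 − b) f_i + b/2]` (b = 0.1), maximized over a
  log-spaced `(bC, bM)` grid with common random numbers
  (`fit_exhaustion_rates()`).
* **Hypothesis testing** — alternate models (one exhaustion rate set to
  zero, the other re-fitted) are compared by a paired bootstrap over
  slides of the difference in log score (DSS), 100,000 replicates, with
  Bonferroni adjustment (`bootstrap_dss()`, `bonferroni_adjust()`).
* **Fencing** — connected clusters of exhausted T cells in contact with
  melanoma (lattice adjacency for simulations, 15 µm point-cloud adjacency
  for imaging tables); the fencing fraction is referenced against a
  label-permutation null (`fencing_clusters()`, `fencing_null()`).
* **Trajectory statistics** — ensemble autocorrelation, coefficient of
  variation, transition time, and closed-form Yule (pure-birth)
  comparisons for late-time growth (`fit_yule()`, `yule_moments()`,
  `yule_autocorrelation()`).
* **Synthetic data** — slides and labeled cohorts with uniform, clustered,
  or segregated spatial structure, plus the position-randomization
  perturbation (`generate_slide()`, `generate_cohort()`,
  `randomize_positions()`), so the entire pipeline runs and is tested
  without any external data.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` ggplot2 graphics.

## Worked example: spatial organization decides the outcome

A segregated slide — tumor on the left, activated T cells on the right —
is a nonresponder: T cells that reach the tumor edge become exhausted
there and the resulting fence shields the bulk. Re-seeding the *same*
T cells uniformly at random flips the prediction.

```r
library(icsim)
spec <- slide_spec(
  n_melanoma = 250, n_t_active = 200,
  patterns = list(
    melanoma = pattern_segregated(xlim = c(0, 150)),
    t_active = pattern_segregated(xlim = c(350, 500))
  ),
  width = 500, height = 500
)
slide   <- generate_slide(spec, seed = 1)
lattice <- slide_to_lattice(slide, width = 500, height = 500)
lattice
#> <ics_lattice> 50 x 50 chambers (l0 = 10 um, cap = 4): melanoma=250, t_active=200, t_exhausted=0, tam=0

params <- rate_params(l = 0.3, bC = 0.01, bM = 0,
                      r_prolif_T0 = 0, k_prolif = 0,
                      r_recruit0 = 0, k_recruit = 0)
config <- sim_config(t_end = 333, record_every = 333)

ens <- simulate_ensemble(lattice, 50, params = params, config = config, seed = 2)
table(predict_response(fold_change(ens)$fold_change))
#> nonresponder
#>           50

moved <- randomize_positions(slide, "t_active", width = 500, height = 500, seed = 3)
lat2  <- slide_to_lattice(moved, width = 500, height = 500)
ens2  <- simulate_ensemble(lat2, 50, params = params, config = config, seed = 2)
table(predict_response(fold_change(ens2)$fold_change))
#> responder
#>        50
```

All 50 stochastic runs of the intact slide grow the tumor (nonresponder);
after randomizing only the T-cell positions, all 50 runs eliminate it.
The rates here put lysis far above exhaustion (l = 0.3 vs bC = 0.01 h⁻¹)
with feedback off, so the initial geometry alone decides the outcome.

The methods vignette (`vignettes/ics-model.Rmd`) documents the model, its
assumptions, every tunable parameter, and the design choices behind the
calibration and testing machinery.

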