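# fxseeg

EEG biomarkers for Fragile X Syndrome (FXS): resting-state spectral
variables, auditory-chirp time-frequency variables, a from-scratch
Gaussian naive Bayes classifier, and ground-truth simulators that make
the whole pipeline testable without access to restricted human data.

## The scientific problem

FXS, the most common inherited cause of intellectual disability, has
robust electrophysiological signatures: elevated resting theta and gamma
power, a slowed alpha peak, and reduced phase locking to an auditory
"chirp" stimulus whose amplitude modulation sweeps 0–100 Hz in 2 s. This
package asks the translational question: how well do those EEG variables,
alone and in combination, separate FXS participants from controls — in the
whole cohort and in the genetically meaningful subgroups (males, females,
non-mosaic males) — under a simple, transparent classifier?

Because per-subject recordings of the reference cohorts are
access-restricted, `fxseeg` ships two simulators with known ground truth:

* **feature level** — participants drawn from the class-conditional
  Gaussians of bundled cohort summary statistics (52 variables ×
  7 cohort cells), clipped to native bounds;
* **signal level** — multichannel EEG synthesized from 1/f noise,
  oscillators with a controllable alpha-peak frequency, and chirp trials
  with controllable per-trial phase jitter.

Every analysis stage is validated by round trips against these generators
and by analytic oracles (exact AUC laws, ITPC null levels, Bayes error
rates, and independent reference implementations).

## What is implemented

* `amplitude_spectrum()`, `band_power()`, `peak_alpha_frequency()`,
  `resting_feature_vector()` — Hann/FFT spectra on 2 s epochs at 0.5 Hz
  resolution; 7 bands × 3 scalp regions, absolute (picovolt scale) and
  relative power, peak alpha frequency: 45 named variables.
* `morlet_transform()`, `itpc()`, `single_trial_power()`,
  `chirp_feature_vector()` — Morlet wavelets (1→30 cycles across 2–100 Hz),
  inter-trial phase coherence and baseline-corrected single-trial power in
  7 time-frequency regions of interest, including ITPC along the chirp's
  50 Hz/s sweep diagonal: 7 named variables.
* `nbc_fit()`, `nbc_posterior()`, `nbc_predict()` — Gaussian naive Bayes
  with fixed 0.5 priors, log-space arithmetic, variance flooring and a
  control-class tie rule.
* `stratified_split()`, `roc_auc()`, `kfold_cv_error()`,
  `evaluate_variable_set()` — the 70/30 holdout AUC, full-dataset AUC and
  stratified 10-fold CV protocol.
* `build_variable_sets()`, `run_full_study()`, `write_study_report()` —
  enumeration of all a-priori variable sets (25 absolute, 25 relative,
  4 alpha-peak, 11 chirp), top-set selection, subgroup re-analysis, and a
  signal-level reduction to the standard 20-channel clinical montage.

## A worked example

```r
library(fxseeg)

tab <- simulate_feature_table(cohort_stats("relative"),
                              default_composition("rest"), seed = 1)
sets <- build_variable_sets("relative")
ev <- evaluate_variable_set(tab, sets[["All Whole Head Variables"]], seed = 1,
                            name = "All Whole Head Variables")
print(ev$summary, width = Inf)
#> # A tibble: 1 × 11
#>   variable_set                 n n_features auc_holdout auc_full cv_error    tp
#>   <chr>                    <int>      <int>       <dbl>    <dbl>    <dbl> <int>
#> 1 All Whole Head Variables   141          7       0.921    0.949    0.128    61
#>      fp    tn    fn  seed
#>   <int> <int> <int> <dbl>
#> 1     9    62     9     1
```

The complete study — every variable set, every family, subgroups and the
clinical-montage stage — runs in seconds and is bit-identical under a
fixed seed:

```r
study <- run_full_study(study_config(seed = 1))
write_study_report(study, "results/study")
```

Note one deliberate simulator property: feature-level draws are
independent across variables, whereas real EEG variables are strongly
correlated, so multi-variable sets separate the simulated groups better
than they could on real recordings. Directions of effects are faithful to
the cohort statistics; composite-set AUC magnitudes are not clinical
estimates. See `vignettes/fxseeg-methods.Rmd` for the methods in full.

## Analysis workflow

Numbered scripts under `analysis/` reproduce the study end to end:

```sh
Rscript analysis/01_simulate_cohort.R      --seed 1 --out results
Rscript analysis/02_extract_rest_features.R --seed 1 --montage standard1020-20
Rscript analysis/03_extract_chirp_features.R --seed 1
Rscript analysis/04_run_study.R            --seed 1 --out results/study
```

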