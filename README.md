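# eegicc

Test–retest reliability of phase-lag EEG connectivity across epoch
segmentation schemes.

## What this package is for

Infant (and other data-limited) EEG yields only a few minutes of clean,
variable-length signal per session. That signal can be cut into many short
epochs or few long ones before estimating functional connectivity, and the
choice interacts with the estimator: the **phase lag index**

PLI = | E{ sgn 𝕀{X} } |

(X the cross-spectrum of a channel pair, 𝕀 its imaginary part, E the
average over epochs) is positively biased at small epoch counts — under
independence E[PLI] = √(2/πn) — while the **debiased weighted PLI**
(dbWPLI), the pairwise-product estimator

dbWPLI = [ (Σₑ Iₑ)² − Σₑ Iₑ² ] / [ (Σₑ |Iₑ|)² − Σₑ Iₑ² ],  Iₑ = 𝕀{Xₑ},

removes this inflation and down-weights near-zero lags that volume
conduction and noise contaminate. Whether a subject-level score is usable
for individual-differences research is a question of **test–retest
reliability**, quantified by the two-way fixed-model consistency
intra-class correlation

ICC(3,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E),

with categories poor < 0.40 ≤ fair < 0.60 ≤ good < 0.75 ≤ excellent.

`eegicc` implements the full chain as a tested pipeline:

* **Synthetic two-session recordings** with known subject-level pairwise
  phase coupling, session-state drift, instantaneous (volume-conduction
  style) mixing and sensor noise, so design-level reliability is known by
  construction (`population_config()`, `make_population()`,
  `simulate_session()`, `simulate_study()`).
* **Epoch segmentation designs** — low numbers of long epochs, high
  numbers of short epochs, and a constant 120 s re-cut four ways from the
  same 6-s parents (`cut_epochs()`, `sample_epochs()`,
  `nested_resegment()`, `segmentation_schemes()`).
* **Spectral phase-lag connectivity** from Hanning-tapered Fourier
  coefficients, band-averaged over 6–8 Hz (infant alpha):
  `fourier_coefficients()`, `pli_matrix()`, `wpli_matrix()`,
  `dbwpli_matrix()`, `whole_brain()`.
* **Surrogate-normalised weighted graph metrics**: clustering
  coefficient, characteristic path length, small-worldness index
  (`rescale_weights()`, `weighted_clustering()`, `weighted_path_length()`,
  `surrogate_normalise()`).
* **Reliability**: `icc_3_1()` with F-based 95% CIs, p-values,
  negative-ICC clipping and categories; `run_experiment()` orchestrates
  everything into a tidy table with per-scheme subject exclusion, and
  `autoplot()` draws the ICC profiles.

## Worked example

```r
library(eegicc)

cfg <- population_config(n_subjects = 12, n_channels = 16,
                         sampling_rate = 64,
                         session_noise_sd = design_session_noise(0.7, 0.1),
                         seed = 42)

rt <- run_experiment(cfg,
  schemes = tibble::tibble(approach = "short_epochs",
                           n_epochs = c(30L, 90L, 150L), epoch_length = 1),
  methods = c("dbwpli", "pli"), metrics = "whole_brain")
rt[, c("n_epochs", "method", "icc", "ci_low", "ci_high", "p_value", "category")]
#>   n_epochs method   icc ci_low ci_high  p_value  category
#> 1       30 dbwpli 0.742  0.321   0.918 0.001832      good
#> 2       30    pli 0.732  0.301   0.915 0.002223      good
#> 3       90 dbwpli 0.802  0.447   0.939 0.000491 excellent
#> 4       90    pli 0.760  0.358   0.925 0.001278 excellent
#> 5      150 dbwpli 0.838  0.532   0.951 0.000171 excellent
#> 6      150    pli 0.827  0.504   0.947 0.000247 excellent
```

The population was designed with a between-subject coupling SD of 0.1 and
a session-noise SD putting the reliability ceiling at 0.7; ICC grows
towards (and, for a lucky 12-subject draw like this one, beyond) that
ceiling as epochs accumulate, and each cell carries its 95% CI, p-value
and category.

Lower-level pieces compose the same way:

```r
pop <- make_population(cfg)
rec <- simulate_session(pop[[1]], cfg, 1)
es  <- sample_epochs(cut_epochs(rec, 1), 90, seed = 1)
cm  <- dbwpli_matrix(fourier_coefficients(es), band = c(6, 8))
cm
#> <connectivity_matrix> dbWPLI, 6-8 Hz, 16 channels, 90 epochs
#>   whole-brain mean 0.0743, range [-0.0202, 0.3133]

surrogate_normalise(cm, n_surrogates = 200, seed = 1, absolute = TRUE)
#> <graph_metric_set> C_w 0.1587 (norm 0.9594), L_w 2.9502 (norm 0.9741),
#>   SWI 0.9850 [200 surrogates]

fit <- icc_3_1(dplyr::filter(experiment_scores(rt),
                             method == "dbwpli", n_epochs == 150))
fit
#> ICC(3,1) = 0.838 [0.532, 0.951], p = 0.000171 (excellent; n = 12, k = 2)
tidy(fit)    # broom-style one-row tibble; glance(fit) exposes the ANOVA
```

A thin command-line wrapper with `simulate`, `full-run` and `reliability`
subcommands is installed at `inst/scripts/eegicc-cli.R`. The methods
vignette (`vignettes/epoch-reliability-methods.Rmd`) documents the
generative model, estimator conventions and every numerical choice.

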