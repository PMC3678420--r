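# pmdtune

Neural-tuning and population-decoding analysis for dorsal premotor (PMd)
spike recordings from *separated* reach and grasp paradigms — plus a
ground-truth spike-train simulator that makes every stage testable.

## The problem

PMd neurons modulate with both the direction of a reach and the type of an
upcoming grasp. When a recording day contains one task that varies reach
direction (four directions, object fixed) and one that varies the grasped
object (four objects, direction fixed), each neuron can be classified as
tuned to reaching only, to grasping only, to both, or to neither — and the
contribution of each class to decoding the four actions can be measured.
`pmdtune` is for computational neuroscientists who want that analysis chain
as tested, scriptable R.

The core statistic is the plug-in mutual information between a 10-ms binary
spike indicator and the action label,

    I(spk; y) = Σ_y p(y) Σ_spk p(spk|y) log2[ p(spk|y) / p(spk) ]   (bits),

with p(y) = 1/4 under the balanced designs. Per task, neurons are ranked by
MI and the cumulative sum accumulated to 90% of the ensemble total; the
last MI added is the task's tuning threshold, and the two thresholds define
the four categories. Decoding uses a one-vs-one soft-margin SVM with RBF
kernel (an in-package SMO solver — no external SVM dependency), features =
per-trial 100-ms binned rates of a neuron subset, hyperparameters from a
log2 grid by stratified 2-fold cross-validation. One-way ANOVA screens for
task-related (rest vs movement) and per-bin action-tuned activity.

Because the motivating recordings are not deposited, sessions are simulated:
balanced trials with a realistic trial clock (1–2.5 s darkness, Light ON,
600 ms movement allowance, 1–2 s hold, Light OFF) and inhomogeneous-Poisson
neurons whose movement rate is `baseline * gain * (1 ± depth)` with planted
categories. See `vignettes/methods.Rmd` for every modelling decision.

## Worked example

```r
library(pmdtune)
ens <- default_ensemble(n_reach_only = 2, n_grasp_only = 2, n_both = 3,
                        n_untuned = 3, effect = "strong", seed = 42)
reach <- simulate_session(session_config("reach", ens, seed = 43))
grasp <- simulate_session(session_config("grasp", ens, seed = 44))
prof <- mi_profile(indicator_samples(align_and_window(reach)),
                   indicator_samples(align_and_window(grasp)))
cbind(round(prof[2:3], 4), planted = ens$category, recovered = prof$category)
#>  mi_reach mi_grasp    planted  recovered
#>    0.0057   0.0000 REACH_ONLY REACH_ONLY
#>    0.0040   0.0000 REACH_ONLY REACH_ONLY
#>    0.0001   0.0055 GRASP_ONLY GRASP_ONLY
#>    0.0001   0.0054 GRASP_ONLY GRASP_ONLY
#>    0.0025   0.0045       BOTH       BOTH
#>    0.0045   0.0051       BOTH       BOTH
#>    0.0055   0.0048       BOTH       BOTH
#>    0.0001   0.0000    UNTUNED    UNTUNED
#>    0.0001   0.0000    UNTUNED    UNTUNED
#>    0.0001   0.0000    UNTUNED    UNTUNED
```

Every planted category is recovered: tuned neurons carry ~0.004–0.006 bits
per 10-ms indicator sample in their task, untuned neurons ~1e-4 (the
plug-in bias floor). The thresholds (last MI inside 90% of the cumulative
total) were 0.0025 bits (reach) and 0.0045 bits (grasp):

```r
ct <- contribution_table(prof)
ct[ct$task == "reach", ]
#>   task   category  share_pct n_neurons
#>  reach REACH_ONLY 42.8892171         2
#>  reach GRASP_ONLY  0.7434329         2
#>  reach       BOTH 55.2642219         3
#>  reach    UNTUNED  1.1031281         3
```

The BOTH category carries the largest share of reach information (55.3%),
the pattern the analysis is designed to expose. Decoding the four reach
directions from 100-ms rate vectors:

```r
br <- bin_rates(align_and_window(reach))
res <- experiment_ensembles(br, prof, seed = 45)
res$full;  res$tuned;  res$top10
#> decoding_result [full_ensemble]: accuracy 0.830 (C = 2, gamma = 0.0078125, cv)
#> decoding_result [tuned_subset]: accuracy 0.920 (C = 128, gamma = 3.05176e-05, cv)
#> decoding_result [top10]: accuracy 0.830 (C = 2, gamma = 0.0078125, cv)
```

Chance is 0.25; the 7-neuron tuned subset decodes at least as well as the
full 10-neuron ensemble (here better — the untuned neurons only add noise).
`experiment_addition()` runs the companion comparison (single-property
subset vs the same plus BOTH neurons) and `run_pipeline(run_config(...))`
orchestrates everything, writing TSV reports, a JSON summary and figures.

A command-line interface is installed at `inst/cli/pmdtune`
(`pmdtune simulate ...`, `pmdtune run --config config.json`).

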