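---
title: "Methods: tuning, information and decoding in simulated premotor ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tuning, information and decoding in simulated premotor ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Neurons in the dorsal premotor cortex (PMd) modulate their firing with both
the direction of an upcoming reach and the type of object about to be
grasped. When the two factors are separated behaviourally — one task varies
reach direction while the grasped object is fixed, the other varies the
object while the direction is fixed — each neuron can be asked two
independent questions: does it carry information about reach direction, and
does it carry information about grasp type? `pmdtune` implements the full
analysis chain for that question: spike alignment and binning, ANOVA
screening, a mutual-information (MI) measure of tuning with a
cumulative-information threshold that sorts neurons into *reach-only*,
*grasp-only*, *both*, and *untuned* categories, and support-vector-machine
(SVM) decoding experiments that measure what each category contributes to
classifying the four actions of a task.

Because the motivating recordings are not publicly deposited, the package
ships a first-class spike-train simulator whose sessions have the same trial
structure, so every stage of the pipeline is testable against planted ground
truth.

## The simulated world

A session is a sequence of balanced trials (four actions; 25 trials per
reach direction or 50 per grasp object by default). Each trial is: darkness
for an intertrial interval drawn uniformly from 1–2.5 s, cue onset
(Light ON), a 600 ms movement allowance, a hold drawn uniformly from 1–2 s,
and cue offset (Light OFF). Spike trains are inhomogeneous Poisson with a
piecewise-constant rate: a neuron fires at its baseline rate $b$ outside the
cue period and, if it is task-related, at

$$r = b \cdot g \cdot (1 + d \cdot s)$$

between Light ON and Light OFF, where $g \ge 1$ is a movement gain, $d \in
[0,1]$ a tuning depth, and $s$ is $+1$ on the neuron's preferred action,
$-1$ on the others, and $0$ in a task where it has no preference. Untuned
neurons keep $b$ throughout.

Deliberate simplifications: the rate profile is a step, not the ramping
PSTH of real PMd neurons — the analyses under test (binned ANOVA, pooled
indicator MI, rate-vector decoding) are insensitive to within-epoch shape,
and a step keeps every expectation in closed form for oracle tests; no
refractory period or spike-sorting noise is modelled; reaction time is not
separated from the hold, because all analyses align to Light ON only. A
green test therefore establishes correctness of the statistics on a
stationary-within-epoch Poisson world, not realism of PMd dynamics.

### Ensemble presets

The source recordings report no baseline rates or modulation depths, so the
`default_ensemble()` presets are this package's own stated world, chosen
once by pilot calibration and then frozen:

* **strong** — baseline $U(2.5, 3.5)$ Hz, gain $U(1.9, 2.1)$, depth
  $U(0.42, 0.48)$. Two properties motivated the choice. First, tuning
  strength is deliberately *homogeneous*: the cumulative-90% threshold rule
  (below) always discards the weakest ~10% of tuned information, so the
  fewer very-weak outliers an ensemble has, the closer the categoriser gets
  to the planted truth (~93% per-neuron recovery). Second, rates are
  moderate — a handful of extra spikes per trial — so that decoding from a
  7-neuron subset is reliably below ceiling and adding more neurons
  measurably helps, as in the motivating study. Stronger settings push
  every decoder to 100% and make the subset comparisons vacuous.
* **weak** — baseline $U(2, 8)$ Hz, gain $U(1.2, 1.8)$, depth
  $U(0.15, 0.35)$: near-threshold tuning for power/robustness exploration.

## Preprocessing

Spikes are re-expressed relative to Light ON and kept in the half-open
window $[-0.5, +1.7)$ s (or $+1.3$ s for a faster subject). All bins and
10-ms steps are half-open, so no spike is ever counted twice; a spike
exactly at Light ON belongs to the first post-cue bin. Firing rates use
100-ms bins (22 for the 2.2-s window, 18 for 1.8 s); bins ending at or
before the cue are tagged REST, the rest MOVE.

## ANOVA screening

A neuron is *task-related* when a two-group one-way ANOVA (equivalently an
equal-variance t-test, $F = t^2$) separates per-trial mean rates in REST
bins from those in MOVE bins at $\alpha = 0.05$. It is *tuned* by the ANOVA
criterion when the across-action one-way ANOVA is significant in at least
two MOVE bins. Choices the source text left open: observations for the
task-related test are per-trial means (a per-bin variant is exposed via
`observations = "bins"`); no multiple-testing correction is applied, and no
post-hoc pairwise test follows the ANOVA, matching the minimal published
procedure. Note the per-bin observations are counts on a 100-ms Poisson
scale, not Gaussians; at 100 trials the F-test's size is nevertheless
within Monte-Carlo error of its nominal level (tested).

## Mutual information and the threshold rule

For each neuron and task, every 10-ms step of every trial contributes one
binary sample `spk` (≥1 spike in the step) paired with the trial's action
label $y$. The plug-in MI on the pooled 2×4 contingency table is

$$I(\mathrm{spk}; y) = \sum_{y} p(y) \sum_{\mathrm{spk} \in \{0,1\}}
p(\mathrm{spk} \mid y) \log_2
\frac{p(\mathrm{spk} \mid y)}{p(\mathrm{spk})},$$

with $p(y) = 1/4$ fixed by the balanced design (an empirical-$p(y)$
override exists for unbalanced data), $0 \log 0 = 0$, and the result
clipped at zero against round-off. No small-sample bias correction is
applied — the plug-in estimate is biased upward by roughly
$(|spk|-1)(|y|-1)/(2N\ln 2)$ bits, about $10^{-4}$ bits at the default
22,000 samples, which is negligible against tuned-neuron MI here. Samples
pool the full analysis window by default (`scope = "movement_only"` is
available); pooling rest steps dilutes but never reverses tuning contrast.

Per task, neurons are sorted by MI descending and the running sum
accumulated until it reaches 90% of the ensemble total; the last MI added
is the task's threshold. Comparison is inclusive (≥): the threshold neuron
was added, so it is tuned, and ties count as tuned. A neuron above both
thresholds is `BOTH`, above exactly one is `REACH_ONLY`/`GRASP_ONLY`, else
`UNTUNED`. By construction this rule demotes tuned neurons carrying the
last ~10% of information — that is intrinsic to the published procedure,
not an estimation error, and it is why category-recovery accuracy plateaus
near 90–95% even with noiseless parameters.

The contribution table reports, per task, each category's share of summed
MI (shares across the four categories total 100%); with several sessions
the per-session shares are averaged arithmetically, which is also how the
acceptance property for the "BOTH carries the larger share" pattern is
evaluated — at the single-session level the threshold rule's ~10% demotions
occasionally flip the comparison, while the 5-session average (the unit the
motivating table reports) is stable.

## Decoding

Features for a trial are the binned rates of the chosen neuron subset over
`feature_bins`, flattened neuron-major. The published feature counts (m =
18 of 22 bins, m = 14 of 18) do not identify *which* four bins are
dropped; the default slice is therefore the last m bins of the window and
the slice is configurable.

The classifier is a soft-margin SVM with RBF kernel, one-vs-one across the
four actions with majority vote (ties to the lowest class index). Because
no SVM library is available in the target environment, the binary C-SVC
dual is solved by an in-package SMO implementation (maximal-violating-pair
working-set selection, precomputed kernel, stopping tolerance $10^{-3}$)
that was validated against LIBSVM-family references during development;
its box/equality/KKT conditions are property-tested. Features are
standardized per dimension with training-fold statistics (RBF kernels need
comparable scales; the fit/transform split avoids information leak).
Hyperparameters come from the classic grid $\log_2 C \in \{-5, -3, \dots,
15\}$, $\log_2 \gamma \in \{-15, \dots, 3\}$ by stratified 2-fold
cross-validated accuracy.

How the reported accuracy is evaluated was left open by the source text.
The default (`eval_scheme = "cv"`) reports the best grid point's own
2-fold CV accuracy — the natural reading of "determined by 2-fold cross
validation" — but it inherits a selection bias: maximising over ~110
correlated grid points lifts the null expectation from 0.25 to roughly
0.28–0.29 with 200 trials. The alternative `"held_out"` scheme (grid chosen
by an inner CV inside fold 1, scored once on fold 2) is unbiased and is
provided for analyses where the floor matters.

Two experiments mirror the motivating comparisons: `experiment_ensembles()`
decodes from the full ensemble, the tuned subset (MI at/above the task
threshold), and the top-10 neurons by task MI; `experiment_addition()`
compares the single-property subset (a = reach-only or b = grasp-only)
against that subset plus the BOTH neurons (c), reporting the relative
improvement.

## Numerical choices and degenerate inputs

* Half-open intervals everywhere; window/bin arithmetic uses a $10^{-9}$ s
  guard against floating-point edge effects.
* `mi_threshold` of an all-zero list is 0 (every neuron then counts as
  tuned, the only reading under ≥); an empty list is an error.
* Zero-variance ANOVA inputs: identical data give $p = 1$, distinct
  constant groups give $p = 0$.
* Constant feature dimensions get unit scale during standardization.
* Grid-search ties resolve to the first grid point (smallest $\gamma$,
  then smallest $C$); fold assignment is seeded and stratified.
* Spike times serialize at 1 µs; MI is invariant to that rounding in all
  tested sessions (edge coincidences have measure zero).

## Known limitations

* The simulator's step-rate profile cannot exercise latency- or
  shape-based analyses; nothing here validates PSTH-shape claims.
* Plug-in MI is reported without bias correction, as in the source
  procedure; at much smaller sample counts than the defaults the upward
  bias would matter.
* The SMO solver targets the small problems of this design (≤ a few
  hundred trials); it has no shrinking/caching and is not meant for
  thousands of samples.
* Published percentages (information shares, decoding accuracies, the
  50.9–70.6% improvement range) depend on the undeposited recordings; the
  package reproduces the procedures and their qualitative pattern, and its
  tests assert only quantities its own code computes.
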