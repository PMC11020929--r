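---
title: "Curricula, continual learning, and task-switching metrics on composed digit scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curricula, continual learning, and task-switching metrics on composed digit scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Many learning problems are easier with a curriculum: a supporting task is
learned first and a more complex main task builds on the representations it
leaves behind. `curricnet` implements a controlled test bed for this idea
and for its sharpest failure mode, *automated* curricula — the hope that a
learner can decide for itself, from signals available during a single run,
when it has had enough pre-training.

The test bed composes scenes of one or two 28×28 digit glyphs scattered on
a white 84×84 canvas. Three tasks are defined on these scenes:

* **Single-digit recognition** (the supporting task): one glyph per scene,
  a 10-class label.
* **Parity of the digit sum**: two glyphs; the scene is labelled *even* or
  *odd* according to the sum of the two digits. Crucially, this error
  signal is *orthogonal* to digit identity: every digit appears equally
  often in odd-sum and even-sum scenes, so over a balanced batch the loss
  gradient carries no net information about any individual digit. Unless
  digit representations already exist (and an XOR-like readout can latch
  onto them), weight updates that would build those representations cancel.
* **Magnitude-encoded sum**: the same two-glyph scenes, but the label is a
  20-bit vector whose first X bits are 1, where X is the digit sum. This
  signal is *not* orthogonal to identity — the expected sum given that
  digit d is present grows linearly in d — so the main task itself can
  drive single-digit learning.

The package trains a deliberately small convolutional network on these
tasks under several curricula, and evaluates four families of
task-switching signals against a top-decile optimal-window criterion.

## The model

The network is a two-headed convolutional stack:

```
conv 3x3, 64 filters, relu  ->  2x2 average pool
conv 3x3, 32 filters, relu  ->  2x2 average pool
[optional third conv 3x3, 32 filters, relu -> pool]
dense, 10 units
dense, 2 units, relu        \   parity head
dense, 2 units, softmax     /
   — or —
dense, 20 units, logistic   -   magnitude head
```

The supporting-task loss is a softmax cross-entropy computed *from the
10-unit dense layer*; that layer is linear, so its outputs are the
single-digit logits and the upper head reads them directly. (A rectifier
there would be fatal to the design: softmax cross-entropy constrains only
relative logits, their absolute level drifts negative during
supporting-task training, and a rectified 10-unit layer then hands the
head an all-zero vector for most two-digit scenes — no signal and no
gradient. The rectifiers belong to the convolutional layers and to the
intermediate 2-unit layer.) The parity loss is a softmax
cross-entropy at the final 2-unit layer. The magnitude head replaces the
2–2 stack with 20 independent logistic outputs trained with per-output
mean absolute error and no softmax; its evaluation metric is the mean
squared error of the predicted sum, where the predicted sum counts outputs
above 0.5. Optimisation is Adam at a constant rate of 1e-3 (5e-4 as the
slow variant), batch size 32, no regulariser anywhere, and no weight is
ever frozen: during main-task training the gradient flows through the
whole trunk, which is exactly what makes heavy pre-training fragile under
continual data.

Choices the architecture sketch leaves open were fixed once:

* *Pooling* is 2×2 average with stride 2, the smallest standard choice;
  odd trailing rows are dropped (84 → 42 → 21 → 10).
* *Padding* is "same", keeping spatial arithmetic simple.
* *Initialisation* is Glorot-uniform with zero biases, the common default
  for this kind of stack; it is a pure function of the seed.
* The 10-unit dense layer is linear (see above); only the final
  classification layer carries a softmax; the intermediate 2-unit layer is
  rectified.
* Adam uses the classic defaults (0.9/0.999, eps 1e-8) with per-tensor
  bias-correction counters, since the supporting-task loss does not touch
  the upper head's tensors.

A consequence of the tiny parity head worth knowing about: a 2-unit
rectified layer fed by non-negative activations can initialise *dead*
(both units negative for every input), in which case that replicate never
learns parity no matter the curriculum. This is inherent to the
architecture at this width — replicate averaging is the intended remedy,
and it is one reason the main task is only "barely learnable" by design.

The numerical core (im2col convolutions backed by BLAS, single-precision
trunk, double-precision Fisher accumulators) lives in `src/convnet.cpp`.
All randomness — weight draws, shuffling, Fisher label sampling — flows
through R's RNG, so every run is bit-reproducible given its seed.

## The synthetic glyph corpus

`make_glyph_corpus()` emulates the statistical structure of a
handwritten-digit pool without any download: ten digit-shaped stroke
templates built from arcs, loops and diagonals (so classes differ in
locally discriminative curvature and stroke orientation, the cue a
translation-invariant recogniser relies on), a fixed style per writer — rotation up to ±15°, shear, translation up
to ±2 px, stroke-width scaling, and a per-writer noise level — and
per-image Gaussian pixel noise (σ drawn per writer around 0.05, clipped to
[0,1]). Glyphs are dark ink on a white background; writers are assigned
round-robin within class so classes and writers stay balanced.

What this emulates well: balanced classes, source ("writer") variance,
within-writer exemplar noise, and linearly separable classes. What it does
not emulate: the topological diversity of real handwriting (open loops,
variable stroke counts), correlations between writer style and class, or
ambiguous exemplars. Passing tests on this corpus therefore demonstrate
the *mechanisms* — orthogonal versus informative error signals, curriculum
benefit, continual-learning drag — not performance levels on real
handwriting data. The IDX reader/writer (`load_idx()`, `write_idx()`) lets
real data be substituted; note that standard light-on-dark digit data
should be loaded with `invert = TRUE` to match the white-background
polarity of composed scenes.

Scene composition pastes glyphs at uniform integer offsets with a
pixel-wise minimum (dark ink wins), so glyph pixels survive exactly; for
two glyphs, axis-aligned 28×28 bounding boxes are kept disjoint by
rejection sampling. Coordinates are 0-based (row, col) with half-open
boxes. Two-digit *training* sets cycle a shuffled list of the 55
unordered digit pairs, so pair classes are balanced to within one cycle;
exemplars are drawn without replacement and exhaustion is an error, never
silent reuse.

Evaluation sets use a different sampling design, and deliberately so.
Balancing the 55 unordered pair classes gives the parity task a 30/55 ≈
0.545 even-sum prior, so on such a set a network that has learned nothing
and collapsed to the majority class reads ≈ 54.5% — an instrument whose
"chance" is not 50%. Held-out evaluation sets therefore draw the two
digits independently and uniformly (`pair_sampling = "digit_uniform"`),
which balances the parity classes at 1/2 in expectation and puts chance
at 50%, the scale on which chance-level performance is conventionally
reported. Digit–label orthogonality holds under both designs.

## Curricula

A `schedule()` fixes slice size, epochs per slice (3), batch size (32),
the number of pre-training slices `n_pretrain` and main-task slices
`n_main`. Regimes:

* **static** — the pre-training budget is pooled into one subset presented
  for three epochs in shuffled batches;
* **continual** — `n` disjoint slices presented sequentially, three epochs
  each (exemplar-incremental non-stationarity);
* **reversed** — the main task is trained first, then the supporting task;
  the main task is re-evaluated at the very end;
* **class_incremental** — pre-training slices are staged so each stage
  introduces two previously unseen digit classes (five stages), the
  canonical forgetting scenario.

The main task always uses disjoint consecutive slices, for comparability
across regimes. Held-out performance is evaluated after every slice.
Replicate k of a grid uses seed `base_seed + k * 10007`, so replicates are
deterministic and paired across cells.

## Switching metrics

Four families, computed from a single run's trace:

* **Performance thresholds** (`performance_threshold_probe`): the first
  pre-training slice at which held-out supporting-task accuracy crosses a
  threshold; thresholds never crossed are flagged, not errors.
* **Initial competence** (`initial_competence`): held-out main-task
  performance after its first slice.
* **Prediction gain** (`prediction_gain`): the change in held-out
  performance across one slice.
* **Fisher Information** (`fisher_information`): the diagonal empirical
  Fisher of the weights. For each example a label is sampled from the
  model's own predictive distribution (categorical at the softmax heads,
  20 independent Bernoullis at the magnitude head) and the squared
  gradient of its log-likelihood is accumulated per weight in double
  precision; the reported value is the per-weight mean of the per-example
  mean. Only weights that receive gradient under the chosen loss enter
  the average, so supporting-task FI covers the trunk and dense-10 layer,
  main-task FI the whole network. The FI probe sample is the full
  upcoming slice of the task in question. The estimate is invariant to
  sample order and batch partitioning once each example keeps its label
  draw, and `logistic_unit()` provides the one-weight analytic case
  (E[p(1-p)x²]) used to validate the estimator.

The **optimal switching window** is the set of pre-training amounts whose
mean final main-task performance reaches the top decile of the observed
means — implemented as mean ≥ the 90th percentile (linear interpolation,
R's type-7 quantile) — and the optimal moment is its smallest element.
"FI at the moment of switching" is the supporting-task FI recorded on the
last pre-training slice. Pairwise FI comparisons across pre-training
amounts use Welch t-tests with raw p-values; the FI/performance
association is a plain Pearson correlation with a two-sided p-value.

The report machinery (`switching_report`, `aggregate_records`,
`report_bundle`) is deliberately agnostic: it exposes disagreement between
the metrics and the window rather than assuming any signal exists, because
the central negative finding this package operationalises is that none of
the four families is required to localise the window.

## Representations

`extract_activations()` probes the 10-unit dense layer with composed
scenes of diagnostic classes (singles and pairs of 1, 3, 8 by default, 100
probes per class). `embed_2d()` is a compact exact t-SNE for such small
activation matrices — all-pairs Gaussian affinities calibrated to the
target perplexity by bisection, Student-t output kernel, momentum gradient
descent with early exaggeration — with defaults of 2 components, 300
iterations, perplexity 40, and no prior dimensionality reduction; it is
deterministic given (activations, parameters, seed).
`neuron_preference_heatmap()` orders the ten units by their preferred
digit (the single-digit class maximising mean activation, ties broken by
unit index).

## Desk scales, problem sizes, and numerical choices

Scenario fixtures (`make_scenario()`) pin every studied phenomenon to a
configuration that trains end to end on one CPU core:

* **small** (the test-suite scale): 5,000-glyph corpus over 25 writers,
  slices of 150 scenes, 6 main-task slices, 300-scene held-out evaluation,
  4 replicates.
* **standard** (the acceptance-script scale): 13,000-glyph corpus over 50
  writers, slices of 400, 8 main-task slices, 1,000-scene evaluation, 4
  replicates.

Each scenario's total budget stays under a 60,000-gradient-step ceiling.
The sizes were fixed once, from pilot calibration of the desk-scale
learning curves, before the phenomenon tests were written; they are part
of the study conditions, not tuning knobs.

Numerical details worth recording: the trunk runs in float32 (sums that
feed reported statistics accumulate in float64); evaluation and loss are
computed in 32-image sub-batches to bound the im2col workspace; the
package asks the allocator to retain large scratch blocks between batches
(`mallopt`) because page-fault churn otherwise dominates training time;
softmax is max-shifted; cross-entropy clamps probabilities at 1e-12;
magnitude gradients use the sign of the residual times the logistic slope.
Degenerate inputs fail loudly: empty test sets, exhausted exemplar pools,
budget-exceeding slicing, zero-variance correlation inputs and
inconsistent schedules in aggregation are all errors, and thresholds never
crossed are flagged rather than invented.

## How much budget the parity breakthrough needs

The desk-scale scenarios reproduce the *negative* phenomena — chance-level
parity without pre-training, chance under reversed order, forgetting under
class-incremental staging — but not the claims that require converged
main-task training: the curriculum benefit itself, and the insensitivity
of the converged magnitude error to pre-training. It is worth being
precise about why. The bottleneck is not the
representation: it is the XOR readout. A head-only experiment (below,
not run at build time) trains the 10→2→2 stack on *ideal* inputs — exact
one-hot superpositions of the two digits plus small noise — with the same
Adam(1e-3), batch-32 regime, and the head reliably needs on the order of
1,500–2,500 batches (50–80k presentations) before parity accuracy leaves
chance. That floor matches the full-scale protocol, which gives the main
task 24 × 1250 × 3 / 32 ≈ 2,800 batches, and it matches the observation
that merely doubling the epochs makes the task learnable even without
pre-training. A desk-scale main phase of 6–24 slices of 200–400 scenes
provides 100–450 batches — an order of magnitude below the floor — so no
amount or quality of pre-training can produce the benefit at this scale,
and the corresponding phenomenon test documents this as an expected
failure rather than passing vacuously. The magnitude comparison is in the
same position for a different reason: at desk scale neither the
zero-pre-training nor the full-pre-training arm converges — both sit near
the constant-predictor error floor (the variance of the digit sum) — so
the "difference within one run-to-run SD" statistic compares boundary
noise, not converged performance, and its test is likewise allowed to
fail rather than being loosened. Reproducing either positive claim
requires full-scale main-task budgets (minutes of GPU time or hours of
CPU time per run), which is exactly what the scenario fixtures are scaled
to avoid.

```{r head-floor, eval = FALSE}
# ideal-representation floor for the 2-unit XOR readout
d1 <- sample(0:9, 32, TRUE); d2 <- sample(0:9, 32, TRUE)
X <- 3 * (outer(d1, 0:9, "==") + outer(d2, 0:9, "==")) +
  matrix(rnorm(320, 0, 0.2), 32, 10)
y <- (d1 + d2) %% 2
# train the 10->2(relu)->2(softmax) head on such batches with Adam(1e-3):
# parity accuracy stays at chance for >~1.5e3 batches before breaking through
```

## Known limitations

* The glyph corpus is far cleaner than handwriting; absolute accuracies
  are not comparable to real-data results, only the qualitative contrasts.
* The 2-unit parity head can initialise dead (both rectified units
  negative for every input); replicate means absorb this, single runs may
  not.
* Translation invariance over the 84×84 canvas is the dominant
  sample-complexity cost of the supporting task at desk scale (stride-2
  average pooling is not shift-equivariant, so every glyph position and
  pooling phase must be experienced); small slices learn it slowly, which
  is faithful to the "barely learnable" design but means desk-scale
  accuracies sit well below full-scale ones.
* The desk scales demonstrate the negative phenomena only; the curriculum
  benefit itself needs full-scale main-task budgets (see the budget
  section above).
* True non-stationarity and catastrophic-forgetting modelling are out of
  scope; the class-incremental scenario demonstrates the failure, it does
  not remedy it.
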