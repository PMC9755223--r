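---
title: "Sleep replay consolidation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep replay consolidation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepreplay)
```

## The problem and the model

A network with one shared set of parameters that learns tasks one after
another tends to overwrite the earlier tasks: in a class-incremental
setting, after training on the last pair of classes the softmax argmax
lands almost exclusively on those classes. The premise of this package is
that an *offline* phase — no labels, no stored examples, only noise and a
local learning rule — can undo much of that damage, because information
about old tasks survives in the weight matrices even when classification
accuracy has collapsed. Two observations in the package's own test suite
make that premise concrete: sequentially trained toy networks keep a
positive cosine similarity to their old-task-only weights, and
noise-driven reactivation restores the old task's accuracy.

Wake training is deliberately plain: bias-free dense layers (`init_network`),
ReLU hidden units, softmax cross-entropy over a single global output head,
mini-batch SGD with momentum, inverted dropout on hidden layers only.
Bias-freeness matters twice. First, it makes the wake network positively
homogeneous (scaling the input scales every pre-activation), which is what
allows a *single multiplicative scale per layer* to translate wake-mode
activation magnitudes into sleep-mode spiking drive. Second, it means the
spiking view needs no per-neuron offset, only a per-layer threshold.

The sleep phase (`sleep_replay`) views the same weight matrices through
integrate-and-fire semantics. Per time step: a fresh binary input vector is
drawn (each pixel spikes with probability equal to its running mean
intensity over all training inputs seen so far); voltages accumulate the
scaled synaptic drive layer by layer; units whose voltage strictly exceeds
the layer threshold emit a spike and reset to zero; then every synapse onto
a spiking unit is potentiated by `inc` if its source also spiked and
depressed by `dec` if it was silent. Synapses onto silent units never
change — the test suite asserts this "conservation of silence" and the
exact decomposition of the total change into
`inc * (co-spike count) - dec * (post-only count)`.

## Why the rule works, in one paragraph

After new-task training the new task's output and hidden units sit on the
strongest pathways, so under unstructured noise they fire most. Whenever
they fire, inputs that did *not* contribute (pixels characteristic of the
old task but silent at that step) get depressed. Over many steps this makes
the connections from old-task-specific inputs to new-task units inhibitory,
which is precisely the cross-talk that caused the misclassification. The
toy binary-patch model makes this visible pixel by pixel
(`weight_category_histograms`); on multilayer networks the same process
shows up as decorrelation of class representations and a relative increase
in drive to old-task neurons.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `learning_rate` | SGD step size | 0.065 | per-task vector allowed |
| `momentum` | SGD momentum | 0.5 | 0 for the toy trainer |
| `epochs_per_task` | passes per task | 10 | |
| `batch_size` | mini-batch size | 100 | |
| `dropout_rate` | hidden dropout | 0.2 | never on input/output |
| `init_range` | uniform init half-width | 0.02 | |
| `duration` (Ts) | sleep steps | 10000 | 1000–2000 at fixture scale |
| `inc`, `dec` | Hebbian step sizes | 1e-3, 1e-4 | task-dependent; tune |
| `thresholds` | spike threshold per layer | 1 | recycled scalar allowed |
| `scale_multiplier` | extra factor on the scales | 1 | recycled |

The training defaults are the standard configuration for the
1200-1200-10 dense architecture on MNIST-class data. The sleep defaults
are conservative placeholders: the effective plasticity magnitudes depend
on the trained weight scale, and on the desk-scale fixture the useful
region is around `inc = dec = 2e-4` with `thresholds = 1` and
`scale_multiplier = 2`. Because these knobs are task-dependent, the
package ships `tune_sleep()`, a grid search scored **only on training-set
accuracy after a trial sleep** — test data never inform the choice. All
protocol runners accept `tune = TRUE` to re-search after each task.

### Layer scales

`ann_to_sleep_ann` derives the propagation scales from one wake pass over
the most recent task's training inputs: layer *l*'s factor is
λ(*l*) = max(max observed activation, max weight), with λ(0) the maximum
input value, and the applied scale is λ(*l*−1)/λ(*l*). Propagating the
reference batch with these scales bounds every layer's scaled activation
by the maximum input value (attained exactly when the max-weight guard is
disabled via `use_max_weight = FALSE`); binary sleep spikes then drive
each layer in a comparable working range, and `scale_multiplier` sets how
vigorous sleep activity is on top of that. Scaling is applied at
propagation time only; the stored weights are bit-identical before and
after conversion.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_images` mirrors the structure the sleep noise relies
on: each class has a binary prototype of 20 bright pixels on a 10×10
canvas, paired cross-task classes share 14 prototype pixels (the same
interference geometry as the toy patches), samples are Bernoulli draws
from the prototype with a 5% pixel-flip rate, 100 training and 50 test
samples per class. This yields class-conditional mean-intensity structure,
heavy cross-task overlap (so sequential training genuinely forgets: task 1
drops to 0% after task 2), and a well-defined global mean-intensity vector
to drive sleep. It does **not** emulate stroke-like pixel correlations,
within-class style variation, or class imbalance; passing tests here show
the mechanism works under controlled interference, not that the tuned
constants transfer to real image data. Real-data runs go through the IDX
reader and the command-line front end, with hyperparameters re-tuned.

## Numerical and design choices

- **Argmax ties** at evaluation break to the lowest class index; spike
  thresholds use a strict `>`; neuron-count ties in the task-specific
  ranking break to the lower neuron index, class ties to the lower class.
- **No leak, no refractory period** beyond reset-to-zero: voltages persist
  across steps until a spike. A consequence worth knowing: any unit with
  positive mean drive eventually spikes regardless of threshold, at a rate
  proportional to drive/threshold, so thresholds shape *rates*, not *who
  can fire*; selectivity comes from the drive ratios.
- **Toy trainer**: the patch network (no hidden layer) trains full-batch,
  no momentum, learning rate 0.1, stopping at a loss plateau of 1e-5 or
  500 epochs.
- **Seeded sleep is RNG-isolated**: a sleep episode with a seed restores
  the ambient RNG state afterwards, so adding, removing or nulling sleep
  phases never changes the surrounding training trajectory — with
  `inc = dec = 0` the interleaved protocol is bit-identical to sequential
  training.
- **Rehearsal batches** are drawn from the union of current data and the
  buffer; the two loss terms are averaged within each batch over the
  samples belonging to each pool, weighted 1/N and 1−1/N; a batch with no
  old samples simply contributes no old-task term.
- **Task order** is permutable; the pairing of classes into tasks is
  fixed.
- **Untuned sleep for untrained networks**: the single-task probe runs its
  zero-epoch arm at fixed sleep settings, because tuning maximises
  training accuracy and a tuned sleep phase can lift even a random
  network well above chance by amplifying whichever pathways happen to be
  class-selective — an interesting effect, but not the question the probe
  asks.

## Problem sizes

The test suite and the acceptance script run entirely at desk scale,
chosen so the full suite completes in minutes: the toy model (100 inputs,
4 outputs, 2000 sleep steps), the synthetic fixture with a
100-400-400-4 network, 10 epochs and 100-sample batches per task,
1000-step sleep episodes, 25-pass/100-neuron replay analysis, and 5-seed
repetitions for every statistical claim. The same code paths accept
full-size data (e.g. 784-1200-1200-10 with 10,000-step sleep) through the
IDX reader.

## Known limitations

- At extreme toy overlap (16 of 20 pixels) sleep cannot fully recover the
  old task: the four unique pixels per image are statistically
  indistinguishable to a noise-driven local rule, and depression
  self-limits once the new-task outputs' mean drive turns negative. Across
  the 12–16 overlap range sleep still strictly improves the mean over the
  no-sleep baseline, with complete recovery at 13–14.
- Sleep hyperparameters do not transfer across architectures or datasets;
  re-tune on training data.
- The sleep loop is stepwise-sequential by nature (each step's spikes
  depend on the previous step's weights), so its cost is linear in `Ts`;
  no mini-batched sleep is provided.
- No convolutional layers, no adaptive optimisers, no biological detail
  beyond the integrate-and-fire caricature (no oscillations, inhibitory
  populations, or sleep staging).
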