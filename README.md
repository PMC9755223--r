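# sleepreplay

Catastrophic forgetting is the tendency of a neural network trained
sequentially on several tasks to lose the earlier tasks as it learns the
latest one. In the brain, sleep is thought to counteract exactly this kind
of interference: neurons spontaneously replay recent and old memory traces
while local synaptic plasticity reorganises connectivity. `sleepreplay`
implements that idea for artificial networks — an offline, noise-driven
**sleep replay consolidation** (SRC) phase interleaved with ordinary
supervised training — together with the class-incremental training
protocols, rehearsal baseline, toy model and replay diagnostics needed to
study it. It is aimed at computational-neuroscience and continual-learning
researchers who want a small, fully inspectable testbed rather than a deep
learning framework.

## The algorithm

Wake training is ordinary mini-batch SGD with momentum on a bias-free
multilayer perceptron (ReLU hidden units, softmax cross-entropy over one
shared output head, inverted dropout). After each task, the network is put
to sleep:

1. **Conversion.** The ReLU activation is replaced by a Heaviside spike
   rule. Each layer *l* gets a propagation-time scale
   *s*(*l*) = λ(*l*−1)/λ(*l*), where λ(*l*) is the larger of the layer's
   maximum observed activation on the last training data and its maximum
   weight (λ(0) = the maximum input value), times a tunable multiplier.
   The stored weights are never rewritten.
2. **Noise drive.** At every time step each input pixel spikes
   independently with probability equal to its *mean intensity over all
   training inputs seen so far* — the only trace of past tasks the method
   keeps, and it does not grow with the number of tasks.
3. **Integrate and fire.** Per layer, membrane voltages accumulate
   *v* ← *v* + *s*(*l*−1)·W·S(*l*−1); units with *v* strictly above the
   layer threshold spike and reset to zero; sub-threshold voltages persist.
4. **Local Hebbian rule.** For every synapse whose post-synaptic unit
   spiked: +`inc` if the pre-synaptic unit also spiked, −`dec` if it was
   silent. Silent post-synaptic units leave their weights untouched.
5. **Back to wake.** After `Ts` steps the Heaviside rule is dropped and
   the (updated, unscaled) weights are used by the ReLU network again.

No stored examples are ever replayed: the weight matrices themselves decide
what reactivates. The package also implements the rehearsal baseline, in
which a stored fraction of old examples is mixed into training under the
task-weighted loss

L_total = (1/N_tasks)·L_current + (1 − 1/N_tasks)·L_old,

and diagnostics that make the mechanism visible: class–class correlation
matrices of hidden activations, top-k task-specific neuron identification
from spike counts, sleep firing-rate comparisons (t statistics with
Bonferroni correction), input-drive changes, per-pixel-category weight
histograms for the toy model, and weight cosine similarity.

## Worked example: the binary-patch toy model

Four 10×10 binary images form two tasks (images 0,1 then 2,3); paired
cross-task images share a controlled number of pixels. With 14 overlapping
pixels, training task 2 erases task 1 — and a tuned sleep phase restores
it:

```r
library(sleepreplay)

res <- run_patches_experiment(
  overlap = 14, seed = 1,
  sleep_cfg = sleep_config(duration = 2000),
  tune = TRUE,
  tune_args = list(thresholds = c(0.2, 0.5, 1), scale_multipliers = c(2, 4),
                   inc = c(0.002, 0.01), dec = c(0.02, 0.05)))
subset(res$table, task_id == "overall")
#>  phase task_id accuracy
#>     T1 overall      0.5
#>     T2 overall      0.5
#>    SRC overall      1.0
```

After task 1 only the two task-1 images are classified (50% of the four);
after task 2 the network classifies everything as task 2 (still 50% —
catastrophic forgetting); after sleep all four images are correct. The
mechanism is visible in the weights: `weight_category_histograms()` shows
the connections from task-1-unique pixels to task-2 output neurons turning
inhibitory during sleep, which removes the cross-talk that caused the
misclassification.

The same pipeline scales to the synthetic image fixture
(`synthetic_fixture()`, two tasks of two classes each): sequential training
ends at 50% overall, and `run_src_protocol(..., tune = TRUE)` with a sleep
phase after each task recovers ~100%, decorrelates the hidden-layer class
representations, and shows task-specific neurons firing above chance during
random-input sleep.

A command-line front end for all protocols lives in
`inst/scripts/src-run.R`; with `--data-dir` it accepts MNIST-layout IDX
files for full-scale runs.

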