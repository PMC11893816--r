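---
title: "Compact 3D CNNs and measurement-condition optimization for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact 3D CNNs and measurement-condition optimization for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieeg3d)
```

## The problem

Motor imagery (MI) — the mental rehearsal of a hand, foot or tongue
movement — produces decodable EEG signatures without any overt movement,
which makes it attractive for brain–machine interfaces that must run on
battery-powered edge hardware. On such hardware every electrode, every
second of recording, every Hz of sampling rate and every model parameter
costs energy. This package implements, in pure R, the toolkit needed to
study that trade-off end to end:

* a **compact 3D convolutional network** whose input is a scalp-grid
  tensor `(C1, C2, T)` rather than a flat channel × time matrix, so the
  electrode geometry is part of the representation;
* the canonical **EEGNet** as the reference compact baseline;
* exact **cost accounting** (trainable parameters, multiply–accumulates,
  a memory estimate) with an instrumented brute-force oracle;
* the **measurement-condition optimization protocol**: staged electrode
  elimination, sample-window and 1:n subsampling sweeps, an
  accuracy-maintenance predicate, and Pareto fronts of accuracy versus
  model size;
* **ERD/ERS topography** for physiological sanity checks; and
* a seeded **synthetic MI-EEG simulator**, so the whole pipeline is
  testable without downloading any benchmark recordings.

## The models

Both networks are built as explicit layer graphs (`model_graph`) with a
hand-written forward pass, exact backpropagation and Adam, so the same
object supports training, inference, parameter iteration and MACC
instrumentation. No external deep-learning runtime is used.

**Compact 3D CNN.** Block 1 is a single 3D convolution with `D * F1`
output maps and kernel `(C1, C2, K_l)`: the spatial extent of the kernel
covers the whole electrode grid (valid padding, so the spatial dimensions
collapse to 1 × 1), while the temporal extent `K_l` is length-preserving.
It carries a bias, followed by batch normalization, ELU, temporal
max-pooling by 8 and dropout. Block 2 is a separable convolution: a
depthwise temporal convolution of kernel length `C1 * C2 * K_s` (no
bias) followed by a pointwise convolution to `F2 = F1 * D` maps (with
bias), then batch-norm, ELU, max-pool by 8 and dropout. Block 3 flattens
`F2 * floor(T/64)` features into a dense softmax classifier.

Two conventions deserve comment because the published layer table is
ambiguous about them:

* **Pooling factors.** The printed pool *sizes* are (1, 1, 4) and
  (1, 1, 8), but the printed *output lengths* are `T//8` and `T//64`.
  The output lengths are authoritative here: only the (8, 8)
  interpretation reproduces the published parameter total of 1.524 k for
  the `K_s = 1, K_l = 4, F1 = 8` configuration on a 3 × 3 grid with
  `T = 500` (flatten width `16 * floor(500/64) = 112`). Both
  interpretations are implemented (`pool_factors = c(8, 8)` default,
  `c(4, 8)` alternative).
* **K_s semantics.** After block 1 the spatial dimensions are degenerate
  (1 × 1), so the nominal `(K_s, K_s, ...)` spatial kernel extent of the
  separable convolution cannot act spatially; the kernel-extension
  coefficient enters only through the depthwise temporal length
  `C1 * C2 * K_s`. This is again anchored by the 1.524 k total.
* **Bias convention.** Conv3D and the pointwise convolution carry
  biases, the depthwise does not, and every batch-norm contributes two
  learnable scalars per map. This is the unique convention that
  reproduces all five published totals (3.444 k, 2.146 k, 1.684 k,
  0.394 k for EEGNet; 1.524 k for the 3D CNN).

**EEGNet** is built in its canonical form: bias-free temporal
convolution (`F1` filters, kernel `(1, K_l)`, same padding), batch-norm,
bias-free depthwise spatial convolution over all channels (depth `D`),
batch-norm, ELU, average-pool 4, dropout, separable convolution
(depthwise `(1, K_l2)` + pointwise, both bias-free), batch-norm, ELU,
average-pool 8, dropout, dense softmax. Max-norm weight constraints of
some published implementations are omitted; they do not affect counts
and are irrelevant at the scales exercised here.

`count_parameters()` sums learnable scalars; `count_maccs()` counts one
multiply(+add) per kernel tap per output element for convolutions and
`in * out` for the dense layer, with biases, batch-norm, pooling,
activations and softmax free. That convention reproduces the three
published EEGNet MACC figures (11.75 M, 1.71 M, 1.09 M) and is checked
against `maccs_oracle()`, a deliberately naive nested-loop forward pass
that increments a counter at every multiply. The published memory
footprints state no convention and could not be reproduced from any
parameter/activation accounting we tried, so `estimate_memory()` reports
its own documented estimate (parameter bytes + peak input/output
activation pair at batch 1 + input bytes, float32) and is compared only
directionally, never numerically, with published values.

## The training and evaluation protocol

Training uses mini-batch Adam (default learning rate 1e-3, the
optimizer's common default; the protocol source names the optimizer but
no rate) on the cross-entropy loss, batch size 64, up to 3000 epochs
with early stopping after 300 epochs without improvement. Early
stopping monitors validation loss — the monitored quantity is not stated
in the protocol source; validation loss is the conventional choice — and
the best-validation snapshot is restored. One seed controls weight
initialization, shuffling and dropout, so a rerun with the same
configuration is bit-identical.

"5-fold cross validation" with a fixed external test set is interpreted
as five rotations of the stratified 80 %/20 % train/validation split,
each producing one accuracy on the fixed test set; a `cv_result` records
their min/mean/max/std. Cohen's kappa is computed per fold from the test
confusion matrix and averaged (whether the source averaged per fold or
pooled predictions is unstated; per-fold averaging is used and
documented). Model comparisons use the paired two-sided Wilcoxon
signed-rank test (exact distribution up to 25 untied pairs, normal
approximation with tie correction beyond).

## Measurement-condition optimization

The **accuracy-maintenance predicate** declares a reduced configuration
acceptable when the *maximum* of its five fold accuracies reaches the
*minimum* of the full-montage, full-window baseline's. It is
deliberately lenient (max against min) and monotone.

The **staged channel elimination** has two phases. While more than ten
channels remain, all `choose(n, n-2)` subsets of size `n - 2` are
cross-validated; channels are scored by how often they appear in the ten
worst subsets minus how often in the ten best, and the two
highest-scoring (least useful) channels are removed — ties first expand
the lists to fifteen, then fall back to keeping the best-accuracy
subset. (The procedure's published description contains arithmetic slips
— e.g. "3C2 = 6" —; the implementation follows the combinatorial
formulas and the trace records actual counts.) From ten channels down,
every leave-one-out subset is evaluated with a configurable number of
repetitions, the best is kept, and the search recurses until the
predicate fails for some subject; the returned trace records every
candidate table, removal and reason. How the top- and bottom-list
counts combine is not pinned down by the source; the difference score
described above is the package's choice and is configurable, as is the
evaluation backend (`eval_fn`), which allows protocol-level testing and
cheap screening classifiers.

Window and subsampling sweeps re-run the protocol over window lengths
(4.0 s down to 0.5 s) and decimation factors `n` = 1..5. Subsampling is
plain 1:n decimation without an anti-alias prefilter — the 0.5–60 Hz
band-pass limits aliasing for n ≤ 2, and for larger n the aliasing is
part of the condition under study. One printed table of effective rates
in the protocol source lists successive halvings (62.5 Hz for n = 3),
which contradicts the source's own 1:n definition and its own sample
counts elsewhere (e.g. `T = 187 = floor(750/4)` at n = 4); the package
follows the definition, so `fs_effective = 250/n`.

`pareto_front()` sorts configurations by parameter count and keeps the
accuracy records — points whose accuracy strictly exceeds every cheaper
point's — matching a brute-force dominance filter (tested on 1000 random
points).

## The simulator

`simulate_session()` generates continuous multichannel EEG at 250 Hz
with the trial paradigm fixation 2 s → cue 1.25 s → motor imagery 4 s →
break 2 s. Each channel is the sum of

* 1/f^α background noise (spectral shaping of white noise; α default 1,
  SD 1), plus a shared common source (SD 0.3) for spatial correlation
  and white sensor noise (SD 0.3);
* band-limited mu (8–12 Hz, amplitude 1) and beta (18–26 Hz, amplitude
  0.5) oscillations, independently per channel.

During each trial's ERD interval (by default the motor-imagery segment)
the oscillation amplitude is multiplied by a class- and channel-specific
attenuation factor, entered and left through a 250 ms raised-cosine ramp
to avoid spectral splatter. The default class→laterality mapping is
contralateral: left hand attenuates the right-hemisphere motor strip,
right hand the left, feet the midline, tongue both hemispheres with a
shallower depth. The default depth (0.6, i.e. −64 % band power) is a
mid-range physiological value; recovery tests use the stronger 0.4. The
simulated SNR defaults are chosen for test stability — no quantitative
SNR is available for the dry-electrode recordings that motivate the
tool — and the simulator makes no attempt at volume conduction,
artifacts (EOG/EMG), or non-stationarity across a session. Passing
tests on this data therefore demonstrate that the pipeline recovers
planted structure, not that any accuracy level transfers to real
recordings.

`make_benchmark_like()` produces benchmark-shaped splits (22 channels /
4 classes / 288 + 288 trials, or 3 channels / 2 classes / 400 + 320) from
independent derived seeds.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at reduced scale, chosen as the
smallest sizes at which the planted effects are recovered reliably:
4-class recovery trains the Table-7-sized 3D CNN (1.5 k parameters) on
160 simulated trials (8 channels, 4 s window, 1:2 subsampling, T = 500)
and requires > 60 % test accuracy against a 25 % chance level;
channel-selection recovery plants discriminative ERD only on C3/C4
within the published five-channel set and runs the leave-one-out phase
in screening mode (T = 125, 80 trials per session, 80-epoch budget) over
three seeds.
The million-trial, 3000-epoch full protocol is supported by the same
functions with their default `train_config()`.

## Numerical and degenerate-input choices

* Filters: 4th-order Butterworth band-pass (0.5–60 Hz) plus 2nd-order
  band-stop (48–52 Hz), applied forward–backward (zero phase; whether
  the reference preprocessing was causal is unstated). Band edges must
  stay below Nyquist or the configuration is rejected.
* Standardization uses the population (divide-by-N) variance of the
  training partition only, matching the StandardScaler convention; a
  zero-variance channel is an error naming the channel.
* Fractional subsampled lengths keep indices 0, n, 2n, … (so
  `ceiling(L/n)` samples).
* Sample indices are 0-based on disk and in events; time windows are
  half-open `[start, end)`.
* Batch-norm uses ε = 1e-5 and momentum 0.1; ELU saturates its
  exponential argument at 50 to avoid overflow; softmax subtracts the
  column maximum.
* A `T` too small for the pooling cascade (flatten width 0) is a
  configuration error naming `T`; degenerate kappa marginals and
  all-zero Wilcoxon differences are reported as undefined rather than
  silently dropped.

## Known limitations

* The EDF/GDF adapters cover the uniform-rate, int16/float subset of
  those formats that MI benchmarks use, with events from a GDF event
  table or an EDF trigger channel; they are validated against fixtures
  written by the test suite, not against third-party recordings.
* Published classification accuracies on the real benchmark data are out
  of reach without the recordings themselves; the adapters make the
  pipeline runnable on them, but no accuracy table is reproduced here.
* The published memory-footprint values and two printed cost figures for
  other configurations (4.132 k; one EEGNet 1.748 k variant) are not
  reproducible under any single convention that fits the other five
  totals, and are not asserted.
* Training is CPU-bound pure R; it is fast at the screening scales used
  in the tests and tolerable (minutes) at a few hundred trials, but not
  intended for full 3000-epoch benchmark training.
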