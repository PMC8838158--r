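---
title: "A 297-parameter beat classifier and its fixed-point datapath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 297-parameter beat classifier and its fixed-point datapath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-lead ambulatory ECG recordings sampled at 360 Hz carry enough
morphological information to distinguish common beat types: normal beats
(`N`), left and right bundle branch block beats (`L`, `R`), premature
ventricular contractions (`V`), atrial premature beats (`A`) and paced
beats (`/`). A classifier intended for an always-on wearable must be
small enough to run on a resource-shared hardware datapath, which rules
out generic CNN topologies and floating-point arithmetic. This package
implements one specific co-designed solution: a fixed 297-parameter
convolutional network and a bit-accurate behavioural simulator of the
integer datapath that executes it, so that software training and
hardware-style inference can be verified against each other.

## The network

One beat is a 48-sample window centred on the R peak (samples R−23 to
R+24), amplitude-normalised to $[-1, 1]$ and reshaped row-major into a
$2 \times 24$ tensor $x$. The input formation is a package convention:
only the $2 \times 9$ shape of the third-layer input is architecturally
fixed, and the $2 \times 24$ input is what that shape back-propagates to
through the pooling stages.

The forward pass is, with $*$ denoting valid (unpadded) row-wise
cross-correlation:

$$
\begin{aligned}
a^{(1)}_k &= \mathrm{ReLU}(x * w^{(1)}_k), && k = 1..3, \; 2\times 18\\
p^{(1)}_k &= \mathrm{maxpool}_{1\times 2}(a^{(1)}_k), && 2\times 9\\
a^{(2)} &= \mathrm{ReLU}\Big(\textstyle\sum_{k} v_k \, p^{(1)}_k\Big), && 2\times 9 \;\; (1\times 1 \text{ conv})\\
a^{(3)}_k &= \mathrm{ReLU}(a^{(2)} * w^{(3)}_k), && k = 1..3, \; 2\times 3\\
p^{(3)}_k &= \mathrm{maxpool}_{1\times 3}(a^{(3)}_k), && 2\times 1\\
f &= \mathrm{flatten}(p^{(3)}), && 6\\
h &= \mathrm{ReLU}(W_1^\top f), && 21\\
s &= W_2^\top h, && 6
\end{aligned}
$$

and the prediction is $\arg\max_j s_j$ with ties to the lowest index.
There are no bias terms anywhere; the parameter count is
$21 + 3 + 21 + 126 + 126 = 297$ (`count_parameters()`). The $1\times 1$
layer collapses the three channels to one before the second $1\times 7$
stage, which is what keeps the third convolution at 21 rather than 63
coefficients. The flatten order is channel-major, row-minor; it is a
convention shared by the float path, the trainer and the datapath and
immaterial beyond consistency.

Two consequences of the bias-free design matter repeatedly below:

* the network is **positively homogeneous**: scaling the input, or any
  single weight group, by $\alpha > 0$ scales all six scores by
  $\alpha$ and leaves the argmax unchanged;
* classes that differ only by a positive amplitude factor are therefore
  *indistinguishable* — the generator (and any user data) must separate
  classes by waveform direction, which real morphologies do.

## The datapath

The simulator (`run_inference()`) executes all eight layers with five
shared units and nothing else:

* **PE** — a seven-lane multiply–accumulate: exactly 7 multiplications
  and 6 additions per invocation, unused lanes zero-padded, full
  precision inside (saturating only at the accumulator width);
* **ReLU unit** — requantises a wide sum to the activation format and
  clamps negatives; in $1\times 1$ mode (S2 = 0) it first accumulates
  the three per-channel partial sums in its internal register;
* **MaxPooling unit** — one comparator tree, S3 selecting the
  $1\times 2$ or $1\times 3$ window;
* **Softmax unit** — accumulates the three PE results per output node
  into registers R0..R5 and returns the index of the maximum (no
  exponential exists at inference time);
* **Control buffer** — 54 registers of intermediate storage.

`schedule_layer()` returns the multiplexer select signals (S1..S6)
active during each layer; the simulator consults it rather than
hard-coding paths. Per beat the PE invocation counts are fixed:
108 / 0 / 54 / 18 / 0 / 0 / 21 / 18 across the eight layers (total 219,
hence 1533 multiplications), and buffer occupancy peaks at exactly 54
— the three pooled $2\times 9$ maps after layer 2. Occupancy counts
values that must persist *between* unit invocations; values inside
unit-internal pipeline registers are not buffer residents. Exceeding 54
raises a simulation fault, since it means the schedule is wrong. Clock
cycles are deliberately not modelled: published latency figures depend
on an unpublished cycle-level schedule, so only invocation counts are
checkable.

### Fixed-point arithmetic

Values are signed two's-complement Q-format integers
(`fixed_point_format()`), by default 16-bit words with 12 fractional
bits (range $\pm 8$, resolution $2^{-12}$), with a 32-bit accumulator
that is never rounded mid-accumulation. Rounding is
round-to-nearest-ties-to-even; overflow saturates. Products of two
Q12 values are Q24; a single requantisation (arithmetic shift with
round-to-even, then saturation) happens at each ReLU-unit output, and
the final node values stay wide. Integers are carried in doubles; the
PE verifies at run time that every product and sum stays below
$2^{52}$, so "bit-accurate" is exact, not approximate. Accumulator
widths up to 52 bits are allowed for fine-format experiments
(fractional precision ≥ 24 bits arithmetically requires more than 32
accumulator bits).

`score_error_bound()` propagates worst-case rounding through the layers
by interval arithmetic (weight error $q/2$ per tap, one requantisation
$q/2$ per stage, ReLU and max non-expansive) and reports whether
saturation can be excluded; whenever the float score margin exceeds
twice this bound, the datapath's predicted class provably equals the
float network's, and the test suite asserts exactly that on random
instances.

### Calibration before quantization

A float-trained network routinely produces activations far beyond the
$\pm 8$ activation rail — cross-entropy keeps growing the logits after
the classes separate — and feeding such weights to the datapath
saturates it into uselessness. `calibrate_weights()` exploits the
multilinearity noted above: it measures per-stage activation maxima on
the training split and rescales each weight group by an
$\alpha_g \le 1$ so every requantised stage stays below half of the
saturation level (a 2× headroom margin covering beats more extreme than
the calibration data). The six scores shrink by $\prod_g \alpha_g > 0$;
the argmax, the only quantity inference reports, is untouched. With
calibration, the default Q4.12 datapath agrees with the float reference
on 100% of a 3,000-beat held-out split in this package's tests; without
it, agreement collapses below 50%. An analytic fallback (kernel
$L_1$ norms) is used when no calibration data is supplied; it is far
more conservative.

## Training

The trainer (`train()`) is deliberately plain: mini-batch SGD with
classical momentum 0.9 on the softmax cross-entropy loss, learning rate
0.01, batch size 64, 100 epochs, mandatory seed (default 1234), and
backpropagation written against the same five layer primitives the
forward pass uses. Gradients are verified against central finite
differences to $10^{-5}$ relative error in the test suite. Training is
bit-reproducible for a fixed seed, and a non-finite loss aborts with a
diagnostic rather than looping on.

Initialisation is Glorot-uniform per group, with one deliberate
exception: the three $1\times 1$ weights are folded to their absolute
value. They multiply non-negative (post-ReLU) maps into the network's
single-channel bottleneck; a draw with an unfavourable sign pattern
makes that channel non-positive everywhere, which zeroes every
activation and every gradient in the network — an unrecoverable dead
start that plain Glorot produces with substantial probability (and did
produce with the default seed during development). Folding the signs
changes nothing about the scale of the initialisation and removes the
failure mode.

No data augmentation, early stopping, weight decay or hyperparameter
search is performed; the published system's actual training procedure
is unknown, so this module is honest plumbing with documented choices
rather than a reproduction.

## The synthetic generator

`generate_dataset()` renders labelled beats as sums of Gaussian bumps
(an ECGSYN-style simplification): each class is a table of components
$(a_i, \mu_i, \sigma_i)$ evaluated at
$s(t) = \sum_i a_i e^{-(t-\mu_i)^2 / 2\sigma_i^2}$ over the 48 window
samples, with per-beat multiplicative jitter on amplitudes (5%) and
widths (5%), additive centre jitter (1.5 ms sd), and white Gaussian
noise (sd 0.02 of the unit R amplitude). Defaults produce the standard
benchmark split: 2,000 train + 500 test beats per class, 15,000 total.

The class morphologies are **caricatures**, not clinical simulations.
Two distortions are worth naming. First, the 48-sample window spans
only about −64 to +67 ms around the R peak, an order of magnitude
shorter than a full cardiac cycle, so the P and T components are
compressed towards the QRS complex rather than placed at physiologic
latencies. Second, class hallmarks (bundle-branch-block notching, PVC
widening, the pacing spike) are exaggerated so that classes are
cleanly separable — a nearest-class-mean baseline already scores far
above chance, which the test suite checks, because a generator whose
classes a trivial baseline cannot separate would make every downstream
green test vacuous in the opposite direction. Consequently, the
high held-out accuracies reached on synthetic data establish that the
*pipeline* (generator → trainer → calibration → quantized datapath)
works end to end; they say nothing about accuracy on real ambulatory
recordings, which depends on beat selection, inter-patient protocol
and label quality that this package does not model. Rhythm-level
structure (RR intervals, heart-rate variability), multi-lead realism
and motion artifacts are out of scope.

## Numerical and degenerate-input choices

* Argmax and max-pooling ties resolve to the lowest index / leftmost
  element, matching deterministic hardware behaviour; gradient routing
  at pooling ties follows the same leftmost mask.
* Pooling windows are left-aligned and trailing remainder columns are
  dropped ($\lfloor C / w \rfloor$ outputs).
* ReLU subgradient at 0 is 0.
* An all-zero input window normalises to all zeros (no division by a
  zero maximum) and yields all-zero scores, predicting class `N` by the
  tie-break.
* Quantization rounds ties to even; requantisation of wide sums uses
  the same rule on the shifted integer, so the two paths agree exactly.
* The finite-difference gradient check uses a symmetric step of
  $10^{-5}$; ReLU/pool kinks make the loss only piecewise smooth, so
  the check samples random weights where the probability of straddling
  a kink is negligible.

## Using the package

```{r pipeline}
library(ecgcnn)

ds  <- generate_dataset(2000, 500, generator_config(seed = 1))
fit <- train(ds, train_config(seed = 1234))
fmt <- fixed_point_format(16, 12)
cal <- calibrate_weights(fit$weights, fmt, ds)
qw  <- quantize_weights(cal$weights, fmt)

evaluate_model(ds, qw = qw, split = "test")          # datapath route
compare_against_reference(ds, cal$weights, fmt)      # vs float reference
```

The same pipeline is scriptable through the CLI (`ecg_cli()`, or the
`inst/cli/ecgcnn` wrapper): `generate`, `train`, `quantize`, `infer`,
`evaluate`, `compare`, each with `--seed` and `--out`.

## Known limitations

* The architecture is fixed; there is deliberately no support for other
  topologies.
* Only invocation counts are simulated, not cycles or power.
* The WFDB reader covers signal formats 212 and 16 and standard MIT
  annotations — enough for MIT-BIH style records — and nothing else.
* Published accuracy figures for the original chip cannot be reproduced
  here: they rest on external clinical data, an unstated training
  procedure, and printed tables that are mutually inconsistent at the
  fraction-of-a-percent level. The package's evaluation code computes
  metrics from counts and leaves adjudication to the reader.
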