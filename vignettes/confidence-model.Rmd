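---
title: "A hierarchical neuro-fuzzy model for base-call confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical neuro-fuzzy model for base-call confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfiscall)
```

## The problem

A base caller converts a four-channel sequencing trace into a string of
nucleotides, and downstream analysis needs to know *how much to trust each
call*. Classic quality estimators (Phred-style lookup tables) map trace
features to a quality value; the model implemented here does the same job
with a cascade of small fuzzy inference systems whose parameters are
learned from data (ANFIS). Each called base is described by six normalized
features in $[0,1]$:

* `NP_called`, `NP_2nd` — peakness (shape quality) of the called peak and
  of the strongest competing peak;
* `NH_called`, `NH_2nd` — normalized heights of the same two peaks;
* `dNS_next`, `dNS_prev` — normalized spacing to the next and previous
  called peak. In a clean read the peaks are evenly spaced, so both values
  sit near a nominal spacing.

A trustworthy call has a well-formed, tall called peak, a weak runner-up,
and near-nominal spacing. A miscall-prone position looks the opposite — in
the bundled worked example (`demo_records()`), the third base (a C) has a
runner-up peak whose peakness *exceeds* the called peak's (0.838 vs 0.794),
and it duly receives the lowest confidence.

## Architecture

Three two-input, one-output subsystems score the three feature groups:

$$NC_P = f(NP_{called}, NP_{2nd}), \quad
  NC_H = f(NH_{called}, NH_{2nd}), \quad
  NC_{\Delta S} = f(\Delta NS_{next}, \Delta NS_{prev}),$$

and a three-input main system combines them into the confidence value
$NC_o \in [0,1]$. All four are **zero-order Sugeno systems on a full grid
partition**: every input carries 5 membership functions (MFs), every
combination of MF indices is a rule ($5^2 = 25$ rules in the subsystems,
$5^3 = 125$ in the main system), and each rule has a constant consequent
$c_i$. Inference is the firing-strength-weighted average

$$\hat y(x) = \frac{\sum_i w_i(x)\, c_i}{\sum_i w_i(x)}, \qquad
  w_i(x) = \prod_v \mu_{i,v}(x_v),$$

with the product t-norm by default (`min` is available but not trainable by
gradient). The output is therefore always inside the consequent range; with
consequents kept in $[0,1]$ every pipeline output is a valid confidence.

The MF families are fixed per system: **triangular** for peakness,
**two-sided Gaussian** (`gauss2`: two Gaussian flanks around a flat top)
for height and for the main system, **trapezoidal** for spacing.

### Initialization

Grid partitions start from centers uniformly spaced on $[0,1]$ (spacing
$h$): triangular feet at the neighboring centers; trapezoidal shoulders at
center $\pm h/4$ and feet at neighboring centers; `gauss2` plateaus of
half-width $h/8$ with $\sigma = h/2.5$. These are the standard choices that
guarantee full domain coverage (every point activates at least one MF).
Rule consequents start at a constant — 0.5 from `grid_partition()`, or the
midpoint of the observed target range when `fit_pipeline()` builds a system
for a concrete training file. The split keeps `anfis_train()` a pure
optimizer: the self-consistency property (training a system on its own
outputs changes nothing) would be destroyed if the trainer re-initialized
consequents behind the caller's back.

## Training

`anfis_train()` minimizes the mean squared error over a training set by
full-batch gradient descent through the weighted-average defuzzifier
(classic ANFIS backpropagation), treating all MF parameters and all
consequents as free. One epoch takes one step of length $\eta$ along the
normalized gradient. The step size adapts: a trial step that would
*increase* the training RMSE is rejected and shrinks $\eta$ by 10%
(backtracking, up to 40 trials per epoch), while four consecutive
first-try successes grow $\eta$ by 10%. The recorded RMSE trace is
therefore non-increasing. Defaults: $\eta_0 = 0.02$, 500 epochs, no early
stopping.

`method = "hybrid"` replaces the consequent part of the step with an exact
linear least-squares solve each epoch (the consequents enter the output
linearly once firing strengths are fixed), followed by one gradient step on
the premises; a ridge of $10^{-8}$ keeps the solve well-posed when some
rules never fire in the training data. Hybrid converges in a handful of
epochs and is never worse than pure backprop at equal epochs; backprop
remains the default because it is the stated training regime of the method
this package implements.

### Numerical choices that matter

* **Feasibility projection.** After every update each MF's parameters are
  projected back to their ordering constraints: sort-and-clamp for
  triangular/trapezoidal (with a minimal support width of $10^{-6}$), a
  $\sigma \ge 10^{-3}$ floor for `gauss2`. The `gauss2` plateau constraint
  $c_1 \le c_2$ is enforced by collapsing both to their midpoint when a
  step crosses them. An earlier variant that *swapped* the two flanks
  instead turned out to be a trap: swapping exchanges the two (generally
  different) $\sigma$s, a discontinuous jump in the membership function, so
  every trial step near the constraint was rejected and the adaptive rate
  collapsed to numerical zero, visibly freezing the 125-rule main system at
  a plateau. The midpoint collapse is the Euclidean projection and is
  continuous.
* **Projected gradient at the consequent bounds.** When consequents are
  bounded (as in `fit_pipeline()`, which clamps them to $[0,1]$), gradient
  components of consequents pinned at a bound and pointing outside the box
  are masked before the step direction is normalized. Without this, blocked
  components dominate the direction and the realized move goes to zero.
* **Degenerate firing.** A total firing strength of exactly zero cannot
  occur on a fresh grid partition (full coverage) but can after training
  shrinks supports; inference then adds an $\varepsilon = 10^{-12}$
  denominator for the affected sample and warns.
* **Out-of-range inputs** are clipped to the variable domain with a
  warning rather than rejected: trace features occasionally leave $[0,1]$
  by rounding in upstream extraction, and refusing to score a whole read
  over one such value would be unhelpful.

Training enforces each MF's *internal* parameter ordering every epoch; the
construction-time guarantee that MF centers increase along a variable's
list is not re-asserted during training (two MFs could in principle trade
places without violating any per-MF constraint; in practice the premises
move little).

## The synthetic world

The original model was trained on four files of 500 labeled samples each
(350 training / 150 testing) that were never published. The generator in
this package is an explicit stand-in, not a reconstruction:

* Records are a mixture of **clean** (70%) and **problem** (30%) bases.
  Clean bases pile up just under $NP_{called} = NH_{called} = 1$
  (Beta-shaped, one-sided), with runner-up features near 0.4/0.5; problem
  bases center near 0.8 on *both* called and runner-up peakness, so the
  runner-up can win, as in the worked example's weak C. All spreads scale
  with `noise_sd` (default 0.03), so the noise-free limit collapses onto
  the exemplars.
* Spacing is one chain of inter-peak gaps along the simulated read —
  `dNS_prev` of record $i$ **equals** `dNS_next` of record $i-1$ exactly,
  as it must for measurements between adjacent peaks. Gaps are Normal
  around the nominal spacing 0.3 (sd $0.02$ for clean, $0.08$ for problem
  bases, scaled by `noise_sd`/0.03).
* Supervision comes from fixed smooth **monotone reference functions**
  (documented in `reference_functions()`): scores increase in called-peak
  quality, decrease in runner-up strength, the spacing score is symmetric
  and maximal at nominal spacing, and the confidence combiner
  $f_C = \sqrt{p\,h}\,(0.7 + 0.3\,s)$ increases in every feature. These
  forms are *chosen*, bounded and monotone; they are **not** claimed to
  match the unpublished targets of the original system.

Consequently a green test establishes that the implementation can learn a
monotone feature-to-confidence mapping of this shape to held-out RMSE
$\le 0.05$ at the stated sample sizes — it does not certify agreement with
the original system's numeric outputs, which is why the worked example is
checked by *ordering* (the weak C is the minimum of the six; it scores
below the dominating T) rather than by value. Real trace data differ in
ways the generator does not emulate: feature correlations induced by local
sequence context, dye-mobility artifacts, heteroscedastic noise along the
read, and miscalled-base label noise.

## Limitations

* Zero-order (constant-consequent) Sugeno systems only; no first-order
  consequents, Mamdani inference, or rule pruning.
* The gradient path requires the product t-norm; `min` systems can be
  evaluated but not trained.
* Monotonicity of trained models holds on the data-supported region, not
  in empty corners of the unit hypercube (fuzzy interpolation makes no
  promise where no rule was ever updated).
* The package starts from extracted trace features; peak detection and
  feature extraction from raw chromatograms are out of scope.

## A short session

```{r demo, eval = FALSE}
files <- make_training_files(generator_config(seed = 1))
model <- fit_pipeline(files, training_config(epochs = 500, seed = 1))
call_sequence(model, demo_records())
run_demo(model = model)   # side-by-side with the reference values
```
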