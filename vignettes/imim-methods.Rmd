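---
title: "Interactive mutual information modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactive mutual information modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(imimr)
```

This vignette is the package's own account of the method it implements:
the model, the estimators behind it, the numerical choices, and what the
synthetic study can and cannot show.

## The weighting model

Feature selection by mutual information classically scores a candidate
subset by a truncated expansion of the multivariate dependency between
the feature vector and the label: a sum of per-feature dependencies
`I(x_i; y)` minus a sum of pairwise interaction-information terms
`I(x_i; x_j; y)`. Relaxing the subset indicator to a continuous weight
`w_i ∈ [0, 1]` turns selection into weighting:

$$\max_{w \in [0,1]^n} \; \lambda\, w^\top D \;-\; w^\top (R + \gamma I)\, w,$$

where `D_i = I(x_i; y)`, `R_ij = I(x_i; x_j; y)` for `i ≠ j` with a zero
diagonal, and `λ` balances dependency against redundancy. `R` is
generally indefinite — interaction information is negative for
synergistic pairs (an XOR pair scores −1 bit) — so the quadratic term
is shifted by `γ = |min eig(R)|`, computed by a symmetric eigensolver
(`γ = 0` if `R` happens to be positive semidefinite, which for a
nonzero `R` with zero trace cannot occur). The shifted program is
concave, so the box-constrained maximum is global. Interaction terms
are never clipped; `γ` alone absorbs the indefiniteness.

The attained optimum `β` doubles as the quality score of a feature set:
decision-level fusion weights each modality's classifier by its `β_q`.
One wrinkle deserves a note: the weighting objective places `λ` on the
linear term, and `β` is defined as that objective's optimal value. A
variant that instead places `λ` on the quadratic term appears in some
write-ups of classifier weighting; the two agree up to a monotone
reparametrization of `λ`, and this package consistently uses the
optimal value of the program above.

Similarly, assembling the pairwise penalty into matrix form is done so
that the quadratic form reproduces the motivated objective: `R` stores
`+I(x_i; x_j; y)` symmetrically (so `w^\top R w` equals twice the sum
over unordered pairs — a constant factor absorbable into `λ`). A sign
convention that stores the negated interaction terms would silently
flip the penalty into a reward and is deliberately not used.

## Estimating the information terms

The estimators are plug-in (maximum-likelihood) on discretized
features. Continuous features are binned — by default into five
equal-frequency bins, which keeps every contingency cell populated for
the strongly right-skewed band-power and HRV features; equal-width
binning is available. Rank ties in equal-frequency binning are broken
by first occurrence (a stable order), so results are
machine-independent; the cost is that heavily tied (e.g. binary-valued)
features can be split across bins, for which equal-width binning is the
appropriate setting. The class label is categorical by construction and
is never binned. All quantities default to bits (base-2 logarithms);
changing the base rescales every output by exactly `log2(e)`.

The raw estimators (`entropy()`, `mutual_information()`,
`interaction_information()`) default to the uncorrected plug-in form,
which is what closed-form oracle checks apply to. The *model layer*
(`build_mi_model()` and everything above it) defaults to the
Miller–Madow small-sample correction, and the reason is structural
rather than cosmetic. The plug-in bias of a mutual-information estimate
between variables with `K_a` and `K_b` occupied cells is approximately
`(K_a−1)(K_b−1)/(2N ln 2)` bits. For an interaction term — a difference
of three such estimates, one of which involves the `K_i × K_j`
pair-encoded variable — the biases combine to approximately
`−(K_y−1)(K_i−1)(K_j−1)/(2N ln 2)`: *systematically negative*. On a
table of thousands of samples and dozens of features this reads as
spurious synergy between perfectly unrelated features, inflates `γ`
through the spectrum of `R`, and — because negative off-diagonals make
joint activation *reduce* the penalty — rewards saturating the weights
of pure-noise features. With the correction (which cancels the
first-order bias exactly, being the same combination of per-entropy
`(m−1)/(2N)` terms) noise features receive near-zero dependency and
near-zero weight, and weight recovery behaves as the model intends.
Corrected dependencies can dip slightly below zero by chance; they are
floored at zero so `D` stays a dependency vector. Kernel-density and
k-nearest-neighbour estimators for continuous mutual information are
out of scope; the estimator is pluggable through `mi_config()`.

## Solving the program

The box QP is handed to a dual active-set solver (`quadprog`), with the
Hessian made strictly negative definite by a `1e-8` ridge. The ridge
serves as the tie-break: when the optimal face is flat (semidefinite
Hessian — e.g. two exact duplicates of one feature, where any split of
their common weight is optimal), the strictly concave perturbed program
returns the minimal-Euclidean-norm optimizer, so outputs are
deterministic (duplicates split evenly: the two-feature fully redundant
case returns `w = (0.5, 0.5)` with objective 0.5). The reported
objective is evaluated *without* the ridge. An accelerated projected
gradient solver is implemented as an independent route; the test suite
requires the two to agree on the objective to `1e-5`, and every
returned solution must satisfy the box KKT conditions to `1e-6` (a
solution failing stationarity raises an error rather than being
returned). For n ≤ 5 the solver is additionally checked against
exhaustive 0.05-grid search.

`λ` has no stable universal value — each feature set carries its own
redundancy mass — so it is re-selected per model: `select_lambda()`
runs the full pipeline per candidate under an inner leave-one-subject-out
loop and picks the accuracy maximizer, breaking ties toward the smaller
(sparser) value. The default grid is 30 logarithmic points on
`[1e-4, 1]`, covering the range where selected optima typically land
(order `1e-3` to `1e-1`); a coarse 10-point grid is used inside nested
cross-validation for desk-scale runtime. Cross-validation can instead
be run at a fixed `λ`; reports record which mode produced them, since
the two are not interchangeable claims. The dominance comparisons in
the test suite use fixed `λ = 1` — the dependency-dominant top of the
default grid — because k-NN scores are invariant to the uniform scale
of the weight vector, so only relative weights matter there, and the
fixed mode keeps the suite fast.

Active features are those with `w_i` above `1e-6` (a solver-zero
threshold). Diagnostics that ask whether noise features received
*negligible* weight use `0.01` instead: with the bias-corrected
estimator, noise weights land around `1e-3`–`1e-2` — above solver zero,
but an order of magnitude below informative weights and immaterial
after scaling.

## Fusion and evaluation

Min–max normalization is fitted on training rows only, and test values
are clipped into `[0, 1]`; features constant in training map to zero.
Fitting the normalizer on all data would leak test-subject statistics
and quietly inflate subject-independent accuracy, so the leakage-free
choice is mandatory for the cross-validation claims to mean anything.
The same applies to every other trained component: one fold per
subject, and mutual information, `λ`, weights and classifiers never see
the held-out subject (the suite asserts bit-identical refits).

IMIM-F prunes zero-weight features and scales the rest; IMIM-C scales
each modality's features by its `w(q)` but does not prune — at the
decision level the weight vector's job is to rebalance a modality
internally, and the per-modality `β_q` already handles wholesale
down-weighting. The `β_q` are clipped at zero and normalized to sum to
one before score averaging, since averaging needs scale-free
coefficients and the raw optima carry the (arbitrary) information
units.

Classifier adapters expose a common score contract: per-class scores in
`[0, 1]` summing to one. k-NN scores are neighbour-vote fractions
(k = 3 by default). The linear SVM is one binary machine per class
(one-vs-rest, soft margin `C = 1e-3` by default) whose decision values
pass through a softmax; the underlying library orients each binary
decision value by the order in which labels appear in the training
data, so each machine's sign is fixed empirically on its own training
set. Argmax ties break toward the lowest class index, so predictions
are deterministic. IMIM-F presumes a weight-sensitive classifier;
scale-invariant learners such as decision trees gain nothing from
feature scaling and are out of scope.

## Signal feature extraction

**Sampling timeline.** 600 s of task signal per subject, cut into 90 s
windows advanced by 3 s — equivalently, 200 stimulus-locked 3 s epochs
in 30-epoch windows with a 1-epoch step — gives 171 samples per
subject-task and 5130 for 10 subjects × 3 levels. EEG and ECG windows
share this timeline so rows align across modalities.

**PSD block.** Per channel, mean spectral density over the five
traditional bands (δ 1–3, θ 5–7, α 9–12, β 14–31, γ 33–42 Hz), two
expanded bands (γ1 33–57, γ2 63–99 Hz), and 39 narrowband 1 Hz
intervals `[i, i+1]`, `i = 1…39` — 46 features per channel, 736 for 16
channels. The narrowband reading "1–40 Hz in 1 Hz steps" is taken as
the 39 unit intervals because only `7 + 39 = 46` matches the per-channel
count; band power is the *mean* density over the interval (not the
integral), which is monotone-equivalent for fixed bins and unit-stable
across sampling rates. Spectra come from Welch's method — 2 s Hamming
segments at 50% overlap by default, one-sided densities scaled so the
integrated spectrum matches the signal variance. Note that with 2 s
segments on 3 s epochs, segments straddle epoch boundaries; exact
invariance to epoch order requires segment length equal to the epoch
length with no overlap, which is how the invariance test configures it.

**ERP block.** Per channel, the epochs of a window are averaged, the
0–1000 ms stimulus-locked waveform is taken to 100 Hz — a zero-phase
antialiasing low-pass (8th-order Butterworth at 40 Hz, run forward and
backward so group delay cancels) followed by interpolation on the
exact 0, 10, …, 1000 ms grid — giving 101 points, plus peak value,
valley value, and their latencies: 105 per channel, 1680 for 16
channels. A naive polyphase resampler was rejected because its
uncompensated group delay shifted peak latencies by tens of
milliseconds. "The frequency of the peak and valley" is implemented as
peak/valley *latency* in ms — an averaged waveform has no per-point
frequency, and latency is the standard ERP reading of that phrase.
Band powers can optionally be log10-transformed before classification;
the default is off.

**Preprocessing.** A zero-phase 0.5–100 Hz Butterworth band-pass is the
only preprocessing. Independent-component artifact removal is out of
scope; the synthetic data are generated artifact-free, so nothing in
the pipeline depends on it.

**HRV block.** From each window's R-R intervals: time-domain (mean RR,
SDNN, RMSSD, pNN50 with its 50 ms threshold fixed in absolute
milliseconds, mean HR), frequency-domain (VLF 0.003–0.04, LF 0.04–0.15,
HF 0.15–0.4 Hz band powers, LF/HF, and normalized LFnu/HFnu), Poincaré
SD1/SD2 (and their ratio), and sample entropy (m = 2, r = 0.2·SDNN;
degenerate series return `NA`). Spectra use the Lomb–Scargle
periodogram directly on the irregular beat times — resampling an R-R
tachogram onto a uniform grid requires interpolation choices the data
do not dictate. The block is a documented 15-feature set; exhaustive
HRV-toolbox outputs (a hundred-plus features) are not reconstructed,
and nothing downstream assumes a particular block width. LF estimates
on windows shorter than two minutes are flagged when the function is
called standalone; the 90 s pipeline windows deliberately suppress that
warning, and LF/HF ratios from 90 s windows should be read as
short-term estimates.

## The synthetic study

The generators emulate the study *conditions*, not its recordings: 10
subjects, three workload levels, 200 epochs per task, 16 channels at
250 Hz (a desk-scale rate; 1000 Hz is supported), 600 s tasks. Effect
directions follow the qualitative physiology of working-memory load —
alpha suppression and theta increase with load, a P300-like positive
bump near 300 ms whose amplitude decreases with load, shorter and less
variable R-R intervals under load — with magnitudes as free
configuration parameters, since no signal-level statistics are
published to match. Subject-level mean offsets (0.3 × within-class SD)
make leave-one-subject-out generalization imperfect but learnable.

The abstract feature-table generator draws informative features
class-conditionally (class means spaced 0.8 within-class SDs apart,
alternating sign), adds two noisy duplicates per informative feature
(copy noise SD 0.3) and twelve pure-noise features, and spreads the
features across the three modality tags. Its default size is 171
samples per subject-task — the count the study timeline itself
produces — for 5130 rows total. Samples are drawn independently,
whereas real sliding-window samples overlap by 87 of 90 seconds and are
strongly autocorrelated; the generator also omits artifacts, volume
conduction, electrode drift and cross-modality coupling. Passing tests
on this data therefore demonstrates that the estimator, solver and
fusion machinery behave as designed under known ground truth — not that
any particular accuracy transfers to real recordings.

Everything is seeded: per-(subject, task) streams are derived
deterministically from the configuration seed, and identical
configurations produce bit-identical data.

## Problem sizes and runtime

The default test and acceptance workloads are sized for a single CPU:
the weighting and fusion checks run on the 5130 × 30 abstract table
(a model build is sub-second; the four-method ten-fold cross-validation
takes seconds), extractor checks use one- or two-channel signals with
a handful of epochs, and the full 16-channel montage is exercised on a
single 30-epoch window where the block widths (736/1680/2416) are
counted from actual columns. The grid-search solver oracle enumerates
up to 21⁵ ≈ 4.1 M grid points in vectorized chunks.

## Known limitations

- The truncated objective keeps only pairwise interactions; triple-wise
  and higher redundancy is invisible to the model by construction.
- Plug-in estimates on 5-bin discretizations are coarse for features
  with fine-grained dependence; the Miller–Madow correction removes the
  first-order bias but not estimator variance, which still sets the
  noise floor of `γ` and of small weights.
- `γ = |min eig(R)|` is the smallest uniform shift that certifies
  concavity, but it penalizes *all* features' self-weight equally; a
  large synergy outlier inflates everyone's shrinkage.
- IMIM-C's `β` normalization makes classifier weights scale-free but
  discards the absolute information mass of a modality.
- The EDF reader of a full acquisition stack is not included; signals
  enter as in-memory arrays, RDS bundles, or CSV feature tables.
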