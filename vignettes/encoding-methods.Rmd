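---
title: "Segment-wise random encoding of clinical time series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-wise random encoding of clinical time series: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enctsf)
```

This vignette is the package's own account of what it computes and why the
design is the way it is. It states no empirical numbers beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## 1. The encoding model

A multivariate time series is a matrix $X \in \mathbb{R}^{F \times T}$:
$F$ 1-d signals (vitals, labs) sampled at $T$ uniform steps. The framework
assumes the series is already pre-processed — uniformly sampled, imputed,
finite. Encoding a series means cutting every signal into segments
$\hat{x}_j$ of length $n$ and transforming each segment independently,

$$ e_j = f(\hat{x}_j), \qquad e = [e_1, e_2, \dots, e_{T/n}], $$

with the same shape out as in. Two properties follow by construction and
are enforced as tests: **shape conservation** (output is exactly
$F \times T$) and **feature locality** (row $i$ of the output depends only
on row $i$ of the input, so the semantic identity of each feature is
retained — nothing is mixed across vitals).

The transform $f$ is drawn once at key-generation time and then frozen.
The key — a JSON file holding either the projection matrix or the circuit
gate list at 17 significant digits (exact double round-trip) — is the
shareable agreement artifact: sites holding the same key encode
identically, and the privacy of the scheme rests on the key staying
secret. Keys never embed raw data; the one acknowledged exception is that
quantum keys may carry frozen per-feature min/max statistics (two summary
numbers per feature).

### Segmentation edge policy

The shipped defaults ($T = 48$ or $12$, $n = 4$) divide evenly. When they
do not, the default `strict` policy refuses with an error naming $T$ and
$n$; `pad_zero_trim` zero-pads to the next multiple, encodes, and trims
back. Padding is opt-in because silently extending a signal changes what
the final segment means.

### Random projection

$e_j = R\hat{x}_j$ with $R$ an $n \times n$ matrix of i.i.d.
$\mathcal{N}(0, 1/n)$ entries. With this variance,
$\mathbb{E}\,\|R\hat{x}\|^2 = \|\hat{x}\|^2$, the classic
norm-preservation property of Gaussian projections; the test suite checks
the pooled entry mean and variance and the norm ratio by Monte Carlo
within three standard errors. Column normalization (used by classic
dimension-reducing projections) is deliberately *not* applied: the
operative definition is the sampling law, the matrix is square, and no
dimensionality reduction is intended. The product is computed exactly in
double precision — no rounding, no normalization of outputs.

The linearity of this encoder is also its weakness: $n$ linearly
independent (segment, encoded) pairs determine $R$ by least squares. The
package implements this recovery *as a test*, to document the threat model
honestly: random projection obfuscates, but an adversary holding a few
known plaintext segments can invert it.

### Random quantum encoding

Each segment is encoded by an $n$-qubit statevector simulation in three
steps:

1. **Angle encoding.** Qubit $k$ starts in $|0\rangle$ and is rotated by
   $RY(\pi \hat{x}_k)$. Inputs are min–max scaled to $[0, 1]$ first, so the
   rotation angle stays in $[0, \pi]$ where $\cos$ is monotone — each
   qubit's marginal carries an unambiguous image of its input value.
2. **Keyed random circuit.** $L$ layers (default $L = 2$) of per-wire
   $RX(\phi)$ rotations with key-fixed angles $\phi \sim U[0, 2\pi)$,
   each layer followed by a CNOT ladder (control $i$, target $i+1$). The
   pictorial circuit this implements contains exactly these components —
   rotation gates and CNOTs on $n = 4$ wires; the specific layout and the
   angle distribution are key-file parameters, not hard-wired constants,
   because no finer specification exists to pin them. The uniform angle
   distribution covers the full rotation range; the ladder entangles every
   adjacent pair so all wires interact after one layer.
3. **Readout.** Each wire's encoded value is the exact Pauli-Z
   expectation $\langle Z_k\rangle = P(k{=}0) - P(k{=}1) \in [-1, 1]$,
   computed from the statevector. Expectations are exact by definition;
   simulating shot noise would only add variance, so shot-based readout is
   out of scope.

Because measurement keeps $2n$ real marginals out of $2^{n+1} - 2$ real
degrees of freedom, the map is many-to-one: the tests construct two
distinct two-qubit states (a Bell pair and an unentangled superposition)
with identical per-wire readouts. This is the structural argument for
irreversibility, in contrast to the projection encoder's closed-form
recovery.

**Conventions.** Wires are numbered $1..n$; wire 1 is the most significant
bit of the basis index. This is fixed and serialized so key files are
portable. Single-qubit gates are applied in $O(2^n)$ by index-pair
arithmetic, never by dense $2^n \times 2^n$ products; the dense
unitary-product construction exists only as the independent oracle in the
test suite, where the optimized path must agree with it within $10^{-10}$
(observed agreement is at machine precision). A batched path simulates all
segments of a cohort simultaneously (an $M \times 2^n$ complex state
matrix, processed in chunks of 65,536 segments); it is tested for
equality against the single-segment path.

Numerical tolerances: state norm must stay within $10^{-12}$ of 1 after
every gate; the empty-circuit closed form
$e_k = \cos(\pi \hat{x}_k)$ must hold to $10^{-12}$ on a grid.

## 2. The synthetic cohort generator

The generator exists so that every downstream component is testable
without credentialed clinical data. It emulates the *shape* of public ICU
benchmarks — default 44 features × 48 hourly steps, a binary outcome with
30% prevalence, 60/20/20 train/validation/test splits, a binary and a
3-class latent attribute — and plants signals whose recoverability is
known by construction:

* every feature has a fixed baseline sinusoid (amplitude
  $a_f \sim U(0.5, 1.5)$, frequency $U(1, 3)$ cycles, random phase),
  shared by all examples;
* the task label adds a linear drift
  $\tau\, y\, a_f\, (t-1)/(T-1)$ on a designated 25% of features — an
  abstraction of progressive physiological deterioration;
* each latent attribute multiplies the baseline amplitude of its own 25%
  subset (overlapping the task subset by half, so task-relevant features
  also carry attribute information — the overlap is what makes leakage
  through a task-trained embedding possible) by
  $1 + e_a \cdot c/(K-1)$ for class $c$;
* i.i.d. Gaussian noise everywhere.

Both planted effects are *linear* in the raw values, so a linear probe can
recover them and probe behavior is interpretable. Defaults
($\tau = e_a = 0.5$, noise sd $1.5$) were calibrated once so that raw-data
task AUROC sits near the top of the realistic band rather than at a
saturated 1.0, and attribute probes land in the 0.65–0.85 band — the
operating region where differences between conditions are measurable at
all. With the 3-class ordinal attribute, the middle class is by
construction not linearly separable one-vs-rest; tests assert the extreme
classes only.

What the generator does **not** emulate: missingness and irregular
sampling, correlated multi-label disorder structure, heavy-tailed lab
distributions, inter-feature physiological coupling. Passing tests
therefore show that the pipeline behaves as designed on temporally
structured, linearly decodable signals — not that the same effect sizes
would be observed on real ICU data.

## 3. The evaluation harness

The harness mirrors the leakage-evaluation protocol at desk scale: for
each condition (original data, projection-encoded, quantum-encoded) it
trains a target-task model, probes its penultimate embedding for each
latent attribute, and estimates mutual information between inputs and
embeddings.

**Target models.** All models train with binary cross-entropy, Adam at a
fixed learning rate of 0.001 and batch size 64, retaining the
parameters with the best validation loss. Full-scale clinical
architectures (LSTM-256, temporal convolutions, transformers) need
GPU-scale training and are not the point here — the protocol is. The
default is a one-hidden-layer MLP (64 ReLU units on the flattened
$F\cdot T$ input; the 64-d hidden activation is the penultimate
embedding); `linear` (logistic regression, embedding = standardized
input) and `recurrent` (32-unit Elman network over time, embedding = last
hidden state) are provided. Inputs are standardized per dimension on the
training split. Hidden weights use He initialization; the output layer
initializes at zero, since the sigmoid readout is convex given fixed
features and a zero start makes the learned direction data-driven from the
first step — with a fixed small learning rate this matters on small
fixtures, where a random-scale output init can dominate the few hundred
optimizer steps taken.

**Probes.** A single dense layer with sigmoid — no hidden layers, no
further feature transformation — trained on frozen training-split
embeddings (Adam, lr 0.001, batch 256, validation-best, default 100
epochs; probes are tiny, so epochs are cheap and the fixed learning rate
needs enough steps to converge). AUROC is reported on the held-out test
split, computed by the Mann–Whitney rank formula with midrank tie
correction (cross-checked against an exhaustive pair-counting oracle and
against pROC in the tests). Multiclass attributes are probed one-vs-rest
with one linear layer per class and reported as macro AUROC (unweighted
mean). Constant embeddings yield a degenerate-input warning and AUROC 0.5.

**Mutual information.** The Kraskov–Stögbauer–Grassberger estimator,
variant 1, with Chebyshev distance and $k = 3$, in nats. Inputs enter
either `averaged` (per-feature time mean, length $F$) or `vectorized`
(row-major flatten, length $F\cdot T$). Columns are standardized before
estimation so the max-norm treats coordinates comparably; exact duplicate
points (which make the $k$-NN radius zero) trigger a seeded jitter of
relative scale $10^{-10}$ and one retry. Calibration is asserted on
Gaussians with known MI: $|\widehat{MI}| \le 0.05$ for independent samples
at $n = 2000$ and within $\pm 0.1$ of $-\tfrac12\ln(1-\rho^2)$ at
$\rho = 0.9$, $n = 5000$.

Two choices here were genuinely open:

* *Which "input" enters the MI estimate for encoded-data models?* The
  package always uses the **original** (pre-encoding) series, for all
  conditions. This keeps the MI axis identical across conditions and makes
  the number directly interpretable as retained information about the raw
  patient data; by the data-processing inequality it also lower-bounds the
  MI between the encoded input and the embedding. MI is estimated on the
  test split.
* *How are relative drops aggregated?* Per seed as
  $100\,(v_{orig} - v_{enc})/v_{orig}$, then averaged (mean-of-drops),
  matching how per-run relative performance is usually reported. For the
  MI metric the acceptance script instead computes the drop from condition
  means, because per-seed KSG estimates on the vectorized reduction sit
  near zero, where a per-seed ratio is numerically meaningless.

**Directional expectations.** On the default cohort over five seeds the
test suite asserts the protocol's qualitative signature: task AUROC on
quantum-encoded data at least 0.15 above chance; mean attribute-probe
AUROC and mean input–embedding MI strictly lower for both encodings than
for original data; and a larger mean task-AUROC drop for projection than
for quantum encoding. The last check is a *mean ordering over seeds*: the
two drops can be close, and seed noise inverting the ordering under other
conditions would not indict the implementation — the suite pins the
comparison at the calibrated defaults where the ordering is stable.

## 4. Problem sizes and reproducibility

The shipped experiments use cohorts of 2000 examples of shape
44 × 48, five seeds, 20 training epochs for target models — sizes chosen
so a complete leakage experiment runs in minutes on one CPU while keeping
every split large enough for stable AUROCs ($\ge 400$ held-out
examples). Every stochastic step (key sampling, cohort generation, weight
initialization, batch order, MI jitter) derives from explicit integer
seeds; reruns with the same configuration are bit-identical, which the
test suite asserts end-to-end through the CLI (`simulate`, `encode`,
`evaluate` twice, comparing serialized bytes).

## 5. Known limitations

* The quantum encoder is a *simulation*; its privacy argument is the
  many-to-one measurement, not physical hardware.
* Min–max scaling statistics frozen into quantum keys leak two numbers
  per feature by design (documented; acceptable for ranges of vitals,
  but worth knowing).
* KSG estimates in high dimension ($F\cdot T$ flattened inputs against
  64-d embeddings at a few hundred test examples) are strongly biased
  toward zero; they are used comparatively across conditions, never as
  absolute information measures.
* The probe-based leakage measure is linear; a nonlinear attacker could
  extract more. This mirrors the evaluation protocol being reproduced,
  which fixes the probe to a single dense layer.
* Generator realism limits are listed in section 2; effect sizes on real
  ICU data will differ from the planted ones.
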