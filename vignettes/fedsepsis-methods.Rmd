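---
title: "Methods: early sepsis warning from sparse multi-modal EHR streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early sepsis warning from sparse multi-modal EHR streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sepsis is a life-threatening dysregulated host response to infection, and
every hour of delayed treatment measurably increases mortality. An
early-warning model watches a patient's electronic health record (EHR) as
it accumulates — vitals, laboratory values, clinical notes — and raises an
alarm before the clinical onset. `fedsepsis` implements such a pipeline at
desk scale, end to end: synthetic cohort generation with planted ground
truth, Sepsis-3 onset labeling, care-episode feature construction under
three missingness strategies, a multi-modal recurrent predictor, simulated
federated training, and evaluation by AUPRC, AUROC, and earliness.

Everything runs on one CPU in minutes, with no external data or
pre-trained weights. The package is a faithful, testable re-implementation
of the modeling pipeline; it does not attempt to reproduce results that
require credentialed ICU databases or GPU-scale training.

# Care episodes and the Sepsis-3 label

The unit of analysis is the *care episode*: up to 48 one-hour windows of
record ending at the episode endpoint — the earliest of first sepsis
onset, death, or discharge. Windows are half-open hours `[k, k+1)` from
admission. Patients must be strictly older than 15 years.

Sepsis-3 is operationalized as the co-occurrence of:

* **Suspected infection** — at least two antimicrobial doses (any drug, at
  distinct times) paired with a culture order. If the first dose precedes
  the culture, the culture must follow within 24 h; if the culture comes
  first, the first dose must follow within 72 h. Both bounds are
  inclusive, matching the "within" phrasing of the rule. The suspicion
  time is the earlier of first dose and culture.
* **Organ dysfunction** — a SOFA score at least 2 points above baseline,
  observed between 48 h before and 24 h after the suspicion time. The
  baseline is the latest score strictly before 72 h prior to suspicion,
  or zero when no such score exists. SOFA arrives as a precomputed score
  channel; recomputing it from raw organ measurements is out of scope.

Where several SOFA observations qualify inside the window we take the
earliest (first clinical evidence). Where several suspicion windows
qualify, the onset is the **latest** qualifying dysfunction time by
default; this follows the stated rule that onset is the latest window
where both criteria hold, and an `earliest` policy is available since
much of the early-warning literature uses the opposite convention. The
72 h baseline lookback is anchored at the suspicion time; the source rule
is ambiguous on this point and the anchoring is configurable only by
editing the labeler, not a user-facing switch.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical shape the pipeline assumes, with planted truth so the labeler
can be tested for exact recovery:

* episode-level sepsis prevalence 9.5% by default;
* episode lengths on a small grid of typical stay durations (default
  12/24/36/48 h, with sub-hour jitter that never crosses a window
  boundary). Lengths cluster at a few values both in real stay
  distributions and, pragmatically, so the (label, length) strata of the
  80/10/10 split stay populated at desk-scale cohort sizes;
* per-channel missingness up to and including 100%, realized by
  independent per-cell thinning, so the realized rate concentrates on the
  configured rate (tested to ±3 points at n ≥ 500);
* antimicrobial/culture/SOFA streams that satisfy the Sepsis-3 rules at
  exactly the planted onset for septic patients, and provably violate at
  least one rule (single dose, culture out of bounds, or SOFA never
  rising 2 points) for the rest;
* note events synthesized as token bags from a shared base vocabulary
  mixed with class-specific vocabularies.

Septic physiology is a mean shift in channel standard deviations: a mild
persistent elevation (30% of the configured effect) from admission on —
septic patients are sicker throughout — rising linearly to the full
effect over the last `signal_ramp` windows before onset. The persistent
component matters: the per-window predictor locks an episode at its first
probability above 0.5, and a cohort whose early windows carry no class
information at all makes the lock a coin flip at window zero for every
model. The ramp gives the recurrent model a temporal pattern to exploit;
the persistent floor gives the lock rule something to be right about.

All randomness flows from one root seed through `derive_seed(seed, tag)`,
a splittable-stream contract: every module draws from its own derived
stream, so regenerating notes, re-splitting, or re-training never
perturbs another module's draws, and every derived seed stays inside R's
32-bit range.

What the generator does **not** emulate: realistic physiology or
pharmacology, inter-channel correlation structure, informative (MNAR)
missingness, note semantics, or real stay-length distributions. Tests
passing on these cohorts demonstrate that the pipeline's logic is
correct and that its qualitative orderings hold under a known
ground truth — not that the models would reach any particular performance
on real ICU data.

# Window grids and missingness

Events are binned per episode into a windows × channels matrix with an
observation mask; multiple values in one window average arithmetically.
Episodes whose overall non-text missing fraction reaches 90% are dropped.
The filter aggregates over the whole episode by default; a per-feature
mode (drop if any single channel reaches the threshold) is available,
since the source phrasing supports either reading.

Three missingness representations feed the predictor:

* **carry-forward + global mean** (missing-at-random reading): each gap
  takes the most recent observed value of its channel; cells before the
  first observation and channels never observed in the episode take the
  global per-channel mean. Global means are computed on the training
  split only — the leakage-safe choice, deliberately stricter than
  computing them over all data;
* **distinct sentinel** (missing-not-at-random reading): missing cells
  take an integer verified absent from every observed value; the default
  is `floor(max observed) + 1`, recomputed per dataset so the "entirely
  absent" property is guaranteed rather than assumed;
* **GAIN**, below.

Splits are 80/10/10 train/test/tune, stratified jointly by label and
episode length; strata with five or fewer episodes are omitted entirely
to keep class and length distributions similar across splits. Within a
stratum, counts follow largest-remainder rounding (deterministic and
proportion-preserving) and assignment follows a seeded shuffle.

Features are z-scored with training-split statistics before training.
Physiological channels span two orders of magnitude and unstandardized
inputs saturate the recurrent gates; the statistics travel with the
split object so test and tune data are transformed identically.

# GAIN

Generative adversarial imputation trains a generator that sees the
observed entries (min–max normalized per column) plus uniform noise
`U(0, 0.01)` in the missing slots, against a discriminator that predicts
the observation mask given the completed sample and a *hint*
`H = B∘M + 0.5(1−B)`, `B ~ Bernoulli(hint rate)`, which reveals most of
the true mask and concentrates the adversarial game on the rest. The
discriminator minimizes cross-entropy on mask recovery; the generator
minimizes the adversarial loss on missing entries plus `alpha` times the
squared reconstruction error on observed entries.

Both networks are fully connected — two hidden layers of width equal to
the feature count by default, rectified-linear hidden units, sigmoid
outputs — trained with Adam at step 1e-3 by hand-written
backpropagation. Reference-scale settings are `alpha` from
{0.1, 1, 10, 100} (default 100), batch 512, hint rate 0.9, and 15,000
iterations; the tests run a desk-scale profile (2,000 iterations, batch
128). Network depth, width, the noise distribution, and the optimizer
follow the original GAIN formulation, since the tuned scalars above are
the only published settings; all are config-exposed. One practical
finding encoded in the defaults: at these problem sizes the
default-width generator generalizes to missing-entry patterns, while
much wider networks saturate their missing-slot outputs and lose to
column-mean imputation. Observed entries always pass through exactly,
because completion happens on the original scale as `M∘X + (1−M)∘G(·)`.

# Text embeddings

Notes are embedded by a pluggable backend. The interface mirrors the
last-four-layers pooling scheme used with clinical transformer encoders:
tokenize, truncate to 512 tokens, obtain per-token states for the last 4
layers (hidden size 768), mean-pool tokens within each layer, then either
average the 4 layer vectors (**short**, 768 dims) or concatenate them in
layer order (**long**, 4 × 768 = 3072 dims). Token-level pooling is mean;
whether the original scheme pooled tokens by mean or used a
classification token is unstated, so both are worth offering in a
pretrained adapter, and mean is the surrogate's default.

The default backend is a deterministic surrogate whose per-token layer
states are seeded pseudo-random vectors: a bag-of-tokens embedding in
disguise. It carries exactly the information the synthetic notes contain
(token identity), which is what the pipeline needs — the text pathway is
testable offline, and a linear probe on surrogate embeddings separates
the synthetic classes well above chance. Pre-trained clinical
transformer weights can back the same interface but are deliberately not
bundled; training or fine-tuning one is a non-goal. Windows with several
notes average their vectors; windows with none carry zero vectors.

# The LSTM predictor

One step of the recurrent cell, per gates (σ the logistic function):

$$
\begin{aligned}
g_f &= \sigma(W_{fx} x_t + W_{fh} h_{t-1} + b_f), \quad
g_i = \sigma(W_{ix} x_t + W_{ih} h_{t-1} + b_i), \quad
g_o = \sigma(W_{ox} x_t + W_{oh} h_{t-1} + b_o) \\
\tilde C &= \tanh(W_{cx} x_t + W_{ch} h_{t-1} + b_c), \qquad
C_t = g_f \odot C_{t-1} + g_i \odot \tilde C
\end{aligned}
$$

The hidden-state update is $h_t = g_o \odot \tanh(C_t)$ by default. A
variant $h_t = g_f \odot \tanh(C_t)$ — reusing the forget gate — is
selectable with `h_mode = "forget"`: a published presentation of these
equations writes the update that way, and rather than silently
correcting it the package implements both and tests both against a
scalar-loop oracle.

A 2-logit log-softmax head scores every window; training minimizes the
masked negative log-likelihood with **every window carrying the episode
label**. The per-window target construction is not fixed by the source
protocol; labeling all windows is the choice consistent with lock-based
early prediction and the earliness metric (the model is rewarded for
alarming early, and the lock rule discards everything after the first
alarm anyway).

Training uses Adam over balanced mini-batches: each batch holds exactly
⌈batch/2⌉ positives (resampled with replacement) and ⌊batch/2⌋
negatives, and one epoch covers the negative class once —
"one epoch" needs a concrete definition under oversampling, and covering
the majority class once is the natural one. Dropout applies to layer
outputs during training only. At prediction time an episode locks at the
first window with positive probability strictly above 0.5; the episode
score for curve metrics is the lock-window probability, or the maximum
window probability when no window locks. Scoring at the episode level
(rather than pooling all windows of all episodes) is the default; the
source is ambiguous, and episode-level scores are what the lock rule and
earliness are defined over.

Hyper-parameter search draws configurations uniformly without
replacement from a grid (reference grid: layers {1,2,3}, neurons
{512, 800, 1024, 2048}, dropout {0, .1, .2, .3}, epochs {1, 2}; 100
draws) and selects by tuning-split AUPRC, ties to the earlier draw. The
desk-scale defaults used in tests are far smaller (hidden 6–16, 1
layer), chosen so the full suite trains dozens of models in minutes; the
reference grid remains available by configuration.

All numerics — forward pass, backpropagation through time for both
hidden-state variants and stacked layers, Adam — are hand-written matrix
code, verified against numerical differentiation and a scalar-loop step
oracle in the test suite.

# Federated simulation

Training episodes are dealt equally across clients (sizes differ by at
most one, disjoint, exhaustive, seeded). When labels are available the
deal is class-stratified — shuffled positives dealt round-robin, then
shuffled negatives — because balanced oversampling requires both classes
on every client, and at desk scale an unstratified deal of a 9.5%
prevalence cohort across ten clients has a realistic chance of producing
an all-negative shard.

Each round: broadcast the global weights, train locally on every client
(fresh local optimizer each round — whether clients retain optimizer
state across rounds is unspecified, and a fresh optimizer is the
conservative reading), collect the updates, aggregate:

* **simple** — the weighted average $W_{r+1} = \sum_c \frac{S_c}{S} W_r^c$
  with client sample shares as weights;
* **opt** — a server optimizer step on the pseudo-gradient
  $\Delta_r = W_r - \sum_c \frac{S_c}{S} W_r^c$; plain gradient descent
  with step 1 (the default, which provably coincides with *simple*) or a
  server-side Adam. "A gradient-based server optimizer" is all the
  source specifies; both options are provided.

The aggregated global model is evaluated on the test split after every
round; per-round metrics are never taken from any single client model. A
one-client federation is numerically identical to centralized training
resumed round by round with the same seeds — an exact equality the test
suite asserts. Client failure aborts the round with a stage-tagged
diagnostic; partial aggregation is not attempted.

Transport: in-process by default. A localhost socket path with
length-prefixed serialized weight frames exists to honor the
client/server architecture and is exercised in the tests; weights
round-trip bit-identically. Five rounds is the default, the count used
in the reference protocol to limit overfitting on small shards.

# Evaluation

* **Confusion counts** at the strict `> 0.5` threshold.
* **AUROC** from ranks, equal to
  $P(\text{score}_+ > \text{score}_-) + \tfrac12 P(\text{tie})$.
* **AUPRC** as the area under the precision–recall step curve, by
  descending-score sweep with tied scores grouped. For uninformative
  scores it concentrates near the prevalence, which the tests assert.
* **Earliness** — the median, over true-positive episodes, of
  `onset window − lock window` in hours; larger is earlier. Undefined
  (with a warning) when there are no true positives.
* **Report comparison** — percentage-point deltas `(a − b)·100`, rounded
  half-up to two decimals, the arithmetic used when contrasting
  modalities or aggregation rules.

Both curve metrics are verified against brute-force oracles (all
positive×negative pairs; exhaustive threshold enumeration) on every
instance with up to 8 episodes.

# Problem sizes used by the tests

The suite trains real models end to end, so sizes are chosen to make
that routine: cohorts of 200–2,000 patients, hidden sizes 4–16, one
layer, 1–2 epochs, embedding width 16, GAIN at 2,000 iterations × batch
128. The directional checks (multi-modal ≥ each single modality;
2-client ≥ 10-client federation, each in at least 4 of 5 seeds) run five
seeds of 800-patient cohorts. These are the package's desk-scale study
conditions; the reference-scale settings remain available through the
configuration objects.

# Known limitations

* The synthetic generator's independence assumptions (across channels,
  windows, and the missingness process) make imputation and prediction
  easier than on real EHR data; passing tests validate logic and
  direction, not clinical performance.
* The GAIN game at desk scale is sensitive to network width; the
  defaults are chosen for the regime the tests run in.
* Earliness on synthetic cohorts is inflated by the persistent severity
  component: a model can lock long before the onset ramp because weak
  evidence is present from admission.
* The pretrained text backend is an interface, not an implementation;
  no transformer weights ship with the package.
* Single-admission patients only; linking repeat admissions is out of
  scope, as is distinguishing community- from hospital-acquired sepsis.
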