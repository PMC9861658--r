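# fedsepsis

Early sepsis warning from sparse, multi-modal electronic health records
(EHR), at desk scale and fully offline. The package is for researchers and
students of clinical machine learning who want a complete, testable
implementation of a modern sepsis early-warning pipeline — synthetic
cohorts with planted ground truth, Sepsis-3 labeling, care-episode
features under three missingness strategies, a multi-modal LSTM
predictor, simulated federated training, and AUPRC/AUROC/earliness
evaluation — without credentialed ICU data, GPUs, or pre-trained
transformer weights.

## The science in brief

A **care episode** is up to 48 one-hour windows of record ending at the
earliest of first sepsis onset, death, or discharge. **Sepsis-3** onset is
the co-occurrence of *suspected infection* (≥2 antimicrobial doses paired
with a culture order, within 24 h when the dose comes first or 72 h when
the culture comes first) and *organ dysfunction* (SOFA score ≥ 2 points
above baseline inside −48 h/+24 h of the suspicion time; baseline is the
latest score before the 72 h lookback, else 0).

Per-window prediction uses an LSTM,

$$C_t = g_f \odot C_{t-1} + g_i \odot \tanh(W_{cx}x_t + W_{ch}h_{t-1} + b_c),
\qquad h_t = g_o \odot \tanh(C_t),$$

with a log-softmax head, balanced (50% positive) oversampled mini-batches,
and the **lock rule**: an episode locks at its first window with positive
probability strictly above 0.5 and later windows are ignored. Missing
values are handled by carry-forward + global mean, a distinct sentinel
value, or **GAIN** (a generator imputes missing cells while a hint-assisted
discriminator predicts the observation mask). Clinical notes enter as
pooled last-four-layer embeddings (short 768-dim mean or long 3072-dim
concatenation; a deterministic surrogate backend is the default).
Federated training shards episodes equally across clients and aggregates
with the sample-weighted average ("simple", FedAvg) or a server-optimizer
step on the pseudo-gradient ("opt"). Evaluation: AUPRC, AUROC, and
**earliness** — the median hours between lock and onset over true
positives.

The LSTM (forward, backpropagation through time, Adam) and GAIN are
hand-written matrix code, verified against numerical differentiation and
brute-force oracles in the test suite.

## Worked example

```r
library(fedsepsis)

preset <- experiment_preset(
  modality    = "multi_modal",
  missingness = "cfmean",
  setting     = "single_server",
  train_cfg   = train_config(hidden = 8, epochs = 2,
                             batch_size = 16, lr = 3e-3, seed = 1),
  embed_spec  = embedder_spec(hidden_size = 16, seed = 1),
  seed        = 121
)
res <- run_experiment(preset, synth_config(n_patients = 800, seed = 121))
res$report
```

```
#> # A tibble: 1 × 9
#>   round auprc auroc earliness_h    tp    fp    tn    fn n_episodes
#>   <int> <dbl> <dbl>       <dbl> <int> <int> <int> <int>      <int>
#> 1    NA 0.743 0.967        23.5     8    13    60     0         81
```

Read: on the held-out test split of a synthetic 800-patient cohort the
multi-modal model reaches AUPRC 0.74 at a roughly 10% prevalence (a
random scorer would sit near 0.10) and AUROC 0.97; all 8 septic test
episodes were caught (`fn = 0`) at the cost of 13 false alarms, and the
true positives locked a median of 23.5 windows (hours) before their
planted onset — synthetic septic patients carry a mild persistent
elevation from admission, so early locks are expected. Swap `modality = "non_text"` or
`missingness = "gain"`, or `setting = "federated"` with
`aggregation = "simple"` and `n_clients = 3`, to walk the experiment grid;
`tidy()`, `glance()`, `autoplot()`, and `plot_pr_curve()` work on the
fitted objects.

A thin command-line wrapper is installed at
`system.file("scripts", "fedsepsis", package = "fedsepsis")` with
`generate`, `label`, and `experiment` subcommands.

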