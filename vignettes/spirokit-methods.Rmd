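---
title: "Models, parameters and design choices in spirokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in spirokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirokit)
```

# Scope

`spirokit` implements the computational stages of a spirometry-to-report
pipeline: synthetic spirogram generation, pulmonary-function metric
extraction with LMS reference equations, cohort quality control, a
CNN-BiLSTM COPD-probability encoder with attention saliency, a
cross-modal projector, rule-based report drafting with lexical guideline
retrieval, and an evaluation harness. This vignette records the models,
their assumptions, the tunable parameters, and the design decisions that
were genuinely open — in enough detail that a maintainer can tell which
behaviours are principled and which are conventions.

# The synthetic curve family

## Model

A forced expiratory maneuver is modelled in the volume domain as a
piecewise flow–volume relationship: a linear rise from zero flow to peak
expiratory flow (PEF) at volume $v_{peak} = f \cdot FVC$ (with
$f \in (0,1)$ the `v_peak_frac` parameter), then a power-law descent

$$\dot V(v) \;=\; PEF \cdot
  \left(\frac{FVC - v}{FVC - v_{peak}}\right)^{k}.$$

The exponent $k$ is the morphology dial: $k>1$ yields the concave
("scooped") descending limb characteristic of airflow obstruction,
$k=1$ a straight limb, $k<1$ a convex limb. This family was chosen over
more physiological models because every spirometric index and the
descending-limb concavity have closed forms — the test suite's oracles
are exact, not simulated. For the concavity index defined as one minus
the ratio of the area under the limb to the area under its chord, the
closed form is $(k-1)/(k+1)$.

## Sampling

`synthesize_curve()` integrates $dv/dt = \dot V(v)$ by forward Euler at
the sampling interval `dt` (default 0.01 s; typical office spirometers
sample at 100 Hz or faster, and the default is not critical because the
metric engine's error falls with `dt`). Because $v=0$ is a fixed point
of the rising limb, integration is seeded with an ignition volume
$v_0 = \min(PEF\cdot dt,\; v_{peak}/100)$ — under 1 % of FVC, so the
volume unaccounted for is negligible against the 1–2 % oracle
tolerances. The maneuver is truncated when the noiseless flow falls
below `end_flow_threshold` (default 0.025 L/s, mirroring standard
end-of-test flow criteria); this matters for $k \ge 1$ limbs, which
approach FVC only asymptotically. Truncation is decided on the noiseless
signal so that curve length does not depend on the noise realisation.
Gaussian flow noise (`noise_sd`, default 0.05 L/s in cohorts) emulates
sensor noise only.

Two consequences are worth stating. First, recovered FVC on a truncated
$k>1$ curve is below `fvc_true` by the analytic tail volume
$u_{end} = (FVC - v_{peak}) (thr/PEF)^{1/k}$ — the tests verify against
this truncation-corrected value exactly, and against `fvc_true` (2 %)
only for $k \le 1$. Second, the sampled maximum flow underestimates PEF
by at most one sampling step times the flow slope at the peak; the
tests bound this explicitly.

## What the generator emulates, and what it does not

Cohorts (`generate_cohort()`) tie demographics to lung size through the
synthetic LMS table (subject FVC is the predicted value perturbed on
the z scale), draw $k$ near 1 for controls and in the obstructive range
(2–4 by default) for cases, depress case PEF and FVC multiplicatively,
add multiplicative between-blow FVC jitter (so the repeatability filter
has something to catch), and attach diagnosis codes consistent with the
label; `label_noise` flips a configurable fraction of labels *against*
physiology to exercise the consistency screen. Not emulated: inspiratory
limbs, cough and glottic-closure artifacts, submaximal effort,
bronchodilator response, or real demographic–disease confounding.
Passing tests therefore demonstrate correctness of the pipeline's
mechanics and its behaviour on clean morphological signal — not
clinical performance on real spirograms.

# The metric engine

All volumes and times are referenced to a time zero, by default the
first sample whose flow reaches 5 % of the eventual peak (the standard
back-extrapolated time zero — the tangent through the peak projected to
zero volume — is available behind the `time_zero` flag; on this curve
family the two differ by a few percent in FEV1). FVC is the final
cumulative (trapezoidal) volume; FEV1 is the volume linearly
interpolated at 1 s after time zero (missing, with a warning, on
maneuvers shorter than 1 s); PEF is the raw maximum of the sampled flow
(no smoothing); `t25`/`t75` are interpolated times at 25 %/75 % of FVC
exhaled; FEF25–75 is `0.5·FVC/(t75 − t25)` by construction; FEF75 is
the interpolated instantaneous flow at 75 % of FVC exhaled. Curves whose
cumulative volume dips more than 1 % of the final volume below its
running maximum are rejected as invalid — the 1 % allowance
distinguishes genuine flow reversal from sensor-noise jitter around the
zero-flow tail.

The LMS machinery is standard:
$z = ((y/M)^L - 1)/(L\,S)$ with the log-limit at $|L| < 10^{-6}$, the
LLN at $z = -1.645$ (5th centile), and
$M = \exp(a_0 + a_1 \ln h + a_2 \ln a + M_{spline}(a))$,
$S = \exp(b_0 + b_1 \ln a + S_{spline}(a))$ with age-spline offsets
linearly interpolated from a lookup table and a range error outside it.
Official reference tables are not redistributed; the shipped table
(`lms_synthetic_table()`, also at `inst/extdata/lms_synthetic/`) is
synthetic with plausible magnitudes, and its FEV1/FVC intercept is
calibrated to the simulator's healthy morphology so that control
z-scores centre near zero — a reference equation is, after all, a
description of its reference population.

# Cohort quality control

The stage order is fixed: label assignment → blow validity → outlier
trimming → blow-consistency filtering → balancing → label-consistency
screening; every exclusion carries a machine-readable stage and reason,
and `stratified_split()` runs downstream. Decisions the sources left
open, resolved here:

- *Trimming metrics*: configurable, default {FVC, FEV1, PEF}; 0.5 % per
  tail with percentiles by linear interpolation (`quantile` type 7);
  exclusion is strict (`<`/`>`), so degenerate distributions lose
  nothing.
- *Blow consistency*: relative difference of the two best blows (by
  FVC, configurable) with the larger value as denominator — symmetric
  and conservative; single-blow records are kept with a warning.
- *Label screen*: the LLM-based screen is abstracted to a checker
  interface. The default deterministic rule flags a case with FEV1/FVC
  z ≥ +1 or a control with z ≤ −3 — a documented stand-in chosen so
  that only gross label-physiology contradictions are removed; a
  failing checker retains the record and logs it.
- *Split rounding*: per class, validation and test each receive
  `ceiling(ratio · n_class)` records. On an 8,245/10,171 cohort at
  8:1:1 this yields 14,730/1,843/1,843 — the unique simple convention
  reproducing that arithmetic.

# The encoder

Three 1-D convolution blocks (channels 32/64/64, kernels 7/5/3, each
followed by ReLU and stride-2 max pooling, all configurable) reduce
time by $r = 2^3 = 8$ and feed a bidirectional LSTM
(`lstm_hidden` 64 per direction), giving an embedding of shape
$\lceil T/r \rceil \times D_{feat}$ with $D_{feat} = 2 \cdot$
`lstm_hidden`. Inputs are per-curve flow scaled by its own peak plus a
constant-`dt` channel. Padding is handled so that no information leaks:
activations beyond each sequence's valid length are zeroed after every
block, the backward LSTM runs on per-sequence reversed valid segments,
and attention pooling assigns padded timesteps zero weight — the tests
assert bit-level padding invariance. Everything (convolution, LSTM,
attention, Adam) is implemented in base R with hand-written backward
passes, pinned by finite-difference gradient checks on a tiny network;
training minimises binary cross-entropy with early stopping on
validation loss and is exactly reproducible by seed.

## Attention pooling and saliency

The classifier head pools the embedding with masked temporal attention
(softmax over scores $s_t = E_t \cdot u / \sqrt{D_{feat}}$) before the
logistic unit, and `encoder_saliency()` reads the learned attention
weights back out, linearly upsampled to the input grid and min–max
normalised. This was a measured decision, not the first design. A plain
activation-norm map was tried and discarded: L2 norms of the final-layer
activations track signal magnitude, which is large on the rising limb,
so the map pointed away from the diagnostic region on every model
tried. A CAM-style class-evidence map ($|E_t \cdot w|$) was
seed-unstable — a bidirectional LSTM can place class evidence at any
timestep. Per-window occlusion mapping failed differently: on a
power-law limb the evidence is redundant, so no single window shifts
the logit. Making attention part of the architecture resolves this
cleanly: the model must *learn* where to look, and on trained models the
attention mass settles on the descending limb of obstructive curves
(100 % of noiseless obstructive curves across the seeds exercised in
the tests, against the ≥80 % property the suite asserts). On normal
curves the attention typically settles early on the limb rather than
spread across it; the saliency property asserted by the tests concerns
obstructive curves. The alternative readouts remain available as
`method = "class_evidence"` and `method = "activation_norm"`.

The separable benchmark used by the classifier-recovery and saliency
tests holds amplitude and duration distributions common across classes
and differs only in the limb exponent (0.8 vs 3), so the encoder can
succeed only by reading morphology. Test-time sizes (400 curves, a
reduced 8/16/16-channel configuration, 4 epochs) were chosen as the
smallest training run that cleanly saturates the task; the defaults
above remain the package's general-purpose configuration.

# The projector

`project_embedding()` applies
$P = \mathrm{Dropout}(\mathrm{ReLU}(E W_1 + b_1)) W_2 + b_2$ row-wise;
dropout (inverted scaling) exists only in training mode, so evaluation
is deterministic and the tests compare against a direct two-line
matrix-algebra oracle at $10^{-6}$. The target width `d_llm` defaults
to 256 — the width of the downstream language model is irrelevant to
correctness. Pre-training minimises mean squared error against target
embedding sequences produced by any pluggable text-embedding function;
the desk-scale stand-in for semantic alignment is recovery of a planted
linear map (final loss below 1 % of initial), which the pre-trainer
achieves by orders of magnitude.

# Prompts, reports, retrieval

`build_prompt()` renders three blocks — demographics, the PFT block
(measured/predicted/LLN/z for FEV1, FVC, FEV1/FVC, PEF, FEF25–75), and
the encoder's COPD-probability line — plus an embedding placeholder
span when projected features are attached. `mask_pft = TRUE` (or
`mask_prompt()` on an existing bundle, which is idempotent) withholds
every digit-bearing PFT line while preserving the section header;
demographics are deliberately not masked — the robustness experiment
removes the *core quantitative metrics*, not the patient description.

`diagnose()` encodes the diagnostic hierarchy: obstruction iff measured
FEV1/FVC is *strictly* below its LLN (a ratio exactly at the LLN is not
obstruction); severity only then, by FEV1 percent predicted
(≥80 → 1, 50–79 → 2, 30–49 → 3, <30 → 4 — the conventional grade
bands); a missing LLN yields an inconclusive result rather than a
guess. The rationale chain always cites the LLN comparison first, and
the reported COPD confidence is a logistic function of the ratio's
relative distance from the LLN (steepness 12 — chosen so confidences
span roughly 0.2–0.98 over the simulator's physiological range; it
orders cases by evidence strength, which is all the rank-based
evaluation metrics consume). Report templates avoid reversibility
claims ("non-fully reversible") since no bronchodilator data exist, and
the rubric judge penalises that phrase.

Retrieval is deliberately lexical: BM25-style scoring
($k_1 = 1.2$, $b = 0.75$, smoothed idf) over snippet text and tags,
ties broken by snippet id — deterministic, order-invariant, and free of
model downloads. The shipped knowledge base contains short original
paraphrase snippets on obstruction diagnosis, severity grading and
management; user snippet files load from JSONL.

# Evaluation harness

Judge scores are 1–5 per dimension, normalised affinely to 0–100
(1 → 0, 5 → 100). The fallback judge computes deterministic proxies:
numeric agreement with the gold report and diagnosis match (factual
accuracy), section coverage (completeness), an LLN-citation check
(logic), a terminology checklist, contradiction/unsafe-phrase flags
(safety), and morphology-tag agreement (curve description). An adapter
judge must return the six raw scores and is retried once, then the
result is invalid. `extract_diagnosis()` parses the structured
impression; refusals and inconclusive impressions are `invalid` and
count against the valid-response rate.

AUROC is the Mann–Whitney statistic with half-weight ties; AUPRC the
area under the precision–recall step curve with thresholds at the
distinct scores; both are asserted equal to exhaustive brute-force
enumeration on all label patterns up to size 8. Bootstrap intervals are
percentile intervals over subject-level resamples — report-level
resampling would understate variance when subjects contribute multiple
reports; undefined resamples (e.g. single-class) are redrawn up to a
cap, then dropped with a log, and the interval is flagged unreliable if
more than half are lost. Coverage on a normal-mean study sits at 92–96 %
across seeds at the sizes the tests use (200 trials, n = 40, 400
resamples — chosen to estimate coverage to a few points of Monte-Carlo
error).

The masking experiment runs the identical record list through the
prompt → report → extraction chain twice. Without a curve channel the
masked rule engine has no quantitative evidence, every impression is
inconclusive, and the valid-response rate collapses to 0; with the
curve channel enabled the pipeline recomputes the indices from the raw
signal and keeps answering at rate 1.0 — the deterministic analogue of
the text-only-versus-multimodal robustness contrast.

# Pipeline and reproducibility

`run_pipeline()` chains simulate/ingest → metrics+QC → split → encoder
training → prompts → reports → evaluation, writing JSON/CSV artifacts
only (model checkpoints are a single JSON of config plus weights). A
stage re-runs only when its artifact is missing or the config hash
(MD5 of the canonical config JSON) changed. All randomness flows from
one root seed through `derive_seed(root, stage_name)` — a small string
hash keeping every derived seed below $2^{31}$ — so stages are
independently reproducible and identical configs reproduce artifacts
byte-for-byte. The default pipeline sizes (120 subjects, prevalence
0.35, a reduced encoder, 200 bootstrap resamples) are desk-scale
choices that keep a full end-to-end run in the minutes range on one
CPU; every component accepts larger configurations unchanged.

# Known limitations

- The curve family is a morphological caricature: no effort-dependence,
  no artifacts, no inspiratory limb. Results on it bound nothing about
  real spirograms.
- The synthetic LMS table is not a published reference equation set;
  z-scores are internally consistent, not clinically interpretable.
- The rule-based report generator and rubric judge are deterministic
  stand-ins at the interfaces where the full system would call external
  models; their scores exercise the evaluation plumbing, not language
  quality.
- The encoder is trained at desk scale; its AUROC on the separable
  benchmark demonstrates recovery of a clean signal, not diagnostic
  performance.
- Attention saliency localises evidence only to the extent the task
  forces it to; on easy tasks attention can be narrower than the full
  diagnostic region.
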