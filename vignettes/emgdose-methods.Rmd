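---
title: "Methods: from synthetic sEMG to an optimized exercise dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from synthetic sEMG to an optimized exercise dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgdose)
```

`emgdose` studies a question from rehabilitation biomechanics: given surface
EMG (sEMG) evidence about how four standard shoulder exercises recruit
superficial muscles and deep rotator-cuff stabilizers, how should a fixed
60-minute therapy session be divided among those exercises? This vignette is
the package's own account of each stage — the signal model, the feature
space, the cross-subject validation protocol, and the constrained
optimization — together with the design decisions that were genuinely open
and the choices we made.

## 1. The synthetic cohort and what it emulates

Human sEMG recordings of this kind are not publicly deposited, so the
package ships a simulator whose *default* configuration is the study
condition every downstream stage is developed and tested against: 8
subjects, 2 sessions each, 4 movements (scaption, internal rotation at the
side, external rotation at the side, external rotation at 90° abduction), 6
muscle channels (medial deltoid, posterior deltoid, trapezius — superficial;
supraspinatus, infraspinatus, teres minor — deep), sampled at 2000 Hz with
all stochastic content band-limited to 20–450 Hz. No 60 Hz line component is
ever injected, so the hardware notch filter is emulated by construction
rather than applied post hoc.

Each channel of a recording is

$$ y_m(t) = g_{m,v}\; a_{\text{subj}}\; e(t)\,
  \bigl(\rho\, z(t) + \sqrt{1-\rho^2}\, n_m(t)\bigr)
  + \sigma_0\, w_m(t), $$

with

| Component | Meaning | Default | Why |
|---|---|---|---|
| $g_{m,v}$ | gain of muscle $m$ in movement $v$ (µV) | 1.0 activated / 0.2 otherwise | encodes the exercise–muscle activation map; high/low contrast is recoverable but overlapping |
| $a_{\text{subj}}$ | per-subject log-normal amplitude multiplier | sdlog 0.2 | stands in for electrode placement and anthropometric variability (~20 % spread); drawn once per subject, shared across sessions and movements |
| $e(t)$ | raised-cosine repetition envelope | period 3 s | emulates slow, controlled exercise repetitions; `envelope_period_s = 0` gives a sustained contraction |
| $z(t)$, $n_m(t)$, $w_m(t)$ | unit-variance band-limited noises (4th-order Butterworth band-pass, applied forward–backward) | 20–450 Hz | $z$ is the latent drive shared across channels; $n_m$, $w_m$ are channel-private |
| $\rho$ | shared-drive weight | 0.9 | makes cross-muscle prediction learnable; $\rho = 0$ removes the shared drive |
| $\sigma_0$ | additive noise floor (µV) | 0.05 | baseline sensor/physiological noise |

Trial duration defaults to 30 s per movement per session — the recording
length is not fixed by any acquisition standard, so we chose a value that
yields a comfortable number of analysis windows (240 per trial) and kept it
configurable.

Determinism is a contract, not an accident: every `(seed, subject, session,
movement)` tuple maps to its own RNG stream (a small arithmetic hash kept
below $2^{31}$), so an individual recording regenerated in isolation is
bit-identical to its in-cohort counterpart, and a whole cohort regenerates
bit-identically.

**What the simulator does not emulate.** Motor-unit physiology, crosstalk
from deep to superficial channels, movement artifacts, electrode drift, and
inter-session electrode repositioning are all absent. Consequently, a model
that performs well here demonstrates that the *pipeline* recovers planted
cross-channel structure under subject-level held-out validation — not that
any model reaches a particular accuracy on real shoulder recordings. The
shared repetition envelope in particular makes windowed RMS values strongly
correlated across channels, which is realistic for cyclic exercise but
flattering to all learners.

One design subtlety follows from that: a "no structure" null condition must
remove the deterministic envelope as well as the latent drive, because a
shared envelope alone induces strong cross-channel RMS correlation even at
$\rho = 0$. The package therefore exposes `envelope_period_s = 0`, and the
null-behaviour test (equal gains, $\rho = 0$, flat envelope) checks that
held-out $R^2$ collapses toward zero under genuinely unlearnable conditions.

## 2. Feature space

Activation is summarized as sliding-window RMS with a 250-sample window
(125 ms at 2000 Hz). Two choices were open:

* **Stride.** "Sliding window" does not fix the overlap; we default to
  `stride = window_len` (non-overlapping) so windows are statistically
  independent and the window count is unambiguous
  ($\lfloor (n - 250)/250 \rfloor + 1$). Overlap is available via the
  `stride` argument.
* **Session merging.** A subject's two sessions are pooled at the *feature*
  level: windows are computed per recording and never straddle a session
  splice (`merge_sessions()` records boundary indices and `sliding_rms()`
  honours them). A window across the splice would mix unrelated signal and
  manufacture a discontinuity feature.

Peak normalization divides each subject × muscle group by its maximum RMS
across both sessions and all four movements — the broadest scope consistent
with making amplitudes comparable across subjects — so every subject attains
1.0 at least once per muscle, and all features live in $[0, 1]$. A
per-session scope is available (`peak_scope = "subject_session"`). The
recorded peaks are kept for the inverse transform. A channel whose group
peak is zero is degenerate and raises an error rather than dividing by zero.

Movements enter the models label-encoded (scaption = 0, internal rotation at
side = 1, external rotation at side = 2, external rotation at 90° abduction
= 3), in the movements' conventional listing order, so the encoding is
stable across runs. A numeric code is an odd feature for kernel and distance
based learners — one-hot encoding would be more principled — but the label
encoding mirrors standard practice in this analysis family and one-hot is
available (`movement_onehot = TRUE`).

## 3. Cross-subject validation

The estimand is *cross-person generalization*: can muscle $m$'s activation
be predicted for a person the model has never seen? Leave-one-subject-out
(LOSO) folds hold out all windows of one subject; features are the five
non-target muscles' normalized RMS plus the movement code, the target is the
target muscle's normalized RMS — one fit per (model, fold, target muscle),
i.e. 6 × 8 fits per model under the default cohort. Structural tests assert
no fold leaks test-subject rows into training and the target muscle never
appears among the features.

Scoring uses MSE and $R^2 = 1 - SS_{res}/SS_{tot}$ about the observed test
mean ($R^2$ may be negative; a constant test target is an error, not a 0/0).
Because the analysis prioritizes explained variance over point error, the
comparison table ranks by $R^2$ first, MSE second. Since the features are
peak-normalized, the reported MSE is dimensionless; we do not attach µV²
units to it.

Aggregation across the 48 cells is the unweighted mean by default (each
fold × muscle cell counts once); weighting by test-window count is available
(`aggregation = "window_weighted"`) — under the default balanced cohort the
two coincide.

The model menu and hyperparameters: SVR (`e1071`, radial kernel, cost 1,
epsilon 0.1), k-NN (`caret::knnreg`, k = 5), gradient-boosted trees
(`xgboost`, 100 rounds, learning rate 0.3, depth 6), and AdaBoost.R2
implemented in-package over depth-3 `rpart` trees (50 estimators, linear
loss, weighted-median prediction) since no installed R package provides the
boosted *regression* variant. No tuning is performed anywhere; the defaults
are recorded verbatim in the report's hyperparameter log so any run is
reproducible from its config. Training time is recorded around the fit call
only and reported for context; it is hardware-dependent and nothing is
asserted about it.

## 4. From predictions to a dose

Pooled out-of-fold predictions (every window is predicted exactly once, by
the fold that held its subject out) are clamped to $[0,1]$ and averaged into
a per-exercise profile: $s_i$ = mean over the three superficial muscles of
the mean predicted activation during exercise $i$; $d_i$ analogously for the
deep layer. Pooling LOSO predictions, rather than refitting on all subjects,
keeps the profile an *out-of-sample* statement.

The allocation $x \in \mathbb{R}^4$ (minutes) minimizes

$$ J(x) = -w_s \sum_i x_i s_i - w_d \sum_i x_i d_i + 0.1\,\mathrm{Var}(x),
\qquad \sum_i x_i = 60,\quad 5 \le x_i \le 30, $$

with $\mathrm{Var}$ the population variance (divide by $n = 4$; the divisor
is a convention we fix and document). The three clinical emphases are
$(w_s, w_d) \in \{(0.7, 0.3), (0.5, 0.5), (0.3, 0.7)\}$.

**Sign convention.** Written with all three terms negative, the variance
term *rewards* spreading… the opposite of a penalty: under minimization a
negative variance term pushes allocations to the bounds. The package's
default (`sign_mode = "goal-consistent"`) therefore takes the variance term
with a positive sign, which is the form that actually "penalizes high
variance" and produces the near-even, stable allocations this analysis
family reports; the fully literal form is available behind
`sign_mode = "literal"` and is never chosen silently. Both activation terms
stay negative, so the weighting cases shift emphasis between superficial and
deep *maximization*.

A consequence worth knowing: when $s \propto d$, the three cases scale only
the linear term, not the fixed variance penalty, so their optima coincide
exactly only at `variance_penalty = 0`; at 0.1 the plans differ slightly
while preserving the exercise ranking. The test suite checks both facts.

**Solver.** The goal-consistent objective is linear plus a convex quadratic,
so the problem is a small convex QP over a box-bounded simplex slice. It is
solved with SLSQP (sequential quadratic programming, `nloptr`), a
derivative-based method that handles the equality constraint and bounds
natively, started from the equal split (15, 15, 15, 15), with the exact
analytic gradient, `xtol_rel = 1e-10` and a 2000-evaluation cap. The
residual of the equality constraint is re-projected (uniformly, preserving
bounds) and must be below $10^{-6}$ minutes. Convexity makes the optimum
independent of the start; a property test confirms agreement within 0.1 min
from 10 random feasible starts, and a symmetry test confirms permutation
equivariance.

**Oracle.** `grid_oracle()` enumerates the full feasible lattice (first
three coordinates on a grid, fourth fixed by the equality; 0.5-min
resolution ≈ 1.2 × 10⁵ points, vectorized) and returns the lattice
minimizer. The solver must never be worse than the lattice best (tolerance
$10^{-3}$); conversely the lattice best can exceed the continuous optimum by
at most the discretization curvature bound
$\lambda (\text{res}/2)^2 = 6.25 \times 10^{-3}$ — the continuous optimum
generically falls between lattice points — so the oracle comparison is
asserted as those two one-sided checks, plus allocation agreement within
0.5 min.

Closed forms anchor everything: for $s = (1,0,0,0)$, $d = 0$, $w_s = 1$ the
reduction $x_1 = 60 - 3a$ gives the optimum at $a = 10$, i.e.
$(30, 10, 10, 10)$ — recovered exactly by both solver and oracle. Reported
plans carry raw minutes plus a largest-remainder integer rounding that
preserves the 60-minute total and the bounds; all invariants are checked on
the raw values.

## 5. Pipeline and problem sizes

`run_pipeline()` chains simulate → extract → validate → profile → optimize
from a single `run_config()`, persisting `features.csv`, `cv_report.json`
(including the full hyperparameter record), `profile.json`, one plan file
per case, and a `run.log` with seeds and per-stage wall time; a failing
stage aborts with its name and keeps partial outputs. All randomness flows
from the config seeds, and the deterministic artifacts (features, profile,
plans) are byte-identical across reruns. The spec-level commands
(`simulate`, `extract`, `validate`, `profile`, `optimize`, `report`,
`run-all`) map one-to-one onto exported functions, which are the package's
interface.

Problem sizes used in the shipped checks, chosen as a balance between
statistical comfort and a snappy test suite: unit tests run 1–3-subject
cohorts with 1–4 s trials; the planted-structure recovery check and the
acceptance script run the generator's full default condition (8 × 2 × 4 ×
30 s → 15,360 windows, 48 fits per model); solver–oracle agreement uses 50
random profiles.

## 6. Limitations

* Synthetic validation only: passing tests demonstrate pipeline
  correctness and recoverability of planted structure, not clinical
  accuracy; none of the benchmark numbers transfer to real cohorts.
* Deep-muscle "activation" inherits sEMG's indirectness; the simulator does
  not model crosstalk, so the deep channels are optimistic.
* The dose model allocates time only — no sets, reps, load, progression or
  session-to-session adaptation — and the 60/5/30-minute structure is fixed
  by convention, though every constant is a parameter.
* The variance penalty's weight (0.1) is conventional; the package exposes
  it, and at large values the optimizer provably returns the equal split.
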