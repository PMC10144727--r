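---
title: "Methods: deep Q-learning for sEMG gesture recognition"
author: "emgq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep Q-learning for sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgq)
```

## The problem and the model

`emgq` recognises static hand gestures from 8-channel surface
electromyography (sEMG) sampled at 200 Hz, the signal produced by a
consumer armband such as the Myo. Six classes are supported: `fist`,
`waveIn`, `open`, `waveOut`, `pinch` and `relax` (no gesture). Models are
*user-specific*: one agent is trained per user, because inter-person
variability in electrode placement, anatomy and gesture style dominates
the signal.

Labelling a recording is cast as a sequential decision problem. A
recording is segmented into sliding windows (length 300 points, stride
40); each window is summarised by five time-domain features per channel —
absolute envelope (AE), energy (E), root mean square (RMS), sample
standard deviation (STD) and mean absolute value (MAV) — giving a
40-dimensional observation $O_t$. The agent chooses an action $A_t$ (a
gesture label) for each window and receives $+1$ for a correct window
label and $-1$ otherwise. At the end of the episode (one recording) the
full action sequence is post-processed into a per-point label vector; if
its Dice overlap $\rho$ with the ground-truth activity region exceeds
0.75 *and* the dominant label is the true gesture, the agent earns an
extra $+10$, otherwise $-10$. Because identical feature vectors can arise
from different underlying signal windows, the process is partially
observable: the agent sees observations, never a full state.

The action-value function $Q(O, a; \theta)$ is a feed-forward network
(40–50–50–6, ReLU) trained by Q-learning with the two standard
stabilisers:

* **experience replay** — transitions $(O_t, A_t, R_{t+1}, O_{t+1})$ are
  stored in a FIFO buffer (capacity $10^6$) and minibatches of 64 are
  drawn uniformly, breaking temporal correlation;
* **a target network** $\theta^-$ — the bootstrap value is evaluated
  under a slowly moving copy of the online parameters.

The DQN target is
$Y^{DQN}_t = R_{t+1} + \gamma \max_a Q(O_{t+1}, a; \theta^-)$,
and the Double-DQN target decouples selection from evaluation,
$Y^{Double}_t = R_{t+1} + \gamma\, Q(O_{t+1},
\arg\max_a Q(O_{t+1}, a; \theta);\, \theta^-)$,
which provably never exceeds the DQN target and curbs the max operator's
overestimation bias. Both reduce to the same value when
$\theta = \theta^-$; the test suite asserts both properties on random
networks. Training minimises the squared error between
$Q(O_t, A_t; \theta)$ and $Y_t$ (targets held constant, only the taken
action's output contributing) with Adam.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| window length / stride | 300 / 40 points | 1.5 s windows, 200 ms hop |
| energy threshold | 0.18 | relative window-energy gate (see below) |
| $\gamma$ | 0.99 | discount factor |
| $\alpha$ | $3\times10^{-4}$ | Adam learning rate (best of the tuned grid $\{0.09, 0.1, 0.3, 0.5\}\times10^{-3}$) |
| $\varepsilon$ schedule | $1 \to 0.01$, decay $5\times10^{-3}$ | exploration probability |
| target smooth factor $\tau_s$ | $5\times10^{-3}$ | soft-update coefficient |
| target update frequency $\tau$ | 1 (grid: 1, 5, 20, 50) | learn steps between soft updates |
| replay capacity / minibatch | $10^6$ / 64 | experience replay |
| L2 / first-moment decay | $10^{-4}$ / 0.9 | regularisation, Adam $\beta_1$ |
| epochs | 15 | passes over the user's training set |
| overlap threshold | 0.75 (strict) | recognition bonus boundary |

## Decisions where the design was open

Several pieces of the pipeline are under-determined by their usual
informal description; the package fixes them as follows.

**Energy gate reference.** The "18% energy threshold" needs a reference
quantity. We gate each window on its energy *relative to the maximum
window energy of the same recording* (inclusive comparison, so exact ties
pass; an all-zero recording has all windows inactive). This is
self-normalising across users, gains and electrode impedances. An
absolute or calibration-based reference would couple recordings; a
per-channel gate would break the single 40-dim observation contract.

**Absolute envelope.** AE is implemented as the mean of the rectified
signal smoothed by a centred 25-point (125 ms) moving average with
truncated edges — a standard low-complexity envelope. It differs from MAV
through the edge-truncated smoothing. An analytic-signal (Hilbert)
magnitude would be a heavier alternative with no frequency-domain feature
to justify it.

**STD denominator.** The unbiased $L-1$ form, so expected values in the
tests are exact (`sd()` semantics).

**Feature ordering.** Channel-major — the five features of channel 1,
then channel 2, … — is a frozen convention; any fixed order works but it
must never change once models are saved.

**Window truth rule.** The per-window true label is the recording's
gesture when more than half the window's points lie inside the
ground-truth mask, else `relax`.

**Overlap factor.** The Sørensen–Dice form
$\rho = 2|A\cap B| / (|A|+|B|)$, with $A$ the points carrying the
dominant non-relax predicted label and $B$ the non-relax truth points;
$\rho = 1$ when both sets are empty (a correctly predicted `relax`
recording), 0 when exactly one is. Jaccard would be monotone-equivalent;
Dice is the convention in this evaluation lineage.

**Terminal reward composition.** The last window's $\pm 1$ classification
reward and the $\pm 10$ recognition reward are *added*, keeping
per-window credit intact at the terminal step. The recognition bonus
additionally requires the dominant predicted label to equal the true
gesture, so a well-localised but mislabelled burst is never rewarded.

**Majority-vote masking.** The "muscle activity" region inside which the
vote replaces labels is the union of the spans of energy-gated active
windows — the same 18% gate, one source of truth for training reward and
evaluation. Points outside it are forced to `relax`.

**Target maintenance.** The smooth factor and the update frequency are
composed: every $\tau$ learn steps,
$\theta^- \leftarrow \tau_s \theta + (1-\tau_s)\theta^-$. (Whether the
frequency gates hard copies or soft updates is an open choice; composing
both published constants is the conservative reading.)

**$\varepsilon$ schedule.** Multiplicative decay per learn step,
$\varepsilon \leftarrow \max(0.01, \varepsilon\,(1 - 5\times10^{-3}))$;
the floor keeps a residual exploration rate.

**Learning cadence.** One gradient step per environment step once the
buffer holds one minibatch; evaluation is always greedy
($\varepsilon = 0$).

**Input standardisation.** The raw features span four orders of magnitude
(window energy is a sum of 300 squares; MAV is an amplitude), which
stalls gradient training. The agent therefore standardises its network
inputs with per-feature means and standard deviations estimated from the
training set's energy-gated windows; the scaler is stored in the model
and re-applied at prediction time. This is internal to the agent — the
feature contract (inactive window $\Rightarrow$ zero vector) is
unchanged.

**Recurrent variant.** The optional recurrent policy inserts a 27-unit
LSTM (followed by dropout 0.2) between the second hidden layer and the
output. Replay is episodic: whole ordered episodes are stored, four are
drawn per update, and one backpropagation-through-time update runs after
each finished episode, so the hidden state is always well-defined and
resets at episode boundaries. Dropout uses a single per-sequence
(variational) mask. The LSTM gradients are verified against numerical
differentiation in the tests.

**Orientation correction.** Per-channel energies are summed over the
user's `waveOut` synchronization recordings and every recording is
circularly rotated so the maximum-energy channel sits at channel 1 (ties
to the lowest index). A pure circular shift is used — the armband can
rotate about the forearm but not mirror. The whole front end is then
invariant to how the band was worn: the test suite checks bit-identical
feature streams for all eight rotations.

## What the synthetic generator emulates — and what it does not

`generate_user()` produces recordings with the statistical structure the
pipeline relies on: 8 channels at 200 Hz, T = 1000 points (5 s);
zero-mean Gaussian baseline noise (s.d. 0.05) everywhere; inside a burst,
a white Gaussian carrier scaled per channel by a class-specific
amplitude pattern and shaped by a raised-cosine envelope with 10% ramps
(surface EMG is well modelled as amplitude-modulated noise, and the
smooth onset avoids gating edge artifacts). The five active classes use
pairwise-distinct patterns on the channel ring (single bumps on channels
1, 3, 5, 7 and a two-peak pattern for `pinch`); `relax` is baseline only.
Users differ by a log-normal per-channel amplitude jitter (s.d. 0.1).
Bursts cover 75–90% of the recording — the gesture is held for most of
the 5-s acquisition, and the burst is long relative to the 300-point
window so that window-resolution overhang (below) leaves the Dice overlap
above the 0.75 recognition threshold for a correct agent. Defaults are
60 training and 30 test recordings per user, balanced over the six
classes, with 2 `waveOut` sync recordings.

Not emulated: motor-unit physiology, electrode-skin impedance drift,
power-line interference, inter-gesture co-articulation, or inertial
signals. Passing tests on this generator show the *pipeline* (features,
environment, learning dynamics, post-processing, scoring) is correct and
can exploit separable class structure; they do not certify accuracy
levels on real armband data, where class overlap is far larger.

## Numerical choices, degenerate inputs, limitations

* All randomness flows through R's global RNG from a single seed per
  training run; a run is bit-reproducible, and checkpoints (which store
  parameters, Adam moments, $\varepsilon$, counters, replay contents and
  the RNG state) resume bit-compatibly at epoch boundaries.
* Weights are Glorot-uniform; biases zero except the LSTM forget gate
  (1). Adam uses $\beta_2 = 0.999$ and $\epsilon = 10^{-8}$; L2 applies
  to weight matrices only.
* Greedy argmax and vote ties break deterministically (lowest action
  index; earliest first occurrence for label modes).
* Degenerate inputs: recordings shorter than one window raise a
  segmentation error; an all-zero recording has every window inactive and
  therefore a zero feature stream; empty sync lists make orientation
  correction fail loudly rather than guess.
* The on-disk dataset format encodes signals as IEEE 754 binary32 printed
  at 9 significant digits, so save → load is bit-exact at float32
  precision and byte-deterministic.
* **Window-resolution limit.** Because predicted regions are unions of
  window spans, the predicted activity region overhangs a burst by up to
  (window length − gating overlap) on each side; an oracle labeller
  reaches $\rho = 1$ exactly only when the mask tiles whole windows
  (e.g. a full-mask recording of 980 points under the default layout).
  For partial bursts the oracle's $\rho$ is high but below 1 — a
  structural property of window-based labelling, not an implementation
  artifact.
* Desk-scale defaults keep one user's training around a minute on one
  CPU (about 16k learn steps); the cohort sizes used in the acceptance
  script (one user, 60/30 recordings, three agents) were chosen as the
  package's standard worked example.

## What the accompanying checks compute

The test suite freezes hand-evaluated values for every closed-form
contract (window counts, feature values, reward arithmetic, DQN and
Double-DQN targets, soft updates), verifies backpropagation against
numerical gradients, and runs property checks (rotation invariance,
vote idempotence, recognition ≤ classification, replay uniformity).
`scripts/acceptance.R` retrains DQN, Double-DQN and an untrained agent on
a freshly generated synthetic user and reports held-out classification
and recognition accuracy, the chance level, and the mean overlap factor.
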