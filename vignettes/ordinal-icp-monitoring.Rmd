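---
title: "Ordinal-pattern complexity monitoring of ICP waveforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal-pattern complexity monitoring of ICP waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpentropy)
```

## The problem

Intracranial pressure (ICP) is monitored continuously in neurocritical
care, but clinical practice mostly reduces the 200 Hz waveform to its
mean value and a 20 mmHg treatment threshold. The quantity clinicians
actually want — intracranial compliance, the ability of the
cranio-spinal system to buffer added volume — cannot be measured
noninvasively. This package extracts ordinal-pattern complexity features
from the ICP waveform itself and uses them as surrogates for the state
of that buffering capacity: complexity falls as the system loses its
ability to adapt (the loss-of-complexity view of physiological signals
under stress).

## Bandt–Pompe symbolization and the features

Each embedded vector $(x_t, x_{t+\tau}, \dots, x_{t+(m-1)\tau})$ is
mapped to the permutation that sorts it ascending: the *ordinal
pattern*. With `m = 6` there are $6! = 720$ patterns. Over a window, the
pattern relative frequencies $P = (p_1, \dots, p_{m!})$ give

* **Permutation entropy (PE)**: $H[P] = -\sum_{p_i>0} p_i \ln p_i \,/\,
  \ln m!$, in $[0, 1]$. Monotone signals give 0, i.i.d. noise tends
  to 1.
* **Missing patterns (NMP)**: the number of patterns with zero observed
  probability, normalized by $m!$. A smooth, stereotyped waveform visits
  few patterns (NMP near 1); an adaptable, variable one visits many.
* **$p(s_1)$ and $p(s_{m!})$**: probabilities of the fully ascending and
  fully descending patterns. Their order reverses between healthy and
  hypertensive states, so the pair is tracked explicitly.

Numerical conventions (all deliberate, all tested):

* **Ties** are broken by the earlier index (stable sort). Monitor
  exports quantize pressure, so exact ties occur; a deterministic rule
  keeps the symbolization reproducible.
* **Pattern ranking** is strict lexicographic via the Lehmer code:
  ascending is rank 1, descending is rank $m!$, and `pattern_rank()` /
  `unrank_pattern()` are exact inverses. Only the ascending/descending
  endpoints carry scientific meaning; PE and NMP are invariant to the
  interior labelling (there is a test for that invariance).
* `m` is capped at 10 ($10!$ is the last factorial that is comfortably
  tractable as a count vector), `tau` defaults to 1, and $0\ln 0 := 0$.

The default window is 3600 samples (5·6!, i.e. 18 s at 200 Hz) with a
1000-sample shift. A window holds 3595 embedded vectors — five per
pattern on average — which is the conventional minimum for estimating
the 720-bin distribution; `analyze_windows()` warns when a window holds
fewer than $m!$ vectors. `sweep_m()` reproduces the dimension-selection
exercise (windows of $5\,m!$ for $m = 3..7$); `m = 6` is the compromise
between temporal resolution and the cost of estimating $m!$
probabilities.

## Preprocessing

The filtering chain mirrors a standard monitor pipeline at 200 Hz: an
order-4 Butterworth band-stop centred at 50 Hz, then an order-4
Butterworth low-pass at 60 Hz. Two choices the pipeline description
leaves open:

* **Notch width**: only the 50 Hz centre is fixed; we use the
  conventional ±2 Hz (48–52 Hz), configurable.
* **Phase**: filters are applied forward–backward (zero phase) so that
  window features stay aligned in time with the raw pressure; this
  doubles the effective order, which only deepens the notch. Signals are
  odd-reflected at the edges before filtering so the transient decays
  inside the pad (the DC test demands 1e-6 flatness on a constant
  input).

Window mean ICP is computed on the same filtered signal that is
symbolized, keeping a single source of truth per window.

## Compliance

Intracranial compliance is $ICC = dV/dP$. From data it is estimated
between consecutive windows as the ratio of differences of window means,
$\Delta \bar V / \Delta \bar P$, which suppresses pulse-level
oscillation before differencing. Ratios with $|\Delta \bar P| <$ 0.1
mmHg are reported as `NA` (never ±Inf): below that, the difference is
dominated by residual pulsatility rather than the balloon. For the
generating law $P = p_0 + p_1 e^{EV}$ the closed form is
$ICC = 1/(E\,(P - p_0))$ — note the offset: $1/(EP)$ is exact only when
$p_0 = 0$ — and the recovery test holds the estimator to 5% of it on
noise-free ramps.

## The stage rules

The classifier encodes three observed regimes as a rule table over
(PE, normalized NMP, $p(s_1)$, $p(s_{m!})$):

| label | rule |
|---|---|
| injury_free | PE > 0.3 and NMP < 0.90 and $p(s_1) > p(s_{720})$ |
| terminal | NMP ≥ 0.95 and $p(s_{720}) > p(s_1)$ |
| intermediate | 0.90 ≤ NMP < 0.95 |
| indeterminate | anything else |

Boundary semantics follow the quoted inequalities (0.90 is already
intermediate; 0.95 is terminal-eligible). The rules are neither mutually
exclusive in principle nor exhaustive, so evaluation order is fixed
(injury_free, terminal, intermediate, indeterminate) and an explicit
`indeterminate` label absorbs windows matching no rule — e.g. a
monotone ramp (NMP ≈ 1 but ascending-dominant) is indeterminate, not
terminal. The "PE insensitive to ICP changes" property of terminal
stages is deliberately not a rule: it would need a joint PE–ICP window
regression with no agreed definition; it is visible in the report plots
instead. The thresholds are proof-of-concept descriptors, exposed via
`stage_thresholds()` rather than hard-coded. A known tension we document
rather than resolve: reported baseline PE in real porcine recordings
sits near 0.2, below the 0.3 injury-free rule; the synthetic generator
targets the rule set, so its baseline PE is higher (≈ 0.43).

## What the synthetic generator emulates

Real recordings from the balloon-inflation experiment are not
redistributable, so `make_experiment()` generates monitor-style
recordings with the protocol's structure: a 5 min baseline at zero
balloon volume (mean ICP ≈ 5 mmHg), a reversible hypertension episode
(inflation at 4 mL/min to 7 mL ≈ 26 mmHg, a 5 min plateau, deflation at
1 mL/min, recovery), and a terminal stage held near 35 mmHg. The
terminal stage is scaled to 5 min — long enough for ~60 analysis windows
— where the animal protocol held it for an hour; all other durations
are the protocol's own.

The waveform model, an emulation device rather than a mechanistic
circulation model:

* **Mean pressure** follows $P = p_0 + p_1 e^{EV(t)}$ with $p_0 = 2$,
  $p_1 = 3$ mmHg, $E = 0.3$/mL — a Monro–Kellie-consistent monotone
  convex curve giving 5 mmHg at $V = 0$ and ≈ 35 mmHg at 8 mL.
* **Severity** $s(t) \in [0,1]$ maps mean pressure onto the 5–35 mmHg
  range; `terminal*` protocol segments are forced to $s = 1$.
* **Cardiac pulse**: the first three harmonics of an asymmetric
  triangle, 1.8 Hz, amplitude-modulated by respiration (0.25 Hz, depth
  0.2). The ascending fraction of the cycle shrinks from 0.65 at
  baseline to 0.30 at $s = 1$: baseline waves rise slowly and fall
  fast (ascending patterns dominate), terminal waves rise fast and
  decay slowly (descending patterns dominate) — the mechanism behind
  the $p(s_1)/p(s_{720})$ reversal. Pulse amplitude grows as
  $(1 + 2s)$ (pulse pressure rises as compliance falls) and upper
  harmonics soften with severity (terminal waves are near-sinusoidal).
* **Stochastic variability**: smooth broadband noise (correlation time
  0.2 s, sd 0.3 mmHg at baseline, with a 5% white component) plus 5%
  heart-rate jitter. Both shrink with severity through the complexity
  coupling $c = 0.8$: noise amplitude scales as $(1 - cs)^2$, rate
  jitter as $(1 - cs)$. This is the single mechanism that encodes
  loss of complexity: it makes PE fall and NMP rise under hypertension
  *by construction*, which is exactly what makes the end-to-end test a
  check of the pipeline's ability to detect the encoding, not evidence
  about real physiology.
* **50 Hz powerline tone** (0.2 mmHg) to exercise the notch, and a
  single seed driving all randomness (same seed ⇒ bit-identical
  output).

The noise correlation time, rise fractions, amplitude gain, harmonic
rolloff and jitter scale were fixed once so that the three generated
stages land inside the rule bands above (baseline NMP ≈ 0.72, plateau ≈
0.94, terminal ≈ 0.96 under default conditions) and are not revisited
per seed. Features of real data the generator does **not** emulate:
beat-to-beat morphology of the P1/P2/P3 sub-peaks, slow vasogenic
(Lundberg) waves, movement artifacts, and the baseline NMP level of
real recordings (~0.9, versus ~0.7 here — the synthetic baseline is
noisier relative to its pulse than a real one). Passing tests therefore
demonstrate correctness of the measurement pipeline and internal
consistency of the feature definitions, not clinical validity.

## Degenerate inputs and numerical edges

Series shorter than one embedded vector error (or warn and return empty
under `strict = FALSE`); empty rank sequences refuse to form a
distribution; PE is clamped against float dust at the [0, 1] boundary;
compliance with degenerate pressure steps is `NA`; windows are 0-based
half-open with incomplete trailing windows dropped; classification
errors on features outside [0, 1] rather than guessing.

## Problem sizes

The test suite and the reproduction script run entirely on generated
data: the full timeline is 1665 s at 200 Hz (333,000 samples, ~330
windows) and completes in about a second; the brute-force equivalence
check enumerates all 87,380 integer series of length ≤ 8 over values
1–4 for $m \in \{2, 3\}$.

## A worked window

```{r}
rec <- make_experiment("full_timeline", seed = 1)
track <- run_analyze(rec)
summary <- run_report(track)$summary
summary
```

The medians above are computed from the generated recording at run
time; the stage ordering (entropy falling, missing patterns rising from
injury-free through terminal) is the package's central output.
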