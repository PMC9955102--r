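# icpentropy

Ordinal-pattern complexity monitoring of intracranial-pressure (ICP)
waveforms, for researchers and engineers working on neurocritical-care
signal analysis. Continuous ICP monitoring is usually reduced to a mean
value and a 20 mmHg alarm; `icpentropy` instead quantifies the
*complexity* of the 200 Hz waveform, which tracks the brain's volume
buffering capacity (intracranial compliance) — a quantity that cannot be
measured noninvasively.

## What it computes

Every embedded vector `(x_t, x_{t+τ}, …, x_{t+(m−1)τ})` of the waveform
is mapped to the permutation that sorts it ascending (Bandt–Pompe
ordinal pattern; ties broken stably, patterns ranked lexicographically
so rank 1 is fully ascending and rank m! fully descending). Over
sliding windows (default m = 6, τ = 1, 3600 samples, 1000-sample shift)
the pattern frequencies `P = (p_1, …, p_{m!})` yield:

- **Permutation entropy** `H[P] = −Σ p_i ln p_i / ln(m!)` ∈ [0, 1];
- **Missing patterns (NMP)**: the count of patterns with zero observed
  probability, normalized by m! — a surrogate for lost adaptability;
- **p(s1), p(s720)**: probabilities of the ascending and descending
  patterns, whose order reverses under intracranial hypertension;
- **windowed compliance** `ICC = ΔV̄/ΔP̄` when a balloon-volume track is
  available;
- a **three-stage rule classifier**: injury-free (PE > 0.3, NMP < 90%,
  p(s1) > p(s720)), terminal (NMP ≥ 95%, p(s720) > p(s1)),
  intermediate (NMP in 90–95%), else indeterminate.

Preprocessing follows the standard monitor chain: order-4 Butterworth
band-stop at 48–52 Hz (powerline) then order-4 low-pass at 60 Hz, both
zero-phase. A seeded synthetic generator (`make_experiment()`) emulates
the balloon-inflation porcine protocol — baseline near 5 mmHg,
reversible hypertension episodes through `P = p0 + p1·exp(E·V)`,
terminal high-pressure stage — so the entire pipeline is testable
without animal recordings.

## Worked example

The seven-sample reference series, symbolized at m = 3:

```r
library(icpentropy)
x <- c(3, 6, 8, 9, 5, 10, 2)
(s <- symbolize(x, m = 3, tau = 1))
#> [1] 1 1 5 3 5
d <- pattern_distribution(s, m = 3)
d
#> Ordinal-pattern distribution: m = 3, 6 patterns, 5 vectors
#>   observed 3 patterns, missing 3; PE = 0.5888
missing_patterns(d)$count
#> [1] 3
```

Five embedded vectors realize three of the six patterns (ascending
twice, 312 twice, 213 once), so three patterns are missing and the
normalized entropy is 0.5888.

A full synthetic experiment, analyzed and classified:

```r
rec <- make_experiment("full_timeline", seed = 1)   # 333,000 samples, 200 Hz
track <- run_analyze(rec)                           # filter + window + classify
run_report(track)$summary
#>     stage_label n_windows median_pe median_nmp_norm median_mean_icp
#> 1 indeterminate        51     0.217           0.843           12.58
#> 2   injury_free       121     0.429           0.726            5.02
#> 3  intermediate        78     0.174           0.939           26.51
#> 4      terminal        80     0.167           0.961           35.08
```

Reading the table: baseline windows (classified injury-free, mean ICP
≈ 5 mmHg) have high entropy and low missing-pattern fraction; the
hypertensive plateau (≈ 26 mmHg) drops entropy and pushes NMP into the
90–95% band; the terminal stage (≈ 35 mmHg) saturates NMP above 95%
with the descending pattern dominant. Indeterminate windows are the
inflation/deflation transitions. `run_report()` also returns the
ICP-vs-PE, ICP-vs-NMP and per-stage NMP box plots.

A thin command-line front end with `simulate`, `analyze`, `classify`
and `report` subcommands is installed at
`system.file("cli", "icpe.R", package = "icpentropy")`.

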