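# Synthetic porcine-style ICP + balloon-volume generator.
#
# Emulates a three-stage balloon-inflation experiment: a baseline period,
# reversible intracranial-hypertension episodes driven by a balloon-volume
# protocol through an exponential pressure-volume relation, and a terminal
# high-pressure low-variability stage.  The waveform model is an emulation
# device, not a mechanistic circulation model: mean pressure follows
# P(t) = p0 + p1 * exp(E * V(t)); a skewed, respiration-modulated cardiac
# pulse (fundamental plus two harmonics) rides on top; stochastic
# variability (smooth broadband noise plus heart-rate jitter) shrinks as
# severity rises, encoding the loss-of-complexity behaviour the ordinal
# features are designed to detect; 50 Hz powerline contamination exercises
# the notch filter.

# Waveform morphology constants (fixed study conditions, see the methods
# vignette for rationale). Severity 0 = baseline, 1 = terminal.
.SIM <- list(
  rise_frac_base = 0.65,   # ascending fraction of the cardiac cycle at baseline
  rise_frac_term = 0.30,   # terminal pulses rise fast and decay slowly
  pulse_gain = 2,          # pulse amplitude scales by (1 + gain * severity)
  harm_rolloff = 0.5,      # harmonics 2..3 shrink by (1 - rolloff*sev)^(k-1)
  hr_jitter = 0.05,        # fractional heart-rate jitter at baseline
  hr_jitter_tau_s = 2,     # correlation time of the rate-jitter process
  noise_tau_s = 0.2,       # correlation time of the broadband noise
  noise_white_frac = 0.05, # small uncorrelated component of the noise
  resp_mod = 0.2           # respiratory amplitude-modulation depth
)

.default_stage_plan <- function() {
  data.frame(
    stage_id = c("baseline", "inflate", "plateau", "deflate", "recovery",
                 "terminal_rise", "terminal"),
    duration_s = c(300, 105, 300, 420, 120, 120, 300),
    target_volume_ml = c(0, 7, 7, 0, 0, 8, 8),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic ICP experiment. The defaults are the study
#' conditions: 200 Hz sampling, a baseline mean near 5 mmHg
#' (`p0 + p1` at zero balloon volume), an exponential pressure-volume
#' relation `P = p0 + p1 * exp(E * V)`, balloon deflation at 1 mL/min, and
#' complexity coupling that damps waveform variability as pressure rises.
#'
#' @param fs Sampling rate, Hz.
#' @param heart_rate_hz Cardiac fundamental frequency.
#' @param resp_rate_hz Respiratory rate (amplitude modulation).
#' @param p0_mmhg,p1_mmhg Baseline offset and exponential scale of the
#'   pressure-volume relation (mean ICP is `p0 + p1` at `V = 0`).
#' @param elastance_per_ml Elastance coefficient `E` (1/mL).
#' @param pulse_amp_mmhg Baseline cardiac pulse amplitude.
#' @param noise_sd_mmhg Baseline broadband-noise standard deviation.
#' @param powerline_amp_mmhg Amplitude of the 50 Hz mains tone.
#' @param complexity_coupling In `[0, 1]`: how strongly stochastic
#'   variability shrinks as severity rises (noise amplitude scales as
#'   `(1 - coupling * severity)^2`, rate jitter as one power).
#' @param seed Integer seed; all randomness flows from it.
#' @param stage_plan `data.frame` with columns `stage_id`, `duration_s`,
#'   `target_volume_ml` describing the balloon protocol segment by
#'   segment. Segment ids starting with `"terminal"` are simulated at
#'   maximal severity (near-periodic waveform).
#' @param deflation_rate_ml_per_min Balloon deflation rate.
#' @param inflation_rate_ml_per_min Balloon inflation (pump) rate.
#' @param severity_ref_mmhg Mean ICP mapped to severity 1 (default 35,
#'   the terminal-plateau pressure).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(fs = 200, heart_rate_hz = 1.8, resp_rate_hz = 0.25,
                       p0_mmhg = 2, p1_mmhg = 3, elastance_per_ml = 0.3,
                       pulse_amp_mmhg = 2, noise_sd_mmhg = 0.3,
                       powerline_amp_mmhg = 0.2, complexity_coupling = 0.8,
                       seed = 1L, stage_plan = .default_stage_plan(),
                       deflation_rate_ml_per_min = 1,
                       inflation_rate_ml_per_min = 4,
                       severity_ref_mmhg = 35) {
  if (fs <= 100)
    stop("`fs` must exceed 100 Hz so 50 Hz contamination is representable",
         call. = FALSE)
  for (nm in c("heart_rate_hz", "resp_rate_hz", "deflation_rate_ml_per_min",
               "inflation_rate_ml_per_min"))
    if (get(nm) <= 0) stop("`", nm, "` must be > 0", call. = FALSE)
  if (complexity_coupling < 0 || complexity_coupling > 1)
    stop("`complexity_coupling` must be in [0, 1]", call. = FALSE)
  need <- c("stage_id", "duration_s", "target_volume_ml")
  if (!is.data.frame(stage_plan) || !all(need %in% names(stage_plan)))
    stop("`stage_plan` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(stage_plan) > 0 && any(stage_plan$duration_s <= 0))
    stop("stage durations must be > 0", call. = FALSE)
  if (nrow(stage_plan) > 0 && any(stage_plan$target_volume_ml < 0))
    stop("balloon volumes cannot be negative", call. = FALSE)
  structure(list(fs = fs, heart_rate_hz = heart_rate_hz,
                 resp_rate_hz = resp_rate_hz, p0_mmhg = p0_mmhg,
                 p1_mmhg = p1_mmhg, elastance_per_ml = elastance_per_ml,
                 pulse_amp_mmhg = pulse_amp_mmhg,
                 noise_sd_mmhg = noise_sd_mmhg,
                 powerline_amp_mmhg = powerline_amp_mmhg,
                 complexity_coupling = complexity_coupling,
                 seed = as.integer(seed), stage_plan = stage_plan,
                 deflation_rate_ml_per_min = deflation_rate_ml_per_min,
                 inflation_rate_ml_per_min = inflation_rate_ml_per_min,
                 severity_ref_mmhg = severity_ref_mmhg),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "ICP simulation config: fs = %g Hz, %d protocol segments (%.0f s), seed %d\n",
    x$fs, nrow(x$stage_plan), sum(x$stage_plan$duration_s), x$seed))
  invisible(x)
}

#' Balloon-volume protocol
#'
#' Expands a segment plan into a per-sample volume trace: within each
#' segment the volume ramps linearly from its previous value toward the
#' segment target at the pump rate (inflation) or the deflation rate, then
#' holds. A target of 3 mL deflated at 1 mL/min is reached after exactly
#' 180 s.
#'
#' @param stage_plan Segment plan, see [sim_config()].
#' @param deflation_rate_ml_per_min,inflation_rate_ml_per_min Rates in
#'   mL/min.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of balloon volume (mL), one value per sample;
#'   segment boundaries (sample counts per segment) attached as attribute
#'   `"segment_lengths"`.
#' @export
volume_protocol <- function(stage_plan, deflation_rate_ml_per_min = 1,
                            inflation_rate_ml_per_min = 4, fs = 200) {
  if (nrow(stage_plan) == 0L)
    return(structure(numeric(0), segment_lengths = integer(0)))
  if (any(stage_plan$target_volume_ml < 0))
    stop("balloon volumes cannot be negative", call. = FALSE)
  v_prev <- 0
  out <- vector("list", nrow(stage_plan))
  seg_len <- integer(nrow(stage_plan))
  for (k in seq_len(nrow(stage_plan))) {
    n_k <- as.integer(round(stage_plan$duration_s[k] * fs))
    target <- stage_plan$target_volume_ml[k]
    rate <- if (target >= v_prev) inflation_rate_ml_per_min
            else deflation_rate_ml_per_min
    step <- rate / (60 * fs)  # mL per sample
    j <- seq_len(n_k)
    v <- if (target >= v_prev) pmin(v_prev + step * j, target)
         else pmax(v_prev - step * j, target)
    out[[k]] <- v
    seg_len[k] <- n_k
    v_prev <- v[n_k]
  }
  structure(unlist(out), segment_lengths = seg_len)
}

# evaluate code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Ornstein-Uhlenbeck-style smooth noise, unit stationary variance
.ou_noise <- function(n, tau_s, fs) {
  a <- exp(-1 / (tau_s * fs))
  as.numeric(stats::filter(stats::rnorm(n) * sqrt(1 - a^2), a,
                           method = "recursive"))
}

# Skewed cardiac pulse: first K harmonics of a zero-mean asymmetric
# triangle rising over the fraction `r` of the cycle. `u` is cycle phase
# in [0, 1); `r` may vary per sample; `rolloff` damps upper harmonics.
.pulse_shape <- function(u, r, rolloff = 0, K = 3L) {
  f <- numeric(length(u))
  for (k in seq_len(K)) {
    ck <- -(1 - exp(-2i * pi * k * r)) / (2 * pi^2 * k^2 * r * (1 - r))
    f <- f + 2 * Re((1 - rolloff)^(k - 1) * ck * exp(2i * pi * k * u))
  }
  f
}

#' Generate a synthetic ICP + balloon-volume recording
#'
#' Runs the waveform model under a [sim_config()]: the balloon protocol
#' sets mean pressure through `P = p0 + p1 * exp(E * V)`; severity (0 at
#' baseline pressure, 1 at `severity_ref_mmhg`, forced to 1 inside
#' `terminal*` segments) steers the morphology -- pulse amplitude grows,
#' the ascending fraction of the cycle shrinks (so the descending pattern
#' overtakes the ascending one), harmonics soften, and stochastic
#' variability collapses as `(1 - coupling * severity)^2`. The same seed
#' gives bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @return A [waveform_record()] with `icp` and `volume`; the per-segment
#'   annotation (`stage_id`, `start_s`, `end_s`) is attached as attribute
#'   `"stages"`.
#' @export
generate_icp <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  v <- volume_protocol(cfg$stage_plan, cfg$deflation_rate_ml_per_min,
                       cfg$inflation_rate_ml_per_min, cfg$fs)
  seg_len <- attr(v, "segment_lengths")
  n <- length(v)
  if (n == 0L) stop("stage plan produced an empty recording", call. = FALSE)
  t <- (seq_len(n) - 1) / cfg$fs
  pbar <- cfg$p0_mmhg + cfg$p1_mmhg * exp(cfg$elastance_per_ml * v)
  p_base <- cfg$p0_mmhg + cfg$p1_mmhg
  sev <- pmin(1, pmax(0, (pbar - p_base) / (cfg$severity_ref_mmhg - p_base)))
  seg_of <- rep.int(seq_along(seg_len), seg_len)
  sev[grepl("^terminal", cfg$stage_plan$stage_id)[seg_of]] <- 1
  g <- 1 - cfg$complexity_coupling * sev

  icp <- .with_seed(cfg$seed, {
    finst <- cfg$heart_rate_hz *
      (1 + .SIM$hr_jitter * g * .ou_noise(n, .SIM$hr_jitter_tau_s, cfg$fs))
    u <- cumsum(finst) / cfg$fs
    r <- .SIM$rise_frac_base + (.SIM$rise_frac_term - .SIM$rise_frac_base) * sev
    amp <- cfg$pulse_amp_mmhg * (1 + .SIM$pulse_gain * sev) *
      (1 + .SIM$resp_mod * sin(2 * pi * cfg$resp_rate_hz * t))
    wf <- .SIM$noise_white_frac
    noise <- cfg$noise_sd_mmhg * g^2 *
      (sqrt(1 - wf^2) * .ou_noise(n, .SIM$noise_tau_s, cfg$fs) +
         wf * stats::rnorm(n))
    pbar + amp * .pulse_shape(u %% 1, r, .SIM$harm_rolloff * sev) + noise +
      cfg$powerline_amp_mmhg * sin(2 * pi * 50 * t)
  })

  rec <- waveform_record(icp, fs = cfg$fs, volume = as.numeric(v))
  ends <- cumsum(cfg$stage_plan$duration_s)
  attr(rec, "stages") <- data.frame(stage_id = cfg$stage_plan$stage_id,
                                    start_s = c(0, ends[-length(ends)]),
                                    end_s = ends,
                                    stringsAsFactors = FALSE)
  rec
}

#' Preset synthetic experiments
#'
#' Convenience wrappers around [generate_icp()] for the canonical
#' protocol pieces:
#' \describe{
#'   \item{baseline}{5 min at zero balloon volume (mean ICP near 5 mmHg).}
#'   \item{reversible_episode}{baseline, inflation to 7 mL, a 5 min
#'     hypertensive plateau near 26 mmHg, deflation at 1 mL/min, recovery.}
#'   \item{terminal}{inflation to 8 mL and a sustained high-pressure
#'     near-periodic plateau above the 20 mmHg treatment threshold.}
#'   \item{full_timeline}{all three stages in sequence.}
#' }
#'
#' @param preset One of `"baseline"`, `"reversible_episode"`,
#'   `"terminal"`, `"full_timeline"`.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A [waveform_record()] with the `"stages"` annotation attribute,
#'   as from [generate_icp()].
#' @export
make_experiment <- function(preset = c("full_timeline", "baseline",
                                       "reversible_episode", "terminal"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  full <- .default_stage_plan()
  plan <- switch(preset,
    baseline = full[full$stage_id == "baseline", ],
    reversible_episode = full[full$stage_id %in%
      c("baseline", "inflate", "plateau", "deflate", "recovery"), ],
    terminal = full[full$stage_id %in% c("terminal_rise", "terminal"), ],
    full_timeline = full)
  rownames(plan) <- NULL
  generate_icp(sim_config(seed = seed, stage_plan = plan, ...))
}

#' Map sliding windows to protocol segments
#'
#' Assigns each window of a track the `stage_id` of the protocol segment
#' that contains it entirely, or `NA` for windows straddling a boundary.
#'
#' @param track A `"window_track"` from [analyze_windows()].
#' @param stages Segment annotation (`stage_id`, `start_s`, `end_s`), as
#'   attached by [generate_icp()].
#' @param fs Sampling rate used for the analysis.
#' @return Character vector of segment ids, one per window.
#' @export
window_stage <- function(track, stages, fs = 200) {
  wl <- attr(track, "window_len")
  if (is.null(wl)) stop("track lacks a window_len attribute", call. = FALSE)
  t0 <- track$window_start_idx / fs
  t1 <- (track$window_start_idx + wl) / fs
  out <- rep(NA_character_, nrow(track))
  for (k in seq_len(nrow(stages))) {
    inside <- t0 >= stages$start_s[k] & t1 <= stages$end_s[k]
    out[inside] <- stages$stage_id[k]
  }
  out
}
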