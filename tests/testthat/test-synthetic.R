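# Synthetic balloon-experiment generator.

test_that("the balloon protocol ramps and holds at the stated rates", {
  plan <- data.frame(stage_id = c("inflate", "deflate"),
                     duration_s = c(200, 200),
                     target_volume_ml = c(3, 0))
  v <- volume_protocol(plan, deflation_rate_ml_per_min = 1,
                       inflation_rate_ml_per_min = 4, fs = 200)
  expect_length(v, 200 * 200 * 2)
  # inflation: 3 mL at 4 mL/min -> 45 s; holds at target afterwards
  expect_equal(v[45 * 200], 3)
  expect_equal(v[200 * 200], 3)
  # deflation from 3 mL at 1 mL/min reaches 0 after exactly 180 s
  defl <- v[(200 * 200 + 1):(400 * 200)]
  expect_equal(defl[180 * 200], 0)
  expect_gt(defl[180 * 200 - 1], 0)
  expect_true(all(defl[(180 * 200):(200 * 200)] == 0))

  one <- volume_protocol(data.frame(stage_id = "hold", duration_s = 60,
                                    target_volume_ml = 0), fs = 200)
  expect_length(one, 12000L)      # duration x fs
  expect_true(all(one == 0))      # no inflation target -> all-zero volume
  expect_length(volume_protocol(data.frame(stage_id = character(0),
                                           duration_s = numeric(0),
                                           target_volume_ml = numeric(0))), 0L)
  expect_error(volume_protocol(data.frame(stage_id = "x", duration_s = 10,
                                          target_volume_ml = -1)),
               "negative")
})

test_that("with all stochastic and oscillatory terms off, ICP is the closed form", {
  cfg <- sim_config(noise_sd_mmhg = 0, pulse_amp_mmhg = 0,
                    powerline_amp_mmhg = 0, seed = 3,
                    stage_plan = data.frame(stage_id = "baseline",
                                            duration_s = 10,
                                            target_volume_ml = 0))
  rec <- generate_icp(cfg)
  expect_equal(rec$icp, rep(5, 2000))  # p0 + p1 at V = 0
})

test_that("generation is seed-deterministic", {
  a <- make_experiment("baseline", seed = 5)
  b <- make_experiment("baseline", seed = 5)
  c <- make_experiment("baseline", seed = 6)
  expect_identical(a$icp, b$icp)
  expect_false(identical(a$icp, c$icp))
})

test_that("baseline pressure sits near 5 mmHg and terminal above 20 mmHg", {
  base <- make_experiment("baseline", seed = 2)
  tr <- analyze_windows(filter_icp(base))
  expect_true(all(abs(tr$mean_icp - 5) < 2))
  term <- make_experiment("terminal", seed = 2)
  stages <- attr(term, "stages")
  hold <- term$icp[term$t >= stages$start_s[stages$stage_id == "terminal"]]
  expect_gt(mean(hold), 20)
})

test_that("hypertension reverses: post-deflation ICP returns to baseline", {
  rec <- make_experiment("reversible_episode", seed = 8)
  st <- attr(rec, "stages")
  seg_mean <- function(id) {
    r <- st[st$stage_id == id, ]
    mean(rec$icp[rec$t >= r$start_s & rec$t < r$end_s])
  }
  expect_gt(seg_mean("plateau"), 20)
  expect_lt(abs(seg_mean("recovery") / seg_mean("baseline") - 1), 0.10)
})

test_that("the 50 Hz contamination exists and the notch removes it", {
  rec <- make_experiment("baseline", seed = 4)
  mid <- 10001:30000  # integer number of 50 Hz cycles at 200 Hz
  before <- fft_amplitude(rec$icp[mid], 50, rec$fs)
  after <- fft_amplitude(filter_icp(rec)$icp[mid], 50, rec$fs)
  expect_gt(before, 0.1)                  # the tone is really there
  expect_lt(after / before, 10^(-40 / 20))  # >= 40 dB suppression
})

test_that("compliance recovery on noise-free generated data matches theory", {
  plan <- data.frame(stage_id = "inflate", duration_s = 480,
                     target_volume_ml = 8)
  cfg <- sim_config(noise_sd_mmhg = 0, pulse_amp_mmhg = 0,
                    powerline_amp_mmhg = 0, seed = 1, stage_plan = plan,
                    inflation_rate_ml_per_min = 1)
  rec <- generate_icp(cfg)
  ct <- compliance_track(rec)
  mp <- vapply(ct$window_start_idx, function(s)
    mean(rec$icp[(s + 1):(s + 3600)]), numeric(1))
  ok <- !is.na(ct$icc)
  # ICP = p0 + p1 exp(EV) => ICC = 1/(E * (ICP - p0))
  closed <- 1 / (0.3 * (mp[ok] - 2))
  expect_true(all(abs(ct$icc[ok] / closed - 1) < 0.05))
})

test_that("unknown presets and invalid configs are rejected", {
  expect_error(make_experiment("zebra"), "arg")
  expect_error(sim_config(complexity_coupling = 1.5), "coupling")
  expect_error(sim_config(fs = 50), "50 Hz")
  expect_error(sim_config(stage_plan = data.frame(stage_id = "x",
                                                  duration_s = -1,
                                                  target_volume_ml = 0)),
               "duration")
})
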