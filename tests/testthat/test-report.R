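# Pipeline orchestration and per-stage reporting.

test_that("run_analyze windows a 5600-sample input into three rows", {
  set.seed(2)
  rec <- waveform_record(5 + rnorm(5600), fs = 200)
  tr <- suppressMessages(run_analyze(rec, filter = FALSE))
  expect_identical(nrow(tr), 3L)
  expect_identical(tr$window_start_idx, c(0L, 1000L, 2000L))
  expect_true("stage_label" %in% names(tr))
  expect_error(suppressMessages(run_analyze(waveform_record(rnorm(1000),
                                                            fs = 200))),
               "no complete")
})

test_that("analysis output CSVs are reproducible byte for byte", {
  rec <- make_experiment("baseline", seed = 31)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(run_analyze(rec, output = p1))
  suppressMessages(run_analyze(rec, output = p2))
  expect_identical(readLines(p1), readLines(p2))
  # provenance header present and re-readable
  expect_true(any(grepl("^# m: 6", readLines(p1))))
  back <- read_track_csv(p1)
  expect_identical(nrow(back), length(window_starts(length(rec), 3600, 1000)))
})

test_that("compliance columns are appended when volume is present", {
  rec <- make_experiment("reversible_episode", seed = 12)
  tr <- suppressMessages(run_analyze(rec))
  expect_true(all(c("dv", "dicp", "icc") %in% names(tr)))
  ok <- !is.na(tr$icc)
  expect_gt(sum(ok), 0)
  expect_equal(tr$icc[ok] * tr$dicp[ok], tr$dv[ok], tolerance = 1e-12)
})

test_that("per-stage summaries use the standard median", {
  one <- data.frame(t_start_s = 0, mean_icp = 5, pe = 0.4, nmp_norm = 0.7,
                    p_first = 0.3, p_last = 0.2, stage_label = "injury_free")
  rep1 <- run_report(one)
  expect_identical(rep1$summary$median_pe, 0.4)
  expect_identical(nrow(rep1$summary), 1L)
  allind <- data.frame(t_start_s = 0:3, mean_icp = 5, pe = c(0.1, 0.2, 0.3, 0.4),
                       nmp_norm = 0.5, p_first = 0.1, p_last = 0.4,
                       stage_label = "indeterminate")
  rep2 <- run_report(allind)
  expect_identical(rep2$summary$stage_label, "indeterminate")
  expect_equal(rep2$summary$median_pe, 0.25)  # even-length median
  expect_named(rep2$plots, c("icp_pe", "icp_nmp", "nmp_box"))
  expect_error(run_report(one[0, ]), "non-empty")
  expect_error(run_report(one[, -7]), "stage_label")
})

test_that("report files land in the output directory", {
  rec <- make_experiment("baseline", seed = 13)
  tr <- suppressMessages(run_analyze(rec))
  dir <- withr::local_tempdir()
  run_report(tr, output_dir = dir)
  expect_true(file.exists(file.path(dir, "stage_summary.csv")))
  expect_true(all(file.exists(file.path(dir, c("icp_pe.png", "icp_nmp.png",
                                               "nmp_box.png")))))
})
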