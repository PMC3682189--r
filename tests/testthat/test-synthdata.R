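test_that("schedules have exact class counts and no immediate repeats", {
  for (seed in 1:25) {
    s <- make_schedule(3, 20, seed = seed)
    expect_equal(nrow(s), 60)
    expect_equal(as.integer(table(s$class_label)), rep(20L, 3))
    expect_false(any(diff(s$class_label) == 0))
    expect_true(all(diff(s$recall_onset_s) > 0))
  }
  # uneven class counts still respect the constraint
  s <- make_schedule(4, 7, seed = 11)
  expect_false(any(diff(s$class_label) == 0))
})

test_that("schedule onsets are regularly spaced by recall + gap + cue", {
  s <- make_schedule(3, 5, seed = 2, recall_duration_s = 7,
                     inter_trial_gap_s = 12, cue_duration_s = 2)
  expect_equal(diff(s$recall_onset_s), rep(21, 14))
  expect_equal(s$recall_onset_s - s$cue_onset_s, rep(2, 15))
})

test_that("schedule generation is deterministic and rejects one class", {
  expect_identical(make_schedule(3, 6, seed = 9), make_schedule(3, 6, seed = 9))
  expect_error(make_schedule(1, 3, seed = 1), "unsatisfiable")
  # two trials, two classes: both orderings are legal, constraints hold
  s <- make_schedule(2, 1, seed = 4)
  expect_equal(sort(s$class_label), 1:2)
  # tiny case checked against the full constraint set
  s6 <- make_schedule(3, 2, seed = 7)
  expect_equal(as.integer(table(s6$class_label)), rep(2L, 3))
  expect_false(any(diff(s6$class_label) == 0))
})

test_that("canonical HRF has the double-gamma shape", {
  tg <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_equal(tg[which.max(h)], 6, tolerance = 0.02)
  expect_lt(h[tg == 16], 0)                  # undershoot
  expect_lt(abs(h[tg == 32]), 0.01)          # decayed by 32 s
  expect_error(canonical_hrf(numeric(0)), "empty")
  expect_error(canonical_hrf(c(3, 2, 1)), "increasing")
})

test_that("simulated behaviour produces the three exclusion mechanisms", {
  s <- make_schedule(3, 20, seed = 1)
  b0 <- simulate_behaviour(s, 0, seed = 2)
  f0 <- filter_trials(b0)
  expect_true(all(f0$included))

  b <- simulate_behaviour(s, 0.5, seed = 3)
  f <- filter_trials(b)
  flagged <- sum(!f$included)
  expect_equal(nrow(f) - flagged, sum(f$included))  # recount
  expect_gt(flagged, 0)
  expect_true(all(f$exclude_reason[!f$included] %in%
                    c("too_fast", "too_slow", "low_rating")))
  # every premature press is flagged
  fast <- !is.na(f$press_latency_s) & f$press_latency_s < 5.5
  expect_true(all(!f$included[fast]))
  # retained trials respect window and ratings
  kept <- f[f$included, ]
  expect_true(all(kept$press_latency_s >= 5.5 & kept$press_latency_s <= 10))
  expect_true(all(kept$vividness >= 3 & kept$accuracy >= 3))
  expect_error(simulate_behaviour(s, 1, seed = 1), "exclusion_rate")
})

test_that("simulate_run is deterministic and validates its config", {
  cfg <- micro_config(seed = 5, grid = c(10, 10, 6), radii = c(1.5, 1.5, 1),
                      n_trials_per_class = 3)
  a <- simulate_run(cfg)
  b <- simulate_run(cfg)
  expect_identical(a$run$data, b$run$data)
  expect_identical(a$trials, b$trials)

  expect_error(synth_config(signal_amplitude = -1), "nonnegative")
  expect_error(
    synth_config(roi_specs = list(
      roi_spec("A", "L", c(5, 5, 5), c(2, 2, 2)),
      roi_spec("B", "R", c(6, 5, 5), c(2, 2, 2)))),
    "overlap")
  expect_error(
    synth_config(roi_specs = list(roi_spec("A", "L", c(1, 5, 5), c(3, 2, 2)))),
    "outside the grid")
})

test_that("run covers all trials plus the leading dummy volumes", {
  cfg <- micro_config(seed = 2, n_trials_per_class = 12)
  sim <- simulate_run(cfg)
  expect_equal(sum(filter_trials(sim$trials)$included), 36)
  nvol <- dim(sim$run$data)[4]
  last <- max(sim$trials$recall_onset_s)
  expect_gte(nvol, 6 + ceiling(last / cfg$tr_s))
  # extraction window of the last trial fits after preprocessing
  pp <- discard_dummies(sim$run)
  expect_gte(dim(pp$data)[4], floor(last / cfg$tr_s) + 3 + 4)
})

test_that("planted signal is linear in amplitude and absent at amplitude 0", {
  base <- list(grid = c(10, 10, 6), radii = c(1.5, 1.5, 1),
               n_trials_per_class = 3)
  cfg1 <- micro_config(seed = 8, signal_amplitude = 1, noise_sd = 0,
                       grid = base$grid, radii = base$radii,
                       n_trials_per_class = base$n_trials_per_class)
  cfg2 <- micro_config(seed = 8, signal_amplitude = 2, noise_sd = 0,
                       grid = base$grid, radii = base$radii,
                       n_trials_per_class = base$n_trials_per_class)
  cfg1$drift_slope <- 0; cfg2$drift_slope <- 0
  r1 <- simulate_run(cfg1); r2 <- simulate_run(cfg2)
  expect_equal(r2$run$data, 2 * r1$run$data, tolerance = 1e-12)

  # amplitude 0: per-class voxel means in the ROI are statistically equal
  cfg0 <- micro_config(seed = 21, signal_amplitude = 0)
  ps <- micro_patterns(cfg0)
  ps_f <- vapply(seq_len(ncol(ps$X)), function(j)
    summary(aov(ps$X[, j] ~ factor(ps$y)))[[1]][["Pr(>F)"]][1], numeric(1))
  # no voxel should show a wildly extreme class effect; p-values ~ uniform
  expect_gt(min(ps_f), 0.001 / length(ps_f))
  expect_gt(mean(ps_f > 0.05), 0.7)
})

test_that("after detrending, the fitted per-voxel drift slope vanishes", {
  cfg <- micro_config(seed = 4, grid = c(8, 8, 4), radii = c(1.5, 1.5, 1),
                      n_trials_per_class = 3)
  cfg$drift_slope <- 0.5
  sim <- simulate_run(cfg)
  det <- linear_detrend(discard_dummies(sim$run))
  nt <- dim(det$data)[4]
  M <- matrix(det$data, ncol = nt)
  tt <- seq_len(nt) - 1
  slopes <- apply(M[1:20, ], 1, function(v) coef(lm(v ~ tt))[2])
  expect_lt(max(abs(slopes)), 1e-10)
})

test_that("silent ROIs decode at chance even with strong common activation", {
  accs <- vapply(1:4, function(s) {
    cfg <- micro_config(seed = 30 + s, signal_amplitude = 2,
                        signal_present = FALSE, n_trials_per_class = 6,
                        grid = c(12, 12, 6), radii = c(2, 1.5, 1))
    loto_crossval(micro_patterns(cfg))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("synthetic outputs round-trip through NIfTI and TSV", {
  cfg <- micro_config(seed = 6, grid = c(8, 8, 4), radii = c(1.5, 1.5, 1),
                      n_trials_per_class = 2, exclusion_rate = 0.3)
  sim <- simulate_run(cfg)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "run.nii.gz")
  write_bold_nifti(sim$run, p1)
  back <- read_bold_nifti(p1)
  expect_equal(back$data, sim$run$data, tolerance = 1e-6)
  expect_equal(back$tr_s, 3.5)
  expect_equal(back$voxel_size_mm, 1.5)

  p2 <- file.path(td, "mask.nii.gz")
  write_roi_nifti(sim$masks[[1]], p2)
  m <- read_roi_nifti(p2, "HC", "R")
  expect_identical(m$mask, sim$masks[[1]]$mask)

  p3 <- file.path(td, "trials.tsv")
  write_trials_tsv(sim$trials, p3)
  tt <- read_trials_tsv(p3)
  expect_equal(tt$class_label, sim$trials$class_label)
  expect_equal(tt$recall_onset_s, sim$trials$recall_onset_s)
})
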