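make_run <- function(arr) bold_run(arr, tr_s = 3.5, voxel_size_mm = 1.5)

test_that("dummy discard drops exactly the leading volumes", {
  arr <- array(seq_len(2 * 2 * 2 * 100), dim = c(2, 2, 2, 100))
  run <- make_run(arr)
  out <- discard_dummies(run, 6)
  expect_equal(dim(out$data)[4], 94)
  expect_equal(out$data[1, 1, 1, 1], arr[1, 1, 1, 7])
  expect_identical(discard_dummies(run, 0), run)
  expect_error(discard_dummies(run, 100), "cannot discard")
  # raw volume 8 becomes volume 2 after dropping six dummies
  expect_equal(adjust_onsets(8L, 6L), 2L)
  expect_error(adjust_onsets(3L, 6L), "dummies")
})

test_that("Gaussian smoothing preserves constants and matches the kernel", {
  arr <- array(5, dim = c(8, 8, 8, 2))
  run <- make_run(arr)
  expect_identical(smooth_gaussian(run, 0), run)
  sm <- smooth_gaussian(run, 3)
  expect_equal(sm$data, arr, tolerance = 1e-12)   # constants preserved
  expect_error(smooth_gaussian(run, -1), "nonnegative")

  # unit impulse: centre value equals the cube of the 1-D kernel weight
  imp <- array(0, dim = c(9, 9, 9, 1))
  imp[5, 5, 5, 1] <- 1
  fwhm <- 2 * 1.5   # two voxels
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / 1.5
  R <- ceiling(3.5 * sigma)
  k <- exp(-0.5 * (-R:R)^2 / sigma^2)
  k <- k / sum(k)
  sm2 <- smooth_gaussian(make_run(imp), fwhm)
  expect_equal(sm2$data[5, 5, 5, 1], k[R + 1]^3, tolerance = 1e-12)
  expect_equal(sum(sm2$data), 1, tolerance = 1e-12)  # mass conserved
})

test_that("linear detrending annihilates affine series and is idempotent", {
  nt <- 40
  tt <- 0:(nt - 1)
  arr <- array(0, dim = c(2, 2, 1, nt))
  arr[1, 1, 1, ] <- 2 + 0.5 * tt
  arr[2, 1, 1, ] <- sin(tt / 3)
  arr[1, 2, 1, ] <- sin(tt / 3) + 7 - 1.2 * tt
  run <- make_run(arr)
  out <- linear_detrend(run)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-10)
  # adding an affine trend leaves the projection unchanged
  expect_equal(out$data[2, 1, 1, ], out$data[1, 2, 1, ], tolerance = 1e-10)
  # refit slope is zero
  fit <- coef(lm(out$data[2, 1, 1, ] ~ tt))
  expect_lt(abs(fit[2]), 1e-10)
  # idempotence
  twice <- linear_detrend(out)
  expect_equal(twice$data, out$data, tolerance = 1e-10)
})

test_that("HRF convolution is causal and matches a direct oracle", {
  nt <- 30
  x <- rnorm(nt)
  arr <- array(rep(x, each = 1), dim = c(1, 1, 1, nt))
  run <- make_run(arr)
  expect_identical(hrf_convolve(run, 1)$data, run$data)   # delta kernel
  h <- c(0, 0.8, 0.4, -0.1)
  out <- hrf_convolve(run, h)$data[1, 1, 1, ]
  # direct convolution oracle
  ref <- vapply(seq_len(nt), function(t)
    sum(h[seq_len(min(t, length(h)))] * x[t - seq_len(min(t, length(h))) + 1]),
    numeric(1))
  expect_equal(out, ref, tolerance = 1e-12)
  # step input -> cumulative sum of the kernel
  step <- make_run(array(1, dim = c(1, 1, 1, nt)))
  so <- hrf_convolve(step, h)$data[1, 1, 1, ]
  expect_equal(so[seq_along(h)], cumsum(h), tolerance = 1e-12)
  expect_equal(so[nt], sum(h), tolerance = 1e-12)
  # no future leakage: changing late samples leaves early output alone
  x2 <- x; x2[20:nt] <- 99
  out2 <- hrf_convolve(make_run(array(x2, dim = c(1, 1, 1, nt))), h)$data[1, 1, 1, ]
  expect_equal(out2[1:19], out[1:19], tolerance = 1e-12)
  expect_error(hrf_convolve(run, numeric(0)), "empty")
})

test_that("onset shift rounds the delay to the nearest volume", {
  expect_identical(compute_onset_shift(3.5, 12), 3L)
  expect_identical(compute_onset_shift(2, 0), 0L)
  expect_identical(compute_onset_shift(2, 5), 3L)  # half away from zero
  expect_identical(compute_onset_shift(3.5, 10), 3L)
  expect_error(compute_onset_shift(0, 12), "positive")
})

test_that("trial screening applies inclusive boundaries and reason codes", {
  tr <- data.frame(trial_index = 1:6, class_label = c(1, 2, 3, 1, 2, 3),
                   recall_onset_s = seq(0, 100, length.out = 6),
                   press_latency_s = c(5.5, 4.0, 10.0, 10.5, NA, 7),
                   vividness = c(3, 5, 5, 4, 4, 5),
                   accuracy = c(3, 5, 5, 4, 4, 2))
  f <- filter_trials(tr)
  expect_equal(f$included, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$exclude_reason[2], "too_fast")
  expect_equal(f$exclude_reason[4], "too_slow")
  expect_equal(f$exclude_reason[5], "too_slow")   # missing press
  expect_equal(f$exclude_reason[6], "low_rating")
  expect_error(filter_trials(transform(tr, vividness = 7)), "1..5")
})

test_that("pattern extraction windows, averaging and masking are exact", {
  nt <- 24
  dims <- c(3, 3, 2, nt)
  arr <- array(rnorm(prod(dims)), dim = dims)
  run <- make_run(arr)
  mask <- roi_mask("HC", "L", array(c(TRUE, rep(FALSE, 8), TRUE,
                                      rep(FALSE, 8)), dim = c(3, 3, 2)))
  tr <- data.frame(trial_index = 1:2, class_label = c(1, 2),
                   recall_onset_s = c(7.5, 28), press_latency_s = c(6, 6),
                   vividness = c(4, 4), accuracy = c(4, 4))
  ps <- extract_trial_patterns(run, tr, mask, shift_volumes = 3,
                               n_vols_per_trial = 4)
  # trial 1: floor(7.5/3.5)=2, +3 shift -> volumes 6..9 (1-based)
  w <- 6:9
  expect_equal(ps$X[1, 1], mean(arr[1, 1, 1, w]))
  expect_equal(ps$X[1, 2], mean(arr[1, 1, 2, w]))
  expect_equal(ps$y, c(1L, 2L))
  # voxel coordinates identify the extracted columns (ordering contract)
  for (j in seq_len(ncol(ps$X))) {
    cc <- ps$voxel_coords[j, ]
    # trial 2: floor(28/3.5)=8, +3 shift -> volumes 12..15
    expect_equal(ps$X[2, j], mean(arr[cc[1], cc[2], cc[3], 12:15]))
  }
  # n_vols_per_trial = 1 is the single shifted volume
  ps1 <- extract_trial_patterns(run, tr, mask, 3, n_vols_per_trial = 1)
  expect_equal(ps1$X[1, 1], arr[1, 1, 1, 6])
  # per-volume mode keeps each volume as a row
  psv <- extract_trial_patterns(run, tr, mask, 3, n_vols_per_trial = 4,
                                average = FALSE)
  expect_equal(nrow(psv$X), 8)
  expect_equal(psv$y, rep(c(1L, 2L), each = 4))
  # window overflow names the trial
  tr_bad <- transform(tr, recall_onset_s = c(7.5, 80))
  expect_error(extract_trial_patterns(run, tr_bad, mask, 3), "trial 2")
  # excluded trials drop out; all excluded -> zero rows
  tr$included <- c(FALSE, FALSE)
  ps0 <- extract_trial_patterns(run, tr, mask, 3)
  expect_equal(nrow(ps0$X), 0)
})

test_that("pattern row count always equals the included-trial count", {
  for (seed in c(3, 9)) {
    cfg <- micro_config(seed = seed, exclusion_rate = 0.4,
                        n_trials_per_class = 8, grid = c(10, 10, 6),
                        radii = c(1.5, 1.5, 1))
    sim <- simulate_run(cfg)
    pp <- preprocess_run(sim$run)
    trials <- filter_trials(sim$trials)
    ps <- extract_trial_patterns(pp, trials, sim$masks[[1]],
                                 compute_onset_shift(cfg$tr_s, 12))
    expect_equal(nrow(ps$X), sum(trials$included))
    expect_true(all(is.finite(ps$X)))
  }
})

test_that("pattern sets round-trip through CSV + JSON", {
  ps <- toy_patterns()
  ps$tr_s <- 3.5; ps$shift_volumes <- 3L
  td <- withr::local_tempdir()
  write_pattern_set(ps, file.path(td, "pat"))
  back <- read_pattern_set(file.path(td, "pat"))
  expect_equal(back$X, ps$X, tolerance = 1e-12)
  expect_identical(back$y, ps$y)
  expect_equal(back$voxel_coords, matrix(as.integer(ps$voxel_coords),
                                         ncol = 3), ignore_attr = TRUE)
})
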