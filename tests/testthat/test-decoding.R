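test_that("searchlight membership follows the lattice-sphere geometry", {
  # interior voxel of a large ROI at radius 3: 123 lattice points
  # (independent enumeration oracle)
  offs <- expand.grid(dx = -3:3, dy = -3:3, dz = -3:3)
  n123 <- sum(offs$dx^2 + offs$dy^2 + offs$dz^2 <= 9)
  expect_equal(n123, 123)

  mask <- roi_mask("box", "L", array(TRUE, dim = c(9, 9, 9)))
  sls <- build_searchlights(mask, 3)
  expect_equal(length(sls), 9^3)
  centre_sl <- sls[[which(vapply(sls, function(s)
    all(s$centre == c(5, 5, 5)), logical(1)))]]
  expect_equal(length(centre_sl$members), 123)
  expect_true(centre_sl$centre_col %in% centre_sl$members)
  # corner sphere is clipped by the ROI border
  corner <- sls[[1]]
  expect_lt(length(corner$members), 123)
  # 1-voxel ROI: a single self-sphere
  m1 <- array(FALSE, dim = c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  sl1 <- build_searchlights(roi_mask("dot", "L", m1), 3)
  expect_equal(length(sl1), 1)
  expect_equal(sl1[[1]]$members, 1L)
})

test_that("linear SVM solves the margin problem and matches LIBSVM", {
  skip_if_not_installed("e1071")
  # 1-D symmetric pair: boundary at zero, positive weight
  f <- train_binary(matrix(c(-1, 1), 2), c(-1, 1))
  expect_equal(f$bias, 0, tolerance = 1e-8)
  expect_gt(f$weights, 0)
  expect_equal(predict(f, matrix(c(-2, 0.5), 2)), c(-1L, 1L))

  # duplicated separable points leave the boundary unchanged
  set.seed(1)
  X <- rbind(matrix(rnorm(10, -2), 5), matrix(rnorm(10, 2), 5))
  y <- rep(c(-1, 1), each = 5)
  f1 <- train_binary(X, y)
  f2 <- train_binary(rbind(X, X[c(2, 7), , drop = FALSE]), c(y, y[c(2, 7)]))
  expect_equal(f2$weights, f1$weights, tolerance = 1e-3)
  expect_equal(f2$bias, f1$bias, tolerance = 1e-3)

  # XOR is not linearly separable: at most 3 of 4 training points correct
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- c(1, 1, -1, -1)
  fx <- train_binary(Xx, yx, c_param = 100)
  expect_lte(mean(predict(fx, Xx) == yx), 0.75)

  expect_error(train_binary(X, rep(1, 10)), "both classes")

  # decision values agree with the LIBSVM reference on random problems
  set.seed(42)
  for (i in 1:25) {
    n <- sample(8:30, 1); p <- sample(2:8, 1)
    Xi <- matrix(rnorm(n * p), n)
    yi <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(yi)) < 2) next
    mine <- train_binary(Xi, yi)
    dec_my <- drop(Xi %*% mine$weights + mine$bias)
    ref <- e1071::svm(Xi, factor(yi, levels = c(-1, 1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    w_ref <- drop(t(ref$coefs) %*% ref$SV)
    dec_ref <- drop(Xi %*% w_ref) - ref$rho
    # both optima attain the same primal objective
    obj <- function(w, b) 0.5 * sum(w^2) +
      sum(pmax(0, 1 - yi * drop(Xi %*% w + b)))
    expect_equal(obj(mine$weights, mine$bias),
                 min(obj(w_ref, -ref$rho), obj(-w_ref, ref$rho)),
                 tolerance = 1e-3)
    # e1071 orients decisions toward its first factor level; compare up to
    # that global sign, skipping degenerate w ~ 0 optima where the
    # decision function is not unique
    if (sum(w_ref^2) > 1e-6) {
      d <- min(max(abs(dec_my - dec_ref)), max(abs(dec_my + dec_ref)))
      expect_lt(d, 1e-2)
    }
  }
})

test_that("exhaustive ECOC codebooks are valid and Hamming decoding exact", {
  cb <- ecoc_codebook(3)
  expect_equal(dim(cb), c(3L, 3L))                  # 2^(3-1) - 1 dichotomies
  expect_equal(ncol(ecoc_codebook(4)), 7)
  expect_equal(dim(ecoc_codebook(2)), c(2L, 1L))    # reduces to one split
  expect_true(all(cb %in% c(-1L, 1L)))
  expect_false(any(duplicated(cb)))                 # distinct codewords
  expect_true(all(apply(cb, 2, function(col) length(unique(col)) == 2)))

  # brute-force minimal-distance oracle over all 8 bit patterns
  brute <- function(bits) {
    d <- apply(cb, 1, function(cw) sum(cw != bits))
    unname(which(d == min(d))[1])
  }
  grid <- expand.grid(b1 = c(-1, 1), b2 = c(-1, 1), b3 = c(-1, 1))
  for (i in seq_len(nrow(grid))) {
    bits <- as.integer(grid[i, ])
    expect_identical(hamming_nearest(bits, cb), brute(bits))
  }
  # exact codeword match decodes to its class
  for (k in 1:3) expect_identical(hamming_nearest(cb[k, ], cb), k)
})

test_that("ECOC training relabels per dichotomy and predicts separably", {
  ps <- toy_patterns(n_per_class = 3, n_noise_vox = 2)
  cb <- ecoc_codebook(3)
  fits <- ecoc_train(ps, cb)
  expect_length(fits, 3)
  # perfectly separable: every binary classifier is perfect on training data
  for (j in 1:3) {
    ybin <- cb[ps$y, j]
    expect_equal(predict(fits[[j]], ps$X), ybin, ignore_attr = TRUE)
  }
  preds <- vapply(seq_len(nrow(ps$X)), function(i)
    ecoc_predict(fits, cb, ps$X[i, ]), integer(1))
  expect_equal(preds, ps$y)
  # missing class -> named column error
  bad <- ps; bad$y[bad$y == 3] <- 2
  expect_error(ecoc_train(bad, cb), "column")
})

test_that("searchlight scoring is chance-calibrated and finds signal", {
  # perfectly separable single voxel: nested LOTO accuracy 1
  ps <- toy_patterns(n_per_class = 4, n_noise_vox = 0)
  expect_equal(score_searchlight(ps), 1)

  # class absent from the patterns is an error
  ps3 <- toy_patterns()
  expect_error(score_searchlight(ps3, codebook = ecoc_codebook(4)),
               "present")

  # three trials, one per class: every nested fold strips the held-out
  # trial's class from training, so all folds are skipped
  ps4 <- toy_patterns(n_per_class = 1, n_noise_vox = 0)
  expect_error(score_searchlight(ps4), "degenerate")
})

test_that("feature selection picks the informative sphere deterministically", {
  set.seed(11)
  n <- 18
  y <- rep(1:3, each = 6)
  # voxel columns 1:3 carry signal; 4:12 are noise
  X <- cbind(outer(y, 1:3) + matrix(rnorm(n * 3, sd = 0.1), n),
             matrix(rnorm(n * 9), n))
  coords <- cbind(seq_len(ncol(X)) * 10, 1L, 1L)  # isolated voxels
  sls <- build_searchlights(coords, radius_voxels = 3)
  expect_length(sls, 12)
  ps <- list(X = X, y = y)
  best <- select_features(ps, sls)
  expect_true(best$centre_col %in% 1:3)

  # single searchlight is returned regardless of score
  one <- select_features(ps, sls[5])
  expect_equal(one$centre_col, 5)

  # identical data in all spheres: lowest centre index wins
  Xc <- matrix(rep(rnorm(n), 4), n)
  pc <- list(X = Xc, y = y)
  slc <- build_searchlights(cbind(c(10, 20, 30, 40), 1L, 1L), 3)
  expect_equal(select_features(pc, slc)$centre_col, 1)
})

test_that("leave-one-trial-out decoding recovers planted signal", {
  cfg <- micro_config(seed = 12, signal_amplitude = 1, noise_sd = 1)
  ps <- micro_patterns(cfg)
  res <- loto_crossval(ps)
  expect_equal(res$n_folds, nrow(ps$X))
  expect_equal(res$accuracy,
               mean(res$folds$predicted_label == res$folds$true_label))
  expect_gt(res$accuracy, 0.45)
  # determinism
  res2 <- loto_crossval(ps)
  expect_identical(res$folds, res2$folds)
  # class with < 2 trials is rejected
  bad <- ps
  keep <- c(which(bad$y == 1)[1], which(bad$y != 1))
  bad$X <- bad$X[keep, ]; bad$y <- bad$y[keep]
  bad$trial_index <- bad$trial_index[keep]
  expect_error(loto_crossval(bad), ">= 2 trials")
})

test_that("uninformative features decode at chance", {
  set.seed(3)
  y <- rep(1:3, each = 6)
  coords <- cbind(1:5, 1L, 1L)
  accs <- replicate(8, {
    # one constant voxel plus pure-noise voxels: no class information
    X <- cbind(1, matrix(rnorm(length(y) * 4), ncol = 4))
    loto_crossval(list(X = X, y = y, voxel_coords = coords))$accuracy
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("label permutation leaves the full decoder at chance", {
  cfg <- micro_config(seed = 99, signal_amplitude = 0,
                      n_trials_per_class = 12, grid = c(12, 12, 6),
                      radii = c(1.5, 1.5, 1))
  ps <- micro_patterns(cfg)
  set.seed(7)
  perms <- replicate(200, {
    p <- ps
    p$y <- sample(p$y)
    loto_crossval(p)$accuracy
  })
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - 1 / 3), 3 * max(se, 0.005))
})

test_that("held-out trial features cannot influence their own fold", {
  cfg <- micro_config(seed = 14, n_trials_per_class = 4,
                      grid = c(12, 12, 6), radii = c(2, 1.5, 1))
  ps <- micro_patterns(cfg)
  res <- loto_crossval(ps)
  for (t in c(1, 5, 9)) {
    mut <- ps
    mut$X[t, ] <- rnorm(ncol(mut$X)) * 50 + 100
    res_mut <- loto_crossval(mut)
    # fold t's searchlight selection is bit-identical
    expect_identical(res_mut$folds$sphere_index[t], res$folds$sphere_index[t])
  }
})

test_that("decoding accuracy is nondecreasing in signal amplitude", {
  amps <- c(0, 0.35, 1)
  means <- vapply(amps, function(a) {
    mean(vapply(1:20, function(s) {
      cfg <- micro_config(seed = 100 + s, signal_amplitude = a,
                          n_trials_per_class = 6, grid = c(12, 12, 6),
                          radii = c(1.5, 1.5, 1))
      loto_crossval(micro_patterns(cfg))$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= -0.02))
  expect_gt(means[3], means[1] + 0.15)
})
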