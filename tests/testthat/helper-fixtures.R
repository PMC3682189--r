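# Shared micro-scale fixtures, built in code at test time.

# single signal ROI on a small grid; fast to simulate and decode
micro_config <- function(seed, signal_amplitude = 1, noise_sd = 1,
                         n_trials_per_class = 12, exclusion_rate = 0,
                         signal_present = TRUE, grid = c(16, 16, 8),
                         radii = c(2.5, 2, 1.5)) {
  synth_config(grid_shape = grid,
               n_trials_per_class = n_trials_per_class,
               exclusion_rate = exclusion_rate,
               signal_amplitude = signal_amplitude, noise_sd = noise_sd,
               roi_specs = list(roi_spec("HC", "R", round(grid / 2), radii,
                                         signal_present = signal_present)),
               seed = seed)
}

# simulate + preprocess + extract patterns for the micro config's single ROI
micro_patterns <- function(cfg) {
  sim <- simulate_run(cfg)
  pp <- preprocess_run(sim$run)
  trials <- filter_trials(sim$trials)
  shift <- compute_onset_shift(cfg$tr_s, 12)
  extract_trial_patterns(pp, trials, sim$masks[[1]], shift)
}

# small separable pattern set: the first n_classes voxels one-hot encode the
# class, so every dichotomy of every ECOC codebook is linearly separable
toy_patterns <- function(n_per_class = 4, n_classes = 3, n_noise_vox = 5,
                         seed = 1) {
  set.seed(seed)
  y <- rep(seq_len(n_classes), each = n_per_class)
  onehot <- outer(y, seq_len(n_classes), `==`) + 0
  X <- cbind(onehot, matrix(rnorm(length(y) * n_noise_vox),
                            nrow = length(y)))
  coords <- cbind(seq_len(ncol(X)), 1L, 1L)
  structure(list(X = X, y = y, voxel_coords = coords, roi_label = "toy",
                 hemisphere = "L", trial_index = seq_along(y)),
            class = "trial_pattern_set")
}
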