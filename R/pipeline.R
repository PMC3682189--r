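#' Configuration for a simulated multi-subject decoding experiment
#'
#' Bundles the cohort description (number of subjects, which ROIs are
#' silenced per subject) with every preprocessing and decoding parameter.
#' Defaults are the modelled study's constants: TR 3.5 s, 6 dummy volumes,
#' 3 mm FWHM smoothing, 12 s total haemodynamic delay, 4 volumes per trial,
#' searchlight radius 3 voxels, C = 1, press window 5.5-10 s, minimum
#' rating 3.  The default cohort is the "left-HS" configuration: nine
#' subjects whose left hippocampus carries no class-specific signal while
#' all other MTL regions do.
#'
#' @param n_subjects cohort size (default 9).
#' @param master_seed integer seed; per-subject seeds are derived with
#'   [derive_subject_seed()].
#' @param silent_rois character vector of "label_hemisphere" ids silenced in
#'   every subject (default \code{"HC_L"}).
#' @param synth named list of overrides passed to [synth_config()].
#' @param fwhm_mm,delay_s,n_vols_per_trial,radius_voxels,c_param,n_dummies
#'   preprocessing and decoding parameters.
#' @param min_press_s,max_press_s,min_rating trial screening thresholds.
#' @param roi_jitter per-subject uniform fractional jitter applied to ROI
#'   semi-axes so ROI volumes vary across subjects (0 disables).
#' @param score_mode searchlight scoring mode ("nested" or "training").
#' @return a validated \code{experiment_config} list.
#' @export
experiment_config <- function(n_subjects = 9, master_seed = 1,
                              silent_rois = "HC_L", synth = list(),
                              fwhm_mm = 3, delay_s = 12,
                              n_vols_per_trial = 4, radius_voxels = 3,
                              c_param = 1, n_dummies = 6,
                              min_press_s = 5.5, max_press_s = 10,
                              min_rating = 3, roi_jitter = 0.15,
                              score_mode = "nested") {
  cfg <- list(n_subjects = as.integer(n_subjects),
              master_seed = as.integer(master_seed),
              silent_rois = as.character(silent_rois), synth = synth,
              fwhm_mm = fwhm_mm, delay_s = delay_s,
              n_vols_per_trial = as.integer(n_vols_per_trial),
              radius_voxels = radius_voxels, c_param = c_param,
              n_dummies = as.integer(n_dummies),
              min_press_s = min_press_s, max_press_s = max_press_s,
              min_rating = min_rating, roi_jitter = roi_jitter,
              score_mode = score_mode)
  stopifnot(cfg$n_subjects >= 1, cfg$roi_jitter >= 0, cfg$roi_jitter < 1)
  class(cfg) <- "experiment_config"
  cfg
}

#' Save / load an experiment configuration as JSON
#'
#' The representation round-trips: \code{load_config(save_config(cfg))}
#' reproduces the configuration exactly.
#'
#' @param cfg an [experiment_config()].
#' @param path JSON file path.
#' @return \code{save_config} returns \code{path} invisibly;
#'   \code{load_config} returns the configuration.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$synth <- as.list(raw$synth)
  if (length(raw$synth) == 0) raw$synth <- list()
  do.call(experiment_config, raw)
}

#' Derive a per-subject seed from the master seed
#'
#' Counter-based mixing: two rounds of the multiplicative-congruential step
#' \code{h <- (h * 48271 + k) mod (2^31 - 1)} seeded from the master seed
#' with the subject index injected between rounds.  The map is affine and
#' invertible in the subject index modulo 2^31 - 1, so seeds are
#' collision-free across subject indices for any fixed master seed.
#'
#' @param master_seed nonnegative integer.
#' @param subject_index nonnegative integer.
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_subject_seed <- function(master_seed, subject_index) {
  stopifnot(master_seed >= 0, subject_index >= 0)
  m <- 2147483647
  h <- (as.numeric(master_seed) %% m)
  h <- (h * 48271 + as.numeric(subject_index) + 1) %% m
  h <- (h * 48271 + 12345) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Per-subject synthetic-session configuration
#'
#' Derives the subject's seed from the master seed, applies the cohort's
#' ROI layout (including the silent regions and the per-subject radius
#' jitter) and returns the fully resolved [synth_config()] for that
#' subject.  Both [simulate_subject()] and the staged analysis scripts use
#' this, so a cohort is identical whichever route generates it.
#'
#' @param exp_cfg an [experiment_config()].
#' @param subject_index 1-based subject number.
#' @return a [synth_config()].
#' @export
subject_synth_config <- function(exp_cfg, subject_index) {
  seed <- derive_subject_seed(exp_cfg$master_seed, subject_index)
  synth_args <- exp_cfg$synth
  if (is.null(synth_args$roi_specs)) {
    radii <- c(2.5, 2, 1.5)
    if (!is.null(synth_args$roi_radii)) {
      radii <- synth_args$roi_radii
      synth_args$roi_radii <- NULL
    }
    if (exp_cfg$roi_jitter > 0) {
      old <- .save_seed(); on.exit(.restore_seed(old))
      set.seed(seed + 7L)
      radii <- radii * runif(3, 1 - exp_cfg$roi_jitter,
                             1 + exp_cfg$roi_jitter)
    }
    synth_args$roi_specs <- default_roi_specs(silent = exp_cfg$silent_rois,
                                              radii = radii)
  }
  synth_args$seed <- seed
  synth_args$n_dummy_volumes <- exp_cfg$n_dummies
  do.call(synth_config, synth_args)
}

#' Simulate and preprocess one subject, returning per-ROI pattern sets
#'
#' @param exp_cfg an [experiment_config()].
#' @param subject_index 1-based subject number.
#' @return list with \code{patterns} (named list of pattern sets, one per
#'   ROI), \code{trials}, \code{masks}, \code{roi_volumes_mm3},
#'   \code{seed}.
#' @export
simulate_subject <- function(exp_cfg, subject_index) {
  scfg <- subject_synth_config(exp_cfg, subject_index)
  seed <- scfg$seed
  sim <- simulate_run(scfg)

  pp <- preprocess_run(sim$run, n_dummies = exp_cfg$n_dummies,
                       fwhm_mm = exp_cfg$fwhm_mm,
                       hrf_params = scfg$hrf_params)
  trials <- filter_trials(sim$trials, exp_cfg$min_press_s,
                          exp_cfg$max_press_s, exp_cfg$min_rating)
  shift <- compute_onset_shift(scfg$tr_s, exp_cfg$delay_s)
  patterns <- lapply(sim$masks, function(m)
    extract_trial_patterns(pp, trials, m, shift,
                           n_vols_per_trial = exp_cfg$n_vols_per_trial))
  names(patterns) <- vapply(sim$masks, function(m)
    paste(m$label, m$hemisphere, sep = "_"), character(1))
  vols <- vapply(sim$masks, roi_volume_mm3, numeric(1),
                 voxel_size_mm = scfg$voxel_size_mm)
  names(vols) <- names(patterns)
  list(patterns = patterns, trials = trials, masks = sim$masks,
       roi_volumes_mm3 = vols, seed = seed, synth_config = scfg)
}

#' Decode every ROI of one simulated subject
#'
#' @param subject output of [simulate_subject()].
#' @param exp_cfg the [experiment_config()].
#' @return data frame with one row per ROI: subject accuracy and metadata.
#' @export
decode_subject <- function(subject, exp_cfg) {
  rows <- lapply(names(subject$patterns), function(id) {
    ps <- subject$patterns[[id]]
    res <- loto_crossval(ps, c_param = exp_cfg$c_param,
                         radius_voxels = exp_cfg$radius_voxels,
                         score_mode = exp_cfg$score_mode)
    data.frame(region = ps$roi_label, hemisphere = ps$hemisphere,
               n_trials = res$n_folds, accuracy = res$accuracy,
               roi_volume_mm3 = subject$roi_volumes_mm3[[id]])
  })
  do.call(rbind, rows)
}

#' Run the full simulate - preprocess - decode - group-stats experiment
#'
#' End-to-end driver: simulates each subject's session, preprocesses it,
#' decodes every ROI under leave-one-trial-out cross-validation with
#' searchlight feature selection, and computes the group statistics
#' (per-region t-tests against chance, paired left-right hippocampal
#' contrast, hemisphere-by-region repeated-measures ANOVA, and the
#' accuracy-volume Pearson correlation).  With a single subject the group
#' statistics are skipped with a notice.
#'
#' When \code{out_dir} is given, the accuracy table, group summary and a
#' JSON report are written there together with a manifest of file hashes
#' and the parameter snapshot; re-running with the same configuration
#' reproduces identical hashes.
#'
#' @param exp_cfg an [experiment_config()].
#' @param out_dir optional output directory.
#' @param verbose print per-subject progress.
#' @return list with \code{accuracy_table}, \code{summary} (mean, SEM and
#'   percentage per region x hemisphere), \code{group_stats},
#'   \code{exclusions} and \code{manifest}.
#' @export
run_experiment <- function(exp_cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(exp_cfg, "experiment_config"))
  acc <- list(); excl <- list()
  for (s in seq_len(exp_cfg$n_subjects)) {
    step <- sprintf("subject %d", s)
    sub <- tryCatch(simulate_subject(exp_cfg, s),
                    error = function(e) stop("simulate stage failed for ",
                                             step, ": ", conditionMessage(e)))
    d <- tryCatch(decode_subject(sub, exp_cfg),
                  error = function(e) stop("decode stage failed for ",
                                           step, ": ", conditionMessage(e)))
    d <- cbind(subject = s, d)
    acc[[s]] <- d
    ex <- sub$trials[!sub$trials$included, c("trial_index", "exclude_reason")]
    if (nrow(ex)) excl[[s]] <- cbind(subject = s, ex)
    if (verbose)
      message(sprintf("subject %d: %d trials, mean accuracy %.1f%%",
                      s, d$n_trials[1], 100 * mean(d$accuracy)))
  }
  accuracy_table <- do.call(rbind, acc)
  rownames(accuracy_table) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject = integer(0), trial_index = integer(0),
               exclude_reason = character(0))

  summary_tab <- do.call(rbind, lapply(
    split(accuracy_table,
          list(accuracy_table$region, accuracy_table$hemisphere)),
    function(d) data.frame(region = d$region[1], hemisphere = d$hemisphere[1],
                           mean_accuracy = mean(d$accuracy),
                           sem = sd(d$accuracy) / sqrt(nrow(d)),
                           mean_accuracy_pct = 100 * mean(d$accuracy),
                           chance = 1 / 3)))
  rownames(summary_tab) <- NULL

  group_stats <- NULL
  if (exp_cfg$n_subjects >= 2) {
    group_stats <- group_statistics(accuracy_table)
  } else {
    message("single-subject cohort: group statistics skipped")
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "accuracies.csv")
    fs <- file.path(out_dir, "summary.csv")
    fr <- file.path(out_dir, "report.json")
    utils::write.csv(accuracy_table, fa, row.names = FALSE)
    utils::write.csv(summary_tab, fs, row.names = FALSE)
    jsonlite::write_json(report_list(summary_tab, group_stats), fr,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(fa, fs, fr)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }

  list(accuracy_table = accuracy_table, summary = summary_tab,
       group_stats = group_stats, exclusions = exclusions,
       manifest = manifest, config = exp_cfg)
}

#' Group-level statistics for an accuracy table
#'
#' @param accuracy_table data frame with subject, region, hemisphere,
#'   accuracy and roi_volume_mm3 columns (one row per subject x ROI).
#' @return list of test results.
#' @export
group_statistics <- function(accuracy_table) {
  at <- accuracy_table
  cells <- split(at, list(at$region, at$hemisphere), drop = TRUE)
  # degenerate cells (zero variance, e.g. ceiling effects in tiny cohorts)
  # yield NULL rather than aborting the whole report
  vs_chance <- lapply(cells, function(d)
    tryCatch(t_vs_chance(d$accuracy), error = function(e) NULL))

  wide <- function(region, hemi)
    at$accuracy[at$region == region & at$hemisphere == hemi][
      order(at$subject[at$region == region & at$hemisphere == hemi])]
  regions <- sort(unique(at$region))
  pairwise_lr <- lapply(regions, function(r)
    tryCatch(paired_t(wide(r, "L"), wide(r, "R")), error = function(e) NULL))
  names(pairwise_lr) <- regions

  anova <- tryCatch(rm_anova_2x3(at), error = function(e) NULL)

  # accuracy-volume correlation within the (possibly sclerotic) left HC
  hc_l <- at[at$region == "HC" & at$hemisphere == "L", ]
  volume_cor <- if (nrow(hc_l) >= 3 && sd(hc_l$roi_volume_mm3) > 0)
    pearson_r(hc_l$accuracy, hc_l$roi_volume_mm3) else NULL

  list(vs_chance = vs_chance, pairwise_lr = pairwise_lr, anova = anova,
       volume_cor = volume_cor)
}

report_list <- function(summary_tab, group_stats) {
  rep <- list(summary = summary_tab)
  if (!is.null(group_stats)) {
    if (!is.null(group_stats$anova))
      rep$anova_interaction <- list(
        F = group_stats$anova$interaction$statistic,
        df = group_stats$anova$interaction$df,
        p = group_stats$anova$interaction$p)
    rep$vs_chance <- lapply(Filter(Negate(is.null), group_stats$vs_chance),
                            function(t)
                              list(t = t$statistic, df = t$df, p = t$p))
    if (!is.null(group_stats$volume_cor))
      rep$volume_cor <- list(r = group_stats$volume_cor$r,
                             p = group_stats$volume_cor$p)
  }
  rep
}
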