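# Scaled test configurations: identical scientific structure (burst rates,
# FACS map, planted effects) to the full-scale defaults, with reduced
# sampling rate and durations so the suite runs at desk scale.

test_synth_config <- function(n = 4, seed = 7, snr = 30, ...) {
  args <- utils::modifyList(
    list(n_participants = n, sample_rate = 50, scene_duration = 60,
         baseline_duration = 120, calibration_hold = 4,
         calibration_reps = 2, snr = snr, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

test_model_config <- function(seed = 11, ...) {
  expression_model(optimizer = list(lr = 1e-3, batch_size = 64,
                                    max_epochs = 15, patience = 4),
                   seed = seed, ...)
}

test_window <- function(cfg) {
  windowing_params(as.integer(cfg$sample_rate * cfg$window_duration))
}

# Calibration windows for a cohort: profile estimation, normalization,
# zero-overlap segmentation.
calibration_windows <- function(cohort) {
  wp <- test_window(cohort$config)
  wins <- list()
  for (p in names(cohort$calibration)) {
    prof <- compute_calibration_profile(cohort$calibration[[p]])
    nc <- normalize_recording(cohort$calibration[[p]], prof)
    wins <- c(wins, segment_windows(nc, wp))
  }
  wins
}

random_label_seq <- function(n, prob = NULL) {
  factor(sample(expression_levels(), n, replace = TRUE, prob = prob),
         levels = expression_levels())
}

# Expensive shared fixtures for the acceptance checks, computed once per
# test run.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.acceptance_cache$cohort))
    .acceptance_cache$cohort <- generate_cohort(
      test_synth_config(n = 12, seed = 42, snr = 30))
  .acceptance_cache$cohort
}

acceptance_lopo <- function() {
  if (is.null(.acceptance_cache$lopo)) {
    co <- acceptance_cohort()
    .acceptance_cache$windows <- calibration_windows(co)
    .acceptance_cache$lopo <- lopo_cross_validate(
      .acceptance_cache$windows, test_model_config(seed = 42))
  }
  .acceptance_cache$lopo
}

acceptance_windows <- function() {
  invisible(acceptance_lopo())
  .acceptance_cache$windows
}
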