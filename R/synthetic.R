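#' Configuration for the synthetic fEMG cohort generator
#'
#' Bundles every tunable of the simulator: cohort size, signal geometry,
#' burst process rates, amplitude ranges, and the linear-mixed-model used to
#' generate NASA-TLX workload ratings. Defaults reflect the acquisition
#' protocol the pipeline targets: 7 amplitude channels at 1000 Hz, 2-minute
#' stressor scenes, a 5-minute baseline scene, and 8 workload subscales on a
#' 0-10 scale.
#'
#' @param n_participants cohort size (>= 2; leave-one-participant-out needs
#'   at least 3 for model evaluation).
#' @param sample_rate sampling rate in Hz.
#' @param scene_duration stressor-scene length in seconds.
#' @param baseline_duration baseline-scene length in seconds.
#' @param window_duration expression-script step (and analysis window) length
#'   in seconds.
#' @param burst_rate_per_scene named list: scene -> named numeric vector of
#'   burst onset rates (bursts per minute of neutral occupancy) for the three
#'   non-neutral expressions. Defaults plant the scene ordering
#'   cognitive < baseline ~ emotional < physical ~ dual in non-neutral
#'   occupancy, with physical/dual bursts predominantly smiles and emotional
#'   bursts enriched in raised eyebrows.
#' @param burst_duration_range burst length range in seconds (uniform draw).
#' @param burst_peak_range burst peak amplitude as a fraction of the channel's
#'   MVIC-minus-tone span (uniform draw per burst).
#' @param snr amplitude signal-to-noise ratio: the additive Gaussian noise SD
#'   per channel is (mvic - tone) / snr.
#' @param baseline_tone_range per-channel resting-tone amplitude range.
#' @param mvic_range per-channel maximal-contraction amplitude range; must lie
#'   strictly above `baseline_tone_range`.
#' @param crosstalk optional mixing coefficient in \[0, 1): fraction of each
#'   channel replaced by the mean of the other channels (0 = off).
#' @param calibration_hold seconds each calibration block is held.
#' @param calibration_reps repetitions of each maximal expression in the
#'   calibration session.
#' @param calibration_ramp fraction of a maximal block spent ramping up/down.
#' @param subscales names of the 8 workload subscales.
#' @param tlx_intercept global rating intercept (0-10 scale units).
#' @param scene_effects named numeric: additive scene effect on ratings.
#' @param planted_betas named list: subscale -> named numeric vector of
#'   effects (rating units per SD) on z-scored expression features.
#' @param random_intercept_sd SD of the participant random intercept
#'   (rating units).
#' @param noise_sd residual rating noise SD (rating units).
#' @param seed integer master seed for [generate_cohort()].
#'
#' @return A list of class `femg_synth_config`.
#' @export
synthetic_config <- function(n_participants = 12,
                             sample_rate = 1000,
                             scene_duration = 120,
                             baseline_duration = 300,
                             window_duration = 1,
                             burst_rate_per_scene = NULL,
                             burst_duration_range = c(1, 4),
                             burst_peak_range = c(0.6, 0.95),
                             snr = 10,
                             baseline_tone_range = c(0.05, 0.3),
                             mvic_range = c(0.8, 2.0),
                             crosstalk = 0,
                             calibration_hold = 5,
                             calibration_reps = 3,
                             calibration_ramp = 0.1,
                             subscales = c("mental", "physical", "temporal",
                                           "performance", "effort",
                                           "frustration", "emotional",
                                           "overall"),
                             tlx_intercept = 4,
                             scene_effects = c(baseline = 0, emotional = 1,
                                               cognitive = 1.5, physical = 1.5,
                                               dual = 2, recovery = 0.5),
                             planted_betas = list(),
                             random_intercept_sd = 1,
                             noise_sd = 1,
                             seed = 1L) {
  if (is.null(burst_rate_per_scene)) {
    burst_rate_per_scene <- list(
      baseline  = c(smile = 1.6, frown = 0.8, raised_eyebrow = 1.6),
      emotional = c(smile = 1.0, frown = 0.8, raised_eyebrow = 2.2),
      cognitive = c(smile = 0.5, frown = 0.7, raised_eyebrow = 0.4),
      physical  = c(smile = 5.5, frown = 0.5, raised_eyebrow = 2.0),
      dual      = c(smile = 5.5, frown = 0.5, raised_eyebrow = 2.0),
      recovery  = c(smile = 1.5, frown = 0.5, raised_eyebrow = 1.0))
  }
  cfg <- list(n_participants = n_participants, sample_rate = sample_rate,
              scene_duration = scene_duration,
              baseline_duration = baseline_duration,
              window_duration = window_duration,
              burst_rate_per_scene = burst_rate_per_scene,
              burst_duration_range = burst_duration_range,
              burst_peak_range = burst_peak_range, snr = snr,
              baseline_tone_range = baseline_tone_range,
              mvic_range = mvic_range, crosstalk = crosstalk,
              calibration_hold = calibration_hold,
              calibration_reps = calibration_reps,
              calibration_ramp = calibration_ramp,
              subscales = subscales, tlx_intercept = tlx_intercept,
              scene_effects = scene_effects, planted_betas = planted_betas,
              random_intercept_sd = random_intercept_sd, noise_sd = noise_sd,
              seed = seed)
  class(cfg) <- "femg_synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "femg_synth_config"))
  check_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop(what, " must be a non-degenerate finite range c(lo, hi)")
  }
  if (cfg$sample_rate <= 0) stop("sample_rate must be > 0")
  for (f in c("scene_duration", "baseline_duration", "window_duration"))
    if (cfg[[f]] <= 0) stop(f, " must be > 0")
  if (cfg$snr <= 0) stop("snr must be > 0")
  check_range(cfg$baseline_tone_range, "baseline_tone_range")
  check_range(cfg$mvic_range, "mvic_range")
  check_range(cfg$burst_duration_range, "burst_duration_range")
  if (cfg$burst_duration_range[1] <= 0) stop("burst durations must be > 0")
  if (min(cfg$mvic_range) <= max(cfg$baseline_tone_range))
    stop("mvic_range must lie strictly above baseline_tone_range")
  if (cfg$crosstalk < 0 || cfg$crosstalk >= 1)
    stop("crosstalk must be in [0, 1)")
  if (length(cfg$subscales) < 1) stop("need at least one subscale")
  for (sc in names(cfg$burst_rate_per_scene)) {
    if (!sc %in% scene_levels()) stop("unknown scene in burst rates: ", sc)
    if (any(cfg$burst_rate_per_scene[[sc]] < 0))
      stop("burst rates must be >= 0")
  }
  invisible(cfg)
}

#' Draw a participant calibration profile
#'
#' Per-channel resting tone is drawn uniformly from
#' `config$baseline_tone_range` and maximal-contraction (MVIC) amplitude from
#' `config$mvic_range`; the config invariant guarantees MVIC > tone on every
#' channel. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param config a [synthetic_config()].
#' @param participant participant identifier.
#' @return An object of class `femg_profile` with fields `participant`,
#'   `neutral_baseline`, and `mvic` (named per channel).
#' @export
generate_participant_profile <- function(seed, config,
                                         participant = "P01") {
  validate_synth_config(config)
  ch <- femg_channels()
  with_seed(seed, {
    tone <- stats::runif(7, config$baseline_tone_range[1],
                         config$baseline_tone_range[2])
    mvic <- stats::runif(7, config$mvic_range[1], config$mvic_range[2])
    new_profile(participant, stats::setNames(tone, ch),
                stats::setNames(mvic, ch))
  })
}

new_profile <- function(participant, neutral_baseline, mvic) {
  stopifnot(length(neutral_baseline) == 7, length(mvic) == 7,
            all(mvic > neutral_baseline))
  structure(list(participant = participant,
                 neutral_baseline = neutral_baseline, mvic = mvic),
            class = "femg_profile")
}

#' @export
print.femg_profile <- function(x, ...) {
  cat("fEMG calibration profile for", x$participant, "\n")
  print(round(rbind(neutral_baseline = x$neutral_baseline,
                    mvic = x$mvic), 4))
  invisible(x)
}

#' Generate a ground-truth expression script for one scene
#'
#' A two-state renewal process at window granularity: a neutral background is
#' interrupted by expression bursts. While neutral, a burst starts in a step
#' with probability `1 - exp(-r * dt / 60)` where `r` is the scene's total
#' burst rate (per minute); the burst class follows the scene's rate mixture
#' and its duration is uniform over `burst_duration_range` (at least one
#' step). Scene defaults plant lower non-neutral occupancy under cognitive
#' demand and elevated, smile-dominated occupancy under physical/dual demand.
#'
#' @param scene one of [scene_levels()].
#' @param n_steps number of script steps (>= 1).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param participant participant identifier.
#' @return An object of class `femg_script`: list with `participant`, `scene`,
#'   `labels` (factor of length `n_steps`), `window_duration`.
#' @export
generate_expression_script <- function(scene, n_steps, config, seed,
                                       participant = "P01") {
  validate_synth_config(config)
  scene <- match.arg(scene, scene_levels())
  if (n_steps < 1) stop("n_steps must be >= 1")
  rates <- config$burst_rate_per_scene[[scene]]
  if (is.null(rates)) stop("no burst rates configured for scene ", scene)
  classes <- c("smile", "frown", "raised_eyebrow")
  rates <- rates[classes]
  total <- sum(rates)
  dt <- config$window_duration
  labels <- with_seed(seed, {
    out <- character(n_steps)
    p_start <- 1 - exp(-total * dt / 60)
    t <- 1L
    while (t <= n_steps) {
      if (total > 0 && stats::runif(1) < p_start) {
        cls <- sample(classes, 1, prob = rates / total)
        dur_s <- stats::runif(1, config$burst_duration_range[1],
                              config$burst_duration_range[2])
        dur <- max(1L, as.integer(round(dur_s / dt)))
        idx <- t:min(n_steps, t + dur - 1L)
        out[idx] <- cls
        t <- t + dur
      } else {
        out[t] <- "neutral"
        t <- t + 1L
      }
    }
    out
  })
  structure(list(participant = participant, scene = scene,
                 labels = as_expression_factor(labels),
                 window_duration = dt),
            class = "femg_script")
}

# Raised-cosine (Hann) rise-and-fall envelope of length n peaking at 1:
# matches the transient peaks that rise and return to baseline.
hann_envelope <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))
}

# Trapezoidal plateau envelope used for held calibration blocks.
trapezoid_envelope <- function(n, ramp_frac) {
  r <- max(1L, as.integer(floor(n * ramp_frac)))
  env <- rep(1, n)
  if (2 * r < n) {
    env[seq_len(r)] <- seq_len(r) / r
    env[(n - r + 1):n] <- rev(seq_len(r)) / r
  }
  env
}

#' Render a multi-channel fEMG amplitude recording from a script
#'
#' Each channel's amplitude is the participant's resting tone, plus one
#' raised-cosine burst envelope per maximal run of a non-neutral label on
#' every channel whose muscle group that expression involves (FACS map),
#' plus zero-mean Gaussian noise with SD `(mvic - tone) / snr`; amplitudes
#' are rectified to be non-negative. The burst peak is a per-burst uniform
#' draw from `burst_peak_range` times the channel's MVIC-minus-tone span.
#'
#' @param script a `femg_script`.
#' @param profile the same participant's `femg_profile`.
#' @param config a [synthetic_config()].
#' @param seed integer seed for envelopes and noise.
#' @return A `femg_recording` (see [new_recording()]) with one scene-level
#'   event covering the whole recording.
#' @export
render_femg <- function(script, profile, config, seed = 1L) {
  validate_synth_config(config)
  if (!identical(script$participant, profile$participant))
    stop("script participant (", script$participant,
         ") does not match profile participant (", profile$participant, ")")
  spw <- as.integer(round(config$window_duration * config$sample_rate))
  n_steps <- length(script$labels)
  n <- n_steps * spw
  ch <- femg_channels()
  tone <- profile$neutral_baseline
  span <- profile$mvic - tone
  x <- matrix(rep(tone, each = n), nrow = n, ncol = 7,
              dimnames = list(NULL, ch))
  with_seed(seed, {
    runs <- rle(as.character(script$labels))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$values)) {
      lab <- runs$values[i]
      if (lab == "neutral") next
      involved <- involved_channels(lab)
      s0 <- (starts[i] - 1L) * spw + 1L
      s1 <- ends[i] * spw
      env <- hann_envelope(s1 - s0 + 1L)
      peak <- stats::runif(1, config$burst_peak_range[1],
                           config$burst_peak_range[2])
      for (cc in involved)
        x[s0:s1, cc] <- x[s0:s1, cc] + peak * span[cc] * env
    }
    if (config$crosstalk > 0) {
      act <- sweep(x, 2, tone, "-")
      mixed <- (1 - config$crosstalk) * act +
        config$crosstalk * matrix(rowMeans(act), nrow = n, ncol = 7)
      x <- sweep(mixed, 2, tone, "+")
    }
    noise <- matrix(stats::rnorm(n * 7), nrow = n, ncol = 7)
    noise <- sweep(noise, 2, span / config$snr, "*")
    x <- pmax(x + noise, 0)
  })
  new_recording(participant = script$participant, samples = x,
                sample_rate = config$sample_rate,
                events = data.frame(label = script$scene, start = 0L,
                                    end = n, stringsAsFactors = FALSE),
                scene = script$scene)
}

#' Generate a labeled calibration session
#'
#' Alternating held blocks: each maximal expression (smile, frown, raised
#' eyebrow) is repeated `calibration_reps` times, each block preceded by a
#' neutral block and the session closed by a final neutral block. Maximal
#' blocks use a trapezoidal envelope whose plateau drives the involved
#' channels to the channel MVIC; block-level labels are stored as events.
#'
#' @param profile a `femg_profile`.
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return A labeled `femg_recording` with one event per block.
#' @export
generate_calibration_session <- function(profile, config, seed = 1L) {
  validate_synth_config(config)
  spb <- as.integer(round(config$calibration_hold * config$sample_rate))
  block_labels <- character(0)
  for (r in seq_len(config$calibration_reps))
    for (expr in c("smile", "frown", "raised_eyebrow"))
      block_labels <- c(block_labels, "neutral", expr)
  block_labels <- c(block_labels, "neutral")
  nb <- length(block_labels)
  n <- nb * spb
  ch <- femg_channels()
  tone <- profile$neutral_baseline
  span <- profile$mvic - tone
  x <- matrix(rep(tone, each = n), nrow = n, ncol = 7,
              dimnames = list(NULL, ch))
  with_seed(seed, {
    for (b in seq_len(nb)) {
      lab <- block_labels[b]
      if (lab == "neutral") next
      idx <- ((b - 1L) * spb + 1L):(b * spb)
      env <- trapezoid_envelope(spb, config$calibration_ramp)
      for (cc in involved_channels(lab))
        x[idx, cc] <- x[idx, cc] + span[cc] * env
    }
    noise <- matrix(stats::rnorm(n * 7), nrow = n, ncol = 7)
    noise <- sweep(noise, 2, span / config$snr, "*")
    x <- pmax(x + noise, 0)
  })
  events <- data.frame(label = block_labels,
                       start = (seq_len(nb) - 1L) * spb,
                       end = seq_len(nb) * spb,
                       stringsAsFactors = FALSE)
  new_recording(participant = profile$participant, samples = x,
                sample_rate = config$sample_rate, events = events,
                scene = "calibration")
}

#' Generate NASA-TLX workload ratings from expression features
#'
#' For each configured subscale, the rating of a participant-scene
#' observation is `intercept + scene effect + participant random intercept +
#' sum(planted beta * z-scored feature) + Gaussian noise`, truncated to the
#' 0-10 scale. Planted betas act on features z-scored across the supplied
#' rows, so coefficients are in rating units per SD.
#'
#' @param features data frame with columns `participant`, `scene`, and one
#'   column per expression feature (one row per participant-scene).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return Long data frame: `participant`, `scene`, `subscale`, `rating`.
#' @export
generate_workload_ratings <- function(features, config, seed = 1L) {
  validate_synth_config(config)
  stopifnot(all(c("participant", "scene") %in% names(features)))
  feat_cols <- setdiff(names(features), c("participant", "scene"))
  for (ss in names(config$planted_betas)) {
    if (!ss %in% config$subscales)
      stop("planted_betas references unknown subscale: ", ss)
    bad <- setdiff(names(config$planted_betas[[ss]]), feat_cols)
    if (length(bad) > 0)
      stop("planted_betas references unknown feature(s): ",
           paste(bad, collapse = ", "))
  }
  z <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  zfeat <- as.data.frame(lapply(features[feat_cols], z))
  participants <- sort(unique(features$participant))
  n <- nrow(features)
  with_seed(seed, {
    b_i <- stats::setNames(
      stats::rnorm(length(participants), 0, config$random_intercept_sd),
      participants)
    out <- vector("list", length(config$subscales))
    for (k in seq_along(config$subscales)) {
      ss <- config$subscales[k]
      mu <- config$tlx_intercept +
        unname(config$scene_effects[as.character(features$scene)]) +
        unname(b_i[as.character(features$participant)])
      betas <- config$planted_betas[[ss]]
      if (!is.null(betas) && length(betas) > 0)
        mu <- mu + as.matrix(zfeat[, names(betas), drop = FALSE]) %*% betas
      rating <- as.numeric(mu) + stats::rnorm(n, 0, config$noise_sd)
      out[[k]] <- data.frame(participant = features$participant,
                             scene = features$scene, subscale = ss,
                             rating = pmin(10, pmax(0, rating)),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate a full synthetic cohort
#'
#' Per participant: one calibration session, one baseline-scene recording,
#' and four stressor-scene recordings (emotional, cognitive, physical, dual),
#' each with its ground-truth expression script; plus a workload ratings
#' table generated from the script-derived feature vectors. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()] with `n_participants >= 2`.
#' @return An object of class `femg_cohort`: list with `config`, `profiles`,
#'   `calibration`, `recordings` (per participant, per scene), `scripts`,
#'   `true_features` (script-derived), and `ratings`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  if (config$n_participants < 2)
    stop("n_participants must be >= 2 (leave-one-participant-out undefined)")
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  scenes <- c("baseline", "emotional", "cognitive", "physical", "dual")
  profiles <- calibration <- stats::setNames(vector("list", length(ids)), ids)
  recordings <- scripts <- stats::setNames(vector("list", length(ids)), ids)
  feats <- list()
  for (p in ids) {
    profiles[[p]] <- generate_participant_profile(
      derive_seed(config$seed, p, "profile"), config, participant = p)
    calibration[[p]] <- generate_calibration_session(
      profiles[[p]], config, seed = derive_seed(config$seed, p, "calib"))
    recordings[[p]] <- scripts[[p]] <-
      stats::setNames(vector("list", length(scenes)), scenes)
    for (sc in scenes) {
      dur <- if (sc == "baseline") config$baseline_duration else
        config$scene_duration
      n_steps <- as.integer(floor(dur / config$window_duration))
      scr <- generate_expression_script(
        sc, n_steps, config, seed = derive_seed(config$seed, p, sc, "script"),
        participant = p)
      scripts[[p]][[sc]] <- scr
      recordings[[p]][[sc]] <- render_femg(
        scr, profiles[[p]], config,
        seed = derive_seed(config$seed, p, sc, "render"))
      fv <- compute_feature_vector(scr$labels)
      feats[[length(feats) + 1L]] <-
        data.frame(participant = p, scene = sc, t(fv),
                   stringsAsFactors = FALSE)
    }
  }
  true_features <- do.call(rbind, feats)
  ratings <- generate_workload_ratings(
    true_features, config, seed = derive_seed(config$seed, "ratings"))
  structure(list(config = config, profiles = profiles,
                 calibration = calibration, recordings = recordings,
                 scripts = scripts, true_features = true_features,
                 ratings = ratings),
            class = "femg_cohort")
}

#' @export
print.femg_cohort <- function(x, ...) {
  cat("Synthetic fEMG cohort:", length(x$profiles), "participants,",
      length(x$recordings[[1]]), "scenes each +1 calibration session\n")
  cat("  sample rate:", x$config$sample_rate, "Hz; scene duration:",
      x$config$scene_duration, "s\n")
  invisible(x)
}
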