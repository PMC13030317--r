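#' Predict a continuous expression sequence for a scene recording
#'
#' Applies the trained shared classifier to a normalized scene recording
#' using the same windowing procedure as training (zero-overlap stride by
#' default); one argmax label per retained complete window. Trailing partial
#' windows are discarded, as in training. No temporal smoothing is applied:
#' downstream features depend on the raw transition structure.
#'
#' @param model a trained `femg_model`.
#' @param rec a normalized `femg_recording` with a scene.
#' @param params a [windowing_params()]; `w` must match the training window.
#' @return Object of class `femg_sequence`: list with `participant`, `scene`,
#'   `labels` (factor, one per window), `window_times` (start seconds).
#' @export
predict_sequence <- function(model, rec, params) {
  stopifnot(inherits(model, "femg_model"), inherits(rec, "femg_recording"))
  if (!rec$normalized)
    stop("recording must be normalized with the participant's profile")
  if (params$w != model$w)
    stop("window length ", params$w, " does not match training w = ",
         model$w)
  windows <- segment_windows(rec, params)
  if (length(windows) == 0) {
    warning("recording shorter than one window; empty sequence")
    return(new_sequence(rec$participant, rec$scene,
                        factor(character(0), levels = expression_levels()),
                        numeric(0)))
  }
  labels <- predict(model, windows)
  starts <- vapply(windows, function(z) z$start, numeric(1)) / rec$sample_rate
  new_sequence(rec$participant, rec$scene, labels, starts)
}

new_sequence <- function(participant, scene, labels, window_times) {
  stopifnot(!is.unsorted(window_times))
  structure(list(participant = participant, scene = scene,
                 labels = as_expression_factor(labels),
                 window_times = window_times),
            class = "femg_sequence")
}

#' @export
print.femg_sequence <- function(x, ...) {
  cat(sprintf("Expression sequence %s/%s: %d windows\n", x$participant,
              x$scene, length(x$labels)))
  if (length(x$labels) > 0) print(round(class_proportions(x), 3))
  invisible(x)
}

seq_labels <- function(seq) {
  if (inherits(seq, "femg_sequence")) seq$labels else as_expression_factor(seq)
}

#' Class proportions of an expression sequence
#'
#' @param seq a `femg_sequence` or a label vector.
#' @return Named numeric vector of 4 proportions (canonical class order),
#'   summing to 1.
#' @export
class_proportions <- function(seq) {
  labels <- seq_labels(seq)
  if (length(labels) == 0) stop("empty sequence")
  tab <- table(labels)
  as.numeric(tab) / length(labels) -> p
  stats::setNames(p, names(tab))
}

#' Per-participant scene summaries with baseline correction
#'
#' `scene_summary()` tabulates per participant x scene class proportions and
#' the non-neutral proportion; `baseline_corrected()` subtracts each
#' participant's own baseline-scene proportions, so the baseline row has
#' delta identically 0 and per-row class deltas sum to 0.
#'
#' @param sequences list of `femg_sequence` objects (all scenes of one or
#'   more participants; each participant must include the baseline scene for
#'   correction).
#' @return Data frame with proportions (`prop_*`, `non_neutral`) and, after
#'   correction, deltas (`delta_*`, `delta_non_neutral`).
#' @export
scene_summary <- function(sequences) {
  rows <- lapply(sequences, function(s) {
    stopifnot(inherits(s, "femg_sequence"))
    p <- class_proportions(s)
    data.frame(participant = s$participant, scene = s$scene,
               prop_neutral = p["neutral"], prop_smile = p["smile"],
               prop_frown = p["frown"],
               prop_raised_eyebrow = p["raised_eyebrow"],
               non_neutral = 1 - p["neutral"], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname scene_summary
#' @param summaries output of `scene_summary()`.
#' @export
baseline_corrected <- function(summaries) {
  prop_cols <- c("prop_neutral", "prop_smile", "prop_frown",
                 "prop_raised_eyebrow")
  out <- list()
  for (p in unique(summaries$participant)) {
    sub <- summaries[summaries$participant == p, , drop = FALSE]
    base <- sub[sub$scene == "baseline", , drop = FALSE]
    if (nrow(base) != 1)
      stop("missing baseline scene for participant ", p)
    for (cc in prop_cols)
      sub[[sub_delta_name(cc)]] <- sub[[cc]] - base[[cc]]
    sub$delta_non_neutral <- sub$non_neutral - base$non_neutral
    out[[p]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

sub_delta_name <- function(prop_col) sub("^prop_", "delta_", prop_col)

#' Cohort-level scene table
#'
#' Long-format participant x scene table plus per-scene means of the class
#' deltas across participants and median/IQR of the non-neutral delta.
#'
#' @param summaries baseline-corrected summaries from [baseline_corrected()].
#' @return List with `table` (one row per participant x scene) and
#'   `scene_means` (per-scene mean deltas, median and IQR of the non-neutral
#'   delta).
#' @export
cohort_scene_table <- function(summaries) {
  if (nrow(summaries) < 1) stop("need at least one participant")
  delta_cols <- grep("^delta_", names(summaries), value = TRUE)
  scenes <- unique(summaries$scene)
  means <- lapply(scenes, function(sc) {
    sub <- summaries[summaries$scene == sc, , drop = FALSE]
    row <- data.frame(scene = sc, n = nrow(sub), stringsAsFactors = FALSE)
    for (cc in delta_cols) row[[paste0("mean_", cc)]] <- mean(sub[[cc]])
    q <- stats::quantile(sub$delta_non_neutral, c(0.25, 0.5, 0.75),
                         names = FALSE)
    row$median_delta_non_neutral <- q[2]
    row$iqr_delta_non_neutral <- q[3] - q[1]
    row
  })
  list(table = summaries, scene_means = do.call(rbind, means))
}
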