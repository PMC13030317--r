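#' Compute a calibration profile from a labeled calibration session
#'
#' Two-stage normalization parameters: the per-channel neutral baseline is
#' the median amplitude over all neutral blocks (robust to transients), and
#' the per-channel MVIC is the 95th percentile of amplitude pooled over all
#' maximal-expression blocks (robust to single-sample spikes). The session
#' must contain at least one neutral block and at least one maximal block,
#' and MVIC must exceed the baseline on every channel.
#'
#' @param rec a labeled calibration `femg_recording` (block events carrying
#'   expression labels).
#' @return A `femg_profile`.
#' @export
compute_calibration_profile <- function(rec) {
  stopifnot(inherits(rec, "femg_recording"))
  labs <- sample_labels(rec, "expression")
  if (!any(labs %in% "neutral", na.rm = TRUE))
    stop("calibration session has no neutral block")
  maximal <- setdiff(expression_levels(), "neutral")
  if (!any(labs %in% maximal, na.rm = TRUE))
    stop("calibration session has no maximal-expression block")
  neu <- rec$samples[which(labs == "neutral"), , drop = FALSE]
  mx <- rec$samples[which(labs %in% maximal), , drop = FALSE]
  baseline <- apply(neu, 2, stats::median)
  mvic <- apply(mx, 2, stats::quantile, probs = 0.95, names = FALSE)
  bad <- which(mvic <= baseline + 1e-6)
  if (length(bad) > 0)
    stop("MVIC does not exceed neutral baseline on channel(s): ",
         paste(femg_channels()[bad], collapse = ", "))
  new_profile(rec$participant, baseline, mvic)
}

#' Two-stage amplitude normalization
#'
#' Applies neutral correction then MVIC scaling per channel:
#' `x' = (x - neutral_baseline) / (mvic - neutral_baseline)`, so resting tone
#' maps to about 0 and maximal contraction to about 1. Values outside
#' \[0, 1\] are allowed (spontaneous activity may exceed calibration MVIC);
#' nothing is clipped. The transform is affine and invertible given the
#' profile (see [denormalize_recording()]).
#'
#' @param rec an unnormalized `femg_recording`.
#' @param profile the participant's `femg_profile`.
#' @return The normalized recording (flag set).
#' @export
normalize_recording <- function(rec, profile) {
  stopifnot(inherits(rec, "femg_recording"), inherits(profile, "femg_profile"))
  if (rec$normalized) stop("recording is already normalized")
  if (!identical(rec$participant, profile$participant))
    stop("profile participant (", profile$participant,
         ") does not match recording participant (", rec$participant, ")")
  span <- profile$mvic - profile$neutral_baseline
  if (any(span <= 1e-6))
    stop("degenerate profile: mvic - baseline <= 1e-6 on some channel")
  rec$samples <- sweep(sweep(rec$samples, 2, profile$neutral_baseline, "-"),
                       2, span, "/")
  rec$normalized <- TRUE
  rec
}

#' @rdname normalize_recording
#' @export
denormalize_recording <- function(rec, profile) {
  stopifnot(inherits(rec, "femg_recording"), inherits(profile, "femg_profile"))
  if (!rec$normalized) stop("recording is not normalized")
  span <- profile$mvic - profile$neutral_baseline
  rec$samples <- sweep(sweep(rec$samples, 2, span, "*"),
                       2, profile$neutral_baseline, "+")
  rec$normalized <- FALSE
  rec
}

#' Windowing parameters
#'
#' @param w window length in samples (>= 1).
#' @param s stride in samples (default `w`: zero overlap).
#' @return An object of class `femg_windowing`.
#' @export
windowing_params <- function(w, s = w) {
  if (w < 1 || s < 1) stop("w and s must be >= 1")
  structure(list(w = as.integer(w), s = as.integer(s)),
            class = "femg_windowing")
}

#' Segment a normalized recording into fixed-length windows
#'
#' Within each contiguous tagged segment of length `T` the retained window
#' starts are `0, s, 2s, ...` while a full window fits, i.e.
#' `floor((T - w)/s) + 1` windows for `T >= w` and none otherwise — only
#' complete windows are kept. A window inherits an expression label only when
#' all of its samples carry that label (guaranteed here because windows never
#' cross segment boundaries). If the recording has no expression events but a
#' scene, the whole recording is one unlabeled segment.
#'
#' @param rec a normalized `femg_recording`.
#' @param params a [windowing_params()].
#' @return List of windows; each is a list with `data` (w x 7 matrix),
#'   `label` (expression or NA), `participant`, `scene`, `start` (0-based
#'   sample index).
#' @export
segment_windows <- function(rec, params) {
  stopifnot(inherits(rec, "femg_recording"),
            inherits(params, "femg_windowing"))
  if (!rec$normalized) stop("recording must be normalized before windowing")
  w <- params$w; s <- params$s
  ev <- rec$events[rec$events$label %in% expression_levels(), , drop = FALSE]
  if (nrow(ev) == 0) {
    if (is.null(rec$scene)) return(list())
    ev <- data.frame(label = NA_character_, start = 0L,
                     end = nrow(rec$samples), stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ev))) {
    T_len <- ev$end[i] - ev$start[i]
    if (T_len < w) next
    starts <- ev$start[i] + s * (0:((T_len - w) %/% s))
    for (st in starts) {
      out[[length(out) + 1L]] <- list(
        data = rec$samples[(st + 1L):(st + w), , drop = FALSE],
        label = ev$label[i], participant = rec$participant,
        scene = rec$scene, start = st)
    }
  }
  out
}

# Stack a list of windows into a (B, w, 7) array plus label/participant
# vectors for the model stage.
stack_windows <- function(windows) {
  if (length(windows) == 0)
    stop("no windows to stack")
  w <- nrow(windows[[1]]$data)
  B <- length(windows)
  x <- array(0, dim = c(B, w, 7))
  for (i in seq_len(B)) x[i, , ] <- windows[[i]]$data
  list(x = x,
       y = vapply(windows, function(z) as.character(z$label), character(1)),
       participant = vapply(windows, function(z) z$participant, character(1)),
       w = w)
}
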