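# Expression-dynamics feature taxonomy: 81 named scalar descriptors of one
# participant-x-scene categorical expression sequence, grouped into static
# occupancy measures (ratios, counts), temporal organization (transitions,
# bursts, switches, latency), information measures (entropy), and balance
# measures (dominance, Gini-like inequality).

non_neutral_classes <- function() c("frown", "smile", "raised_eyebrow")

#' Expression ratios and counts
#'
#' Per-class frame counts, the total frame count, and per-class occupancy
#' ratios `count / T`.
#'
#' @param seq a `femg_sequence` or label vector (length >= 1).
#' @return Named numeric vector: 4 ratios, 4 counts, `total_frames`.
#' @export
compute_ratios_counts <- function(seq) {
  labels <- seq_labels(seq)
  if (length(labels) == 0) stop("empty sequence")
  cnt <- table(labels)
  Tt <- length(labels)
  out <- c(as.numeric(cnt) / Tt, as.numeric(cnt), Tt)
  stats::setNames(out, c(paste0("ratio_", names(cnt)),
                         paste0("count_", names(cnt)), "total_frames"))
}

#' Transition counts and probabilities
#'
#' Counts over adjacent ordered label pairs (including self-transitions; the
#' total is `T - 1`), row-normalized transition probabilities (all-zero rows
#' for never-visited source states stay zero), and the three neutral-to-X
#' transition counts.
#'
#' @inheritParams compute_ratios_counts
#' @return List with `counts` (4x4), `probs` (4x4), `neutral_to` (named
#'   3-vector).
#' @export
compute_transition_matrix <- function(seq) {
  labels <- seq_labels(seq)
  lev <- expression_levels()
  counts <- matrix(0, 4, 4, dimnames = list(from = lev, to = lev))
  Tt <- length(labels)
  if (Tt >= 2) {
    a <- labels[-Tt]; b <- labels[-1]
    tab <- table(a, b)
    counts[rownames(tab), colnames(tab)] <- tab
  }
  probs <- counts
  rs <- rowSums(counts)
  nz <- rs > 0
  probs[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  list(counts = counts, probs = probs,
       neutral_to = stats::setNames(counts["neutral", non_neutral_classes()],
                                    non_neutral_classes()))
}

run_lengths <- function(labels) {
  r <- rle(as.character(labels))
  split(r$lengths, factor(r$values, levels = expression_levels()))
}

pop_sd <- function(x) {
  if (length(x) <= 1) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' Burst (run-length) statistics
#'
#' A burst is a maximal run of identical consecutive labels. Per class this
#' returns count, mean, median, min, max, and population-SD of run lengths
#' (all 0 for classes that never occur), plus the average burst length of
#' each non-neutral class.
#'
#' @inheritParams compute_ratios_counts
#' @return Named numeric vector: 24 per-class descriptors
#'   (`burst_<class>_<stat>`) and 3 `avg_burst_len_*` aliases.
#' @export
compute_burst_statistics <- function(seq) {
  labels <- seq_labels(seq)
  if (length(labels) == 0) stop("empty sequence")
  runs <- run_lengths(labels)
  stats_one <- function(x) {
    if (length(x) == 0) return(c(count = 0, mean = 0, median = 0, min = 0,
                                 max = 0, std = 0))
    c(count = length(x), mean = mean(x), median = stats::median(x),
      min = min(x), max = max(x), std = pop_sd(x))
  }
  out <- numeric(0)
  for (cls in expression_levels()) {
    st <- stats_one(runs[[cls]])
    out <- c(out, stats::setNames(st, paste0("burst_", cls, "_", names(st))))
  }
  for (cls in non_neutral_classes())
    out[paste0("avg_burst_len_", cls)] <- out[paste0("burst_", cls, "_mean")]
  out
}

#' Shannon entropy of the class distribution
#'
#' `H = -sum(p * log2(p))` over the 4-class empirical distribution (with
#' `0 log 0 = 0`), and the normalized entropy `H / log2(4)`.
#'
#' @inheritParams compute_ratios_counts
#' @return Named numeric vector `c(entropy, entropy_norm)`; entropy is in
#'   bits, in `[0, 2]`.
#' @export
compute_entropy <- function(seq) {
  labels <- seq_labels(seq)
  if (length(labels) == 0) stop("empty sequence")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  c(entropy = h, entropy_norm = h / 2)
}

#' Global sequence dynamics
#'
#' Switches (adjacent label changes), switch rate `switches / (T - 1)` (0
#' for T = 1), and persistence, the global mean run length `T / #runs`.
#'
#' @inheritParams compute_ratios_counts
#' @return Named numeric vector `c(switches, switch_rate, persistence)`.
#' @export
compute_dynamics <- function(seq) {
  labels <- seq_labels(seq)
  Tt <- length(labels)
  if (Tt == 0) stop("empty sequence")
  switches <- if (Tt >= 2) sum(labels[-Tt] != labels[-1]) else 0
  rate <- if (Tt >= 2) switches / (Tt - 1) else 0
  n_runs <- length(rle(as.character(labels))$lengths)
  c(switches = switches, switch_rate = rate, persistence = Tt / n_runs)
}

#' Dominance and Gini-like inequality of non-neutral expressions
#'
#' Over the 3 non-neutral occupancy proportions `p`: dominance is
#' `max(p) / sum(p)` and the Gini-like inequality is
#' `sum_ij |p_i - p_j| / (2 * 3 * sum(p))`, which ranges over `[0, 2/3]`.
#' Both are 0 by convention for an all-neutral sequence.
#'
#' @inheritParams compute_ratios_counts
#' @return Named numeric vector `c(dominance, gini_inequality)`.
#' @export
compute_dominance <- function(seq) {
  labels <- seq_labels(seq)
  if (length(labels) == 0) stop("empty sequence")
  p <- as.numeric(table(labels))[match(non_neutral_classes(),
                                       expression_levels())] /
    length(labels)
  s <- sum(p)
  if (s == 0) return(c(dominance = 0, gini_inequality = 0))
  gini <- sum(abs(outer(p, p, "-"))) / (2 * 3 * s)
  c(dominance = max(p) / s, gini_inequality = gini)
}

#' Latency after neutral
#'
#' For each non-neutral class: the 0-based index of the first window of that
#' class preceded (anywhere earlier) by at least one neutral window, divided
#' by `T`; sentinel 1.0 when no such occurrence exists.
#'
#' @inheritParams compute_ratios_counts
#' @return Named numeric vector of 3 latency indices.
#' @export
compute_latency <- function(seq) {
  labels <- seq_labels(seq)
  Tt <- length(labels)
  if (Tt == 0) stop("empty sequence")
  first_neutral <- match("neutral", as.character(labels))
  out <- numeric(3)
  names(out) <- paste0("latency_", non_neutral_classes())
  for (cls in non_neutral_classes()) {
    idx <- which(as.character(labels) == cls)
    idx <- if (!is.na(first_neutral)) idx[idx > first_neutral] else integer(0)
    out[paste0("latency_", cls)] <-
      if (length(idx) > 0) (idx[1] - 1) / Tt else 1
  }
  out
}

#' Feature registry
#'
#' Fixed, versioned ordering of the 81 expression-dynamics features.
#'
#' @return Data frame with columns `name`, `category`, `definition`.
#' @export
feature_registry <- function() {
  lev <- expression_levels()
  nn <- non_neutral_classes()
  rows <- list(
    data.frame(name = paste0("ratio_", lev), category = "ratios",
               definition = "proportion of frames in class"),
    data.frame(name = c(paste0("count_", lev), "total_frames"),
               category = "counts",
               definition = "frame count per class; total frames"),
    data.frame(name = paste0("neutral_to_", nn),
               category = "neutral_transitions",
               definition = "count of neutral -> class transitions"),
    data.frame(name = paste0("avg_burst_len_", nn),
               category = "avg_burst_length",
               definition = "mean run length of class"),
    data.frame(name = c("entropy", "entropy_norm"), category = "entropy",
               definition = "Shannon entropy (bits); normalized by log2(4)"),
    data.frame(name = c("switches", "switch_rate", "persistence"),
               category = "dynamics",
               definition = "label changes; changes/(T-1); T/#runs"),
    data.frame(name = c("dominance", "gini_inequality"),
               category = "dominance",
               definition = "balance of non-neutral occupancy"),
    data.frame(name = paste0("latency_", nn), category = "latency",
               definition = "first occurrence after neutral, index/T"),
    data.frame(name = as.vector(t(outer(lev, lev, function(a, b)
      paste0("trans_count_", a, "_", b)))), category = "transition_counts",
      definition = "adjacent-pair transition count"),
    data.frame(name = as.vector(t(outer(lev, lev, function(a, b)
      paste0("trans_prob_", a, "_", b)))), category = "transition_probs",
      definition = "row-normalized transition probability"),
    data.frame(name = as.vector(t(outer(lev,
      c("count", "mean", "median", "min", "max", "std"), function(a, b)
        paste0("burst_", a, "_", b)))), category = "burst_statistics",
      definition = "run-length distribution descriptor"))
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  reg
}

#' Assemble the full 81-feature vector
#'
#' Concatenates all sub-operation outputs in registry order. A pure function
#' of the label sequence.
#'
#' @inheritParams compute_ratios_counts
#' @return Named numeric vector of length 81, ordered as
#'   [feature_registry()].
#' @export
compute_feature_vector <- function(seq) {
  labels <- seq_labels(seq)
  if (length(labels) == 0) stop("empty sequence")
  rc <- compute_ratios_counts(labels)
  tm <- compute_transition_matrix(labels)
  bs <- compute_burst_statistics(labels)
  lev <- expression_levels()
  tc <- as.vector(t(tm$counts))
  names(tc) <- as.vector(t(outer(lev, lev, function(a, b)
    paste0("trans_count_", a, "_", b))))
  tp <- as.vector(t(tm$probs))
  names(tp) <- as.vector(t(outer(lev, lev, function(a, b)
    paste0("trans_prob_", a, "_", b))))
  out <- c(rc,
           stats::setNames(tm$neutral_to,
                           paste0("neutral_to_", non_neutral_classes())),
           bs[paste0("avg_burst_len_", non_neutral_classes())],
           compute_entropy(labels), compute_dynamics(labels),
           compute_dominance(labels), compute_latency(labels),
           tc, tp,
           bs[setdiff(names(bs),
                      paste0("avg_burst_len_", non_neutral_classes()))])
  out <- out[feature_registry()$name]
  stopifnot(length(out) == 81, !anyNA(out))
  out
}

#' Feature table for a list of sequences
#'
#' @param sequences list of `femg_sequence` objects.
#' @return Data frame: `participant`, `scene`, and the 81 feature columns.
#' @export
feature_table <- function(sequences) {
  rows <- lapply(sequences, function(s) {
    data.frame(participant = s$participant, scene = s$scene,
               t(compute_feature_vector(s)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
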