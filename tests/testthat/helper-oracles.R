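# Independent brute-force oracles, deliberately written with naive loops and
# kept separate from the package implementations they check.

oracle_window_starts <- function(T_len, w, s) {
  starts <- integer(0)
  st <- 0L
  while (st + w <= T_len) {
    starts <- c(starts, st)
    st <- st + s
  }
  starts
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Per-class contingency-table metrics computed with explicit loops.
oracle_metrics <- function(true, pred) {
  lev <- c("neutral", "smile", "frown", "raised_eyebrow")
  prec <- rec <- f1 <- sup <- numeric(4)
  for (k in seq_len(4)) {
    tp <- sum(true == lev[k] & pred == lev[k])
    fp <- sum(true != lev[k] & pred == lev[k])
    fn <- sum(true == lev[k] & pred != lev[k])
    sup[k] <- sum(true == lev[k])
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  present <- sup > 0
  list(accuracy = sum(true == pred) / length(true),
       macro_precision = mean(prec[present]),
       macro_recall = mean(rec[present]),
       macro_f1 = mean(f1[present]),
       weighted_f1 = sum((f1 * sup)[present]) / sum(sup),
       weighted_precision = sum((prec * sup)[present]) / sum(sup),
       weighted_recall = sum((rec * sup)[present]) / sum(sup))
}

# Brute-force versions of all 81 sequence features, assembled in registry
# order. `labels` is a character vector.
oracle_features <- function(labels) {
  lev <- c("neutral", "smile", "frown", "raised_eyebrow")
  nn <- c("frown", "smile", "raised_eyebrow")
  Tt <- length(labels)
  out <- c()
  cnt <- sapply(lev, function(l) sum(labels == l))
  out[paste0("ratio_", lev)] <- cnt / Tt
  out[paste0("count_", lev)] <- cnt
  out["total_frames"] <- Tt
  # transitions
  tc <- matrix(0, 4, 4, dimnames = list(lev, lev))
  if (Tt >= 2) for (t in 1:(Tt - 1))
    tc[labels[t], labels[t + 1]] <- tc[labels[t], labels[t + 1]] + 1
  out[paste0("neutral_to_", nn)] <- tc["neutral", nn]
  # runs by scanning
  runs_val <- character(0); runs_len <- integer(0)
  if (Tt >= 1) {
    cur <- labels[1]; len <- 1L
    for (t in seq_len(Tt)[-1]) {
      if (labels[t] == cur) len <- len + 1L
      else {
        runs_val <- c(runs_val, cur); runs_len <- c(runs_len, len)
        cur <- labels[t]; len <- 1L
      }
    }
    runs_val <- c(runs_val, cur); runs_len <- c(runs_len, len)
  }
  for (cls in nn) {
    r <- runs_len[runs_val == cls]
    out[paste0("avg_burst_len_", cls)] <- if (length(r)) mean(r) else 0
  }
  p <- cnt / Tt
  h <- 0
  for (k in 1:4) if (p[k] > 0) h <- h - p[k] * log2(p[k])
  out["entropy"] <- h
  out["entropy_norm"] <- h / log2(4)
  sw <- if (Tt >= 2) sum(labels[-Tt] != labels[-1]) else 0
  out["switches"] <- sw
  out["switch_rate"] <- if (Tt >= 2) sw / (Tt - 1) else 0
  out["persistence"] <- Tt / length(runs_len)
  pn <- p[nn]
  s <- sum(pn)
  if (s == 0) {
    out["dominance"] <- 0; out["gini_inequality"] <- 0
  } else {
    out["dominance"] <- max(pn) / s
    g <- 0
    for (i in 1:3) for (j in 1:3) g <- g + abs(pn[i] - pn[j])
    out["gini_inequality"] <- g / (2 * 3 * s)
  }
  for (cls in nn) {
    lat <- 1
    seen_neutral <- FALSE
    for (t in seq_len(Tt)) {
      if (labels[t] == cls && seen_neutral) { lat <- (t - 1) / Tt; break }
      if (labels[t] == "neutral") seen_neutral <- TRUE
    }
    out[paste0("latency_", cls)] <- lat
  }
  for (a in lev) for (b in lev)
    out[paste0("trans_count_", a, "_", b)] <- tc[a, b]
  for (a in lev) {
    rs <- sum(tc[a, ])
    for (b in lev)
      out[paste0("trans_prob_", a, "_", b)] <- if (rs > 0) tc[a, b] / rs else 0
  }
  for (cls in lev) {
    r <- runs_len[runs_val == cls]
    if (length(r) == 0) {
      st <- c(count = 0, mean = 0, median = 0, min = 0, max = 0, std = 0)
    } else {
      st <- c(count = length(r), mean = mean(r), median = median(r),
              min = min(r), max = max(r),
              std = sqrt(sum((r - mean(r))^2) / length(r)))
    }
    out[paste0("burst_", cls, "_", names(st))] <- st
  }
  out
}
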