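#' Z-score a feature table
#'
#' Standardizes each feature column across all participant-x-scene rows
#' using the population SD (divide by n), so a column like `(1, 2, 3)` maps
#' to `(-1.2247, 0, 1.2247)`. Zero-variance columns are dropped and logged.
#'
#' @param features data frame with `participant`, `scene`, and feature
#'   columns (>= 2 rows).
#' @return List of class `femg_std`: `data` (standardized table), `dropped`
#'   (names of removed columns), `center`, `scale`.
#' @export
standardize_features <- function(features) {
  if (nrow(features) < 2) stop("need >= 2 observations to standardize")
  id_cols <- intersect(c("participant", "scene"), names(features))
  feat_cols <- setdiff(names(features), id_cols)
  center <- scale_ <- stats::setNames(numeric(length(feat_cols)), feat_cols)
  keep <- character(0)
  out <- features[id_cols]
  for (cc in feat_cols) {
    v <- features[[cc]]
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    center[cc] <- mu; scale_[cc] <- sd_pop
    if (sd_pop < 1e-12) next
    keep <- c(keep, cc)
    out[[cc]] <- (v - mu) / sd_pop
  }
  dropped <- setdiff(feat_cols, keep)
  if (length(dropped) > 0)
    warning("dropped zero-variance feature column(s): ",
            paste(dropped, collapse = ", "))
  structure(list(data = out, dropped = dropped, center = center[keep],
                 scale = scale_[keep], feature_cols = keep),
            class = "femg_std")
}

#' Principal component analysis of standardized features
#'
#' Eigendecomposition of the population covariance of the (already
#' z-scored) columns. Components are ordered by explained variance; each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive, making reports reproducible.
#'
#' @param std a [standardize_features()] result (or a plain data frame of
#'   numeric columns).
#' @param n_components number of components to retain.
#' @return Object of class `femg_pca`: `loadings` (features x components),
#'   `scores` (observations x components), `explained` (variance fractions
#'   of the retained components), `explained_all`.
#' @export
run_pca <- function(std, n_components = 2) {
  X <- if (inherits(std, "femg_std"))
    as.matrix(std$data[std$feature_cols]) else as.matrix(std)
  if (nrow(X) < 2) stop("need >= 2 observations")
  if (ncol(X) < n_components)
    stop("fewer retained columns (", ncol(X), ") than components requested")
  Xc <- sweep(X, 2, colMeans(X), "-")
  C <- crossprod(Xc) / nrow(Xc)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank_ok <- sum(ev > max(ev) * 1e-12)
  if (rank_ok < n_components)
    stop("rank deficiency: only ", rank_ok, " informative components")
  load <- eg$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(n_components))
  scores <- Xc %*% load
  structure(list(loadings = load, scores = scores,
                 explained = ev[seq_len(n_components)] / sum(ev),
                 explained_all = ev / sum(ev), center = colMeans(X)),
            class = "femg_pca")
}

#' @export
print.femg_pca <- function(x, ...) {
  cat("PCA:", ncol(x$loadings), "components;",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), 100 * x$explained),
            collapse = ", "),
      sprintf("(total %.1f%%)\n", 100 * sum(x$explained)))
  invisible(x)
}

lmm_control <- function() {
  lme4::lmerControl(optimizer = "bobyqa",
                    check.conv.singular = lme4::.makeCC("ignore", 1e-4))
}

#' Scene-contrast mixed model for component scores
#'
#' Fits `score ~ scene + (1 | participant)` by REML with the baseline scene
#' as reference, using the derivative-free BOBYQA optimizer; per-scene fixed
#' effects are returned with Satterthwaite standard errors and p-values.
#'
#' @param scores numeric vector (e.g. a PC score per observation).
#' @param scenes scene labels per observation (must include baseline).
#' @param participants participant ids per observation.
#' @return Data frame: `scene`, `beta`, `se`, `p`, plus attributes
#'   `converged` and `ranef_var`.
#' @export
fit_scene_model <- function(scores, scenes, participants) {
  scenes <- factor(as.character(scenes))
  if (nlevels(scenes) < 2) stop("need >= 2 scenes including baseline")
  if (!"baseline" %in% levels(scenes)) stop("baseline scene missing")
  if (length(unique(participants)) < 2) stop("need >= 2 participants")
  scenes <- stats::relevel(scenes, ref = "baseline")
  df <- data.frame(y = scores, scene = scenes,
                   participant = factor(participants))
  fit <- lmerTest::lmer(y ~ scene + (1 | participant), data = df,
                        REML = TRUE, control = lmm_control())
  sm <- stats::coef(summary(fit))
  rows <- grep("^scene", rownames(sm))
  out <- data.frame(scene = sub("^scene", "", rownames(sm)[rows]),
                    beta = sm[rows, "Estimate"],
                    se = sm[rows, "Std. Error"],
                    p = sm[rows, "Pr(>|t|)"], row.names = NULL)
  attr(out, "converged") <- length(fit@optinfo$conv$lme4$messages) == 0
  attr(out, "ranef_var") <- as.numeric(lme4::VarCorr(fit)$participant[1])
  out
}

#' Feature-workload mixed-effects models
#'
#' For every (feature, subscale) pair fits
#' `rating ~ feature + scene + feature:scene + (1 | participant)` by REML
#' (BOBYQA optimizer), with the feature z-scored, so betas are in rating
#' units per SD. The feature main effect and, optionally, each
#' feature-by-scene interaction enter the FDR family; q-values use
#' Benjamini-Hochberg over the configured family.
#'
#' @param std a [standardize_features()] result.
#' @param ratings long data frame `participant`, `scene`, `subscale`,
#'   `rating`.
#' @param features which feature columns to model (default: all retained).
#' @param subscales which subscales (default: all present).
#' @param include_interactions include feature:scene interaction terms in
#'   the model and the FDR family.
#' @param fdr_family "all" (one family over every feature x subscale effect)
#'   or "per_subscale".
#' @param q_threshold FDR significance threshold.
#' @return Data frame of class `femg_mm`: feature, subscale, term, beta, se,
#'   p, q, significant, ranef_var, converged, singular.
#' @export
fit_feature_workload_models <- function(std, ratings, features = NULL,
                                        subscales = NULL,
                                        include_interactions = TRUE,
                                        fdr_family = c("all", "per_subscale"),
                                        q_threshold = 0.05) {
  stopifnot(inherits(std, "femg_std"))
  fdr_family <- match.arg(fdr_family)
  if (is.null(features)) features <- std$feature_cols
  if (is.null(subscales)) subscales <- unique(ratings$subscale)
  bad <- setdiff(features, std$feature_cols)
  if (length(bad) > 0)
    stop("unknown or dropped feature(s): ", paste(bad, collapse = ", "))
  tab <- std$data
  out <- list()
  for (ss in subscales) {
    rt <- ratings[ratings$subscale == ss, , drop = FALSE]
    m <- merge(tab, rt, by = c("participant", "scene"))
    n_drop <- nrow(tab) - nrow(m) + sum(is.na(m$rating))
    m <- m[!is.na(m$rating), , drop = FALSE]
    for (ff in features) {
      df <- data.frame(rating = m$rating, feature = m[[ff]],
                       scene = stats::relevel(factor(m$scene),
                                              ref = "baseline"),
                       participant = factor(m$participant))
      if (stats::sd(df$feature) < 1e-12) {
        out[[length(out) + 1L]] <- data.frame(
          feature = ff, subscale = ss, term = "feature", beta = NA_real_,
          se = NA_real_, p = NA_real_, ranef_var = NA_real_,
          converged = FALSE, singular = NA, n_dropped = n_drop,
          note = "collinear/constant feature")
        next
      }
      form <- if (include_interactions)
        rating ~ feature + scene + feature:scene + (1 | participant) else
        rating ~ feature + scene + (1 | participant)
      fit <- tryCatch(
        lmerTest::lmer(form, data = df, REML = TRUE,
                       control = lmm_control()),
        error = function(e) e)
      if (inherits(fit, "error")) {
        out[[length(out) + 1L]] <- data.frame(
          feature = ff, subscale = ss, term = "feature", beta = NA_real_,
          se = NA_real_, p = NA_real_, ranef_var = NA_real_,
          converged = FALSE, singular = NA, n_dropped = n_drop,
          note = conditionMessage(fit))
        next
      }
      sm <- stats::coef(summary(fit))
      terms <- "feature"
      if (include_interactions)
        terms <- c(terms, grep("^feature:scene", rownames(sm), value = TRUE))
      conv <- length(fit@optinfo$conv$lme4$messages) == 0
      for (tm in terms) {
        out[[length(out) + 1L]] <- data.frame(
          feature = ff, subscale = ss, term = tm,
          beta = sm[tm, "Estimate"], se = sm[tm, "Std. Error"],
          p = sm[tm, "Pr(>|t|)"],
          ranef_var = as.numeric(lme4::VarCorr(fit)$participant[1]),
          converged = conv, singular = lme4::isSingular(fit),
          n_dropped = n_drop, note = "")
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- NA_real_
  res$significant <- NA
  ok <- !is.na(res$p)
  if (fdr_family == "all") {
    fd <- apply_fdr(res$p[ok], q_threshold)
    res$q[ok] <- fd$q
    res$significant[ok] <- fd$significant
  } else {
    for (ss in unique(res$subscale)) {
      sel <- ok & res$subscale == ss
      fd <- apply_fdr(res$p[sel], q_threshold)
      res$q[sel] <- fd$q
      res$significant[sel] <- fd$significant
    }
  }
  class(res) <- c("femg_mm", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity; the significance
#' mask is `q < q_threshold`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q_threshold FDR level.
#' @return List: `q` (adjusted values), `significant` (logical mask).
#' @export
apply_fdr <- function(p, q_threshold = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q < q_threshold)
}
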