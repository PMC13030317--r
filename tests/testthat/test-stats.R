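test_that("standardization uses population SD and drops constants", {
  df <- data.frame(participant = c("P01", "P01", "P02"),
                   scene = c("baseline", "physical", "baseline"),
                   a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(standardize_features(df), "zero-variance")
  std <- suppressWarnings(standardize_features(df))
  expect_equal(std$data$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_identical(std$dropped, "b")
  expect_false("b" %in% names(std$data))
  expect_error(standardize_features(df[1, ]), ">= 2")

  # retained columns: mean 0, population SD 1
  set.seed(2)
  df2 <- data.frame(participant = "P", scene = "baseline",
                    x = rnorm(50), y = runif(50))
  std2 <- standardize_features(df2)
  for (cc in c("x", "y")) {
    expect_lt(abs(mean(std2$data[[cc]])), 1e-9)
    expect_lt(abs(sqrt(mean(std2$data[[cc]]^2)) - 1), 1e-9)
  }
})

test_that("PCA explains variance correctly and reconstructs the data", {
  set.seed(3)
  # two perfectly collinear columns: PC1 explains everything
  u <- rnorm(40)
  col <- data.frame(x = u, y = 2 * u)
  p1 <- run_pca(scale(col, scale = FALSE), n_components = 1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-9)

  # isotropic Gaussian: each of 5 components near 20%
  X <- matrix(rnorm(2000 * 5), 2000, 5)
  p5 <- run_pca(X, n_components = 5)
  expect_true(all(abs(p5$explained - 0.2) < 0.03))
  expect_equal(sum(p5$explained_all), 1, tolerance = 1e-12)
  expect_true(all(diff(p5$explained) <= 1e-12))

  # loadings orthonormal; full components reconstruct the centered data
  expect_equal(crossprod(p5$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  Xc <- sweep(X, 2, colMeans(X), "-")
  expect_lt(max(abs(p5$scores %*% t(p5$loadings) - Xc)), 1e-9)

  # sign convention: largest-|loading| entry positive
  for (j in 1:5) {
    lj <- p5$loadings[, j]
    expect_gt(lj[which.max(abs(lj))], 0)
  }

  # cross-check against prcomp (sample-vs-population scaling cancels in
  # variance fractions)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(p5$explained_all, unname(pr$sdev^2 / sum(pr$sdev^2)),
               tolerance = 1e-9)

  expect_error(run_pca(X[, 1:2], n_components = 3), "fewer retained")
  expect_error(run_pca(cbind(u, u), n_components = 2), "rank")
})

test_that("scene-contrast mixed model recovers a planted scene shift", {
  set.seed(11)
  n <- 100
  scenes <- c("baseline", "emotional", "cognitive", "physical", "dual")
  df <- expand.grid(participant = sprintf("P%03d", 1:n), scene = scenes,
                    stringsAsFactors = FALSE)
  b_i <- rnorm(n, 0, 1)
  names(b_i) <- sprintf("P%03d", 1:n)
  df$y <- b_i[df$participant] + ifelse(df$scene == "cognitive", -2, 0) +
    rnorm(nrow(df), 0, 1)
  fit <- fit_scene_model(df$y, df$scene, df$participant)
  expect_true(attr(fit, "converged"))
  b_cog <- fit$beta[fit$scene == "cognitive"]
  expect_lt(abs(b_cog - (-2)), 0.3)
  expect_lt(fit$p[fit$scene == "cognitive"], 1e-6)
  # random-intercept variance within a factor of 2 of the planted 1.0
  expect_gt(attr(fit, "ranef_var"), 0.5)
  expect_lt(attr(fit, "ranef_var"), 2)

  expect_error(fit_scene_model(df$y[df$scene == "baseline"],
                               df$scene[df$scene == "baseline"],
                               df$participant[df$scene == "baseline"]),
               ">= 2 scenes")
})

test_that("feature-workload models return the documented structure", {
  set.seed(13)
  n <- 30
  scenes <- c("baseline", "physical")
  feats <- expand.grid(participant = sprintf("P%02d", 1:n), scene = scenes,
                       stringsAsFactors = FALSE)
  feats$ratio_smile <- runif(nrow(feats))
  feats$switch_rate <- runif(nrow(feats))
  std <- standardize_features(feats)
  ratings <- data.frame(participant = rep(feats$participant, 2),
                        scene = rep(feats$scene, 2),
                        subscale = rep(c("physical", "mental"),
                                       each = nrow(feats)),
                        rating = 5 - std$data$ratio_smile + rnorm(2 * nrow(feats), 0, 0.5))
  mm <- fit_feature_workload_models(std, ratings)
  expect_s3_class(mm, "femg_mm")
  # feature main effect + interaction per (feature, subscale)
  expect_equal(nrow(mm), 2 * 2 * 2)
  expect_true(all(mm$q >= mm$p - 1e-12, na.rm = TRUE))
  got <- mm[mm$feature == "ratio_smile" & mm$subscale == "physical" &
              mm$term == "feature", ]
  expect_lt(got$beta, -0.5)
  expect_true(got$converged)

  expect_error(fit_feature_workload_models(std, ratings,
                                           features = "nonexistent"),
               "unknown")
})

test_that("BH adjustment matches hand cases and the brute-force oracle", {
  fd <- apply_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(fd$q, rep(0.04, 4))
  expect_true(all(fd$significant))
  expect_equal(apply_fdr(0.05)$q, 0.05)
  expect_error(apply_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    q <- apply_fdr(p)$q
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})
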