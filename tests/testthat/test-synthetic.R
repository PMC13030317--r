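test_that("participant profiles are deterministic and respect ranges", {
  cfg <- test_synth_config()
  p1 <- generate_participant_profile(5, cfg)
  p2 <- generate_participant_profile(5, cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$mvic > p1$neutral_baseline))

  # degenerate intervals pin both parameters exactly
  cfgd <- test_synth_config(baseline_tone_range = c(0.2, 0.2),
                            mvic_range = c(1.2, 1.2))
  pd <- generate_participant_profile(1, cfgd)
  expect_equal(unname(pd$neutral_baseline), rep(0.2, 7))
  expect_equal(unname(pd$mvic), rep(1.2, 7))

  # inverted range rejected
  expect_error(test_synth_config(baseline_tone_range = c(0.3, 0.1)),
               "range")

  # empirical support of tone draws stays inside the configured range
  cfgr <- test_synth_config(baseline_tone_range = c(0.1, 0.3))
  tones <- unlist(lapply(1:150, function(s)
    generate_participant_profile(s, cfgr)$neutral_baseline))
  expect_gte(min(tones), 0.1)
  expect_lte(max(tones), 0.3)
})

test_that("expression scripts follow the configured renewal process", {
  cfg <- test_synth_config()
  zero <- lapply(scene_levels(), function(s) c(smile = 0, frown = 0,
                                               raised_eyebrow = 0))
  names(zero) <- scene_levels()
  cfg0 <- test_synth_config(burst_rate_per_scene = zero)
  s0 <- generate_expression_script("physical", 200, cfg0, seed = 3)
  expect_true(all(s0$labels == "neutral"))

  s1 <- generate_expression_script("emotional", 100, cfg, seed = 9)
  s2 <- generate_expression_script("emotional", 100, cfg, seed = 9)
  expect_identical(s1, s2)
  expect_error(generate_expression_script("unknown_scene", 10, cfg, 1))
  expect_error(generate_expression_script("baseline", 0, cfg, 1))

  # Monte-Carlo occupancy ordering at 10k steps: cognitive < baseline ~
  # emotional < physical ~ dual; physical smile-dominant, emotional
  # eyebrow-enriched
  occ <- sapply(c("cognitive", "baseline", "emotional", "physical", "dual"),
                function(sc) {
    s <- generate_expression_script(sc, 10000, cfg, seed = 77)
    mean(s$labels != "neutral")
  })
  expect_lt(occ["cognitive"], occ["baseline"])
  expect_lt(occ["cognitive"], occ["physical"])
  expect_lt(occ["baseline"], occ["physical"])
  sp <- generate_expression_script("physical", 10000, cfg, seed = 78)
  tab <- table(sp$labels)
  expect_gt(tab["smile"], tab["frown"] + tab["raised_eyebrow"])
  se <- generate_expression_script("emotional", 10000, cfg, seed = 79)
  tabe <- table(se$labels)
  expect_gt(tabe["raised_eyebrow"], tabe["smile"])
})

test_that("script occupancy converges to the renewal-process expectation", {
  # expected occupancy of the two-state renewal process: mean neutral dwell
  # 1/p_start steps vs mean burst length, occupancy = d / (d + 1/p)
  cfg <- test_synth_config()
  rates <- cfg$burst_rate_per_scene$physical
  p_start <- 1 - exp(-sum(rates) * cfg$window_duration / 60)
  d_mean <- mean(pmax(1, round(
    seq(cfg$burst_duration_range[1], cfg$burst_duration_range[2],
        length.out = 200) / cfg$window_duration)))
  expected <- d_mean / (d_mean + 1 / p_start)
  s <- generate_expression_script("physical", 10000, cfg, seed = 5)
  occ <- mean(s$labels != "neutral")
  se_mc <- sqrt(expected * (1 - expected) / 10000) *
    sqrt(d_mean * 2)  # runs are correlated; inflate the binomial SE
  expect_lt(abs(occ - expected), max(3 * se_mc, 0.03))
})

test_that("rendered fEMG activates involved channels per the FACS map", {
  cfg <- test_synth_config()
  prof <- generate_participant_profile(2, cfg)
  mk_script <- function(lab, n = 30) {
    s <- generate_expression_script("baseline", n, cfg, seed = 1)
    s$labels <- factor(rep(lab, n), levels = expression_levels())
    s
  }
  rec_smile <- render_femg(mk_script("smile"), prof, cfg, seed = 4)
  rec_neu <- render_femg(mk_script("neutral"), prof, cfg, seed = 4)
  for (cc in involved_channels("smile"))
    expect_gt(mean(rec_smile$samples[, cc]), mean(rec_neu$samples[, cc]))

  rec_frown <- render_femg(mk_script("frown"), prof, cfg, seed = 4)
  for (cc in involved_channels("frown"))
    expect_gt(mean(rec_frown$samples[, cc]), mean(rec_neu$samples[, cc]))
  # zygomaticus unchanged within noise for a frown
  span <- prof$mvic - prof$neutral_baseline
  noise_se <- span["zygomaticus_left"] / cfg$snr /
    sqrt(nrow(rec_frown$samples))
  expect_lt(abs(mean(rec_frown$samples[, "zygomaticus_left"]) -
                  mean(rec_neu$samples[, "zygomaticus_left"])),
            4 * noise_se)

  # noise-free, burst-free limit: every sample equals the channel tone
  cfg_nf <- test_synth_config(snr = 1e9)
  s_neu <- mk_script("neutral")
  rec_nf <- render_femg(s_neu, prof, cfg_nf, seed = 1)
  for (cc in femg_channels())
    expect_equal(unname(rec_nf$samples[, cc]),
                 rep(unname(prof$neutral_baseline[cc]),
                     nrow(rec_nf$samples)), tolerance = 1e-6)

  expect_error(render_femg(mk_script("smile"), {
    p2 <- prof; p2$participant <- "other"; p2
  }, cfg), "participant")
})

test_that("class-conditional channel means separate involved from
           non-involved channels", {
  cfg <- test_synth_config(n = 2, seed = 21)
  prof <- generate_participant_profile(8, cfg)
  scr <- generate_expression_script("physical", 300, cfg, seed = 31)
  rec <- render_femg(scr, prof, cfg, seed = 32)
  spw <- cfg$sample_rate * cfg$window_duration
  lab_per_sample <- rep(as.character(scr$labels), each = spw)
  for (expr in c("smile", "frown", "raised_eyebrow")) {
    sel <- lab_per_sample == expr
    if (sum(sel) < 5 * spw) next
    for (cc in involved_channels(expr))
      expect_gt(mean(rec$samples[sel, cc]),
                mean(rec$samples[lab_per_sample == "neutral", cc]))
  }
})

test_that("calibration sessions cover all labels and reach MVIC", {
  cfg <- test_synth_config(snr = 40)
  prof <- generate_participant_profile(3, cfg)
  ses <- generate_calibration_session(prof, cfg, seed = 6)
  expect_setequal(unique(ses$events$label), expression_levels())

  labs <- sample_labels(ses, "expression")
  smile_amp <- ses$samples[labs == "smile", "zygomaticus_left"]
  expect_lt(abs(quantile(smile_amp, 0.95) - prof$mvic["zygomaticus_left"]) /
              prof$mvic["zygomaticus_left"], 0.05)
  neu <- ses$samples[labs == "neutral", ]
  for (cc in femg_channels())
    expect_lt(abs(median(neu[, cc]) - prof$neutral_baseline[cc]),
              4 * (prof$mvic[cc] - prof$neutral_baseline[cc]) / cfg$snr)
})

test_that("workload ratings follow the planted linear mixed model", {
  cfg <- test_synth_config(noise_sd = 0, random_intercept_sd = 0)
  feats <- data.frame(participant = rep(c("P01", "P02"), each = 2),
                      scene = rep(c("baseline", "physical"), 2),
                      ratio_smile = c(0.1, 0.4, 0.2, 0.3))
  r <- generate_workload_ratings(feats, cfg, seed = 1)
  # with no noise, no random intercepts, no planted betas: intercept + scene
  expect_equal(r$rating,
               cfg$tlx_intercept + unname(cfg$scene_effects[r$scene]))

  cfg2 <- test_synth_config()
  r2 <- generate_workload_ratings(feats, cfg2, seed = 2)
  expect_true(all(r2$rating >= 0 & r2$rating <= 10))
  expect_equal(nrow(r2), nrow(feats) * length(cfg2$subscales))

  expect_error(generate_workload_ratings(
    feats, test_synth_config(planted_betas = list(
      physical = c(not_a_feature = -1))), seed = 1), "unknown feature")

  # planted negative effect produces a negative feature-rating correlation
  cfgb <- test_synth_config(
    planted_betas = list(physical = c(ratio_smile = -1)),
    noise_sd = 0.3, random_intercept_sd = 0)
  n <- 200
  fb <- data.frame(participant = sprintf("P%03d", 1:n),
                   scene = "physical",
                   ratio_smile = runif(n))
  rb <- generate_workload_ratings(fb, cfgb, seed = 3)
  rb <- rb[rb$subscale == "physical", ]
  expect_lt(cor(fb$ratio_smile, rb$rating), -0.5)
})

test_that("cohort generation counts, determinism, and guards", {
  cfg <- synthetic_config(n_participants = 3, seed = 13, sample_rate = 20,
                          scene_duration = 20, baseline_duration = 30,
                          calibration_hold = 3, calibration_reps = 1,
                          snr = 30)
  co <- generate_cohort(cfg)
  expect_length(co$calibration, 3)
  expect_equal(sum(lengths(co$recordings)), 3 * 5)
  expect_equal(nrow(co$true_features), 15)
  expect_equal(nrow(co$ratings), 15 * 8)

  co2 <- generate_cohort(cfg)
  expect_identical(serialize(co, NULL), serialize(co2, NULL))

  expect_error(generate_cohort(test_synth_config(n = 1)),
               "n_participants")
})
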