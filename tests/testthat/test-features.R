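lab <- function(...) factor(c(...), levels = expression_levels())
N <- "neutral"; S <- "smile"; Fr <- "frown"; R <- "raised_eyebrow"

test_that("ratios, counts, and worked transition examples are exact", {
  rc <- compute_ratios_counts(lab(N, N, S, Fr))
  expect_equal(unname(rc[paste0("count_", expression_levels())]),
               c(2, 1, 1, 0))
  expect_equal(unname(rc["total_frames"]), 4)
  expect_equal(unname(rc[paste0("ratio_", expression_levels())]),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(compute_ratios_counts(rep(lab(N), 10))["ratio_neutral"]),
               1)

  tm <- compute_transition_matrix(lab(N, S, N, Fr))
  expect_equal(sum(tm$counts), 3)
  expect_equal(unname(tm$counts["neutral", "smile"]), 1)
  expect_equal(unname(tm$counts["smile", "neutral"]), 1)
  expect_equal(unname(tm$counts["neutral", "frown"]), 1)

  tm2 <- compute_transition_matrix(rep(lab(S), 5))
  expect_equal(unname(tm2$counts["smile", "smile"]), 4)
  expect_equal(unname(tm2$probs["smile", "smile"]), 1)
  expect_equal(sum(tm2$probs["neutral", ]), 0)  # never-visited row stays 0

  tm3 <- compute_transition_matrix(lab(N, S, S, N, Fr, N))
  expect_equal(unname(tm3$probs["neutral", "smile"]), 0.5)
  expect_equal(unname(tm3$probs["neutral", "frown"]), 0.5)
})

test_that("burst statistics match hand-enumerated run lengths", {
  bs <- compute_burst_statistics(lab(S, S, S, N, S))
  expect_equal(unname(bs[c("burst_smile_count", "burst_smile_mean",
                           "burst_smile_median", "burst_smile_min",
                           "burst_smile_max", "burst_smile_std")]),
               c(2, 2, 2, 1, 3, 1))
  expect_equal(unname(bs["avg_burst_len_smile"]), 2)

  bs2 <- compute_burst_statistics(rep(lab(N), 7))
  expect_equal(unname(bs2["burst_neutral_count"]), 1)
  expect_equal(unname(bs2["burst_neutral_mean"]), 7)
  expect_true(all(bs2[grep("burst_smile", names(bs2))] == 0))
})

test_that("entropy, dynamics, dominance, latency hand cases", {
  expect_equal(unname(compute_entropy(rep(lab(N), 4))), c(0, 0))
  expect_equal(unname(compute_entropy(lab(N, S, Fr, R))), c(2, 1))
  expect_equal(unname(compute_entropy(lab(N, N, S, S))), c(1, 0.5))

  expect_equal(unname(compute_dynamics(lab(N, S, N, S))), c(3, 1, 1))
  expect_equal(unname(compute_dynamics(rep(lab(Fr), 10))), c(0, 0, 10))

  expect_equal(unname(compute_dominance(lab(S, Fr, R))),
               c(1 / 3, 0))
  expect_equal(unname(compute_dominance(lab(S, S, N))), c(1, 2 / 3))
  expect_equal(unname(compute_dominance(rep(lab(N), 5))), c(0, 0))

  expect_equal(unname(compute_latency(lab(N, N, S, N, N, N, N, N, N, N))
                      ["latency_smile"]), 0.2)
  expect_equal(unname(compute_latency(rep(lab(N), 5))["latency_smile"]), 1)
  # leading smile without a preceding neutral does not count
  expect_equal(unname(compute_latency(lab(S, N, N))["latency_smile"]), 1)
})

test_that("feature vector has the 81 registry names and composes sub-ops", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 81)
  v <- compute_feature_vector(lab(N, S, S, N, Fr))
  expect_length(v, 81)
  expect_identical(names(v), reg$name)

  allneu <- compute_feature_vector(rep(lab(N), 6))
  expect_equal(unname(allneu["ratio_neutral"]), 1)
  smile_feats <- grep("smile", names(allneu), value = TRUE)
  expect_true(all(allneu[setdiff(smile_feats, "latency_smile")] == 0))
  expect_equal(unname(allneu["latency_smile"]), 1)

  set.seed(99)
  for (i in 1:25) {
    sq <- random_label_seq(sample(1:40, 1))
    v <- compute_feature_vector(sq)
    expect_equal(unname(v["total_frames"]), length(sq))
    # compositional consistency with sub-operations
    expect_equal(v[names(compute_entropy(sq))], compute_entropy(sq))
    expect_equal(unname(v["switches"]),
                 unname(compute_dynamics(sq)["switches"]))
  }
})

test_that("conservation and reversal invariances hold on random sequences", {
  set.seed(7)
  for (i in 1:50) {
    sq <- random_label_seq(sample(2:50, 1))
    v <- compute_feature_vector(sq)
    expect_equal(sum(v[paste0("ratio_", expression_levels())]), 1)
    expect_equal(sum(v[paste0("count_", expression_levels())]),
                 unname(v["total_frames"]))
    expect_equal(sum(v[grep("^trans_count_", names(v))]),
                 unname(v["total_frames"]) - 1)
    # per class, run lengths sum to the class count
    for (cls in expression_levels())
      expect_equal(unname(v[paste0("burst_", cls, "_count")] *
                            v[paste0("burst_", cls, "_mean")]),
                   unname(v[paste0("count_", cls)]))
    # switches + 1 = number of runs
    expect_equal(unname(v["switches"] + 1),
                 sum(v[paste0("burst_", expression_levels(), "_count")]))

    rv <- compute_feature_vector(rev(sq))
    expect_equal(rv[paste0("ratio_", expression_levels())],
                 v[paste0("ratio_", expression_levels())])
    expect_equal(rv["entropy"], v["entropy"])
    # transition counts transpose under reversal
    for (a in expression_levels()) for (b in expression_levels())
      expect_equal(unname(rv[paste0("trans_count_", a, "_", b)]),
                   unname(v[paste0("trans_count_", b, "_", a)]))
  }
})

test_that("empty sequences are rejected", {
  empty <- factor(character(0), levels = expression_levels())
  expect_error(compute_feature_vector(empty), "empty")
  expect_error(compute_ratios_counts(empty), "empty")
})
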