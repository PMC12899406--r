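test_that("simulated trials have the declared shapes and metadata", {
  spec <- cohort_spec(trial_duration = 1.5, seed = 5)
  tr <- simulate_trial(spec, "S01", 14, 1, "active", 1)
  expect_s3_class(tr, "trial_record")
  expect_equal(dim(tr$emg), c(8L, 1500L))
  expect_length(tr$velocity, 750L)
  expect_equal(tr$parity, 1L)           # even action -> return/flexion
  expect_equal(tr$label, encode_label(1, 1))
  expect_error(simulate_trial(spec, "S01", 19, 1), "1..18")
  expect_error(simulate_trial(spec, "S01", 1, 3), "score")
})

test_that("trial generation is deterministic and parity-consistent", {
  spec <- cohort_spec(n_subjects_per_group = 1, trials_per_action = 1,
                      trial_duration = 1, seed = 9)
  a <- simulate_trial(spec, "S02", 7, 2, "passive", 1)
  b <- simulate_trial(spec, "S02", 7, 2, "passive", 1)
  expect_identical(a, b)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1, co2)
  expect_equal(co1$manifest$parity,
               as.integer(co1$manifest$action_id %% 2L == 0L))
  for (tr in co1$trials[c(1, 20, 50)])
    expect_equal(tr$parity, as.integer(tr$action_id %% 2L == 0L))
})

test_that("sEMG channels are band-limited to 20-450 Hz", {
  tr <- simulate_trial(cohort_spec(seed = 3), "S01", 1, 2, "active", 1)
  for (ch in c(1L, 6L)) {
    ps <- welch_psd <- amwfnet:::welch_psd(tr$emg[ch, ], 1000, 512)
    inband <- ps$freq >= 20 & ps$freq <= 450
    expect_lt(sum(ps$power[!inband]) / sum(ps$power), 0.01)
  }
})

test_that("cohort enumeration, balance and imbalance options work", {
  co <- fx_recovery_splits()$cohort
  # 10 subjects x 18 actions x 2 trials x 2 stages
  expect_equal(length(co$trials), 720L)
  expect_equal(nrow(co$manifest), 720L)
  expect_setequal(unique(co$manifest$stage), c("passive", "active"))
  # balanced spec -> equal trial counts per score
  bal <- fx_tiny_cohort()
  expect_true(all(table(bal$manifest$score) == table(bal$manifest$score)[1]))
  # stroke-like grouping: score-2 subjects are the healthy group
  expect_setequal(unique(bal$manifest$group[bal$manifest$score == 2]), "healthy")
  expect_setequal(unique(bal$manifest$group[bal$manifest$score < 2]), "stroke")
  # imbalance option shaped like the study's sample table: 2 > 1 > 0
  spec_imb <- cohort_spec(n_subjects_per_group = 1, trials_per_action = 1,
                          trial_duration = 0.8, class_counts = c(40, 60, 90),
                          seed = 2)
  imb <- simulate_cohort(spec_imb)
  counts <- table(imb$manifest$score)
  expect_equal(as.integer(counts), c(40L, 60L, 90L))
  expect_true(counts["2"] > counts["1"] && counts["1"] > counts["0"])
  # infeasible counts (below one trial per cell) are rejected
  expect_error(
    simulate_cohort(cohort_spec(n_subjects_per_group = 1,
                                class_counts = c(10, 40, 40), seed = 2)),
    "infeasible")
})

test_that("zero class effect removes score dependence of the signal stats", {
  spec0 <- cohort_spec(class_effect_size = 0, trial_duration = 1, seed = 21)
  stats_for <- function(score) {
    tr <- simulate_trial(spec0, "SX", 3, score, "active", 1)
    c(mean(abs(tr$emg)), max(tr$velocity))
  }
  s <- vapply(0:2, stats_for, numeric(2))
  # identical RNG substreams + no effect => identical statistics
  expect_equal(s[, 1], s[, 2], tolerance = 1e-12)
  expect_equal(s[, 2], s[, 3], tolerance = 1e-12)
})

test_that("score separability grows with the class effect size", {
  burst_fdr <- function(ces) {
    spec <- cohort_spec(n_subjects_per_group = 2, trials_per_action = 2,
                        trial_duration = 1, class_effect_size = ces, seed = 33)
    co <- simulate_cohort(spec)
    keep <- co$manifest$stage == "active"
    amp <- vapply(co$trials[keep], function(t) mean(abs(t$emg)), numeric(1))
    fisher_discriminant_ratio(amp, co$manifest$score[keep])
  }
  f <- vapply(c(0, 1, 3), burst_fdr, numeric(1))
  expect_true(f[1] <= f[2] && f[2] <= f[3])
  # with the effect off, only subject idiosyncrasy separates the groups;
  # switching it on must dominate that baseline
  expect_gt(f[3], 2 * f[1])
})

test_that("cohorts round-trip through save/load", {
  co <- fx_tiny_cohort()
  dir <- withr::local_tempdir()
  save_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_identical(load_cohort(dir)$manifest, co$manifest)
})
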