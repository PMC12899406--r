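test_that("metrics reproduce hand-computed confusion arithmetic", {
  # perfect prediction
  r <- compute_metrics(c(0, 1, 2, 3, 4, 5), c(0, 1, 2, 3, 4, 5))
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_precision, 1)
  expect_equal(r$macro_recall, 1)
  expect_equal(r$macro_f1, 1)
  # two-class hand example: acc 3/4, macro precision (1/1 + 2/3)/2 = 5/6
  r2 <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)
  expect_equal(r2$accuracy, 0.75)
  expect_equal(r2$macro_precision, 5 / 6)
  expect_equal(r2$macro_recall, (1 / 2 + 1) / 2)
  expect_equal(as.integer(r2$confusion), c(1L, 0L, 1L, 2L))
  # single-class truth predicted correctly: that class recall 1
  r3 <- compute_metrics(rep(4L, 5), rep(4L, 5))
  expect_equal(r3$per_class$recall[5], 1)
  expect_equal(sum(r3$confusion), r3$n)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
  expect_error(compute_metrics(0, 7), "labels")
})

test_that("confusion totals are conserved and macro-F1 is order-invariant", {
  set.seed(11)
  y <- sample(0:5, 120, replace = TRUE)
  p <- y
  flip <- sample(120, 30)
  p[flip] <- sample(0:5, 30, replace = TRUE)
  r <- compute_metrics(y, p)
  expect_equal(sum(r$confusion), 120)
  # relabelling classes by a permutation permutes the matrix consistently
  perm <- amwfnet:::with_seed(3, sample(0:5))
  r2 <- compute_metrics(perm[y + 1], perm[p + 1])
  expect_equal(r2$accuracy, r$accuracy)
  expect_equal(r2$macro_f1, r$macro_f1, tolerance = 1e-12)
  expect_equal(r2$confusion[as.character(perm), as.character(perm)],
               r$confusion, ignore_attr = TRUE)
  # stratified sub-report restricted to the stroke-like labels 0..3
  keep <- y <= 3
  rs <- stratified_metrics(y, p, keep)
  expect_equal(rs$n, sum(keep))
  expect_equal(sum(rs$confusion[1:4, ]), sum(keep))
})

test_that("Fisher ratio matches the two-line hand calculation", {
  # groups {0,1} and {2,3}: means 0.5/2.5, within-var 0.5, between 1 -> 2
  expect_equal(fisher_discriminant_ratio(c(0, 1, 2, 3), c(0, 0, 1, 1)), 2)
  # identical distributions: near zero
  set.seed(5)
  x <- stats::rnorm(2000)
  expect_lt(fisher_discriminant_ratio(x, rep(0:1, 1000)), 0.01)
  # degenerate zero-within-variance groups flag Inf with a warning
  expect_warning(v <- fisher_discriminant_ratio(c(0, 0, 1, 1), c(0, 0, 1, 1)),
                 "Inf")
  expect_identical(v, Inf)
  expect_error(fisher_discriminant_ratio(1:4, rep(1, 4)), "2 groups")
  expect_error(fisher_discriminant_ratio(1:3, c(1, 1, 2)), "2 observations")
})

test_that("attention extraction aggregates per-sample softmax weights", {
  fx <- fx_std_splits()
  m <- do.call(amwfnet_model, c(fx_model_args(), list(seed = 2)))
  ts <- amwfnet:::tensor_subset(fx$splits$active_val, 1:12)
  att <- extract_attention(m, ts)
  expect_equal(rowSums(att$alpha_emg), rep(1, 12), tolerance = 1e-9)
  expect_equal(rowSums(att$alpha_kine), rep(1, 12), tolerance = 1e-9)
  expect_equal(rowSums(att$w), rep(1, 12), tolerance = 1e-9)
  expect_equal(sum(att$emg_mean), 1, tolerance = 1e-9)
  expect_named(att$emg_mean, muscle_names())
  # aggregation over k identical samples equals the single-sample weights
  ts1 <- amwfnet:::tensor_subset(fx$splits$active_val, c(1, 1, 1))
  att1 <- extract_attention(m, ts1)
  expect_equal(att1$emg_mean, att$alpha_emg[1, ], tolerance = 1e-12)
  # per-action rows are convex weights
  rows <- stats::na.omit(att$emg_by_action)
  expect_equal(rowSums(rows), rep(1, nrow(rows)), ignore_attr = TRUE)
})

test_that("the ablation driver runs named variants only", {
  expect_error(ablation_suite(list(), variants = c("full", "nope")),
               "unknown variant")
})

test_that("the temperature sweep reports one deterministic row per tau", {
  fx <- fixture("sweep", {
    co <- simulate_cohort(cohort_spec(n_subjects_per_group = 2,
                                      trials_per_action = 1,
                                      trial_duration = 1.5,
                                      class_effect_size = 2, seed = 19))
    sp <- subject_split(co$manifest, seed = 1)
    splits <- prepare_training_data(co, sp, cwt = fx_cwt(), balance = FALSE,
                                    seed = 1, stages = "active")
    cfg <- train_config(stage2_lr = 1e-3, stage2_epochs = 1, patience = 5)
    margs <- utils::modifyList(fx_model_args(),
                               list(channels = c(4, 8, 8, 8),
                                    gate_hidden = 16, head_hidden = 16))
    list(splits = splits, cfg = cfg, margs = margs,
         res = temperature_sweep(splits, model_args = margs, cfg = cfg,
                                 seed = 6))
  })
  res <- fx$res
  expect_equal(nrow(res), 9L)
  expect_equal(res$tau, c(0.5, 1, 1.5, 2, 2.5, 3, 5, 8, 10))
  expect_true(all(abs(res$w_emg + res$w_kine - 1) < 1e-9))
  expect_true(all(res$gate_entropy >= 0 & res$gate_entropy <= log(2) + 1e-9))
  # identical seed and tau reproduce the row exactly
  again <- temperature_sweep(fx$splits, taus = 2.5, model_args = fx$margs,
                             cfg = fx$cfg, seed = 6)
  expect_equal(again, res[res$tau == 2.5, ], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(temperature_sweep(fx$splits, taus = c(1, -1)), "positive")
})

test_that("plot helpers run headlessly on real objects", {
  r <- compute_metrics(c(0, 1, 2), c(0, 1, 1))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot_confusion(r))
  fx <- fx_std_splits()
  m <- do.call(amwfnet_model, c(fx_model_args(), list(seed = 2)))
  att <- extract_attention(m, amwfnet:::tensor_subset(fx$splits$active_val, 1:6))
  expect_no_error(plot_attention(att, "emg"))
  hist <- data.frame(epoch = 1:3, w_emg = c(0.5, 0.4, 0.3),
                     w_kine = c(0.5, 0.6, 0.7))
  expect_no_error(plot_gate_trajectory(hist))
  grDevices::dev.off()
})
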