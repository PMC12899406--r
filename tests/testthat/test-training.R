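fake_manifest <- function(n_subjects) {
  data.frame(subject_id = rep(sprintf("P%02d", seq_len(n_subjects)), each = 2),
             stage = "active")
}

test_that("subject-wise split gives 24/8/8 for 40 subjects with no overlap", {
  sp <- subject_split(fake_manifest(40), seed = 5)
  expect_equal(lengths(sp$subjects),
               c(train = 24L, val = 8L, test = 8L))
  expect_length(intersect(sp$subjects$train, sp$subjects$val), 0)
  expect_length(intersect(sp$subjects$train, sp$subjects$test), 0)
  expect_length(intersect(sp$subjects$val, sp$subjects$test), 0)
  # every trial inherits its subject's partition
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:80)
})

test_that("splits are deterministic in the seed and validate fractions", {
  m <- fake_manifest(10)
  expect_identical(subject_split(m, seed = 3), subject_split(m, seed = 3))
  expect_false(identical(subject_split(m, seed = 3)$subjects$train,
                         subject_split(m, seed = 4)$subjects$train))
  expect_error(subject_split(m, fractions = c(0.7, 0.2, 0.2)), "sum to 1")
  expect_error(subject_split(fake_manifest(4)), "5 subjects")
})

raw_trial <- function(seed = 1) {
  simulate_trial(cohort_spec(trial_duration = 1, seed = seed), "S01", 2, 1)
}

test_that("identity augmentation is a no-op and warping rescales durations", {
  tr <- raw_trial()
  cfg0 <- augmentation_config(amplitude_range = c(1, 1), warp_range = c(1, 1),
                              noise_sigma_emg = 0, noise_sigma_kine = 0)
  same <- augment_trial(tr, cfg0)
  expect_equal(same$emg, tr$emg)
  expect_equal(same$velocity, tr$velocity)
  aug <- augment_trial(tr, factors = list(amp_emg = 1, amp_kine = 1,
                                          warp = 0.9))
  expect_equal(ncol(aug$emg), round(0.9 * ncol(tr$emg)), tolerance = 1)
  expect_equal(length(aug$velocity), round(0.9 * length(tr$velocity)),
               tolerance = 1)
  # both modalities share the single warp factor
  expect_equal(ncol(aug$emg) / ncol(tr$emg),
               length(aug$velocity) / length(tr$velocity), tolerance = 2e-3)
  expect_error(augment_trial(tr, factors = list(warp = 1.5)), "warp factor")
  expect_error(augment_trial(tr, factors = list(amp_emg = 0.5)),
               "amplitude factor")
  expect_error(augment_trial(preprocess_trial(tr)), "raw trials")
})

test_that("jerk of an augmented trial is the derivative chain of its speed", {
  aug <- augment_trial(raw_trial(3), factors = list(amp_emg = 1.05,
                                                    amp_kine = 0.95,
                                                    warp = 1.1))
  k <- derive_kinematics(aug$velocity, aug$kine_fs)
  fsp <- filter_spec()
  recomputed <- amwfnet:::two_stage_smooth(
    amwfnet:::central_diff(k$acceleration, aug$kine_fs), aug$kine_fs, fsp)
  expect_equal(k$jerk, recomputed, tolerance = 1e-10)
})

test_that("class balancing tops up minorities and refuses other partitions", {
  tiny <- function(score, n) replicate(n, {
    tr <- raw_trial(score + 10)
    tr$score <- as.integer(score)
    tr$label <- encode_label(tr$score, tr$parity)
    tr
  }, simplify = FALSE)
  trials <- c(tiny(0, 4), tiny(1, 8), tiny(2, 16))
  bal <- balance_training_set(trials, rep("train", length(trials)), seed = 2)
  scores <- vapply(bal$trials, function(t) t$score, integer(1))
  expect_equal(as.integer(table(scores)), c(16L, 16L, 16L))
  expect_length(bal$trials, 48L)          # 12 + 8 augmented additions
  expect_equal(bal$origin[1:28], 1:28)
  # already balanced -> no additions
  bal2 <- balance_training_set(c(tiny(0, 2), tiny(1, 2), tiny(2, 2)),
                               rep("train", 6))
  expect_length(bal2$trials, 6L)
  expect_error(balance_training_set(trials, rep("val", length(trials))),
               "training partition")
})

test_that("early stopping halts after the configured patience", {
  st <- NULL
  losses <- c(1, 0.8, 0.79, rep(0.8, 10))   # no improvement after epoch 3
  stopped_at <- NA
  for (i in seq_along(losses)) {
    st <- amwfnet:::early_stop_update(st, losses[i], patience = 10)
    if (st$stop) { stopped_at <- i; break }
  }
  expect_equal(stopped_at, 13)            # 10 bad epochs after the best
  expect_equal(st$best_epoch, 3)
  expect_equal(st$best, 0.79)
})

test_that("two-stage training learns, clips gradients and keeps histories", {
  fx <- fx_std_splits()
  m <- do.call(amwfnet_model, c(fx_model_args(), list(seed = 31)))
  cfg <- train_config(stage1_epochs = 3, stage2_epochs = 4, patience = 10)
  fit <- train_two_stage(m, fx$splits$passive_train, fx$splits$passive_val,
                         fx$splits$active_train, fx$splits$active_val,
                         cfg = cfg, seed = 8)
  expect_lte(nrow(fit$stage1), 3)
  expect_lte(nrow(fit$stage2), 4)
  expect_true(all(fit$stage1$grad_norm <= cfg$clip_norm + 1e-9))
  expect_true(all(fit$stage2$grad_norm <= cfg$clip_norm + 1e-9))
  expect_lt(utils::tail(fit$stage2$train_loss, 1), fit$stage1$train_loss[1])
  # gate weights recorded every epoch, summing to 1
  expect_equal(fit$stage2$w_emg + fit$stage2$w_kine, rep(1, nrow(fit$stage2)),
               tolerance = 1e-9)
  expect_error(train_two_stage(m, NULL, NULL,
                               amwfnet:::tensor_subset(fx$splits$active_train,
                                                       integer(0)),
                               fx$splits$active_val, cfg = cfg),
               "empty stage dataset")
})

test_that("training is reproducible under fixed seeds", {
  fx <- fx_std_splits()
  cfg <- train_config(stage2_epochs = 2, patience = 10)
  run <- function() {
    m <- do.call(amwfnet_model, c(fx_model_args(), list(seed = 5)))
    train_two_stage(m, NULL, NULL, fx$splits$active_train,
                    fx$splits$active_val, cfg = cfg, seed = 4)$stage2
  }
  expect_equal(run(), run(), tolerance = 1e-12)
})

test_that("stage-1 pretraining does not slow convergence to threshold", {
  fx <- fx_std_splits()
  cfg_pre <- train_config(stage1_epochs = 3, stage2_epochs = 5, patience = 10)
  threshold <- 0.8
  epochs_to <- function(hist) {
    hit <- which(hist$val_accuracy >= threshold)
    if (length(hit) == 0) nrow(hist) + 1L else hit[1]
  }
  res <- vapply(1:3, function(s) {
    m <- do.call(amwfnet_model, c(fx_model_args(), list(seed = 40 + s)))
    pre <- train_two_stage(m, fx$splits$passive_train, fx$splits$passive_val,
                           fx$splits$active_train, fx$splits$active_val,
                           cfg = cfg_pre, seed = s)
    m2 <- do.call(amwfnet_model, c(fx_model_args(), list(seed = 40 + s)))
    scr <- train_two_stage(m2, NULL, NULL, fx$splits$active_train,
                           fx$splits$active_val, cfg = cfg_pre, seed = s)
    c(pre = epochs_to(pre$stage2), scratch = epochs_to(scr$stage2))
  }, numeric(2))
  expect_lte(stats::median(res["pre", ]), stats::median(res["scratch", ]))
})
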