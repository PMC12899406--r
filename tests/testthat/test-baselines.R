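test_that("sEMG descriptors match hand-computed values", {
  # constant signal: energy features only
  f <- emg_features(rep(3, 100), 1000)
  expect_equal(unname(f[c("RMS", "MAV", "VAR", "WL", "ZC", "SSC")]),
               c(3, 3, 0, 0, 0, 0))
  # alternating signal: waveform length and zero crossings by hand
  f2 <- emg_features(c(1, -1, 1, -1), 1000)
  expect_equal(unname(f2["WL"]), 6)
  expect_equal(unname(f2["ZC"]), 3)
  expect_equal(unname(f2["SSC"]), 2)
  expect_error(emg_features(numeric(0)), "2 samples")
})

test_that("spectral features locate a pure tone", {
  fs <- 1000
  x <- sin(2 * pi * 120 * (1:2048) / fs)
  f <- emg_features(x, fs)
  bin <- fs / 256                      # Welch segment resolution
  expect_lt(abs(f[["MDF"]] - 120), bin + 1e-9)
  expect_lt(abs(f[["MPF"]] - 120), bin + 1e-9)
})

test_that("feature scale covariance and invariance hold", {
  set.seed(9)
  x <- stats::rnorm(1000)
  a <- emg_features(x, 1000)
  b <- emg_features(2.5 * x, 1000)
  expect_equal(unname(b[c("RMS", "MAV", "WL")]),
               2.5 * unname(a[c("RMS", "MAV", "WL")]))
  expect_equal(unname(b["VAR"]), 2.5^2 * unname(a["VAR"]))
  expect_equal(unname(b[c("ZC", "SSC", "MDF", "MPF")]),
               unname(a[c("ZC", "SSC", "MDF", "MPF")]))
})

test_that("kinematic statistics behave on degenerate and smooth profiles", {
  kin <- structure(list(velocity = rep(2, 200), acceleration = numeric(200),
                        jerk = numeric(200), fs = 500),
                   class = "kinematic_channels")
  f <- kinematic_features(kin)
  expect_length(f, 30L)
  expect_equal(unname(f[c("velocity.mean", "velocity.std", "velocity.max",
                          "velocity.min", "velocity.median", "velocity.IQR",
                          "velocity.p2p")]),
               c(2, 0, 2, 2, 2, 0, 0))
  # smoothness ordering: ripple lengthens the spectral arc
  fs <- 500; t <- (1:500) / fs
  bell <- 30 * (t / 1)^2 * (1 - t / 1)^2
  sal_smooth <- spectral_arc_length(bell, fs)
  sal_rough <- spectral_arc_length(bell + 0.1 * sin(2 * pi * 8 * t), fs)
  expect_lt(abs(sal_smooth), abs(sal_rough))
  expect_lt(sal_rough, sal_smooth)      # more negative = less smooth
})

test_that("the 112-dimensional feature vector has the documented layout", {
  fv <- build_feature_vector(fx_trial())
  expect_length(fv, 112L)
  expect_equal(names(fv)[1], "FCR.RMS")
  expect_equal(names(fv)[64], "TBLa.MPF")
  expect_equal(names(fv)[65], "velocity.mean")
  expect_equal(names(fv)[95], "action.1")
  # action block one-hot at the trial's action
  act <- fv[95:112]
  expect_equal(sum(act), 1)
  expect_equal(unname(which(act == 1)), fx_trial()$action_id)
  expect_error(build_feature_vector(simulate_trial(cohort_spec(seed = 2),
                                                   "S1", 1, 1)),
               "preprocessed")
})

test_that("SVM and RF separate a strongly structured cohort and stay honest", {
  fx <- fx_std_splits()
  act <- which(fx$cohort$manifest$stage == "active")
  fe <- fixture("std_features", cohort_to_features(fx$cohort$trials[act]))
  man <- fx$cohort$manifest[act, ]
  sp <- subject_split(man, seed = 3)
  fb <- fit_baselines(fe$features, fe$labels, fe$subjects, sp, seed = 1)
  expect_equal(fb$rf_report$accuracy, 1)   # separable synthetic features
  expect_gt(fb$svm_report$accuracy, 0.8)
  # determinism
  fb2 <- fit_baselines(fe$features, fe$labels, fe$subjects, sp, seed = 1)
  expect_equal(predict(fb2$rf, scale(fe$features[sp$test, ],
                                     fb2$center, fb2$scale)),
               predict(fb$rf, scale(fe$features[sp$test, ],
                                    fb$center, fb$scale)))
  # label shuffling collapses accuracy to chance
  shuffled <- amwfnet:::with_seed(7, sample(fe$labels))
  fbs <- fit_baselines(fe$features, shuffled, fe$subjects, sp, seed = 1)
  expect_lt(abs(fbs$rf_report$accuracy - 1 / 6), 0.12)
  # leakage rejected
  bad <- sp; bad$test <- sp$train[1:5]
  expect_error(fit_baselines(fe$features, fe$labels, fe$subjects, bad),
               "leakage")
})

test_that("the dual-stream 1-D CNN mirrors the fusion head and learns", {
  fx <- fixture("cnn1d", {
    co <- simulate_cohort(cohort_spec(n_subjects_per_group = 3,
                                      trials_per_action = 1,
                                      class_effect_size = 3, seed = 17))
    act <- which(co$manifest$stage == "active")
    ss <- cohort_to_signals(co$trials[act], decimate = 8L)
    sp <- subject_split(co$manifest[act, ], seed = 1)
    r <- dual_stream_1dcnn(ss, sp,
                           model_args = list(channels = c(4, 8, 16, 16),
                                             gate_hidden = 16,
                                             head_hidden = 16),
                           cfg = train_config(stage2_lr = 1e-3,
                                              stage2_epochs = 16),
                           seed = 2)
    list(signals = ss, run = r)
  })
  m <- fx$run$model
  expect_equal(ncol(m$params[["head.fc2.W"]]), 6L)
  # encoder blocks are 1-D (1 x 9 kernels); fusion head identical in shape
  expect_equal(nrow(m$params[["enc_emg.b1.conv1.W"]]), 9L)
  m2d <- amwfnet_model(input_size = 16, channels = c(4, 8, 16, 16),
                       gate_hidden = 16, head_hidden = 16)
  non_enc <- function(mm) {
    nm <- names(mm$params)[!grepl("^enc_", names(mm$params))]
    lapply(mm$params[nm], dim)
  }
  expect_identical(non_enc(m), non_enc(m2d))
  # raw-signal training reaches above-chance accuracy on held-out subjects
  expect_gt(max(fx$run$history$val_accuracy), 1 / 6 + 0.1)
  expect_lte(nrow(fx$run$history), 16)
})
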