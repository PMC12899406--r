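# Shared fixtures, built once per test session and cached. Sizes are the
# desk-scale study conditions described in the methods vignette: 16x16
# scalograms at 48 scales and a width-reduced encoder keep every training
# experiment CPU-friendly while exercising the full architecture.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_cwt <- function() cwt_spec(n_scales = 48, out_size = c(16, 16))

# Width-reduced model arguments shared by all training experiments.
fx_model_args <- function() {
  list(input_size = 16, channels = c(8, 16, 32, 32),
       gate_hidden = 64, head_hidden = 64)
}

# A one-subject-per-group, 1 s cohort for fast shape/unit tests.
fx_tiny_cohort <- function() fixture("tiny_cohort", {
  simulate_cohort(cohort_spec(n_subjects_per_group = 1, trials_per_action = 1,
                              trial_duration = 1, class_effect_size = 1,
                              seed = 42))
})

# One preprocessed 3 s trial (default spec).
fx_trial <- function() fixture("trial", {
  preprocess_trial(simulate_trial(cohort_spec(seed = 7), "S01", 3, 1))
})

# Strongly separated 720-trial cohort (10 subjects, both stages) with
# subject-wise split and per-stage tensor sets: the recovery-suite data.
fx_recovery_splits <- function() fixture("recovery_splits", {
  co <- simulate_cohort(cohort_spec(n_subjects_per_group = c(3, 3, 4),
                                    trials_per_action = 2,
                                    class_effect_size = 3, seed = 101))
  sp <- subject_split(co$manifest, seed = 1)
  list(cohort = co, split = sp,
       splits = prepare_training_data(co, sp, cwt = fx_cwt(),
                                      balance = TRUE, seed = 1))
})

# Standard small cohort (both modalities informative) for ablation and
# training-protocol properties; active and passive stages tensorised.
fx_std_splits <- function() fixture("std_splits", {
  co <- simulate_cohort(cohort_spec(n_subjects_per_group = 3,
                                    trials_per_action = 1,
                                    class_effect_size = 3, seed = 13))
  sp <- subject_split(co$manifest, seed = 3)
  list(cohort = co, split = sp,
       splits = prepare_training_data(co, sp, cwt = fx_cwt(),
                                      balance = FALSE, seed = 1))
})

# Active-stage tensors for a cohort with the class signal planted in a
# single sEMG channel (ECU, channel 5); kinematics uninformative.
fx_planted_channel <- function() fixture("planted_channel", {
  co <- simulate_cohort(cohort_spec(n_subjects_per_group = 3,
                                    trials_per_action = 2,
                                    class_effect_size = 3,
                                    signal_channels = 5,
                                    effect_kine = FALSE, seed = 11))
  sp <- subject_split(co$manifest, seed = 2)
  prepare_training_data(co, sp, cwt = fx_cwt(), balance = FALSE,
                        seed = 1, stages = "active")
})

# Active-stage tensors with the class signal only in the kinematics.
fx_planted_modality <- function() fixture("planted_modality", {
  co <- simulate_cohort(cohort_spec(n_subjects_per_group = 3,
                                    trials_per_action = 2,
                                    class_effect_size = 3,
                                    effect_emg = FALSE, seed = 12))
  sp <- subject_split(co$manifest, seed = 2)
  prepare_training_data(co, sp, cwt = fx_cwt(), balance = FALSE,
                        seed = 1, stages = "active")
})

# Single-stage training shortcut used by the recovery experiments.
fx_train_single <- function(splits, model_seed, train_seed, epochs = 10,
                            variant = "full") {
  m <- do.call(amwfnet_model,
               c(fx_model_args(), list(seed = model_seed, variant = variant)))
  cfg <- train_config(stage2_lr = 1e-3, stage2_epochs = epochs, patience = 10)
  train_two_stage(m, NULL, NULL, splits$active_train, splits$active_val,
                  cfg = cfg, seed = train_seed)
}
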