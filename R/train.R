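# Subject-wise data handling, physically constrained augmentation, class
# balancing and the two-stage training protocol.

#' Subject-wise train/validation/test split
#'
#' Partitions subjects (never trials) into train/validation/test so no
#' individual contributes data to more than one partition — the split that
#' simulates diagnosing unseen patients. Fractions default to 60:20:20;
#' validation and test sizes are rounded down, the remainder (rounding
#' toward train) becomes training, so 40 subjects give 24/8/8.
#'
#' @param manifest Data frame with a `subject_id` column (one row per
#'   trial), e.g. from [simulate_cohort()].
#' @param fractions Length-3 numeric summing to 1 (train, val, test).
#' @param seed Shuffle seed.
#' @return List of class `subject_split` with integer row-index vectors
#'   `train`, `val`, `test` and the per-partition `subjects`.
#' @export
subject_split <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stop_if_not(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  subjects <- unique(manifest$subject_id)
  n <- length(subjects)
  stop_if_not(n >= 5, "need at least 5 subjects for a subject-wise split")
  ord <- with_seed(seed, sample(subjects))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  subj <- list(train = ord[seq_len(n_train)],
               val = ord[n_train + seq_len(n_val)],
               test = ord[n_train + n_val + seq_len(n_test)])
  idx <- lapply(subj, function(s) which(manifest$subject_id %in% s))
  structure(list(train = idx$train, val = idx$val, test = idx$test,
                 subjects = subj),
            class = "subject_split")
}

#' Augmentation settings
#'
#' Physically constrained augmentation for training trials only: amplitude
#' scaling (independent factor per modality, since activation intensity and
#' sensor gain vary independently), time warping with a single factor
#' applied synchronously to both modalities (temporal alignment must
#' survive), and modality-specific Gaussian noise. Jerk is never perturbed
#' directly: it is recomputed downstream from the augmented speed trace, so
#' higher-order derivatives stay physically consistent.
#'
#' @param amplitude_range,warp_range Length-2 ranges for the multiplicative
#'   factors.
#' @param noise_sigma_emg,noise_sigma_kine Gaussian noise standard
#'   deviations per modality.
#' @return List of class `augmentation_config`.
#' @export
augmentation_config <- function(amplitude_range = c(0.9, 1.1),
                                warp_range = c(0.9, 1.1),
                                noise_sigma_emg = 0.05,
                                noise_sigma_kine = 0.005) {
  structure(list(amplitude_range = amplitude_range, warp_range = warp_range,
                 noise_sigma_emg = noise_sigma_emg,
                 noise_sigma_kine = noise_sigma_kine),
            class = "augmentation_config")
}

#' Augment one raw training trial
#'
#' Draws one amplitude factor per modality and one shared warp factor from
#' the configured ranges, resamples both streams to the warped length by
#' linear interpolation, and adds modality-specific Gaussian noise. The
#' trial must be in raw (pre-CWT) form; downstream preprocessing recomputes
#' acceleration and jerk from the augmented speed trace.
#'
#' @param trial A raw [trial_record()].
#' @param cfg An [augmentation_config()].
#' @param factors Optional list overriding the random draws
#'   (`amp_emg`, `amp_kine`, `warp`); each must lie inside the configured
#'   range.
#' @return The augmented trial (marked with attribute `augmented`).
#' @export
augment_trial <- function(trial, cfg = augmentation_config(), factors = NULL) {
  stopifnot(inherits(trial, "trial_record"))
  stop_if_not(!trial$preprocessed,
              "augmentation operates on raw trials (before preprocessing)")
  draw <- function(r) stats::runif(1, r[1], r[2])
  f <- list(amp_emg = factors$amp_emg %||% draw(cfg$amplitude_range),
            amp_kine = factors$amp_kine %||% draw(cfg$amplitude_range),
            warp = factors$warp %||% draw(cfg$warp_range))
  in_range <- function(x, r) x >= r[1] - 1e-12 && x <= r[2] + 1e-12
  stop_if_not(in_range(f$amp_emg, cfg$amplitude_range) &&
                in_range(f$amp_kine, cfg$amplitude_range),
              "amplitude factor outside the configured range")
  stop_if_not(in_range(f$warp, cfg$warp_range),
              "warp factor outside the configured range")
  t_e <- max(2L, round(ncol(trial$emg) * f$warp))
  t_k <- max(2L, round(length(trial$velocity) * f$warp))
  emg <- t(apply(trial$emg, 1L, resample_linear, new_len = t_e)) * f$amp_emg
  vel <- resample_linear(trial$velocity, t_k) * f$amp_kine
  if (cfg$noise_sigma_emg > 0)
    emg <- emg + stats::rnorm(length(emg), 0, cfg$noise_sigma_emg)
  if (cfg$noise_sigma_kine > 0)
    vel <- vel + stats::rnorm(length(vel), 0, cfg$noise_sigma_kine)
  out <- trial
  out$emg <- emg
  out$velocity <- vel
  attr(out, "augmented") <- TRUE
  out
}

#' Balance a training set by augmentation oversampling
#'
#' Generates augmented copies of minority-score trials until every score
#' level reaches the majority count (or an explicit per-score target).
#' Refuses to touch anything but the training partition: validation and
#' test data must stay unaugmented to reflect real-world performance.
#'
#' @param trials List of raw [trial_record()]s.
#' @param partition Character vector labelling each trial's partition; all
#'   must equal `"train"`.
#' @param target Optional per-score target counts (length 3, scores 0..2);
#'   defaults to the majority class count.
#' @param cfg An [augmentation_config()].
#' @param seed RNG seed for the augmentation draws.
#' @return List with `trials` (original + augmented) and `origin` (index of
#'   the source trial for every output trial).
#' @export
balance_training_set <- function(trials, partition, target = NULL,
                                 cfg = augmentation_config(), seed = 1) {
  stop_if_not(length(partition) == length(trials),
              "partition labels must match trials")
  if (any(partition != "train"))
    stop("balance_training_set may only be applied to the training partition",
         call. = FALSE)
  scores <- vapply(trials, function(t) t$score, integer(1))
  counts <- vapply(0:2, function(s) sum(scores == s), integer(1))
  target <- target %||% rep(max(counts), 3L)
  stop_if_not(all(target >= counts | counts == 0),
              "target counts below existing counts")
  out <- trials
  origin <- seq_along(trials)
  with_seed(seed, {
    for (s in 0:2) {
      pool <- which(scores == s)
      need <- target[s + 1L] - counts[s + 1L]
      if (need <= 0 || length(pool) == 0) next
      src <- pool[(seq_len(need) - 1L) %% length(pool) + 1L]
      for (i in src) {
        out[[length(out) + 1L]] <- augment_trial(trials[[i]], cfg)
        origin <- c(origin, i)
      }
    }
  })
  list(trials = out, origin = origin)
}

#' Training protocol settings
#'
#' Two-stage protocol: stage 1 warms up on robot-guided passive trials
#' (learning rate 1e-3), stage 2 fine-tunes on active voluntary trials at a
#' reduced rate (5e-4), initialised from the stage-1 weights. Both stages
#' use AdamW (weight decay 1e-4), cross-entropy loss, batch size 32,
#' gradient clipping at global norm 1.0, and early stopping when validation
#' loss fails to improve for `patience` consecutive epochs (best-validation
#' weights restored).
#'
#' @param stage1_lr,stage2_lr Learning rates.
#' @param stage1_epochs,stage2_epochs Maximum epochs per stage.
#' @param batch_size Minibatch size.
#' @param weight_decay AdamW decoupled weight decay.
#' @param clip_norm Gradient-clipping threshold (global L2 norm).
#' @param patience Early-stopping patience in epochs.
#' @return List of class `train_config`.
#' @export
train_config <- function(stage1_lr = 1e-3, stage2_lr = 5e-4,
                         stage1_epochs = 100, stage2_epochs = 100,
                         batch_size = 32, weight_decay = 1e-4,
                         clip_norm = 1.0, patience = 10) {
  structure(list(stage1_lr = stage1_lr, stage2_lr = stage2_lr,
                 stage1_epochs = stage1_epochs, stage2_epochs = stage2_epochs,
                 batch_size = batch_size, weight_decay = weight_decay,
                 clip_norm = clip_norm, patience = patience),
            class = "train_config")
}

# Early-stopping bookkeeping: track best validation loss, stop after
# `patience` consecutive non-improving epochs.
early_stop_update <- function(state, val_loss, patience) {
  if (is.null(state)) state <- list(best = Inf, bad = 0L, stop = FALSE,
                                    best_epoch = 0L, epoch = 0L)
  state$epoch <- state$epoch + 1L
  if (val_loss < state$best - 1e-12) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= patience) state$stop <- TRUE
  }
  state
}

# Evaluate loss/accuracy and mean gate weight on a tensor_set (eval mode).
evaluate_tensors <- function(model, ts, batch_size = 64) {
  n <- length(ts$labels)
  tot_loss <- 0; correct <- 0
  wsum <- c(0, 0); nw <- 0
  preds <- integer(n)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- model_forward(model, get_batch_x(ts, ix), ts$actions[ix],
                        training = FALSE)
    ls <- softmax_ce_loss(fw$logits, ts$labels[ix])
    tot_loss <- tot_loss + ls$loss * length(ix)
    preds[ix] <- max.col(fw$logits) - 1L
    correct <- correct + sum(preds[ix] == ts$labels[ix])
    if (!is.null(fw$w)) { wsum <- wsum + colSums(fw$w); nw <- nw + length(ix) }
  }
  list(loss = tot_loss / n, accuracy = correct / n, preds = preds,
       gate = if (nw > 0) wsum / nw else c(NA_real_, NA_real_))
}

# One training stage: minibatch AdamW with gradient clipping and early
# stopping on validation loss; returns the best-validation model and a
# per-epoch history (loss, accuracy, mean gate weights, post-clip norms).
train_stage <- function(model, train_ts, val_ts, epochs, lr, cfg, seed,
                        verbose = FALSE) {
  opt <- adamw_init(model$params)
  es <- NULL
  best_params <- model$params
  best_state <- model$state
  hist <- list()
  n <- length(train_ts$labels)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(hash_seed(seed, ep), sample(n))
    with_seed(hash_seed(seed, ep, 7L), {
      ep_loss <- 0; ep_n <- 0
      wsum <- c(0, 0)
      max_norm_seen <- 0
      for (ix in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        fw <- model_forward(model, get_batch_x(train_ts, ix),
                            train_ts$actions[ix], training = TRUE)
        model <- fw$model
        ls <- softmax_ce_loss(fw$logits, train_ts$labels[ix])
        grads <- model_backward(model, fw$cache, ls$dlogits)
        cl <- clip_global_norm(grads, cfg$clip_norm)
        max_norm_seen <- max(max_norm_seen, cl$norm)
        st <- adamw_step(model$params, cl$grads, opt, lr,
                         weight_decay = cfg$weight_decay)
        model$params <- st$params
        opt <- st$opt
        ep_loss <- ep_loss + ls$loss * length(ix)
        ep_n <- ep_n + length(ix)
        if (!is.null(fw$w)) wsum <- wsum + colSums(fw$w)
      }
    })
    val <- evaluate_tensors(model, val_ts, cfg$batch_size)
    es <- early_stop_update(es, val$loss, cfg$patience)
    if (es$best_epoch == es$epoch) {
      best_params <- model$params
      best_state <- model$state
    }
    hist[[ep]] <- data.frame(
      epoch = ep, train_loss = ep_loss / ep_n,
      val_loss = val$loss, val_accuracy = val$accuracy,
      w_emg = wsum[1] / ep_n, w_kine = wsum[2] / ep_n,
      grad_norm = max_norm_seen)
    if (verbose)
      message(sprintf("  epoch %d: train %.4f | val %.4f acc %.3f",
                      ep, ep_loss / ep_n, val$loss, val$accuracy))
    if (es$stop) break
  }
  model$params <- best_params
  model$state <- best_state
  list(model = model, history = do.call(rbind, hist))
}

#' Two-stage training
#'
#' Stage 1 trains on the passive-stage tensors (consistent robot-guided
#' kinematics, minimal voluntary sEMG — a domain-specific warm-up); stage 2
#' fine-tunes the resulting weights on the active-stage tensors at the
#' reduced learning rate. Early stopping on validation loss applies within
#' each stage, and the best-validation weights are carried forward.
#'
#' @param model An [amwfnet_model()].
#' @param passive_train,passive_val,active_train,active_val `tensor_set`s
#'   (see [cohort_to_tensors()]); pass `NULL` passive sets to skip stage 1.
#' @param cfg A [train_config()].
#' @param seed Seed controlling shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return List with the fine-tuned `model`, `stage1` and `stage2` history
#'   data frames (per-epoch loss, validation accuracy, mean gate weights,
#'   post-clip gradient norm).
#' @export
train_two_stage <- function(model, passive_train, passive_val,
                            active_train, active_val,
                            cfg = train_config(), seed = 1, verbose = FALSE) {
  for (ts in list(active_train, active_val))
    stop_if_not(length(ts$labels) > 0, "empty stage dataset")
  h1 <- NULL
  if (!is.null(passive_train)) {
    stop_if_not(length(passive_train$labels) > 0, "empty stage dataset")
    s1 <- train_stage(model, passive_train, passive_val,
                      cfg$stage1_epochs, cfg$stage1_lr, cfg, seed, verbose)
    model <- s1$model
    h1 <- s1$history
  }
  s2 <- train_stage(model, active_train, active_val,
                    cfg$stage2_epochs, cfg$stage2_lr, cfg,
                    hash_seed(seed, 2L), verbose)
  list(model = s2$model, stage1 = h1, stage2 = s2$history)
}
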