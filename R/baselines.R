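# Hand-crafted feature baselines (112-dimensional vectors with SVM and
# random forest) and the raw-signal dual-stream 1-D CNN baseline.

#' Time- and frequency-domain features of one sEMG channel
#'
#' The eight classic surface-EMG descriptors, in fixed order: root mean
#' square (RMS), mean absolute value (MAV), sample variance (VAR), waveform
#' length (WL, sum of absolute successive differences), zero crossings (ZC,
#' sign changes whose amplitude step exceeds the deadband `eps`), slope
#' sign changes (SSC, local extrema with both neighbouring steps above
#' `eps`), median frequency (MDF, frequency splitting the Welch spectrum's
#' power in half) and mean power frequency (MPF, power-weighted mean
#' frequency).
#'
#' @param x Numeric signal vector (length >= 2).
#' @param fs Sampling rate in Hz.
#' @param eps Amplitude deadband for ZC / SSC counting (0 = textbook
#'   definition).
#' @return Named numeric vector of length 8.
#' @export
emg_features <- function(x, fs = 1000, eps = 0) {
  stop_if_not(length(x) >= 2, "signal must have at least 2 samples")
  d <- diff(x)
  zc <- sum(x[-length(x)] * x[-1] < 0 & abs(d) >= eps)
  dl <- d[-length(d)]; dr <- d[-1]
  ssc <- sum(dl * dr < 0 & (abs(dl) >= eps | abs(dr) >= eps))
  ps <- welch_psd(x, fs)
  tot <- sum(ps$power)
  if (tot > 0) {
    cum <- cumsum(ps$power)
    mdf <- ps$freq[which(cum >= tot / 2)[1]]
    mpf <- sum(ps$freq * ps$power) / tot
  } else {
    mdf <- mpf <- 0
  }
  c(RMS = sqrt(mean(x^2)), MAV = mean(abs(x)), VAR = stats::var(x),
    WL = sum(abs(d)), ZC = zc, SSC = ssc, MDF = mdf, MPF = mpf)
}

# Dimensionless jerk-like index of one channel: RMS of the channel's second
# derivative, normalised by duration squared over the channel's peak
# magnitude (so amplitude scaling cancels and rougher profiles score
# higher).
jerk_index <- function(x, fs) {
  if (length(x) < 3) return(0)
  dd <- central_diff(central_diff(x, fs), fs)
  pk <- max(abs(x))
  if (pk == 0) return(0)
  dur <- length(x) / fs
  sqrt(mean(dd^2)) * dur^2 / pk
}

#' Spectral arc length (movement-smoothness metric)
#'
#' Negative arc length of the amplitude-normalised magnitude spectrum of a
#' movement profile, evaluated up to `cutoff` Hz on a zero-padded FFT grid
#' with the frequency axis normalised by the cutoff. Smoother profiles have
#' more compact spectra, hence shorter arcs (values closer to 0).
#'
#' @param x Numeric profile (typically the speed trace).
#' @param fs Sampling rate in Hz.
#' @param cutoff Spectral cutoff in Hz.
#' @return Negative scalar (0 for a degenerate all-zero signal).
#' @export
spectral_arc_length <- function(x, fs, cutoff = 20) {
  n <- length(x)
  nfft <- 2^max(9L, ceiling(log2(n)) + 2L)
  sp <- Mod(stats::fft(c(x, numeric(nfft - n))))
  fr <- (0:(nfft - 1)) * fs / nfft
  keep <- fr <= cutoff
  sp <- sp[keep]; fr <- fr[keep]
  if (max(sp) == 0) return(0)
  sp <- sp / sp[1]
  -sum(sqrt(diff(fr / cutoff)^2 + diff(sp)^2))
}

#' Statistical features of the kinematic channels
#'
#' Ten statistics per channel (velocity, acceleration, jerk), in fixed
#' order: mean, standard deviation, maximum, minimum, median, interquartile
#' range, RMS, peak-to-peak, jerk index (see [jerk_index()]) and spectral
#' arc length ([spectral_arc_length()]).
#'
#' @param kin A `kinematic_channels` list from [derive_kinematics()].
#' @param fs Sampling rate in Hz (defaults to the rate recorded in `kin`).
#' @return Named numeric vector of length 30.
#' @export
kinematic_features <- function(kin, fs = NULL) {
  fs <- fs %||% kin$fs
  chans <- kin[c("velocity", "acceleration", "jerk")]
  stop_if_not(all(lengths(chans) >= 2), "channels must have >= 2 samples")
  stats10 <- function(x) {
    c(mean = mean(x), std = stats::sd(x), max = max(x), min = min(x),
      median = stats::median(x), IQR = stats::IQR(x),
      RMS = sqrt(mean(x^2)), p2p = max(x) - min(x),
      jerk_index = jerk_index(x, fs),
      sal = spectral_arc_length(x, fs))
  }
  out <- unlist(lapply(chans, stats10))
  names(out) <- paste(rep(names(chans), each = 10L),
                      rep(names(stats10(chans[[1]])), 3L), sep = ".")
  out
}

#' Assemble the 112-dimensional feature vector of a trial
#'
#' Concatenates 64 sEMG features (8 muscles x 8 descriptors, muscles in
#' recording order, positions 1-64), 30 kinematic features (3 channels x
#' 10 statistics, positions 65-94) and the 18-dimensional action one-hot
#' (positions 95-112).
#'
#' @param trial A preprocessed [trial_record()].
#' @param eps ZC/SSC deadband passed to [emg_features()].
#' @return Named numeric vector of length 112.
#' @export
build_feature_vector <- function(trial, eps = 0) {
  stopifnot(inherits(trial, "trial_record"))
  stop_if_not(trial$preprocessed, "trial must be preprocessed first")
  stop_if_not(nrow(trial$emg) == 8L, "trial must carry 8 sEMG channels")
  emg_block <- unlist(lapply(seq_len(8L), function(ch)
    emg_features(trial$emg[ch, ], trial$emg_fs, eps)))
  names(emg_block) <- paste(rep(muscle_names(), each = 8L),
                            rep(c("RMS", "MAV", "VAR", "WL", "ZC", "SSC",
                                  "MDF", "MPF"), 8L), sep = ".")
  kine_block <- kinematic_features(trial$kinematics)
  action_block <- onehot(trial$action_id, 18L)
  names(action_block) <- paste0("action.", 1:18)
  c(emg_block, kine_block, action_block)
}

#' Feature matrix for a list of trials
#'
#' @param trials A `cohort` or list of trials (preprocessed trials are used
#'   as is; raw trials are preprocessed with `filter`).
#' @param filter A [filter_spec()].
#' @param eps ZC/SSC deadband.
#' @return List with `features` (n x 112 matrix), `labels`, `scores`,
#'   `actions`, `subjects`, `stages`.
#' @export
cohort_to_features <- function(trials, filter = filter_spec(), eps = 0) {
  if (inherits(trials, "cohort")) trials <- trials$trials
  n <- length(trials)
  feats <- matrix(0, n, 112L)
  labels <- actions <- scores <- integer(n)
  subjects <- stages <- character(n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    if (!tr$preprocessed) tr <- preprocess_trial(tr, filter)
    fv <- build_feature_vector(tr, eps)
    if (i == 1L) colnames(feats) <- names(fv)
    feats[i, ] <- fv
    labels[i] <- tr$label; actions[i] <- tr$action_id
    subjects[i] <- tr$subject_id; scores[i] <- tr$score
    stages[i] <- tr$stage
  }
  list(features = feats, labels = labels, scores = scores,
       actions = actions, subjects = subjects, stages = stages)
}

#' Fit the SVM and random-forest baselines
#'
#' Standardises features by training-partition statistics, fits an RBF
#' support vector machine (C = 10, "scale" gamma = 1 / (p * var(X_train)))
#' and a random forest (300 trees, minimum node size 2), both with
#' inverse-frequency class weighting, and evaluates on the held-out test
#' partition with the shared metrics.
#'
#' @param features n x p feature matrix.
#' @param labels Integer class labels 0..5.
#' @param subjects Subject ID per row (used to verify the split is
#'   subject-wise).
#' @param split A [subject_split()] whose indices refer to rows of
#'   `features`.
#' @param seed RNG seed for the forest.
#' @return List with `svm`, `rf` (fitted models), `svm_report`,
#'   `rf_report` (`eval_report`s on the test partition) and the
#'   standardisation `center`/`scale`.
#' @export
fit_baselines <- function(features, labels, subjects, split, seed = 1) {
  tr <- split$train; te <- split$test
  if (length(intersect(subjects[tr], subjects[te])) > 0)
    stop("subject leakage between train and test partitions", call. = FALSE)
  ctr <- colMeans(features[tr, , drop = FALSE])
  scl <- apply(features[tr, , drop = FALSE], 2L, stats::sd)
  scl[scl == 0] <- 1
  std <- function(m) scale(m, center = ctr, scale = scl)
  xtr <- std(features[tr, , drop = FALSE])
  xte <- std(features[te, , drop = FALSE])
  ytr <- droplevels(factor(labels[tr], levels = 0:5))
  yte <- labels[te]
  tab <- table(ytr)
  cw <- 1 / tab
  cw <- cw / mean(cw)                      # inverse-frequency class weights
  gamma_scale <- 1 / (ncol(xtr) * max(stats::var(as.vector(xtr)), 1e-12))
  svm_fit <- with_seed(seed, e1071::svm(
    x = xtr, y = ytr, kernel = "radial", cost = 10, gamma = gamma_scale,
    class.weights = cw))
  rf_fit <- with_seed(hash_seed(seed, 2L), randomForest::randomForest(
    x = xtr, y = ytr, ntree = 300, nodesize = 2,
    classwt = as.numeric(cw)))
  svm_pred <- as.integer(as.character(predict(svm_fit, xte)))
  rf_pred <- as.integer(as.character(predict(rf_fit, xte)))
  list(svm = svm_fit, rf = rf_fit,
       svm_report = compute_metrics(yte, svm_pred),
       rf_report = compute_metrics(yte, rf_pred),
       center = ctr, scale = scl)
}

## ---- raw-signal dual-stream 1-D CNN ---------------------------------------

#' Dual-stream 1-D CNN baseline model
#'
#' The raw-signal counterpart of the scalogram network: each signal channel
#' passes through a branch-shared 1-D encoder (four blocks of double
#' kernel-9 convolutions with batch norm and ReLU, pool 2, channel
#' progression `1 -> channels`), followed by the identical attention
#' pooling, gated fusion (or concatenation) and action-aware head, so the
#' two baselines differ only in the encoder blocks.
#'
#' @param len_emg,len_kine Input lengths per modality in samples; must be
#'   divisible by 16.
#' @param channels,gate_hidden,head_hidden,tau,dropout,n_emg,n_kine,n_actions,n_classes,variant,seed
#'   As in [amwfnet_model()].
#' @param kernel 1-D convolution kernel width.
#' @return An `amwfnet_model` with 1-D encoder configuration.
#' @export
cnn1d_model <- function(len_emg, len_kine, channels = c(32, 64, 128, 128),
                        kernel = 9, gate_hidden = 256, head_hidden = 128,
                        tau = 2.5, dropout = 0.3,
                        n_emg = 8, n_kine = 3, n_actions = 18, n_classes = 6,
                        variant = c("full", "semg_only", "kine_only",
                                    "no_action", "concat"),
                        seed = 42) {
  variant <- match.arg(variant)
  stop_if_not(len_emg %% 16 == 0 && len_kine %% 16 == 0,
              "signal lengths must be divisible by 16")
  stop_if_not(kernel %% 2 == 1, "kernel must be odd")
  D <- channels[4]
  cfg <- list(input_size = NA_integer_, channels = channels, D = D,
              attn_hidden = max(1L, D %/% 2L),
              gate_hidden = gate_hidden, head_hidden = head_hidden,
              tau = tau, dropout = dropout,
              n_emg = n_emg, n_kine = n_kine,
              n_actions = n_actions, n_classes = n_classes,
              variant = variant, bn_momentum = 0.1, bn_eps = 1e-5,
              type = "1d", kh = 1L, kw = as.integer(kernel),
              ph = 0L, pw = (as.integer(kernel) - 1L) %/% 2L,
              pool = c(1L, 2L),
              input_hw_emg = c(1L, as.integer(len_emg)),
              input_hw_kine = c(1L, as.integer(len_kine)))
  build_model(cfg, seed)
}

#' Build a raw-signal set for the 1-D baseline
#'
#' Preprocesses each trial, optionally decimates both streams by an integer
#' factor, and truncates to a common per-modality length divisible by 16.
#' sEMG channels and the three kinematic channels (velocity, acceleration,
#' jerk) become the two branch arrays.
#'
#' @param trials A `cohort` or list of trials.
#' @param filter A [filter_spec()].
#' @param decimate Integer subsampling factor applied after filtering.
#' @return List of class `signal_set`: `x = list(emg (T_e, 8, n),
#'   kine (T_k, 3, n))` plus `labels`, `actions`, `subjects`, `scores`,
#'   `stages`.
#' @export
cohort_to_signals <- function(trials, filter = filter_spec(), decimate = 1L) {
  if (inherits(trials, "cohort")) trials <- trials$trials
  n <- length(trials)
  pp <- lapply(trials, function(tr)
    if (tr$preprocessed) tr else preprocess_trial(tr, filter))
  dec <- function(v) v[seq(1L, length(v), by = decimate)]
  len16 <- function(L) (L %/% 16L) * 16L
  t_e <- len16(min(vapply(pp, function(t) length(dec(t$emg[1, ])), integer(1))))
  t_k <- len16(min(vapply(pp, function(t) length(dec(t$kinematics$velocity)),
                          integer(1))))
  stop_if_not(t_e >= 16 && t_k >= 16, "signals too short after decimation")
  xe <- array(0, c(t_e, 8L, n))
  xk <- array(0, c(t_k, 3L, n))
  labels <- actions <- scores <- integer(n)
  subjects <- stages <- character(n)
  for (i in seq_len(n)) {
    tr <- pp[[i]]
    for (ch in 1:8) xe[, ch, i] <- dec(tr$emg[ch, ])[seq_len(t_e)]
    kin <- tr$kinematics
    xk[, 1, i] <- dec(kin$velocity)[seq_len(t_k)]
    xk[, 2, i] <- dec(kin$acceleration)[seq_len(t_k)]
    xk[, 3, i] <- dec(kin$jerk)[seq_len(t_k)]
    labels[i] <- tr$label; actions[i] <- tr$action_id
    subjects[i] <- tr$subject_id; scores[i] <- tr$score
    stages[i] <- tr$stage
  }
  structure(list(x = list(emg = xe, kine = xk), labels = labels,
                 actions = actions, subjects = subjects, scores = scores,
                 stages = stages),
            class = "signal_set")
}

# Subset a signal_set by trial index.
signal_subset <- function(ss, idx) {
  structure(list(x = list(emg = ss$x$emg[, , idx, drop = FALSE],
                          kine = ss$x$kine[, , idx, drop = FALSE]),
                 labels = ss$labels[idx], actions = ss$actions[idx],
                 subjects = ss$subjects[idx], scores = ss$scores[idx],
                 stages = ss$stages[idx]),
            class = "signal_set")
}

#' Train and evaluate the dual-stream 1-D CNN baseline
#'
#' Single-stage training of [cnn1d_model()] on a raw-signal set with the
#' shared optimiser settings, evaluated on the test partition.
#'
#' @param signals A `signal_set` from [cohort_to_signals()].
#' @param split A [subject_split()] over the signal set's rows.
#' @param model_args Extra arguments for [cnn1d_model()].
#' @param cfg A [train_config()] (stage-2 settings are used).
#' @param seed Training seed.
#' @return List with `model`, `history` and `report` (test `eval_report`).
#' @export
dual_stream_1dcnn <- function(signals, split, model_args = list(),
                              cfg = train_config(), seed = 1) {
  d_e <- dim(signals$x$emg); d_k <- dim(signals$x$kine)
  margs <- utils::modifyList(
    list(len_emg = d_e[1], len_kine = d_k[1], seed = hash_seed(seed, 5L)),
    model_args)
  model <- do.call(cnn1d_model, margs)
  tr <- signal_subset(signals, split$train)
  va <- signal_subset(signals, split$val)
  te <- signal_subset(signals, split$test)
  fit <- train_stage(model, tr, va, cfg$stage2_epochs, cfg$stage2_lr,
                     cfg, seed)
  ev <- evaluate_tensors(fit$model, te)
  list(model = fit$model, history = fit$history,
       report = compute_metrics(te$labels, ev$preds))
}
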