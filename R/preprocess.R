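# Signal conditioning: zero-phase filter cascades for sEMG, kinematic
# differentiation and smoothing, and trial segmentation.

#' Filter settings for the conditioning cascade
#'
#' Defaults follow the acquisition pipeline: a 50 Hz biquad notch
#' (second-order Butterworth-style IIR, Q = 30, i.e. -3 dB bandwidth
#' 50/30 Hz), a fourth-order Butterworth band-pass at 20-450 Hz for sEMG,
#' and for kinematics a fourth-order Butterworth low-pass at 20 Hz followed
#' by a 15 ms Gaussian-weighted moving average. All IIR filters are applied
#' forward-backward (zero phase) with odd-reflection edge padding and
#' steady-state initial conditions.
#'
#' @param notch_freq Notch centre frequency in Hz.
#' @param notch_q Notch quality factor (centre / -3 dB bandwidth).
#' @param bandpass Length-2 numeric, sEMG band-pass edges in Hz.
#' @param bandpass_order Butterworth prototype order of the band-pass.
#' @param kine_lowpass Kinematic low-pass cutoff in Hz.
#' @param kine_lowpass_order Butterworth order of the kinematic low-pass.
#' @param gaussian_window Gaussian moving-average window length in seconds.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        bandpass = c(20, 450), bandpass_order = 4,
                        kine_lowpass = 20, kine_lowpass_order = 4,
                        gaussian_window = 0.015) {
  stop_if_not(bandpass[1] > 0 && bandpass[1] < bandpass[2],
              "bandpass edges must be positive and increasing")
  stop_if_not(gaussian_window > 0, "gaussian_window must be positive")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 bandpass = bandpass, bandpass_order = bandpass_order,
                 kine_lowpass = kine_lowpass,
                 kine_lowpass_order = kine_lowpass_order,
                 gaussian_window = gaussian_window),
            class = "filter_spec")
}

# Edge padding for zero-phase filtering: at least 3x the filter order and,
# for narrow-band IIR filters, the length over which the slowest pole decays
# below 1e-12 — long enough that edge effects die inside the padding, which
# also makes forward-backward filtering commute with time reversal to
# numerical precision.
filter_pad_length <- function(b, a) {
  base <- 3L * (max(length(a), length(b)) - 1L)
  if (length(a) > 1L) {
    p <- max(Mod(polyroot(rev(a))))
    if (p < 1 && p > 0) base <- max(base, ceiling(log(1e-12) / log(p)))
  }
  as.integer(base)
}

# Steady-state initial conditions for a direct-form-II-transposed filter
# (the lfilter_zi construction): scaled by the first sample of the padded
# signal, they suppress the startup transient that plain from-rest filtering
# would inject into high-Q filters like the 50 Hz notch.
iir_steady_state <- function(b, a) {
  k <- max(length(a), length(b)) - 1L
  bb <- c(b, numeric(k + 1L - length(b))) / a[1]
  aa <- c(a, numeric(k + 1L - length(a))) / a[1]
  comp <- matrix(0, k, k)
  comp[1, ] <- -aa[-1]
  if (k > 1) comp[cbind(2:k, 1:(k - 1))] <- 1
  solve(diag(k) - t(comp), bb[-1] - aa[-1] * bb[1])
}

# RBJ-style biquad notch: unit-gain at DC and Nyquist, transmission zero at
# f0, -3 dB bandwidth f0/Q.
design_notch <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase IIR filtering with reflection padding
#'
#' Applies the filter forward and then backward so the magnitude response is
#' squared and the phase response cancels. Edges are extended by odd
#' (point-symmetric) reflection — at least three times the filter order,
#' longer for narrow-band filters with slow transients — and each pass
#' starts from steady-state initial conditions, then the padding is
#' trimmed, so output length equals input length.
#'
#' @param b,a Numerator / denominator coefficient vectors.
#' @param x Numeric signal vector.
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  b <- b / a[1]; a <- a / a[1]
  np <- min(n - 1L, filter_pad_length(b, a))
  stop_if_not(n > 3L * (max(length(a), length(b)) - 1L),
              "signal too short for the requested filter")
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  ext <- c(head_pad, x, tail_pad)
  zi <- iir_steady_state(b, a)
  y <- iir_df2t(b, a, ext, zi * ext[1])
  y <- rev(iir_df2t(b, a, rev(y), zi * y[length(y)]))
  as.numeric(y[(np + 1):(np + n)])
}

#' Condition an 8-channel sEMG trial
#'
#' Two-stage zero-phase cascade: a 50 Hz notch (power-line suppression)
#' followed by a 20-450 Hz Butterworth band-pass that retains motor-unit
#' action potentials while rejecting motion artifact and baseline drift.
#'
#' @param emg Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @param spec A [filter_spec()].
#' @return Filtered matrix with the same dimensions.
#' @export
filter_emg <- function(emg, fs = 1000, spec = filter_spec()) {
  emg <- as.matrix(emg)
  stop_if_not(fs > 2 * spec$bandpass[2],
              sprintf("fs = %g Hz is too low for a %g Hz band edge",
                      fs, spec$bandpass[2]))
  nf <- design_notch(spec$notch_freq, spec$notch_q, fs)
  bp <- signal::butter(spec$bandpass_order, spec$bandpass / (fs / 2),
                       type = "pass")
  out <- emg
  for (i in seq_len(nrow(emg))) {
    y <- zero_phase_filter(nf$b, nf$a, emg[i, ])
    out[i, ] <- zero_phase_filter(bp$b, bp$a, y)
  }
  out
}

# Central-difference derivative scaled by fs; one-sided at the boundaries.
central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d * fs
}

# Unit-sum Gaussian moving average; window length window_s seconds (odd
# number of taps), sigma = window_s / 6 so the window spans +/- 3 sigma.
gaussian_smooth <- function(x, fs, window_s) {
  L <- max(3L, 2L * floor(window_s * fs / 2) + 1L)
  sigma <- window_s * fs / 6
  k <- seq(-(L %/% 2), L %/% 2)
  w <- exp(-0.5 * (k / sigma)^2)
  w <- w / sum(w)
  np <- L %/% 2
  ext <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[length(x)] -
             x[(length(x) - 1):(length(x) - np)])
  as.numeric(stats::filter(ext, w, sides = 2))[(np + 1):(np + length(x))]
}

two_stage_smooth <- function(x, fs, spec) {
  lp <- signal::butter(spec$kine_lowpass_order,
                       spec$kine_lowpass / (fs / 2), type = "low")
  y <- zero_phase_filter(lp$b, lp$a, x)
  gaussian_smooth(y, fs, spec$gaussian_window)
}

#' Derive smoothed acceleration and jerk from a speed trace
#'
#' The raw speed signal is smoothed (zero-phase 20 Hz Butterworth low-pass
#' then 15 ms Gaussian moving average) to suppress quantisation noise, then
#' differentiated by central differences to acceleration; the cascade is
#' repeated (smooth, differentiate, smooth) so every returned channel has
#' passed the two-stage smoother and jerk is always the derivative chain of
#' the smoothed signals.
#'
#' @param velocity Numeric speed vector (length >= 3).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return List of class `kinematic_channels` with equal-length `velocity`,
#'   `acceleration` and `jerk` vectors and the sampling rate `fs`.
#' @export
derive_kinematics <- function(velocity, fs = 500, spec = filter_spec()) {
  stop_if_not(length(velocity) >= 3, "velocity must have at least 3 samples")
  v <- two_stage_smooth(velocity, fs, spec)
  a <- two_stage_smooth(central_diff(v, fs), fs, spec)
  j <- two_stage_smooth(central_diff(a, fs), fs, spec)
  structure(list(velocity = v, acceleration = a, jerk = j, fs = fs),
            class = "kinematic_channels")
}

#' Apply the full conditioning chain to a trial
#'
#' Filters the sEMG block and derives the three smoothed kinematic channels,
#' marking the trial as preprocessed (a precondition of the scalogram and
#' feature extractors).
#'
#' @param trial A [trial_record()].
#' @param spec A [filter_spec()].
#' @return The trial with filtered `emg`, a `kinematics` element and
#'   `preprocessed = TRUE`.
#' @export
preprocess_trial <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "trial_record"))
  trial$emg <- filter_emg(trial$emg, trial$emg_fs, spec)
  trial$kinematics <- derive_kinematics(trial$velocity, trial$kine_fs, spec)
  trial$preprocessed <- TRUE
  trial
}

#' Segment continuous streams into labelled trials
#'
#' Cuts synchronous continuous sEMG and speed streams into discrete trials
#' according to a manifest of onsets and durations, attaching the action ID,
#' score and stage of each segment. Segments shorter than `min_duration`
#' seconds are dropped (and reported in the `dropped` attribute);
#' overlapping segments are rejected.
#'
#' @param emg Numeric matrix, 8 x total samples at `emg_fs`.
#' @param velocity Numeric vector at `kine_fs`.
#' @param manifest Data frame with columns `onset_s`, `duration_s`,
#'   `subject_id`, `action_id`, `score` and `stage`.
#' @param emg_fs,kine_fs Sampling rates in Hz.
#' @param min_duration Minimum admissible segment length in seconds.
#' @return List of [trial_record()] objects; attribute `dropped` holds the
#'   manifest rows excluded by the length check.
#' @export
segment_and_label <- function(emg, velocity, manifest,
                              emg_fs = 1000, kine_fs = 500,
                              min_duration = 0.5) {
  emg <- as.matrix(emg)
  stop_if_not(nrow(emg) == 8L, "emg must have exactly 8 rows")
  need <- c("onset_s", "duration_s", "subject_id", "action_id", "score", "stage")
  stop_if_not(all(need %in% names(manifest)),
              paste("manifest must contain columns:", paste(need, collapse = ", ")))
  m <- manifest[order(manifest$onset_s), , drop = FALSE]
  ends <- m$onset_s + m$duration_s
  if (nrow(m) > 1 && any(m$onset_s[-1] < ends[-nrow(m)] - 1e-9))
    stop("manifest contains overlapping segments", call. = FALSE)
  total_s <- ncol(emg) / emg_fs
  stop_if_not(all(m$onset_s >= 0) && all(ends <= total_s + 1e-9),
              "manifest timestamps fall outside the recorded streams")
  keep <- m$duration_s >= min_duration
  dropped <- m[!keep, , drop = FALSE]
  if (nrow(dropped) > 0)
    message(sprintf("segment_and_label: dropped %d segment(s) shorter than %g s",
                    nrow(dropped), min_duration))
  m <- m[keep, , drop = FALSE]
  trials <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    e0 <- floor(m$onset_s[i] * emg_fs) + 1L
    e1 <- min(ncol(emg), e0 + round(m$duration_s[i] * emg_fs) - 1L)
    k0 <- floor(m$onset_s[i] * kine_fs) + 1L
    k1 <- min(length(velocity), k0 + round(m$duration_s[i] * kine_fs) - 1L)
    trials[[i]] <- trial_record(
      emg = emg[, e0:e1, drop = FALSE], velocity = velocity[k0:k1],
      subject_id = m$subject_id[i], action_id = m$action_id[i],
      score = m$score[i], stage = m$stage[i],
      emg_fs = emg_fs, kine_fs = kine_fs)
  }
  attr(trials, "dropped") <- dropped
  trials
}
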