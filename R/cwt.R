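# Complex Morlet continuous wavelet transform and scalogram standardisation.

.amwfnet_cache <- new.env(parent = emptyenv())

#' Scalogram extraction settings
#'
#' The transform uses a complex Morlet wavelet with centre-frequency
#' parameter `omega0 = 6` and `n_scales` scales whose nominal frequencies
#' span 20-450 Hz for sEMG channels and 0.5-50 Hz for kinematic channels
#' (log-spaced by default). Each power scalogram is compressed with log1p,
#' bilinearly resized to `out_size` and min-max normalised to [0, 1].
#'
#' @param omega0 Morlet centre-frequency parameter.
#' @param n_scales Number of scales (>= 2).
#' @param emg_band,kine_band Frequency bands in Hz for the two modalities.
#' @param out_size Length-2 integer, output (rows, cols) of each scalogram.
#' @param scale_spacing `"log"` (default) or `"linear"` frequency spacing.
#' @return A list of class `cwt_spec`.
#' @export
cwt_spec <- function(omega0 = 6, n_scales = 128,
                     emg_band = c(20, 450), kine_band = c(0.5, 50),
                     out_size = c(128, 128), scale_spacing = c("log", "linear")) {
  scale_spacing <- match.arg(scale_spacing)
  stop_if_not(n_scales >= 2, "n_scales must be >= 2")
  for (b in list(emg_band, kine_band))
    stop_if_not(b[1] > 0 && b[1] < b[2], "band edges must be positive, low < high")
  structure(list(omega0 = omega0, n_scales = as.integer(n_scales),
                 emg_band = emg_band, kine_band = kine_band,
                 out_size = as.integer(out_size),
                 scale_spacing = scale_spacing),
            class = "cwt_spec")
}

# Nominal analysis frequencies for a band: ascending, log- or linear-spaced.
cwt_frequencies <- function(band, n_scales, spacing = "log") {
  if (spacing == "log") exp(seq(log(band[1]), log(band[2]), length.out = n_scales))
  else seq(band[1], band[2], length.out = n_scales)
}

# Frequency-domain Morlet filter bank (analytic, L2-normalised), cached per
# (fs, band, n_scales, nfft, spacing, omega0). Scale/frequency mapping:
# a = omega0 * fs / (2 pi f) samples, i.e. f = omega0 * fs / (2 pi a).
morlet_bank <- function(fs, band, n_scales, nfft, spacing, omega0) {
  key <- paste(fs, band[1], band[2], n_scales, nfft, spacing, omega0, sep = "|")
  bank <- .amwfnet_cache[[key]]
  if (!is.null(bank)) return(bank)
  freqs <- cwt_frequencies(band, n_scales, spacing)
  scales <- omega0 * fs / (2 * pi * freqs)
  omega <- 2 * pi * (0:(nfft - 1)) / nfft
  pos <- omega > 0 & omega <= pi
  bank <- matrix(0, nfft, n_scales)
  for (j in seq_len(n_scales)) {
    bank[pos, j] <- sqrt(scales[j]) * pi^(-0.25) *
      exp(-0.5 * (scales[j] * omega[pos] - omega0)^2)
  }
  attr(bank, "freqs") <- freqs
  .amwfnet_cache[[key]] <- bank
  bank
}

#' Morlet wavelet power of a 1-D signal
#'
#' Computes the complex Morlet continuous wavelet transform over `n_scales`
#' scales whose nominal frequencies cover `band`, via FFT-domain filtering,
#' and returns squared magnitude (power). Rows are ordered from the lowest
#' to the highest analysis frequency.
#'
#' @param x Finite numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 band in Hz; the upper edge must be below `fs / 2`.
#' @param n_scales Number of scales.
#' @param scale_spacing `"log"` or `"linear"`.
#' @param omega0 Morlet centre-frequency parameter.
#' @return `n_scales x length(x)` power matrix with attribute `freqs`
#'   (nominal frequency per row, Hz).
#' @export
cwt_power <- function(x, fs, band, n_scales = 128,
                      scale_spacing = "log", omega0 = 6) {
  stop_if_not(all(is.finite(x)), "signal must be finite")
  stop_if_not(band[2] < fs / 2,
              sprintf("band upper edge %g Hz exceeds Nyquist %g Hz", band[2], fs / 2))
  n <- length(x)
  nfft <- 2^ceiling(log2(max(n, 2)))
  bank <- morlet_bank(fs, band, n_scales, nfft, scale_spacing, omega0)
  X <- stats::fft(c(x, numeric(nfft - n)))
  W <- stats::mvfft(bank * X, inverse = TRUE)[seq_len(n), , drop = FALSE] / nfft
  out <- t(Mod(W)^2)
  attr(out, "freqs") <- attr(bank, "freqs")
  out
}

#' Standardise a power scalogram to a [0, 1] image
#'
#' Pipeline: log1p dynamic-range compression, bilinear resize to `out_size`,
#' then per-scalogram min-max normalisation. A constant input (zero dynamic
#' range) maps to an all-zero image.
#'
#' @param power Non-negative power matrix (scales x time).
#' @param out_size Length-2 integer (rows, cols).
#' @return `out_size` matrix with values in [0, 1].
#' @export
standardize_scalogram <- function(power, out_size = c(128, 128)) {
  stop_if_not(all(power >= 0), "power must be non-negative")
  m <- resize_bilinear(log1p(power), out_size[1], out_size[2])
  rng <- max(m) - min(m)
  if (rng <= 1e-12 * max(1, abs(max(m)))) {
    matrix(0, out_size[1], out_size[2])
  } else {
    (m - min(m)) / rng
  }
}

#' Convert a preprocessed trial to the 11-plane scalogram tensor
#'
#' Produces the network input: 8 sEMG scalograms (20-450 Hz band at the sEMG
#' rate) followed by 3 kinematic scalograms (velocity, acceleration, jerk;
#' 0.5-50 Hz band at the kinematic rate), each standardised to `out_size`
#' and stacked into an array of dimension `(rows, cols, 11)`.
#'
#' @param trial A preprocessed [trial_record()] (see [preprocess_trial()]).
#' @param spec A [cwt_spec()].
#' @return Numeric array `(out_size[1], out_size[2], 11)` of class
#'   `scalogram_tensor`, with attributes `channel_names`, `label`,
#'   `action_id`, `subject_id`, `score` and `stage`.
#' @export
trial_to_tensor <- function(trial, spec = cwt_spec()) {
  stopifnot(inherits(trial, "trial_record"))
  stop_if_not(trial$preprocessed,
              "trial must be preprocessed (preprocess_trial) before CWT")
  stop_if_not(nrow(trial$emg) == 8L, "trial must carry 8 sEMG channels")
  out <- array(0, c(spec$out_size[1], spec$out_size[2], 11L))
  for (ch in 1:8) {
    p <- cwt_power(trial$emg[ch, ], trial$emg_fs, spec$emg_band,
                   spec$n_scales, spec$scale_spacing, spec$omega0)
    out[, , ch] <- standardize_scalogram(p, spec$out_size)
  }
  kin <- trial$kinematics[c("velocity", "acceleration", "jerk")]
  for (i in 1:3) {
    p <- cwt_power(kin[[i]], trial$kine_fs, spec$kine_band,
                   spec$n_scales, spec$scale_spacing, spec$omega0)
    out[, , 8L + i] <- standardize_scalogram(p, spec$out_size)
  }
  structure(out,
            channel_names = c(muscle_names(), "velocity", "acceleration", "jerk"),
            label = trial$label, action_id = trial$action_id,
            subject_id = trial$subject_id, score = trial$score,
            stage = trial$stage,
            class = "scalogram_tensor")
}

#' Build a tensor set from a cohort
#'
#' Preprocesses every trial (unless already preprocessed), extracts the
#' 11-plane scalogram tensor, and collects the stack together with labels
#' and metadata — the dataset object consumed by the training and
#' evaluation drivers.
#'
#' @param trials A `cohort` from [simulate_cohort()] or a list of
#'   [trial_record()] objects.
#' @param spec A [cwt_spec()].
#' @param filter A [filter_spec()] used for any trial not yet preprocessed.
#' @return A list of class `tensor_set`: `x` is an array
#'   `(rows, cols, 11, n_trials)`, plus vectors `labels` (0..5), `actions`,
#'   `subjects`, `scores`, `stages`.
#' @export
cohort_to_tensors <- function(trials, spec = cwt_spec(), filter = filter_spec()) {
  if (inherits(trials, "cohort")) trials <- trials$trials
  n <- length(trials)
  stop_if_not(n > 0, "no trials supplied")
  x <- array(0, c(spec$out_size[1], spec$out_size[2], 11L, n))
  labels <- actions <- scores <- integer(n)
  subjects <- stages <- character(n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    if (!tr$preprocessed) tr <- preprocess_trial(tr, filter)
    x[, , , i] <- trial_to_tensor(tr, spec)
    labels[i] <- tr$label; actions[i] <- tr$action_id
    subjects[i] <- tr$subject_id; scores[i] <- tr$score
    stages[i] <- tr$stage
  }
  structure(list(x = x, labels = labels, actions = actions,
                 subjects = subjects, scores = scores, stages = stages,
                 cwt = spec),
            class = "tensor_set")
}

#' @export
print.tensor_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<tensor_set> %d trials of %d x %d x %d scalograms\n",
              d[4], d[1], d[2], d[3]))
  print(table(label = x$labels))
  invisible(x)
}

# Subset a tensor_set by trial index.
tensor_subset <- function(ts, idx) {
  structure(list(x = ts$x[, , , idx, drop = FALSE],
                 labels = ts$labels[idx], actions = ts$actions[idx],
                 subjects = ts$subjects[idx], scores = ts$scores[idx],
                 stages = ts$stages[idx], cwt = ts$cwt),
            class = "tensor_set")
}
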