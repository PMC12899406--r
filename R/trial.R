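#' Construct a single movement trial record
#'
#' A trial record holds one segmented elbow movement: the 8-channel sEMG
#' matrix (1 kHz), the end-effector speed trace (500 Hz), and the metadata
#' needed for supervised assessment (subject, action, FMA-UE sub-score,
#' acquisition stage). Parity is derived from the action ID (odd = reach
#' out / extension, even = return / flexion) and the six-class label is
#' `y = 2 s + p`.
#'
#' @param emg Numeric matrix, 8 x T_e, one row per muscle (see
#'   [muscle_names()]), in arbitrary mV-scale units.
#' @param velocity Numeric vector of end-effector speed samples.
#' @param subject_id Character or integer subject identifier.
#' @param action_id Integer action ID in 1..18.
#' @param score FMA-UE sub-score in \{0, 1, 2\}.
#' @param stage Acquisition stage, `"passive"` (robot-guided) or `"active"`
#'   (voluntary).
#' @param emg_fs,kine_fs Sampling rates in Hz.
#' @param preprocessed Logical; set by [preprocess_trial()] once the filter
#'   cascade and kinematic derivation have been applied.
#' @param kinematics Optional list with `velocity`, `acceleration`, `jerk`
#'   vectors (filled by [derive_kinematics()]).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(emg, velocity, subject_id, action_id, score,
                         stage = c("active", "passive"),
                         emg_fs = 1000, kine_fs = 500,
                         preprocessed = FALSE, kinematics = NULL) {
  stage <- match.arg(stage)
  emg <- as.matrix(emg)
  if (nrow(emg) != 8L)
    stop("emg must have exactly 8 rows (one per muscle)", call. = FALSE)
  check_action_id(action_id)
  if (!score %in% 0:2) stop("score must be in {0, 1, 2}", call. = FALSE)
  p <- action_parity(action_id)
  structure(list(
    emg = emg, velocity = as.numeric(velocity),
    subject_id = as.character(subject_id),
    action_id = as.integer(action_id),
    parity = p, score = as.integer(score),
    label = encode_label(score, p),
    stage = stage, emg_fs = emg_fs, kine_fs = kine_fs,
    preprocessed = isTRUE(preprocessed), kinematics = kinematics
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> subject %s, action %d (parity %d), score %d, label %d, %s stage\n",
    x$subject_id, x$action_id, x$parity, x$score, x$label, x$stage))
  cat(sprintf("  emg: 8 x %d @ %g Hz | velocity: %d samples @ %g Hz%s\n",
              ncol(x$emg), x$emg_fs, length(x$velocity), x$kine_fs,
              if (x$preprocessed) " | preprocessed" else ""))
  invisible(x)
}
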