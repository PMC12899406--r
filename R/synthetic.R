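# Synthetic cohort generator: reproducible stand-in for the robot-guided
# elbow assessment recordings, with score-dependent signal structure.

#' Specification of a synthetic assessment cohort
#'
#' Describes a cohort of subjects performing the 18-action elbow protocol in
#' both acquisition stages (robot-guided passive, active voluntary). Subjects
#' are partitioned into three score groups: score-0 and score-1 subjects are
#' "stroke-like", score-2 subjects "healthy-like", mirroring a design where
#' healthy controls anchor the top of the scale. The score level modulates
#' four signal properties, each scaled by `class_effect_size`: agonist burst
#' amplitude (up with score), antagonist co-activation (down), peak movement
#' speed (up) and 3-8 Hz tremor-band ripple on the speed trace (down).
#'
#' @param n_subjects_per_group Subjects per score group; scalar or length-3
#'   vector `(score 0, score 1, score 2)`.
#' @param trials_per_action Trials per subject, action and stage.
#' @param class_effect_size Dimensionless effect strength (>= 0); 0 removes
#'   all score dependence.
#' @param emg_fs,kine_fs Sampling rates in Hz; the sEMG rate must exceed
#'   900 Hz (twice the 450 Hz band edge) and the kinematic rate 100 Hz.
#' @param trial_duration Trial length in seconds.
#' @param class_counts Optional length-3 vector of total trial counts per
#'   score (both stages combined), to emulate class imbalance; must admit at
#'   least one trial per (subject, action, stage) cell of the group.
#' @param signal_channels Integer subset of 1..8: sEMG channels whose burst
#'   amplitude carries the score effect (others stay score-independent).
#'   Used by interpretability-recovery experiments that plant the class
#'   signal in designated channels.
#' @param effect_emg,effect_kine Logical switches planting (or removing) the
#'   class effect in each modality.
#' @param seed Master seed; per-trial RNG substreams are derived by hashing
#'   (subject, action, trial, stage) so cohorts extend without reshuffling.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = 3, trials_per_action = 2,
                        class_effect_size = 1,
                        emg_fs = 1000, kine_fs = 500, trial_duration = 3,
                        class_counts = NULL,
                        signal_channels = 1:8,
                        effect_emg = TRUE, effect_kine = TRUE,
                        seed = 1) {
  n <- rep_len(as.integer(n_subjects_per_group), 3L)
  stop_if_not(all(n >= 1), "need at least one subject per score group")
  stop_if_not(emg_fs > 2 * 450, "emg_fs must exceed 900 Hz (2 x 450 Hz band edge)")
  stop_if_not(kine_fs > 2 * 50, "kine_fs must exceed 100 Hz")
  stop_if_not(trial_duration > 0, "trial_duration must be positive")
  stop_if_not(class_effect_size >= 0, "class_effect_size must be >= 0")
  stop_if_not(all(signal_channels %in% 1:8), "signal_channels must lie in 1..8")
  structure(list(n_subjects_per_group = n,
                 trials_per_action = as.integer(trials_per_action),
                 class_effect_size = class_effect_size,
                 emg_fs = emg_fs, kine_fs = kine_fs,
                 trial_duration = trial_duration,
                 class_counts = class_counts,
                 signal_channels = as.integer(signal_channels),
                 effect_emg = isTRUE(effect_emg),
                 effect_kine = isTRUE(effect_kine),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Fixed per-muscle gains (FCR, ECR, FCU, BR, ECU, BB, TBL, TBLa): mild
# heterogeneity so channels are distinguishable.
.muscle_gain <- c(1.0, 0.9, 0.95, 0.85, 0.9, 1.1, 1.0, 0.8)
# Flexor-side muscles act as agonists on return/flexion trials (parity 1),
# extensor-side muscles on reach-out/extension trials (parity 0).
.flexor_idx <- c(1L, 3L, 4L, 6L)   # FCR, FCU, BR, BB

subject_key <- function(subject_id) {
  sum(utf8ToInt(as.character(subject_id)) * seq_along(utf8ToInt(as.character(subject_id))))
}

#' Simulate one movement trial
#'
#' Generates an 8-channel sEMG matrix as 20-450 Hz band-limited noise,
#' amplitude-modulated by a movement-locked Gaussian burst envelope, and a
#' bell-shaped (minimum-jerk-like) speed profile with superimposed tremor
#' ripple. Agonist/antagonist roles follow the trial parity; burst amplitude,
#' co-activation ratio, peak speed and tremor depth depend on the score as
#' configured in the [cohort_spec()]. Passive-stage trials have strongly
#' reduced voluntary sEMG amplitude and attenuated score effects (the robot
#' guides the limb). Deterministic given (seed, subject, action, trial
#' index, stage).
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier.
#' @param action_id Action ID in 1..18.
#' @param score FMA-UE sub-score in \{0, 1, 2\}.
#' @param stage `"active"` or `"passive"`.
#' @param trial_index Within-cell replicate index (part of the RNG stream).
#' @return A [trial_record()].
#' @export
simulate_trial <- function(spec, subject_id, action_id, score,
                           stage = c("active", "passive"), trial_index = 1) {
  stage <- match.arg(stage)
  stopifnot(inherits(spec, "cohort_spec"))
  check_action_id(action_id)
  if (!score %in% 0:2) stop("score must be in {0, 1, 2}", call. = FALSE)
  p <- action_parity(action_id)
  ces <- spec$class_effect_size
  stage_i <- if (stage == "passive") 1L else 2L
  seed <- hash_seed(spec$seed, subject_key(subject_id), action_id,
                    trial_index, stage_i)
  with_seed(seed, {
    t_e <- round(spec$trial_duration * spec$emg_fs)
    t_k <- round(spec$trial_duration * spec$kine_fs)
    eff_stage <- if (stage == "passive") 0.6 else 1
    dev <- score - 1            # centred score level
    e_emg <- if (spec$effect_emg) ces * eff_stage else 0
    e_kin <- if (spec$effect_kine) ces * eff_stage else 0

    # subject idiosyncrasy: stable multiplicative gain
    sgain <- exp(with_seed(hash_seed(spec$seed, subject_key(subject_id)),
                           stats::rnorm(1, 0, 0.1)))

    ## --- sEMG -----------------------------------------------------------
    # Score shapes the signal structurally (so the effects survive the
    # per-scalogram normalisation downstream): burst amplitude and
    # antagonist co-activation scale with score, the burst of impaired
    # movement is wider with a delayed compensatory sub-burst, and the
    # noise spectrum tilts towards low frequencies with impairment
    # (reduced high-frequency motor-unit content).
    tt <- seq_len(t_e) / spec$emg_fs
    # reach-out (extension) bursts early in the trial, return (flexion)
    # bursts later: a subject-invariant temporal signature of the phase
    centre <- (0.38 + 0.14 * p) * spec$trial_duration
    wid <- 0.12 * spec$trial_duration * max(0.4, 1 - 0.12 * e_emg * dev)
    env <- 0.08 + exp(-0.5 * ((tt - centre) / wid)^2)
    sub_amp <- 0.5 * min(1, max(0, -e_emg * dev) / 2)   # impaired only
    if (sub_amp > 0)
      env <- env + sub_amp *
        exp(-0.5 * ((tt - centre - 0.25 * spec$trial_duration) / wid)^2)
    agonists <- if (p == 1L) .flexor_idx else setdiff(1:8, .flexor_idx)
    amp_mod <- pmax(0.1, 1 + 0.35 * e_emg * dev)
    coact <- pmax(0.05, 0.5 * (1 - 0.3 * e_emg * dev))
    hfrac <- min(0.9, max(0.1, 0.5 + 0.15 * e_emg * dev))
    base_amp <- if (stage == "passive") 0.35 else 1
    ny <- spec$emg_fs / 2
    bp <- signal::butter(4, c(20, 450) / ny, type = "pass")
    bp_lo <- signal::butter(4, c(20, 150) / ny, type = "pass")
    bp_hi <- signal::butter(4, c(150, 450) / ny, type = "pass")
    emg <- matrix(0, 8L, t_e)
    for (ch in 1:8) {
      planted <- ch %in% spec$signal_channels
      role <- if (ch %in% agonists) 1 else if (planted) coact else 0.5
      amp <- base_amp * .muscle_gain[ch] * sgain * role
      if (planted) amp <- amp * amp_mod
      hf <- if (planted) hfrac else 0.5
      carrier <- (1 - hf) * zero_phase_filter(bp_lo$b, bp_lo$a, stats::rnorm(t_e)) +
        hf * zero_phase_filter(bp_hi$b, bp_hi$a, stats::rnorm(t_e))
      env_ch <- if (planted) env else
        0.08 + exp(-0.5 * ((tt - centre) / (0.12 * spec$trial_duration))^2)
      raw <- env_ch * carrier * amp + 0.02 * stats::rnorm(t_e)
      emg[ch, ] <- zero_phase_filter(bp$b, bp$a, raw)
    }

    ## --- kinematics -----------------------------------------------------
    # Healthy movement: one fast, compact minimum-jerk speed bell. With
    # impairment the movement slows (wider bell), fragments into a
    # secondary sub-movement, and carries stronger 3-8 Hz tremor ripple.
    tk <- seq_len(t_k) / spec$kine_fs
    dfrac <- min(0.92 - 0.1 * p, max(0.35, 0.75 - 0.1 * e_kin * dev))
    m0 <- (0.06 + 0.12 * p) * spec$trial_duration
    m1 <- m0 + dfrac * spec$trial_duration
    tau <- pmin(1, pmax(0, (tk - m0) / (m1 - m0)))
    bell <- 30 * tau^2 * (1 - tau)^2 / 1.875   # minimum-jerk speed shape
    v_peak <- pmax(0.05, 0.5 * (1 + 0.4 * e_kin * dev)) * sgain
    sub_kin <- 0.35 * min(1, max(0, -e_kin * dev) / 2)
    if (sub_kin > 0) {
      tau2 <- pmin(1, pmax(0, (tk - m0 - 0.55 * (m1 - m0)) / (0.6 * (m1 - m0))))
      bell <- bell + sub_kin * 30 * tau2^2 * (1 - tau2)^2 / 1.875
    }
    tremor_amp <- pmax(0, 0.08 * (1 - 0.45 * e_kin * dev))
    f_tr <- stats::runif(1, 3, 8)
    tremor <- tremor_amp * sin(2 * pi * f_tr * tk + stats::runif(1, 0, 2 * pi)) *
      (tau > 0 & tau < 1)
    velocity <- v_peak * bell + tremor + 0.01 * stats::rnorm(t_k)

    trial_record(emg = emg, velocity = velocity, subject_id = subject_id,
                 action_id = action_id, score = score, stage = stage,
                 emg_fs = spec$emg_fs, kine_fs = spec$kine_fs)
  })
}

# Trials per (subject, action, stage) cell for each score group, honouring
# optional class_counts totals.
cell_counts <- function(spec) {
  n_sub <- spec$n_subjects_per_group
  if (is.null(spec$class_counts)) {
    lapply(1:3, function(s) rep(spec$trials_per_action, n_sub[s] * 18L * 2L))
  } else {
    cc <- rep_len(as.numeric(spec$class_counts), 3L)
    lapply(1:3, function(s) {
      cells <- n_sub[s] * 18L * 2L
      if (cc[s] < cells)
        stop(sprintf(
          "class_counts[%d] = %g is infeasible: score group %d has %d (subject, action, stage) cells",
          s, cc[s], s - 1L, cells), call. = FALSE)
      base <- floor(cc[s] / cells)
      extra <- cc[s] - base * cells
      counts <- rep(base, cells)
      if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
      counts
    })
  }
}

#' Simulate a full synthetic cohort
#'
#' Enumerates subjects by score group and generates every (subject, stage,
#' action, replicate) trial, together with a manifest recording the design.
#' Identical specs (including seed) produce bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with elements `trials` (list of
#'   [trial_record()]), `manifest` (data frame with one row per trial) and
#'   `spec`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects_per_group = 1,
#'                                   trials_per_action = 1,
#'                                   trial_duration = 1))
#' nrow(co$manifest)   # 3 subjects x 18 actions x 2 stages = 108
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sub <- spec$n_subjects_per_group
  counts <- cell_counts(spec)
  subj_scores <- rep(0:2, n_sub)
  subj_ids <- sprintf("S%02d", seq_along(subj_scores))
  trials <- list()
  rows <- list()
  k <- 0L
  for (s in 0:2) {
    group_subjects <- subj_ids[subj_scores == s]
    cnt <- counts[[s + 1L]]
    cell <- 0L
    for (sid in group_subjects) {
      for (stage in c("passive", "active")) {
        for (a in 1:18) {
          cell <- cell + 1L
          for (r in seq_len(cnt[cell])) {
            k <- k + 1L
            trials[[k]] <- simulate_trial(spec, sid, a, s, stage, r)
            rows[[k]] <- data.frame(
              trial = k, subject_id = sid,
              group = if (s == 2) "healthy" else "stroke",
              score = s, action_id = a, parity = action_parity(a),
              label = encode_label(s, action_parity(a)),
              stage = stage, trial_index = r)
          }
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(trials = trials, manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d trials, %d subjects, %g s trials\n",
              length(x$trials), length(unique(x$manifest$subject_id)),
              x$spec$trial_duration))
  print(table(score = x$manifest$score, stage = x$manifest$stage))
  invisible(x)
}

#' Save / load a cohort
#'
#' Writes the trial list to `cohort.rds` and the manifest to a plain-text
#' `manifest.csv` inside `dir`.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Target directory (created if missing).
#' @return `save_cohort()` returns `dir` invisibly; `load_cohort()` the
#'   restored cohort.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(cohort, file.path(dir, "cohort.rds"))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  readRDS(file.path(dir, "cohort.rds"))
}
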