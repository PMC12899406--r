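# Macro-averaged classification metrics, separability statistics,
# interpretability extraction and the ablation / temperature experiment
# drivers.

#' Confusion matrix and macro-averaged metrics
#'
#' Builds the n_classes x n_classes confusion matrix (rows = truth,
#' columns = prediction) and derives accuracy plus macro-averaged
#' precision, recall and F1 (unweighted means of the per-class values).
#' Classes absent from both truth and prediction contribute 0 to the macro
#' means, so small-sample reports stay deterministic.
#'
#' @param y_true,y_pred Integer label vectors in `0..n_classes-1`.
#' @param n_classes Number of classes (6 for the assessment task).
#' @return List of class `eval_report`: `confusion`, `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `per_class` (data frame
#'   with precision/recall/F1/support per class) and `n`.
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)$accuracy
#' @export
compute_metrics <- function(y_true, y_pred, n_classes = 6) {
  stop_if_not(length(y_true) == length(y_pred), "length mismatch")
  stop_if_not(length(y_true) > 0, "empty input")
  stop_if_not(all(y_true %in% 0:(n_classes - 1)) &&
                all(y_pred %in% 0:(n_classes - 1)),
              sprintf("labels must lie in 0..%d", n_classes - 1))
  lv <- 0:(n_classes - 1)
  confusion <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(true = lv, pred = lv))
  diag_v <- diag(confusion)
  rows <- rowSums(confusion)
  cols <- colSums(confusion)
  recall <- ifelse(rows > 0, diag_v / rows, 0)
  precision <- ifelse(cols > 0, diag_v / cols, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    confusion = confusion,
    accuracy = sum(diag_v) / sum(confusion),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    per_class = data.frame(class = lv, precision = precision,
                           recall = recall, f1 = f1, support = rows),
    n = length(y_true)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d | accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Stratified sub-report
#'
#' Restricts an evaluation to a subset of trials (e.g. the stroke cohort,
#' scores 0-1 only) and recomputes the metrics on that subset.
#'
#' @param y_true,y_pred Label vectors.
#' @param keep Logical or integer index of trials to keep.
#' @param n_classes Number of classes.
#' @return An `eval_report` for the subset.
#' @export
stratified_metrics <- function(y_true, y_pred, keep, n_classes = 6) {
  compute_metrics(y_true[keep], y_pred[keep], n_classes)
}

#' Fisher discriminant ratio
#'
#' Separability of a scalar feature across groups: the sample-size-weighted
#' variance of the group means around the grand mean, divided by the
#' sample-size-weighted mean within-group variance. Zero within-group
#' variance with distinct means yields `Inf` with a warning (degenerate
#' separation).
#'
#' @param x Numeric feature vector.
#' @param g Group labels (>= 2 groups with >= 2 observations each).
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' fisher_discriminant_ratio(c(0, 1, 2, 3), c(0, 0, 1, 1))  # 2
#' @export
fisher_discriminant_ratio <- function(x, g) {
  g <- as.factor(g)
  stop_if_not(nlevels(g) >= 2, "need at least 2 groups")
  ns <- tapply(x, g, length)
  stop_if_not(all(ns >= 2), "every group needs at least 2 observations")
  means <- tapply(x, g, mean)
  vars <- tapply(x, g, stats::var)
  n <- length(x)
  between <- sum(ns * (means - mean(x))^2) / n
  within <- sum(ns * vars) / n
  if (within == 0) {
    if (between == 0) return(0)
    warning("zero within-group variance: returning Inf (degenerate separation)")
    return(Inf)
  }
  between / within
}

#' Extract attention and gating summaries
#'
#' Runs a trained model over a tensor set in evaluation mode, captures the
#' per-trial attention weights of both branches and the gate weights, and
#' aggregates them overall and per action — the quantities behind muscle
#' importance heatmaps and modality-contribution analyses.
#'
#' @param model A trained [amwfnet_model()] (variant `"full"` for gate
#'   weights; single-branch variants yield that branch only).
#' @param ts A `tensor_set` (see [cohort_to_tensors()]).
#' @param batch_size Evaluation batch size.
#' @return List of class `attention_summary`: `emg_mean` (length 8, named
#'   by muscle), `kine_mean` (length 3), `emg_by_action` (18 x 8),
#'   `kine_by_action` (18 x 3), `gate_mean` (length 2) and the per-trial
#'   matrices `alpha_emg`, `alpha_kine`, `w`.
#' @export
extract_attention <- function(model, ts, batch_size = 64) {
  n <- length(ts$labels)
  a_emg <- if (model$config$variant != "kine_only")
    matrix(NA_real_, n, model$config$n_emg,
           dimnames = list(NULL, muscle_names()))
  a_kine <- if (model$config$variant != "semg_only")
    matrix(NA_real_, n, model$config$n_kine,
           dimnames = list(NULL, c("velocity", "acceleration", "jerk")))
  w <- if (model$config$variant %in% c("full")) matrix(NA_real_, n, 2)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- model_forward(model, get_batch_x(ts, ix), ts$actions[ix],
                        training = FALSE)
    if (!is.null(fw$alpha_emg)) a_emg[ix, ] <- t(fw$alpha_emg)
    if (!is.null(fw$alpha_kine)) a_kine[ix, ] <- t(fw$alpha_kine)
    if (!is.null(fw$w)) w[ix, ] <- fw$w
  }
  by_action <- function(a) {
    if (is.null(a)) return(NULL)
    out <- matrix(NA_real_, 18L, ncol(a), dimnames = list(1:18, colnames(a)))
    for (act in sort(unique(ts$actions)))
      out[act, ] <- colMeans(a[ts$actions == act, , drop = FALSE])
    out
  }
  structure(list(
    emg_mean = if (!is.null(a_emg)) colMeans(a_emg),
    kine_mean = if (!is.null(a_kine)) colMeans(a_kine),
    emg_by_action = by_action(a_emg),
    kine_by_action = by_action(a_kine),
    gate_mean = if (!is.null(w)) colMeans(w),
    alpha_emg = a_emg, alpha_kine = a_kine, w = w),
    class = "attention_summary")
}

#' @export
print.attention_summary <- function(x, ...) {
  cat("<attention_summary>\n")
  if (!is.null(x$emg_mean)) {
    cat("  mean sEMG attention:\n")
    print(round(x$emg_mean, 3))
  }
  if (!is.null(x$kine_mean)) {
    cat("  mean kinematic attention:\n")
    print(round(x$kine_mean, 3))
  }
  if (!is.null(x$gate_mean))
    cat(sprintf("  mean gate (emg, kine): %.3f, %.3f\n",
                x$gate_mean[1], x$gate_mean[2]))
  invisible(x)
}

# Shared driver: build a model variant, run two-stage training on the given
# tensor splits, evaluate on test.
run_variant <- function(variant, splits, model_args = list(),
                        cfg = train_config(), seed = 1) {
  margs <- utils::modifyList(
    list(variant = variant, seed = hash_seed(seed, 11L)), model_args)
  model <- do.call(amwfnet_model, margs)
  fit <- train_two_stage(model, splits$passive_train, splits$passive_val,
                         splits$active_train, splits$active_val,
                         cfg = cfg, seed = seed)
  ev <- evaluate_tensors(fit$model, splits$active_test)
  rep <- compute_metrics(splits$active_test$labels, ev$preds)
  list(model = fit$model, history = fit, report = rep,
       gate = ev$gate)
}

#' Ablation suite
#'
#' Trains and evaluates the five architecture configurations — sEMG only,
#' kinematics only, no action embedding, concatenation fusion, and the full
#' model — under identical data splits and training settings; each variant
#' differs from the full model only in the named component.
#'
#' @param splits List with `passive_train`, `passive_val`, `active_train`,
#'   `active_val`, `active_test` tensor sets (passive entries may be NULL).
#' @param variants Character vector of variants to run.
#' @param model_args Extra arguments passed to [amwfnet_model()] (e.g.
#'   reduced `input_size` / `channels` for desk-scale runs).
#' @param cfg A [train_config()].
#' @param seed Seed shared across variants.
#' @return Data frame with one row per variant: accuracy, macro metrics and
#'   mean gate weights; attribute `runs` holds the fitted models.
#' @export
ablation_suite <- function(splits,
                           variants = c("semg_only", "kine_only", "no_action",
                                        "concat", "full"),
                           model_args = list(), cfg = train_config(),
                           seed = 1) {
  known <- c("full", "semg_only", "kine_only", "no_action", "concat")
  bad <- setdiff(variants, known)
  if (length(bad) > 0)
    stop("unknown variant(s): ", paste(bad, collapse = ", "), call. = FALSE)
  runs <- lapply(variants, run_variant, splits = splits,
                 model_args = model_args, cfg = cfg, seed = seed)
  names(runs) <- variants
  res <- data.frame(
    variant = variants,
    accuracy = vapply(runs, function(r) r$report$accuracy, numeric(1)),
    macro_precision = vapply(runs, function(r) r$report$macro_precision, numeric(1)),
    macro_recall = vapply(runs, function(r) r$report$macro_recall, numeric(1)),
    macro_f1 = vapply(runs, function(r) r$report$macro_f1, numeric(1)),
    w_emg = vapply(runs, function(r) r$gate[1], numeric(1)),
    w_kine = vapply(runs, function(r) r$gate[2], numeric(1)),
    row.names = NULL)
  attr(res, "runs") <- runs
  res
}

#' Gating temperature sweep
#'
#' Trains the full model once per temperature value and reports test
#' metrics, converged mean gate weights and the gate entropy — the
#' sensitivity analysis of the fusion sharpness parameter.
#'
#' @param splits As in [ablation_suite()].
#' @param taus Positive temperature values (the study grid spans 0.5-10).
#' @param model_args,cfg,seed As in [ablation_suite()].
#' @return Data frame with one row per temperature (accuracy, macro F1,
#'   w_emg, w_kine, gate entropy).
#' @export
temperature_sweep <- function(splits,
                              taus = c(0.5, 1, 1.5, 2, 2.5, 3, 5, 8, 10),
                              model_args = list(), cfg = train_config(),
                              seed = 1) {
  stop_if_not(all(taus > 0), "temperatures must be positive")
  rows <- lapply(taus, function(tau) {
    r <- run_variant("full", splits,
                     utils::modifyList(model_args, list(tau = tau)),
                     cfg, seed)
    w <- pmin(pmax(r$gate, 1e-12), 1)
    data.frame(tau = tau, accuracy = r$report$accuracy,
               macro_f1 = r$report$macro_f1,
               w_emg = r$gate[1], w_kine = r$gate[2],
               gate_entropy = -sum(w * log(w)))
  })
  do.call(rbind, rows)
}
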