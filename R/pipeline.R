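# End-to-end glue: cohort -> subject-wise split -> balanced, augmented
# training tensors per acquisition stage, plus model checkpointing.

#' Prepare the per-stage tensor splits for two-stage training
#'
#' Applies the split-then-augment protocol: trials are partitioned
#' subject-wise, the training partition of each acquisition stage is
#' class-balanced by augmentation oversampling (validation and test remain
#' untouched), and every partition is converted to scalogram tensor sets.
#'
#' @param cohort A `cohort` from [simulate_cohort()] (or a list with
#'   `trials` and `manifest`).
#' @param split A [subject_split()] computed on `cohort$manifest`.
#' @param cwt A [cwt_spec()] (reduced `out_size` keeps desk-scale runs
#'   fast).
#' @param filter A [filter_spec()].
#' @param balance Class-balance the training partitions by augmentation.
#' @param aug An [augmentation_config()].
#' @param seed Seed for the augmentation draws.
#' @param stages Acquisition stages to tensorise (skipping the passive
#'   stage halves the transform cost for single-stage experiments).
#' @return List of `tensor_set`s: `passive_train`, `passive_val`,
#'   `active_train`, `active_val`, `active_test` (and `passive_test`).
#' @export
prepare_training_data <- function(cohort, split, cwt = cwt_spec(),
                                  filter = filter_spec(), balance = TRUE,
                                  aug = augmentation_config(), seed = 1,
                                  stages = c("passive", "active")) {
  man <- cohort$manifest
  out <- list()
  for (stage in stages) {
    for (part in c("train", "val", "test")) {
      idx <- intersect(split[[part]], which(man$stage == stage))
      trials <- cohort$trials[idx]
      if (part == "train" && balance && length(trials) > 0) {
        bal <- balance_training_set(trials, rep("train", length(trials)),
                                    cfg = aug,
                                    seed = hash_seed(seed, match(stage, c("passive", "active"))))
        trials <- bal$trials
      }
      out[[paste(stage, part, sep = "_")]] <-
        if (length(trials) > 0) cohort_to_tensors(trials, cwt, filter) else NULL
    }
  }
  out
}

#' Save / load a trained model
#'
#' Writes the weights and configuration to `model.rds` and a JSON
#' architecture fingerprint (layer names, shapes, total parameter count) to
#' `fingerprint.json` inside `dir`.
#'
#' @param model An [amwfnet_model()].
#' @param dir Target directory (created if missing).
#' @return `save_model()` returns `dir` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  fp <- architecture_fingerprint(model)
  jsonlite::write_json(
    list(variant = fp$variant, total_parameters = fp$total_parameters,
         layers = fp$layers),
    file.path(dir, "fingerprint.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}

#' Save / load a tensor set
#'
#' @param ts A `tensor_set` (see [cohort_to_tensors()]).
#' @param path Path to an `.rds` file.
#' @return `save_tensors()` returns `path` invisibly; `load_tensors()` the
#'   restored set.
#' @export
save_tensors <- function(ts, path) {
  saveRDS(ts, path)
  invisible(path)
}

#' @rdname save_tensors
#' @export
load_tensors <- function(path) readRDS(path)
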