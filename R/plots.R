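# Base-graphics visualisations of evaluation reports and attention
# summaries.

#' Plot a confusion matrix as a heatmap
#'
#' @param report An `eval_report` from [compute_metrics()].
#' @param main Plot title.
#' @return Invisibly, the confusion matrix.
#' @export
plot_confusion <- function(report, main = "Confusion matrix") {
  cm <- report$confusion
  n <- nrow(cm)
  graphics::image(1:n, 1:n, t(cm[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True",
                  main = main)
  graphics::axis(1, at = 1:n, labels = colnames(cm))
  graphics::axis(2, at = 1:n, labels = rev(rownames(cm)))
  for (i in 1:n) for (j in 1:n)
    graphics::text(j, n + 1 - i, cm[i, j],
                   col = if (cm[i, j] > max(cm) / 2) "white" else "black")
  invisible(cm)
}

#' Plot per-action attention heatmaps
#'
#' Displays the 18 x 8 (sEMG) or 18 x 3 (kinematics) mean attention-weight
#' matrix of an [extract_attention()] summary.
#'
#' @param summary An `attention_summary`.
#' @param branch `"emg"` or `"kine"`.
#' @param main Plot title.
#' @return Invisibly, the plotted matrix.
#' @export
plot_attention <- function(summary, branch = c("emg", "kine"),
                           main = NULL) {
  branch <- match.arg(branch)
  m <- if (branch == "emg") summary$emg_by_action else summary$kine_by_action
  stop_if_not(!is.null(m), "summary lacks this branch")
  main <- main %||% sprintf("Mean %s attention by action",
                            if (branch == "emg") "muscle" else "kinematic")
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "Action ID", main = main)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m))
  invisible(m)
}

#' Plot the gate-weight trajectory over training epochs
#'
#' @param history A history data frame from [train_two_stage()] (columns
#'   `epoch`, `w_emg`, `w_kine`).
#' @param main Plot title.
#' @return Invisibly, the history.
#' @export
plot_gate_trajectory <- function(history, main = "Modality gate weights") {
  graphics::plot(history$epoch, history$w_kine, type = "l", col = "steelblue",
                 ylim = c(0, 1), xlab = "Epoch", ylab = "Mean gate weight",
                 main = main, lwd = 2)
  graphics::lines(history$epoch, history$w_emg, col = "firebrick", lwd = 2)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topright", c("kinematics", "sEMG"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(history)
}
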