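# Lightweight base-graphics views of the evaluation battery.

#' Heat map of a cross-subject MSE matrix
#'
#' Rows are the model's subject, columns the test subject; a personalized
#' model shows a visibly darker (smaller) diagonal.
#'
#' @param report An `eval_report` from [cross_subject_mse_matrix()], or a
#'   plain matrix.
#' @param main Plot title.
#' @export
plot_mse_matrix <- function(report, main = "Cross-subject MSE") {
  mat <- if (inherits(report, "eval_report")) report$mse_matrix else report
  S <- nrow(mat)
  graphics::image(seq_len(S), seq_len(S), t(mat[S:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "test subject", ylab = "model subject",
                  main = main)
  graphics::axis(1, at = seq_len(S), labels = colnames(mat))
  graphics::axis(2, at = seq_len(S), labels = rev(rownames(mat)), las = 1)
  for (i in seq_len(S)) for (j in seq_len(S))
    graphics::text(j, S - i + 1, sprintf("%.3f", mat[i, j]), cex = 0.7)
  invisible(mat)
}

#' Learning curves of a training run
#'
#' @param curves Data frame from [train_model()] / [train_decoder()].
#' @param main Plot title.
#' @export
plot_learning_curves <- function(curves, main = "Learning curves") {
  graphics::matplot(curves$epoch, cbind(curves$train_mse, curves$val_mse),
                    type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "MSE", main = main)
  graphics::legend("topright", c("train", "validation"), lty = 1, lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(curves)
}
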