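# CID / CSED plotting and TSV export.

#' Write D/S difference vectors as TSV
#' @param result An `eval_result` from [evaluate_predictions()].
#' @param path Output TSV path.
#' @export
write_eval_tsv <- function(result, path) {
  df <- data.frame(
    rank = seq_len(result$n) - 1L,
    D = result$D,
    S = result$S,
    S_scaled = csed_plot_scale(result$S)
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Plot a CID or CSED difference curve
#'
#' The horizontal axis is the cumulative number of alignments passing the
#' quality threshold (left = strict, right = permissive); the vertical axis
#' is the difference curve, with CSED values compressed through
#' [csed_plot_scale()]. The curve staying below `y = 0` means the
#' challenger's predictions are better at those thresholds.
#'
#' @param result An `eval_result`.
#' @param which `"cid"` or `"csed"`.
#' @return A `ggplot` object.
#' @export
plot_difference_curve <- function(result, which = c("csed", "cid")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  which <- match.arg(which)
  y <- if (which == "cid") result$D else csed_plot_scale(result$S)
  df <- data.frame(i = seq_len(result$n) - 1L, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(
      x = "alignments passing threshold",
      y = if (which == "cid") "D = C' - C" else "sign(S)·log10(|S|+1)",
      title = toupper(which)
    ) +
    ggplot2::theme_minimal()
}
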