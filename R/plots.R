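#' Plot a pitch track, optionally with its Momel stylization
#'
#' @param object A `pitch_track`.
#' @param curve Optional [momel_curve()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot pitch_track
autoplot.pitch_track <- function(object, curve = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$f0_hz)) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.6, colour = "darkgreen") +
    ggplot2::labs(x = "time (s)", y = "f0 (Hz)")
  if (!is.null(curve)) {
    grid <- seq(min(curve$mtps$time_s), max(curve$mtps$time_s), length.out = 200)
    p <- p +
      ggplot2::geom_line(
        data = tibble::tibble(time_s = grid, f0_hz = spline_eval(curve, grid)),
        colour = "firebrick"
      ) +
      ggplot2::geom_point(
        data = curve$mtps, shape = 21, size = 2.5,
        fill = "white", colour = "firebrick"
      )
  }
  p
}

#' Plot an INTSINT annotation over its Momel target points
#'
#' @param object An `intsint_annotation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot intsint_annotation
autoplot.intsint_annotation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$f0_hz)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8) +
    ggplot2::geom_hline(
      yintercept = object$key_hz, linetype = "dashed",
      colour = "grey40"
    ) +
    ggplot2::labs(
      x = "time (s)", y = "f0 (Hz)",
      title = sprintf("key %.0f Hz, span %.2f oct", object$key_hz, object$span_oct)
    )
}

#' Heatmap of a confusion matrix
#'
#' @param object A `prosodia_confusion` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot prosodia_confusion
autoplot.prosodia_confusion <- function(object, ...) {
  d <- tibble::as_tibble(as.data.frame(unclass(object)))
  d <- tidyr::pivot_longer(
    dplyr::mutate(d, truth = rownames(unclass(object))),
    -"truth",
    names_to = "predicted", values_to = "n"
  )
  lv <- rownames(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$predicted, lv),
    y = factor(.data$truth, rev(lv)), fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "predicted", y = "truth") +
    ggplot2::guides(fill = "none")
}

#' Lollipop chart of FIRM importances
#'
#' @param object An `importance_table`.
#' @param top Number of predictors to show (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot importance_table
autoplot.importance_table <- function(object, top = 30L, ...) {
  d <- utils::head(object, top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance)
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature), colour = "grey60") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "FIRM importance", y = NULL)
}

#' Plot one-vs-rest ROC curves
#'
#' @param roc_list Named list of [roc_ovr()] results.
#' @return A ggplot.
#' @export
plot_roc <- function(roc_list) {
  d <- dplyr::bind_rows(
    lapply(roc_list, function(r) r$points),
    .id = "class"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}
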