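# ggplot2 displays for the package's result types.

mat_to_df <- function(m) {
  d <- dim(m)
  tibble::tibble(
    row = rep(seq_len(d[1L]), times = d[2L]),
    col = rep(seq_len(d[2L]), each = d[1L]),
    value = as.vector(m))
}

#' @rdname generate_phantom
#' @param object A `phantom_case`.
#' @param which `"image"` or `"mask"`.
#' @param ... Unused.
#' @method autoplot phantom_case
#' @export
autoplot.phantom_case <- function(object, which = c("image", "mask"), ...) {
  which <- match.arg(which)
  m <- if (which == "image") object$image$pixels else object$mask
  df <- mat_to_df(m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s (%s)", object$image$source_id, which)) +
    ggplot2::theme_minimal()
  if (which == "image")
    p + ggplot2::scale_fill_gradient(low = "black", high = "white",
                                     name = "intensity")
  else
    p + ggplot2::scale_fill_viridis_c(name = "label")
}

#' @rdname score_case
#' @param object A `kauppila_result`.
#' @method autoplot kauppila_result
#' @export
autoplot.kauppila_result <- function(object, ...) {
  df <- object$segments
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$score,
                                   fill = .data$wall)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 3), breaks = 0:3) +
    ggplot2::labs(y = "Kauppila segment score",
                  title = sprintf("total %d/24 (%s)", object$total,
                                  object$severity)) +
    ggplot2::theme_minimal()
}

#' @rdname bland_altman
#' @param object A `bland_altman` result.
#' @param ... Unused.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = attr(object, "means"),
                       diff = attr(object, "differences"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of paired scores", y = "difference (test - ref)",
                  title = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' @rdname agreement_report
#' @param object An `aac_agreement`.
#' @method autoplot aac_agreement
#' @export
autoplot.aac_agreement <- function(object, ...) {
  autoplot.bland_altman(object$bland_altman)
}

#' Severity confusion matrix heat map
#'
#' @param agreement An `aac_agreement` from [agreement_report()].
#' @return A ggplot.
#' @export
plot_severity_confusion <- function(agreement) {
  df <- tibble::as_tibble(as.data.frame(agreement$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$reference,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey25", high = "steelblue") +
    ggplot2::labs(title = sprintf("severity accuracy %.2f",
                                  agreement$accuracy)) +
    ggplot2::theme_minimal()
}

#' Training loss curve
#'
#' @param trace Trace tibble from [train_unet()].
#' @return A ggplot of per-step loss with epoch-mean overlay.
#' @export
plot_training_trace <- function(trace) {
  em <- attr(trace, "epoch_mean")
  emdf <- tibble::tibble(
    step = vapply(split(trace$step, trace$epoch), max, numeric(1)),
    loss = em)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(data = emdf, colour = "firebrick") +
    ggplot2::labs(y = "soft-Dice loss") +
    ggplot2::theme_minimal()
}
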