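#' Plot a 12-lead ECG record
#'
#' Stacked lead traces in canonical order, time in seconds, amplitude in
#' millivolts.
#'
#' @param object An [ecg_record()].
#' @param max_ms Plot at most this many milliseconds (default 5000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, max_ms = 5000, ...) {
  fs <- attr(object, "sampling_rate")
  n <- min(nrow(object), round(max_ms * fs / 1000))
  df <- as.data.frame(object)[seq_len(n), ]
  df$time_s <- (seq_len(n) - 1) / fs
  long <- tidyr::pivot_longer(df, cols = -"time_s", names_to = "lead",
                              values_to = "mV")
  long$lead <- factor(long$lead, levels = canonical_leads())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 3, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)",
                  title = sprintf("%s (%s)", attr(object, "record_id"),
                                  attr(object, "label"))) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot one ECG image set
#'
#' Renders the twelve grayscale lead images of one window as a faceted
#' raster, as the classifier sees them.
#'
#' @param images A `12 x side x side` integer array (one row of the
#'   `images` list-column).
#' @param gray_levels Gray-level count (default 256).
#' @return A ggplot object.
#' @export
plot_image_set <- function(images, gray_levels = 256) {
  leads <- dimnames(images)[[1]] %||% canonical_leads()
  side <- dim(images)[2]
  df <- purrr::map_dfr(seq_along(leads), function(l) {
    tibble::tibble(
      lead = leads[l],
      row = rep(seq_len(side), times = side),
      col = rep(seq_len(side), each = side),
      value = as.vector(images[l, , ])
    )
  })
  df$lead <- factor(df$lead, levels = canonical_leads())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, gray_levels - 1),
                                 guide = "none") +
    ggplot2::facet_wrap(~lead, ncol = 4) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void(base_size = 9) +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 8))
}

#' Plot a training history
#'
#' @param object An `ecg_cnn_fit`.
#' @param ... Unused.
#' @return A ggplot object of loss and training accuracy per epoch.
#' @export
autoplot.ecg_cnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, cols = c("loss", "accuracy"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot a confusion matrix
#'
#' @param object An `ecg_cv_result`.
#' @param ... Unused.
#' @return A ggplot heat map (rows = true class, columns = predicted).
#' @export
autoplot.ecg_cv_result <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("true", "predicted", "n")
  df$true <- factor(df$true, levels = rev(rownames(cm)))
  df$predicted <- factor(df$predicted, levels = colnames(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal(base_size = 10)
}
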