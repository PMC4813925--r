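# ggplot2 visualizations for the main result types.

image_raster_df <- function(m) {
  tibble::tibble(
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    row = rep(seq_len(nrow(m)), ncol(m)),
    value = as.vector(m)
  )
}

#' Plot a B-mode image (optionally with overlays)
#'
#' @param img A [bmode_image] or a plain matrix.
#' @param paths Optional named list of row-vectors to overlay (one line
#'   each).
#' @return A ggplot object (y axis reversed so depth grows downward).
#' @export
plot_bmode <- function(img, paths = NULL) {
  m <- if (inherits(img, "bmode_image")) img$intensities else unclass(img)
  p <- ggplot2::ggplot(image_raster_df(m),
                       ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(paths)) {
    pd <- dplyr::bind_rows(lapply(names(paths), function(nm) tibble::tibble(
      path = nm, col = seq_along(paths[[nm]]), row = paths[[nm]])))
    p <- p + ggplot2::geom_line(
      data = pd, ggplot2::aes(color = .data$path), linewidth = 0.6) +
      ggplot2::labs(color = NULL)
  }
  p
}

#' @export
autoplot.lumen_detection <- function(object, ...) {
  paths <- list()
  if (!is.null(object$rows)) paths[[object$method]] <- object$rows
  plot_bmode(object$image, paths = paths) +
    ggplot2::ggtitle(sprintf("lumen detection (%s%s)", object$method,
                             if (object$fallback) ", fallback" else ""))
}

#' @export
autoplot.lumen_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lumen_report <- function(object, ...) {
  d <- object$performance
  d$snr_plot <- ifelse(is.infinite(d$snr_db), max(object$config$snr_grid_db) + 10,
                       d$snr_db)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$snr_plot, y = .data$mean_pct,
                                  color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                                        ymax = .data$mean_pct + .data$sd_pct),
                           width = 1.5, alpha = 0.5) +
    ggplot2::facet_wrap(~noise_model) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "SNR (dB; right-most point = noiseless)",
                  y = "% correct detections", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
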