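# broom-style accessors and ggplot2 autoplot methods for fitted objects and
# metric reports.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x a `fundseg_fit`.
#' @param ... unused.
#' @return tibble: one row per epoch with losses and validation DSC.
#' @method tidy fundseg_fit
#' @export
tidy.fundseg_fit <- function(x, ...) x$history

#' One-row training summary
#'
#' @param x a `fundseg_fit`.
#' @param ... unused.
#' @return tibble with `epochs`, `best_epoch`, `best_val_dsc`,
#'   `final_train_total`.
#' @method glance fundseg_fit
#' @export
glance.fundseg_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_dsc = x$best_val_dsc,
                 final_train_total = utils::tail(x$history$train_total, 1))
}

#' Tidy a metric report
#'
#' @param x a `fundseg_report`.
#' @param ... unused.
#' @return tibble of per-image, per-region metrics.
#' @method tidy fundseg_report
#' @export
tidy.fundseg_report <- function(x, ...) x$per_image

#' Per-region metric summary
#'
#' @param x a `fundseg_report`.
#' @param ... unused.
#' @return tibble with one row per region.
#' @method glance fundseg_report
#' @export
glance.fundseg_report <- function(x, ...) x$summary

#' Plot a training run
#'
#' Training loss components and validation DSC per epoch.
#'
#' @param object a `fundseg_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fundseg_fit
#' @export
autoplot.fundseg_fit <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("autoplot requires ggplot2")
  h <- object$history
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$train_total, series = "train total loss"),
    data.frame(epoch = h$epoch, value = h$train_dice, series = "train Dice loss"),
    data.frame(epoch = h$epoch, value = h$val_dsc, series = "validation DSC"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a metric report
#'
#' Per-image DSC by region with the per-region mean.
#'
#' @param object a `fundseg_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fundseg_report
#' @export
autoplot.fundseg_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("autoplot requires ggplot2")
  ggplot2::ggplot(object$per_image,
                  ggplot2::aes(x = .data$region, y = .data$dsc)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Dice similarity coefficient") +
    ggplot2::theme_minimal()
}

#' Display a phantom or prediction as a raster plot
#'
#' @param image array `[H, W, 3]` in `[0, 1]`.
#' @param mask optional label mask drawn as contours.
#' @return a ggplot object.
#' @export
plot_fundus <- function(image, mask = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_fundus requires ggplot2")
  H <- dim(image)[1]; W <- dim(image)[2]
  df <- expand.grid(row = seq_len(H), col = seq_len(W))
  df$fill <- grDevices::rgb(image[, , 1], image[, , 2], image[, , 3])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    mdf <- expand.grid(row = seq_len(H), col = seq_len(W))
    mdf$z <- as.vector(mask)
    p <- p + ggplot2::geom_contour(
      data = mdf, ggplot2::aes(z = .data$z), breaks = c(0.5, 1.5),
      colour = "white", linewidth = 0.3)
  }
  p
}
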