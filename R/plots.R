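#' Plot one slice of a volume
#'
#' A quick ggplot2 raster view of an axial (or other) slice, for visual
#' inspection of phantoms, defacing results and segmentations.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param k Slice index (1-based) along `axis`.
#' @param axis Slicing axis, 1-3 (default 3 = axial).
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, k = ceiling(dim(vol$data)[3] / 2), axis = 3) {
  sl <- switch(axis,
               `1` = vol$data[k, , ],
               `2` = vol$data[, k, ],
               `3` = vol$data[, , k])
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.numeric(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice %d / axis %d", k, axis)) +
    ggplot2::theme_minimal()
  if (inherits(vol, "label_volume")) {
    df$tissue <- factor(df$value, levels = 0:3,
                        labels = c("background", "CSF", "GM", "WM"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          fill = .data$tissue)) +
      ggplot2::geom_raster() +
      ggplot2::coord_fixed() +
      ggplot2::scale_fill_manual(values = c(background = "black",
                                            CSF = "#3366cc", GM = "#999999",
                                            WM = "#eeeeee")) +
      ggplot2::theme_minimal()
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient plot of a fitted volume model
#' @param object A `volume_fit`.
#' @param ... Unused.
#' @return A ggplot object (forest plot of coefficients with 95% CIs).
#' @export
autoplot.volume_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "coefficient (ml)", y = NULL,
                  title = sprintf("%s model", object$spec$response)) +
    ggplot2::theme_minimal()
}

#' Success-rate plot across pipeline steps
#' @param object A [success_rate_report()].
#' @param ... Unused.
#' @return A ggplot object (per-group percentage at each pipeline step).
#' @export
autoplot.success_rate_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$percent,
                                       group = .data$group,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "% of selected") +
    ggplot2::theme_minimal()
}
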