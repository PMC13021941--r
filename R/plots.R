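#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sigmoid fit
#'
#' Data points with the fitted formation curve; the lag and transition
#' windows are marked when the fit converged.
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  df <- tibble::tibble(t = object$t, y = object$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "time (h)", y = "response",
                  subtitle = sprintf("lag %.2g h, transition %.2g h [%s]",
                                     object$lag_time,
                                     object$transition_time, object$flag)) +
    ggplot2::theme_minimal()
  if (object$flag != "no_transition" && is.finite(object$d)) {
    tt <- seq(min(df$t), max(df$t), length.out = 200)
    fitdf <- tibble::tibble(
      t = tt, y = sigmoid_curve(tt, object$a, object$b, object$c, object$d))
    p <- p + ggplot2::geom_line(data = fitdf, color = "#b2182b")
    if (is.finite(object$lag_time))
      p <- p + ggplot2::geom_vline(xintercept = object$lag_time,
                                   linetype = "dashed", color = "grey40")
  }
  p
}

#' Plot a displacement-length distribution
#'
#' @param object A `displacement_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.displacement_distribution <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(width = diff(object$edges)[1], fill = "grey60") +
    ggplot2::labs(x = "displacement length r (µm)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a diffusion-state mixture fit over its histogram
#'
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  nb <- length(object$counts)
  mids <- (object$edges[-1] + object$edges[-(nb + 1)]) / 2
  widths <- diff(object$edges)
  df <- tibble::tibble(r = mids, density = object$counts / sum(object$counts) /
                         widths)
  rr <- seq(0, max(object$edges), length.out = 300)
  comp <- purrr::map_dfr(seq_len(object$K), function(k) {
    s2 <- object$sigma2[k]
    tibble::tibble(r = rr, k = factor(k),
                   density = object$f[k] * rr / s2 * exp(-rr^2 / (2 * s2)))
  })
  tot <- comp |>
    dplyr::group_by(.data$r) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$density)) +
    ggplot2::geom_col(width = widths[1], fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(color = .data$k), linetype = "dashed") +
    ggplot2::geom_line(data = tot, color = "black") +
    ggplot2::labs(x = "displacement length r (µm)", y = "density",
                  color = "state") +
    ggplot2::theme_minimal()
}

#' Plot a chronoamperometry trace
#'
#' Raw trace with the 20-point moving average overlaid and light-on
#' periods shaded.
#'
#' @param object A `current_trace`.
#' @param window Smoothing window for the display overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.current_trace <- function(object, window = 20, ...) {
  sm <- smooth_for_display(object, window = min(window, nrow(object)))
  on <- object$light_on
  starts <- object$t_s[which(diff(as.integer(on)) == 1) + 1]
  ends <- object$t_s[which(diff(as.integer(on)) == -1)]
  if (on[1]) starts <- c(object$t_s[1], starts)
  if (on[length(on)]) ends <- c(ends, object$t_s[length(on)])
  shade <- tibble::tibble(xmin = starts, xmax = ends)
  ggplot2::ggplot(object, ggplot2::aes(.data$t_s, .data$current_nA)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "#fee391", alpha = 0.4) +
    ggplot2::geom_line(color = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = sm, color = "#b2182b") +
    ggplot2::labs(x = "time (s)", y = "current (nA)") +
    ggplot2::theme_minimal()
}
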