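# ggplot2 renderings of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ACF curve with its exponential fit
#'
#' @param object An `acf_fit` (with its source curve attached).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acf_fit <- function(object, ...) {
  cv <- if (!is.null(object$curve)) {
    tibble::tibble(lag_s = object$curve$lag_s, acf = object$curve$acf)
  } else {
    tibble::tibble(lag_s = object$mean_curve$lag_s,
                   acf = object$mean_curve$mean_acf)
  }
  cv <- cv[cv$lag_s > 0, ]
  p <- ggplot2::ggplot(cv, ggplot2::aes(.data$lag_s, .data$acf)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "lag (s)", y = "ACF")
  if (object$converged) {
    grid <- tibble::tibble(lag_s = seq(min(cv$lag_s), max(cv$lag_s),
                                       length.out = 200))
    grid$fit <- object$k + object$A * exp(-object$T * grid$lag_s)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(.data$lag_s, .data$fit),
                                color = "firebrick")
  }
  p
}

#' Plot a decay-constant histogram with its two-Gaussian decomposition
#'
#' @param object A `gaussian_pair` from [fit_two_gaussians()].
#' @param ... Unused.
#' @return A ggplot: bin counts, both components, and their sum.
#' @export
autoplot.gaussian_pair <- function(object, ...) {
  h <- object$histogram; f <- object$fitted
  ggplot2::ggplot(h, ggplot2::aes(.data$center, .data$count)) +
    ggplot2::geom_col(width = diff(h$center[1:2]), fill = "grey80",
                      color = "grey40") +
    ggplot2::geom_line(data = f, ggplot2::aes(y = .data$fit1),
                       color = "steelblue") +
    ggplot2::geom_line(data = f, ggplot2::aes(y = .data$fit2),
                       color = "seagreen") +
    ggplot2::geom_line(data = f, ggplot2::aes(y = .data$fit),
                       color = "purple", linewidth = 1) +
    ggplot2::labs(x = "decay constant T (1/s)", y = "pixels")
}

hist2d_long <- function(edges_chi, edges_theta, z, value_name) {
  centers <- function(e) (e[-1] + e[-length(e)]) / 2
  g <- expand.grid(chi = centers(edges_chi), theta = centers(edges_theta))
  g[[value_name]] <- as.vector(z)
  tibble::as_tibble(g)
}

#' Plot a theta-chi motion histogram
#'
#' @param object A `motion_hist2d`.
#' @param ... Unused.
#' @return A ggplot raster of the density.
#' @export
autoplot.motion_hist2d <- function(object, ...) {
  df <- hist2d_long(object$chi_edges, object$theta_edges, object$density,
                    "density")
  ggplot2::ggplot(df, ggplot2::aes(.data$chi, .data$theta,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = sprintf("S_chi (%s)", object$metadata$units %||% ""),
                  y = sprintf("S_theta (%s)", object$metadata$units %||% ""))
}

#' Plot a motion-map subtraction
#'
#' @param object A `motion_diff2d` from [subtract_hists()].
#' @param ... Unused.
#' @return A ggplot raster on a diverging scale centered at 0.
#' @export
autoplot.motion_diff2d <- function(object, ...) {
  df <- hist2d_long(object$chi_edges, object$theta_edges, object$diff, "diff")
  ggplot2::ggplot(df, ggplot2::aes(.data$chi, .data$theta,
                                   fill = .data$diff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "S_chi", y = "S_theta", fill = "density\ndifference")
}

#' Box plot of decay-constant samples per condition
#'
#' Draws the five-number summaries (min, quartiles, max) the blinking
#' analysis reports, one box per condition and group.
#'
#' @param samples Tibble with columns `value`, `condition` and optionally
#'   `group`.
#' @return A ggplot.
#' @export
plot_decay_box <- function(samples) {
  stopifnot(all(c("value", "condition") %in% names(samples)))
  has_group <- "group" %in% names(samples)
  p <- ggplot2::ggplot(samples,
                       ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::labs(x = NULL, y = "decay constant T (1/s)")
  if (has_group) p <- p + ggplot2::facet_wrap(~group)
  p
}
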