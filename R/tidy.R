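# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' Tidy a simulation trace
#'
#' @param x A `polar_trace`.
#' @param ... Unused.
#' @return The metrics tibble (one row per recorded time).
#' @export
tidy.polar_trace <- function(x, ...) x$metrics

#' One-row summary of a simulation trace
#'
#' @param x A `polar_trace`.
#' @param ... Unused.
#' @return A one-row tibble: horizon, final peak/total Rac-GTP, final
#'   tension, polarization flag and time, maximum Rac mass drift per
#'   second, and the negative-concentration clip count.
#' @export
glance.polar_trace <- function(x, ...) {
  m <- x$metrics
  n <- nrow(m)
  pol <- tryCatch(detect_polarization(x), error = function(e)
    list(polarized = NA, polarization_time = NA_real_))
  mass <- m$mass_u + m$mass_v
  tibble::tibble(
    t_end = m$t[n], max_u = m$max_u[n], total_u = m$total_u[n],
    total_f = m$total_f[n], mt = m$mt[n],
    polarity_angle_deg = m$polarity_angle_deg[n],
    polarized = pol$polarized, polarization_time = pol$polarization_time,
    max_mass_drift_per_s = if (n > 1) max(abs(diff(mass))) / diff(m$t)[1] else 0,
    clipped = x$clipped)
}

#' @export
tidy.polar_threshold_curve <- function(x, ...) x$points

#' @export
glance.polar_threshold_curve <- function(x, ...) {
  tibble::tibble(mt0 = x$mt0, n_points = nrow(x$points),
                 min_product = min(x$points$product),
                 max_product = max(x$points$product))
}

#' @export
tidy.polar_threshold_fit <- function(x, ...) x$probes

#' @export
glance.polar_threshold_fit <- function(x, ...) {
  tibble::tibble(mt0 = x$mt0, vary = x$vary, threshold = x$threshold,
                 tol_rel = x$tol_rel, n_probes = nrow(x$probes))
}

#' @export
tidy.polar_stability <- function(x, ...) x$events

#' @export
glance.polar_stability <- function(x, ...) {
  tibble::tibble(mt0 = x$mt0, seed = x$seed, n_s = x$n_s, n_p = x$n_p,
                 ratio = x$ratio)
}

#' Plot a simulation trace
#'
#' Time courses of the maximum membrane Rac-GTP, total F-actin and
#' membrane tension, with stimulus windows shaded.
#'
#' @param object A `polar_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polar_trace <- function(object, ...) {
  m <- object$metrics
  long <- dplyr::bind_rows(
    tibble::tibble(t = m$t, value = m$max_u, quantity = "max Rac-GTP (um^-2)"),
    tibble::tibble(t = m$t, value = m$total_f, quantity = "total F-actin"),
    tibble::tibble(t = m$t, value = m$mt, quantity = "membrane tension (pN/um)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  ev <- object$events
  if (!is.null(ev) && nrow(ev)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::tibble(xmin = ev$onset, xmax = ev$offset),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.12, fill = "#fdae61")
  }
  p
}

#' Plot a threshold curve
#'
#' Amplitude-duration threshold pairs for polarization; hyperbola-like,
#' shifting away from the origin as basal tension grows.
#'
#' @param object A `polar_threshold_curve`, or a list of them (e.g. at
#'   several tensions).
#' @param ... Further `polar_threshold_curve` objects to overlay.
#' @return A ggplot object.
#' @export
autoplot.polar_threshold_curve <- function(object, ...) {
  curves <- c(list(object), Filter(function(z) inherits(z, "polar_threshold_curve"),
                                   list(...)))
  df <- purrr::map_dfr(curves, function(cv) {
    dplyr::mutate(cv$points, mt0 = cv$mt0)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ks_amp, y = .data$ks_dur,
                                   color = factor(.data$mt0))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus amplitude threshold (1/s per um)",
                  y = "stimulus duration (s)", color = "mt0 (pN/um)") +
    ggplot2::theme_minimal()
}

#' Plot a stability run
#'
#' Polarity angle over time with the scheduled stimulus directions.
#'
#' @param object A `polar_stability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polar_stability <- function(object, ...) {
  m <- object$trace$metrics
  ev <- object$events
  ggplot2::ggplot(m, ggplot2::aes(x = .data$t, y = .data$polarity_angle_deg)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE, color = "#2166ac") +
    ggplot2::geom_segment(
      data = ev,
      ggplot2::aes(x = .data$onset, xend = .data$onset + .data$ks_dur,
                   y = .data$direction, yend = .data$direction),
      inherit.aes = FALSE, color = "#d6604d", linewidth = 1.2) +
    ggplot2::scale_y_continuous(breaks = c(0, 90, 180, 270, 360),
                                limits = c(0, 360)) +
    ggplot2::labs(x = "time (s)", y = "angle (deg)",
                  subtitle = sprintf("n_p/n_s = %d/%d", object$n_p, object$n_s)) +
    ggplot2::theme_minimal()
}

#' Plot a concentration field
#'
#' Raster view of a field (e.g. `u` or `f` of a state) with the membrane
#' contour overlaid.
#'
#' @param field Concentration matrix.
#' @param geometry A `polar_geometry`.
#' @param label Legend title.
#' @return A ggplot object.
#' @export
plot_field <- function(field, geometry, label = "concentration") {
  df <- tibble::tibble(x = as.vector(geometry$xc), y = as.vector(geometry$yc),
                       value = as.vector(field * (geometry$phi > 0.02)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = label) +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
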