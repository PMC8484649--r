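#' Plot a recoil fit over its velocity samples
#'
#' Outward orthogonal velocities against time since the cut, with the fitted
#' exponential decay (and, for bootstrapped fits, the v0 confidence interval
#' in the subtitle).
#'
#' @param object A `recoil_fit` or `recoil_boot`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recoil_fit <- function(object, ...) {
  s <- object$samples
  curve <- if (is.finite(object$tau)) {
    tg <- seq(0, max(s$t), length.out = 100)
    tibble(t = tg, v = object$v0 * exp(-tg / object$tau))
  } else tibble(t = numeric(), v = numeric())
  sub <- if (!any(is.na(object$ci_v0)))
    sprintf("v0 95%% CI [%.3g, %.3g] um/s", object$ci_v0[1], object$ci_v0[2])
  else NULL
  ggplot(s, aes(x = .data$t, y = .data$v_perp)) +
    geom_point(alpha = 0.4, colour = "grey30") +
    geom_line(data = curve, aes(y = .data$v), colour = "firebrick",
              linewidth = 1) +
    labs(x = "time since cut (s)", y = "outward velocity (um/s)",
         title = sprintf("recoil fit: v0 = %.3g um/s, tau = %.3g s",
                         object$v0, object$tau),
         subtitle = sub) +
    theme_minimal()
}

#' Quiver-style plot of a binned cortical flow field
#'
#' @param field Tibble from [flow_field()].
#' @param arrow_scale Multiplier from velocity to displayed arrow length.
#' @return A ggplot.
#' @export
plot_flow_field <- function(field, arrow_scale = 1) {
  filled <- filter(field, !.data$empty)
  ggplot(filled, aes(x = .data$x_bin, y = .data$t_bin)) +
    geom_segment(aes(xend = .data$x_bin + arrow_scale * .data$vx,
                     yend = .data$t_bin + arrow_scale * .data$vy),
                 arrow = grid::arrow(length = grid::unit(1.5, "mm"))) +
    labs(x = "position along AP axis (um)", y = "time (s)") +
    theme_minimal()
}

#' Heatmap of a fitted spatiotemporal intensity surface
#'
#' @param object An `st_surface` from [spatiotemporal_surface()].
#' @param ... Unused.
#' @return A ggplot with iso-intensity contour lines.
#' @export
autoplot.st_surface <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$position, y = .data$time)) +
    geom_raster(aes(fill = .data$value)) +
    geom_path(data = object$contours,
              aes(group = .data$contour_id), colour = "black",
              linewidth = 0.2) +
    scale_fill_viridis_c(name = "standardized\nintensity") +
    labs(x = "position from furrow (um)", y = "time from closure (s)") +
    theme_minimal()
}

#' Plot corrected cell means with standard errors
#'
#' @param object A `cell_means` from [cell_means_ar1()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_means <- function(object, ...) {
  ggplot(object$means, aes(x = .data$cell, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$estimate - .data$se,
                        ymax = .data$estimate + .data$se)) +
    labs(x = NULL, y = "relative cortical intensity (I+)") +
    theme_minimal()
}

#' Plot a quadratic intensity time trend with its SE band
#'
#' @param object A `quad_fit` from [quadratic_time_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quad_fit <- function(object, ...) {
  ggplot(object$band, aes(x = .data$t, y = .data$fit)) +
    geom_ribbon(aes(ymin = .data$fit - .data$se, ymax = .data$fit + .data$se),
                fill = "steelblue", alpha = 0.3) +
    geom_line(colour = "steelblue4") +
    labs(x = "time (min)", y = "corrected intensity (I+)",
         title = sprintf("cell %s", object$cell)) +
    theme_minimal()
}

#' Plot per-cell displacements along one axis
#'
#' @param displacements Tibble from [axis_displacements()] (optionally with a
#'   `group` column).
#' @param axis Axis label to show.
#' @return A ggplot.
#' @export
plot_displacements <- function(displacements, axis = "AP") {
  d <- filter(displacements, .data$axis == !!axis)
  mapping <- if ("group" %in% names(d))
    aes(x = .data$cell, y = .data$displacement, colour = .data$group)
  else aes(x = .data$cell, y = .data$displacement)
  ggplot(d, mapping) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    labs(x = NULL, y = sprintf("displacement along %s (um)", axis)) +
    theme_minimal()
}
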