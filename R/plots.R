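# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_path geom_hline labs theme_minimal after_stat geom_histogram
NULL

#' @export
ggplot2::autoplot

#' Plot the NPC structure cross-section
#'
#' @param structure an `npc_structure`.
#' @param positions optional coordinates override.
#' @return a ggplot: beads colored by group in the x-y plane.
#' @export
plot_structure <- function(structure, positions = NULL) {
  b <- structure$beads
  if (!is.null(positions)) {
    b$x <- positions[seq_len(nrow(b)), 1]
    b$y <- positions[seq_len(nrow(b)), 2]
  }
  ggplot(b, aes(x = .data$x, y = .data$y, colour = .data$group,
                size = .data$radius)) +
    geom_point(alpha = 0.7) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    labs(x = "x (nm)", y = "y (nm), cytoplasm up", colour = NULL) +
    theme_minimal()
}

#' @describeIn radial_probability plot the radial histogram with its
#'   Gaussian summary.
#' @param object a `radial_histogram`.
#' @param ... unused.
#' @export
autoplot.radial_histogram <- function(object, ...) {
  peak <- attr(object, "peak")
  ggplot(object, aes(x = .data$r_mid, y = .data$probability)) +
    geom_col(width = diff(object$r_hi - object$r_lo)[1] %||% 1,
             fill = "grey65") +
    ggplot2::geom_vline(xintercept = peak, linetype = 2, colour = "red") +
    labs(x = "channel radius (nm)", y = "probability",
         title = sprintf("radial occupancy: peak %.1f +- %.1f nm", peak,
                         attr(object, "sd"))) +
    theme_minimal()
}

#' @describeIn fit_invgauss plot the fitted density over the sample
#'   histogram.
#' @param object an `igfit`.
#' @param ... unused.
#' @export
autoplot.igfit <- function(object, ...) {
  ts <- seq(max(min(object$times) / 2, 1e-6), max(object$times) * 1.1,
            length.out = 200)
  dens <- tibble(t = ts, f = invgauss_pdf(ts, object$mu, object$lam))
  ggplot(tibble(t = object$times), aes(x = .data$t)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 24,
                   fill = "grey65", colour = "white") +
    geom_line(data = dens, aes(x = .data$t, y = .data$f), colour = "red",
              linetype = 2) +
    labs(x = "first-passage time (ms)", y = "density",
         title = sprintf("inverse Gaussian fit: mu = %.2f ms, lambda = %.2f ms",
                         object$mu, object$lam)) +
    theme_minimal()
}

#' @describeIn run_simulation plot the cargo's axial trajectory with the
#'   channel and basket planes.
#' @param object a `transport_record`.
#' @param ... unused.
#' @export
autoplot.transport_record <- function(object, ...) {
  pl <- object$planes
  ggplot(object$track, aes(x = .data$time_ms, y = .data$y)) +
    geom_path(colour = "steelblue") +
    geom_hline(yintercept = c(pl$channel_top, pl$channel_bottom, pl$exit),
               linetype = 3) +
    labs(x = "time (ms)", y = "axial position y (nm)",
         title = sprintf("transport trajectory (%s)",
                         object$events$outcome)) +
    theme_minimal()
}
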