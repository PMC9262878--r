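#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line geom_tile
#'   geom_point labs scale_fill_viridis_c coord_equal after_stat
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot a fitted detection function over the distance histogram
#'
#' Scaled histogram of truncated perpendicular distances with the fitted
#' average detection curve, the standard visual check of a distance-sampling
#' fit (and the basis of the hazard-rate near-zero exclusion decision).
#'
#' @param object a `det_fit`.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.det_fit <- function(object, bins = 12, ...) {
  w <- object$config$truncation
  pp <- det_unpack(object$par, object$config, ncol(object$Z))
  sigma <- scale_sigma(object$Z, pp$beta)
  xs <- seq(0, w, length.out = 200)
  gbar <- rowMeans(vapply(sigma, function(s)
    evaluate_detection(xs, s, object$config$key, pp$shape, pp$adj,
                       object$config$adj_orders, w),
    numeric(length(xs))))
  df <- tibble::tibble(x = xs, g = gbar)
  ggplot(tibble::tibble(d = object$data$perp_distance)) +
    geom_histogram(aes(x = .data$d,
                       y = after_stat(.data$density) * object$esw),
                   bins = bins, fill = "grey80", colour = "grey40") +
    geom_line(data = df, aes(x = .data$x, y = .data$g),
              colour = "#1f6fb4", linewidth = 0.9) +
    labs(x = "perpendicular distance (m)", y = "detection probability",
         title = sprintf("%s fit: esw = %.0f m, p0 = %.3f",
                         object$config$key, object$esw, object$p_bar))
}

#' Plot fitted versus observed segment counts for a DSM
#'
#' @param object a `dsm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dsm_fit <- function(object, ...) {
  ggplot(tibble::tibble(fitted = object$fitted, observed = object$y)) +
    geom_point(aes(x = .data$fitted, y = .data$observed), alpha = 0.5) +
    labs(x = "fitted groups per segment", y = "observed groups",
         title = sprintf("DSM %s: deviance explained %.1f%%",
                         object$label, object$deviance_explained))
}

#' Map predicted density and CV over the grid
#'
#' Tile map of either predicted group density per km^2 or the prediction CV
#' over the cells (masked or unmasked).
#'
#' @param cells output of [predict_cells()] or [mask_by_cv()].
#' @param what `"density"` or `"cv"`.
#' @return a ggplot.
#' @export
plot_prediction <- function(cells, what = c("density", "cv")) {
  what <- match.arg(what)
  df <- dplyr::mutate(cells, density = .data$mu / .data$area)
  v <- if (what == "density") "density" else "cv"
  ggplot(df) +
    geom_tile(aes(x = .data$x, y = .data$y, fill = .data[[v]])) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)", fill = what)
}
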