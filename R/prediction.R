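#' Build a regular prediction grid
#'
#' Cells of `cell_km` x `cell_km` covering the given extent; cell centres
#' carry the coordinates used for covariate attribution and prediction.
#'
#' @param xlim,ylim extent in projected km.
#' @param cell_km cell edge (default 2.5 km).
#' @return tibble with `x`, `y` (cell centres) and `area` (km^2).
#' @export
make_prediction_grid <- function(xlim, ylim, cell_km = 2.5) {
  xs <- seq(xlim[1] + cell_km / 2, xlim[2], by = cell_km)
  ys <- seq(ylim[1] + cell_km / 2, ylim[2], by = cell_km)
  g <- tidyr::expand_grid(x = xs, y = ys)
  g$area <- cell_km^2
  g
}

#' Predict group abundance per grid cell
#'
#' Expected number of groups per cell `mu = exp(eta + log(area))`, with the
#' link-scale standard error from the coefficient covariance (delta method:
#' `SE_mu = mu * SE_eta`) and the percent coefficient of variation
#' `CV = 100 * SE / mu`.  Cells with missing covariates are returned with NA
#' predictions (flagged, not dropped).
#'
#' @param fit a `dsm_fit`.
#' @param grid prediction grid with covariate columns and `area` (km^2).
#' @return the grid with `mu`, `se`, `cv` columns appended.
#' @export
predict_cells <- function(fit, grid) {
  stopifnot(inherits(fit, "dsm_fit"), "area" %in% names(grid))
  grid <- tibble::as_tibble(grid)
  vars <- unique(unlist(lapply(fit$spec$terms, `[[`, "vars")))
  ok <- complete.cases(grid[, vars, drop = FALSE])
  out <- dplyr::mutate(grid, mu = NA_real_, se = NA_real_, cv = NA_real_)
  if (any(ok)) {
    pr <- predict(fit, grid[ok, , drop = FALSE], area = grid$area[ok])
    out$mu[ok] <- pr$mu; out$se[ok] <- pr$se; out$cv[ok] <- pr$cv
  }
  out
}

#' Mask predicted cells by coefficient of variation
#'
#' Retains cells whose prediction CV is below the threshold (default 100%),
#' restricting the estimate to the area supported by the data and avoiding
#' extrapolation.  Cells without a prediction are dropped.
#'
#' @param cells output of [predict_cells()].
#' @param threshold CV threshold in percent (cells with `cv >= threshold`
#'   are discarded).
#' @return retained cells; total retained area (km^2) in attribute
#'   `retained_area`.
#' @export
mask_by_cv <- function(cells, threshold = 100) {
  keep <- !is.na(cells$cv) & cells$cv < threshold
  out <- cells[keep, , drop = FALSE]
  attr(out, "retained_area") <- sum(out$area)
  out
}

#' Abundance and density over retained cells
#'
#' Sums predicted groups over the (optionally sub-setted) retained cells,
#' converts groups to individuals with the expected group size, and attaches
#' a 95% confidence interval from the model's delta-method standard error
#' (full coefficient covariance: `SE^2 = v' Vb v` with
#' `v = X' mu`).  Densities are per km^2 of retained area.  Detection and
#' group-size uncertainty are not propagated (estimates condition on the
#' selected detection function, as in the standard model-based approach);
#' a log-normal interval is available via `ci_type`.
#'
#' @param cells masked cells from [mask_by_cv()].
#' @param fit the `dsm_fit` that produced the predictions.
#' @param group_size a [expected_group_size()] result, or a single number.
#' @param sub_region optional logical vector or function(x, y) selecting a
#'   sub-region of the retained cells.
#' @param ci_type `"normal"` (N +/- 1.96 SE) or `"lognormal"`.
#' @return one-row tibble of class `abundance_estimate`.
#' @export
summarize_abundance <- function(cells, fit, group_size, sub_region = NULL,
                                ci_type = c("normal", "lognormal")) {
  ci_type <- match.arg(ci_type)
  stopifnot(inherits(fit, "dsm_fit"))
  if (is.data.frame(group_size)) group_size <- group_size$expected_size[1]
  if (group_size < 1) stop("group size must be >= 1")
  if (!is.null(sub_region)) {
    sel <- if (is.function(sub_region)) sub_region(cells$x, cells$y) else sub_region
    cells <- cells[sel, , drop = FALSE]
  }
  cells <- cells[!is.na(cells$mu), , drop = FALSE]
  if (nrow(cells) == 0) stop("no retained cells in the requested region")
  area <- sum(cells$area)
  Xg <- dsm_model_matrix(fit, cells)
  mu <- cells$mu
  v <- as.vector(t(Xg) %*% mu)                 # d(sum mu)/d(beta)
  se_g <- sqrt(max(drop(t(v) %*% fit$Vb %*% v), 0))
  n_groups <- sum(mu)
  if (ci_type == "normal") {
    lo_g <- n_groups - 1.96 * se_g
    hi_g <- n_groups + 1.96 * se_g
  } else {
    cv2 <- (se_g / n_groups)^2
    cfac <- exp(1.96 * sqrt(log(1 + cv2)))
    lo_g <- n_groups / cfac; hi_g <- n_groups * cfac
  }
  lo_g <- max(lo_g, 0)
  out <- tibble::tibble(
    area = area,
    n_groups = n_groups, se_groups = se_g,
    n_individuals = n_groups * group_size,
    se_individuals = se_g * group_size,
    ci_lo = lo_g * group_size, ci_hi = hi_g * group_size,
    density_groups = n_groups / area,
    density_individuals = n_groups * group_size / area,
    group_size_used = group_size)
  class(out) <- c("abundance_estimate", class(out))
  out
}
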