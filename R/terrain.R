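#' Create a covariate raster
#'
#' Lightweight regular-grid raster: a numeric matrix with an origin and a
#' square cell size in projected kilometres.  `values[i, j]` is the cell
#' centred at `x = xmin + (j - 0.5) * cellsize`,
#' `y = ymin + (i - 0.5) * cellsize` (row index increases northward).
#' `NA` encodes no-data.
#'
#' @param values numeric matrix.
#' @param xmin,ymin lower-left corner of the grid (km).
#' @param cellsize cell edge length (km), > 0.
#' @param name covariate name (e.g. "depth").
#' @return an object of class `cov_raster`.
#' @export
cov_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                       name = "depth") {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, name = name),
            class = "cov_raster")
}

#' @export
print.cov_raster <- function(x, ...) {
  cat(sprintf("cov_raster '%s': %d x %d cells of %g km, origin (%g, %g)\n",
              x$name, nrow(x$values), ncol(x$values), x$cellsize,
              x$xmin, x$ymin))
  invisible(x)
}

#' Terrain metrics from a depth raster
#'
#' Derives the standard 3x3-neighbourhood terrain covariates used in
#' habitat models from a bathymetry grid:
#' * TPI (topographic position index): centre minus the mean of its 8
#'   neighbours;
#' * TRI (terrain ruggedness index): mean absolute difference between the
#'   centre and its 8 neighbours;
#' * slope and aspect by Horn's 8-cell weighted finite differences, slope in
#'   degrees, aspect in degrees clockwise from north (flat cells NA).
#'
#' Edge cells and cells whose neighbourhood contains no-data become NA.
#' Depth is taken as-is (negative below sea level).
#'
#' @param depth a `cov_raster` of at least 3x3 cells.
#' @return named list of `cov_raster`s: `TPI`, `TRI`, `slope`, `aspect`.
#' @export
terrain_metrics <- function(depth) {
  stopifnot(inherits(depth, "cov_raster"))
  z <- depth$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("raster must be at least 3 x 3")
  if (all(is.na(z))) stop("raster contains no data")
  cs <- depth$cellsize
  tpi <- tri <- slope <- aspect <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (any(is.na(nb))) next
      ctr <- nb[2, 2]
      ring <- nb[-5]
      tpi[i, j] <- ctr - mean(ring)
      tri[i, j] <- mean(abs(ctr - ring))
      # Horn 1981: rows of nb run south->north (row index northward),
      # columns west->east
      dzdx <- ((nb[1, 3] + 2 * nb[2, 3] + nb[3, 3]) -
                 (nb[1, 1] + 2 * nb[2, 1] + nb[3, 1])) / (8 * cs)
      dzdy <- ((nb[3, 1] + 2 * nb[3, 2] + nb[3, 3]) -
                 (nb[1, 1] + 2 * nb[1, 2] + nb[1, 3])) / (8 * cs)
      slope[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
      if (dzdx != 0 || dzdy != 0)
        aspect[i, j] <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
    }
  }
  mk <- function(v, nm) cov_raster(v, depth$xmin, depth$ymin, cs, nm)
  list(TPI = mk(tpi, "TPI"), TRI = mk(tri, "TRI"),
       slope = mk(slope, "slope"), aspect = mk(aspect, "aspect"))
}

#' Distance from points to the nearest polyline
#'
#' Planar Euclidean distance (km) from each point to the nearest location on
#' any polyline vertex-to-vertex edge, e.g. segment midpoints to the shelf
#' break or coastline.  Points and features must share the projection.
#'
#' @param points data frame with `x`, `y` (km).
#' @param feature data frame of polyline vertices with `x`, `y` and a
#'   `line_id` column separating polylines (a single polyline may omit it).
#' @return numeric vector of distances (km), one per point.
#' @export
distance_to_feature <- function(points, feature) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (is.null(feature) || nrow(feature) == 0) stop("empty feature")
  if (!"line_id" %in% names(feature)) feature$line_id <- 1L
  px <- points$x; py <- points$y
  best <- rep(Inf, length(px))
  for (lid in unique(feature$line_id)) {
    f <- feature[feature$line_id == lid, ]
    if (nrow(f) == 1) {
      best <- pmin(best, sqrt((px - f$x)^2 + (py - f$y)^2))
      next
    }
    for (k in seq_len(nrow(f) - 1)) {
      ax <- f$x[k]; ay <- f$y[k]; bx <- f$x[k + 1]; by <- f$y[k + 1]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) rep(0, length(px)) else
        pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      best <- pmin(best, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
    }
  }
  best
}

# bilinear interpolation of a cov_raster at points; NA outside or where any
# contributing cell is no-data (falls back to nearest cell value if the
# point sits in the outer half-cell margin)
raster_interp <- function(raster, x, y) {
  z <- raster$values; cs <- raster$cellsize
  # cell-centre coordinates
  gx <- (x - raster$xmin) / cs + 0.5
  gy <- (y - raster$ymin) / cs + 0.5
  nr <- nrow(z); nc <- ncol(z)
  out <- rep(NA_real_, length(x))
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  for (k in seq_along(x)) {
    jj <- j0[k]; ii <- i0[k]
    if (is.na(jj) || is.na(ii)) next
    if (jj >= 1 && jj + 1 <= nc && ii >= 1 && ii + 1 <= nr) {
      q <- z[ii:(ii + 1), jj:(jj + 1)]
      if (any(is.na(q))) {
        # nearest-cell fallback
        jn <- pmin(nc, pmax(1, round(gx[k]))); inn <- pmin(nr, pmax(1, round(gy[k])))
        out[k] <- z[inn, jn]
      } else {
        out[k] <- (1 - fy[k]) * ((1 - fx[k]) * q[1, 1] + fx[k] * q[1, 2]) +
          fy[k] * ((1 - fx[k]) * q[2, 1] + fx[k] * q[2, 2])
      }
    } else if (gx[k] >= 0.5 && gx[k] <= nc + 0.5 &&
               gy[k] >= 0.5 && gy[k] <= nr + 0.5) {
      jn <- pmin(nc, pmax(1, round(gx[k]))); inn <- pmin(nr, pmax(1, round(gy[k])))
      out[k] <- z[inn, jn]
    }
  }
  out
}

#' Average a covariate along each segment
#'
#' Samples the covariate at the segment's stored along-track points (0.5 km
#' spacing by default) and averages.  Rasters are sampled with bilinear
#' interpolation; polyline features yield the distance to the feature at
#' each sample point.  No-data samples are excluded; a segment whose samples
#' are all no-data gets `NA` (flagging it for model-specific exclusion).
#'
#' @param segments output of [split_effort()] (carries a `path` list-column).
#' @param source a `cov_raster` or a polyline feature data frame
#'   (see [distance_to_feature()]).
#' @param name column name for the extracted covariate; defaults to the
#'   raster name or `"dist"`.
#' @return `segments` with the new covariate column appended.
#' @export
extract_along_segments <- function(segments, source, name = NULL) {
  stopifnot("path" %in% names(segments))
  is_r <- inherits(source, "cov_raster")
  name <- name %||% if (is_r) source$name else "dist"
  vals <- vapply(segments$path, function(p) {
    v <- if (is_r) raster_interp(source, p$x, p$y)
    else distance_to_feature(p, source)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  segments[[name]] <- vals
  segments
}
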