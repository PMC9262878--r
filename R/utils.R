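#' @importFrom stats optimHess nlminb lm coef integrate pnorm pt qnorm rpois
#'   runif rnorm var sd model.matrix as.formula terms predict quantile
#'   complete.cases setNames approx optimize
#' @importFrom utils head tail
#' @importFrom rlang .data
NULL

# Gauss-Legendre nodes/weights on [a, b] via Golub-Welsch; deterministic and
# accurate to machine precision for the smooth integrands used here.
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

#' Project geographic coordinates to local equal-area kilometres
#'
#' Spherical Lambert azimuthal equal-area projection centred on a reference
#' point (by default the centroid of the supplied coordinates).  Returns
#' planar x/y in kilometres, adequate for regional survey domains of a few
#' hundred kilometres.
#'
#' @param data data frame with `lon` and `lat` columns (decimal degrees).
#' @param lon0,lat0 projection centre in degrees; defaults to the data centroid.
#' @return the input tibble with `x` and `y` columns (km) appended.
#' @export
project_laea <- function(data, lon0 = NULL, lat0 = NULL) {
  stopifnot(all(c("lon", "lat") %in% names(data)))
  R <- 6371.0088
  if (is.null(lon0)) lon0 <- mean(range(data$lon))
  if (is.null(lat0)) lat0 <- mean(range(data$lat))
  to_rad <- pi / 180
  lam <- data$lon * to_rad; phi <- data$lat * to_rad
  lam0 <- lon0 * to_rad; phi0 <- lat0 * to_rad
  kk <- sqrt(2 / (1 + sin(phi0) * sin(phi) +
                    cos(phi0) * cos(phi) * cos(lam - lam0)))
  out <- dplyr::mutate(tibble::as_tibble(data),
    x = R * kk * cos(phi) * sin(lam - lam0),
    y = R * kk * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
  attr(out, "proj_centre") <- c(lon0 = lon0, lat0 = lat0)
  out
}

# numeric gradient (central differences) of scalar-valued f at x
num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(j) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
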