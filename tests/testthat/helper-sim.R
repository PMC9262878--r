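# shared fixtures, all generated in code

# half-normal perpendicular distances truncated at w
sim_hn_distances <- function(n, sigma = 600, w = 1750) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- abs(rnorm(2 * n, 0, sigma))
    out <- c(out, x[x <= w])
  }
  out[seq_len(n)]
}

sim_hn_sightings <- function(n, sigma = 600, w = 1750, lambda_size = 0.3) {
  tibble::tibble(perp_distance = sim_hn_distances(n, sigma, w),
                 group_size = 1L + rpois(n, lambda_size))
}

# closed-form half-normal effective strip width
esw_hn_closed <- function(sigma, w) {
  sigma * sqrt(pi / 2) * (2 * pnorm(w / sigma) - 1)
}

# straight-line effort track fixture
straight_effort <- function(len_km, transect_id = "T1", y = 0, step = 1,
                            on = TRUE) {
  xs <- seq(0, len_km, by = step)
  if (len_km - xs[length(xs)] > 1e-9) xs <- c(xs, len_km)
  tibble::tibble(transect_id = transect_id, timestamp = xs * 60,
                 x = xs, y = y, on_effort = on)
}

# brute-force 3x3 terrain oracle (independent of the package implementation)
terrain_oracle <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  tpi <- tri <- slope <- aspect <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (any(is.na(nb))) next
    ring <- c(nb[1, 1], nb[1, 2], nb[1, 3], nb[2, 1], nb[2, 3],
              nb[3, 1], nb[3, 2], nb[3, 3])
    tpi[i, j] <- nb[2, 2] - mean(ring)
    tri[i, j] <- mean(abs(nb[2, 2] - ring))
    gx <- ((nb[1, 3] + 2 * nb[2, 3] + nb[3, 3]) -
             (nb[1, 1] + 2 * nb[2, 1] + nb[3, 1])) / (8 * cs)
    gy <- ((nb[3, 1] + 2 * nb[3, 2] + nb[3, 3]) -
             (nb[1, 1] + 2 * nb[1, 2] + nb[1, 3])) / (8 * cs)
    slope[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    if (gx != 0 || gy != 0) aspect[i, j] <- (atan2(-gx, -gy) * 180 / pi) %% 360
  }
  list(TPI = tpi, TRI = tri, slope = slope, aspect = aspect)
}

# truth inside a set of retained 2.5-km cells, for end-to-end comparisons
truth_in_cells <- function(groups, cells, cell_km = 2.5) {
  keyr <- paste(round((cells$x - cell_km / 2) / cell_km),
                round((cells$y - cell_km / 2) / cell_km))
  keyg <- paste(floor(groups$x / cell_km), floor(groups$y / cell_km))
  sum(groups$size[keyg %in% keyr])
}
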