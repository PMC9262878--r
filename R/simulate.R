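#' Synthetic aerial-survey configuration
#'
#' Defines the generating conditions for a simulated line-transect survey:
#' a covariate-structured log-linear density surface (optionally with
#' Gaussian-random-field noise and a superimposed cluster process), a
#' zero-truncated group-size law, ad-hoc transect placement, one-sided
#' half-normal (or hazard-rate) detection with covariate-scaled sigma, and
#' right truncation.  Defaults emulate an Antarctic aerial cetacean survey:
#' 600 ft flight altitude, 1750 m truncation, half-normal sigma of 600 m,
#' sparse groups averaging ~1.3 animals, and roughly a thousand kilometres
#' of effort over a 150 x 100 km domain.
#'
#' @param extent domain size `c(width, height)` in km.
#' @param mean_density mean group density over the domain (groups / km^2).
#' @param surface_beta log-linear surface coefficients on scaled coordinates
#'   `c(bx, by)`; `c(0, 0)` gives a homogeneous surface.
#' @param grf optional Gaussian-random-field noise: `list(range, sd)` in km
#'   / log units.
#' @param size_law group-size law: `list(law = "ztpois", lambda = ...)` or
#'   `list(law = "geometric", prob = ...)` (shifted to support >= 1).
#' @param aggregation optional cluster process:
#'   `list(parent_rate, mean_size, radius)` (parents / km^2, animals,
#'   km); superimposes large aggregations on the group process.
#' @param n_transects,transect_km,fix_km transect count, nominal length and
#'   GPS fix spacing (km).
#' @param detection list: `key`, `sigma` (m), `shape` (hazard-rate b),
#'   `beta_seastate` (effect on log sigma per Beaufort step), `truncation`
#'   (m), `altitude` (m).
#' @param both_sides simulate detection on both sides of the track line
#'   (default FALSE: one-sided coverage, as flown).
#' @param seed integer seed fixing every draw.
#' @return a `survey_config` list.
#' @export
survey_config <- function(extent = c(150, 100),
                          mean_density = 0.17,
                          surface_beta = c(1, -0.6),
                          grf = NULL,
                          size_law = list(law = "ztpois", lambda = 0.55),
                          aggregation = NULL,
                          n_transects = 12, transect_km = 100, fix_km = 1,
                          detection = list(key = "half-normal", sigma = 600,
                                           shape = NULL, beta_seastate = 0,
                                           truncation = 1750,
                                           altitude = 182.88),
                          both_sides = FALSE,
                          seed = 1L) {
  det_default <- list(key = "half-normal", sigma = 600, shape = NULL,
                      beta_seastate = 0, truncation = 1750, altitude = 182.88)
  detection <- utils::modifyList(det_default, detection)
  stopifnot(mean_density >= 0, n_transects >= 0, transect_km > 0,
            detection$sigma > 0, detection$truncation > 0)
  structure(list(extent = extent, mean_density = mean_density,
                 surface_beta = surface_beta, grf = grf, size_law = size_law,
                 aggregation = aggregation, n_transects = n_transects,
                 transect_km = transect_km, fix_km = fix_km,
                 detection = detection, both_sides = both_sides,
                 seed = as.integer(seed)),
            class = "survey_config")
}

# intensity surface on a 1-km grid, calibrated so its integral equals
# mean_density * domain area
sim_surface <- function(config) {
  ex <- config$extent
  xs <- seq(0.5, ex[1] - 0.5, by = 1)
  ys <- seq(0.5, ex[2] - 0.5, by = 1)
  lg <- outer(ys, xs, function(y, x)
    config$surface_beta[1] * x / ex[1] + config$surface_beta[2] * y / ex[2])
  if (!is.null(config$grf)) {
    # smoothed white noise: cheap stationary field with ~`range` km scale
    rg <- max(1, round(config$grf$range))
    coarse <- matrix(rnorm(ceiling(length(ys) / rg + 2) *
                             ceiling(length(xs) / rg + 2)),
                     ceiling(length(ys) / rg + 2))
    fld <- cov_raster(coarse, xmin = -rg, ymin = -rg, cellsize = rg, "grf")
    pts <- expand.grid(x = xs, y = ys)
    noise <- matrix(raster_interp(fld, pts$x, pts$y),
                    nrow = length(ys), byrow = TRUE)
    noise[is.na(noise)] <- 0
    lg <- lg + config$grf$sd * (noise - mean(noise)) / max(sd(noise), 1e-9)
  }
  if (any(!is.finite(lg))) stop("non-finite intensity surface")
  a <- log(config$mean_density * prod(ex)) - log(sum(exp(lg)))
  cov_raster(exp(lg + a), xmin = 0, ymin = 0, cellsize = 1, "intensity")
}

rztpois <- function(n, lambda) {
  u <- runif(n)
  stats::qpois(exp(-lambda) + u * (1 - exp(-lambda)), lambda)
}

draw_sizes <- function(n, size_law) {
  switch(size_law$law,
         ztpois = rztpois(n, size_law$lambda),
         geometric = 1L + stats::rgeom(n, size_law$prob),
         stop("unknown size law: ", size_law$law))
}

#' Simulate the whale-group population
#'
#' Draws group locations from an inhomogeneous Poisson process over the
#' configured intensity surface (expected count = surface integral), i.i.d.
#' group sizes from the zero-truncated size law, and optionally superimposes
#' a cluster process of large feeding aggregations.
#'
#' @param config a [survey_config()].
#' @return tibble of groups (`x`, `y`, `size`) with the intensity surface in
#'   attribute `surface`.
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  surf <- sim_surface(config)
  lam <- surf$values            # per-1km cell expected counts
  total <- sum(lam)
  N <- rpois(1, total)
  groups <- if (N > 0) {
    cell <- sample.int(length(lam), N, replace = TRUE, prob = as.vector(lam))
    ij <- arrayInd(cell, dim(lam))
    tibble::tibble(
      x = surf$xmin + (ij[, 2] - 1) + runif(N),
      y = surf$ymin + (ij[, 1] - 1) + runif(N),
      size = draw_sizes(N, config$size_law))
  } else tibble::tibble(x = numeric(), y = numeric(), size = integer())
  if (!is.null(config$aggregation)) {
    ag <- config$aggregation
    np <- rpois(1, ag$parent_rate * prod(config$extent))
    if (np > 0) {
      px <- runif(np, 0, config$extent[1]); py <- runif(np, 0, config$extent[2])
      sz <- pmax(15L, rpois(np, ag$mean_size))
      th <- runif(np, 0, 2 * pi); rr <- ag$radius * sqrt(runif(np))
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        x = px + rr * cos(th), y = py + rr * sin(th), size = sz))
    }
  }
  attr(groups, "surface") <- surf
  groups
}

# clip segment (a, b) to rectangle [0,w]x[0,h]; returns NULL or endpoints
clip_rect <- function(ax, ay, bx, by, w, h) {
  dx <- bx - ax; dy <- by - ay
  t0 <- 0; t1 <- 1
  for (pq in list(c(-dx, ax), c(dx, w - ax), c(-dy, ay), c(dy, h - ay))) {
    p <- pq[1]; q <- pq[2]
    if (p == 0) { if (q < 0) return(NULL) } else {
      r <- q / p
      if (p < 0) { if (r > t1) return(NULL); t0 <- max(t0, r) }
      else { if (r < t0) return(NULL); t1 <- min(t1, r) }
    }
  }
  c(ax + t0 * dx, ay + t0 * dy, ax + t1 * dx, ay + t1 * dy)
}

#' Simulate the aerial survey of a simulated population
#'
#' Places transects at random anchors with random orientations (clipped to
#' the domain), emits effort tracks at fixed GPS spacing, and detects each
#' group on the searched side of the track line within the truncation
#' distance with probability `g(perpendicular distance | sigma)`, where
#' `log(sigma)` may shift with the transect's Beaufort sea state.  Detected
#' groups become sightings with exact perpendicular distances and the
#' equivalent inclinometer declination angle at the flight altitude.
#'
#' @param groups output of [simulate_population()].
#' @param config the same [survey_config()].
#' @return list of class `sim_survey`: `truth` (groups, total groups /
#'   individuals, surface), `effort` (GPS fixes) and `sightings`.
#' @export
simulate_survey <- function(groups, config) {
  if (config$n_transects < 1) stop("need at least one transect")
  set.seed(config$seed + 1L)
  ex <- config$extent
  det <- config$detection
  w_km <- det$truncation / 1000
  eff <- list(); sig <- list()
  lvl <- c("good", "moderate", "poor")
  for (ti in seq_len(config$n_transects)) {
    anc <- c(runif(1, 0, ex[1]), runif(1, 0, ex[2]))
    th <- runif(1, 0, 2 * pi)
    half <- config$transect_km / 2
    cl <- clip_rect(anc[1] - half * cos(th), anc[2] - half * sin(th),
                    anc[1] + half * cos(th), anc[2] + half * sin(th),
                    ex[1], ex[2])
    if (is.null(cl)) next
    a <- cl[1:2]; b <- cl[3:4]
    L <- sqrt(sum((b - a)^2))
    if (L < config$fix_km) next
    u <- (b - a) / L
    seastate <- sample(0:4, 1)
    subjective <- sample(lvl, 1, prob = c(0.5, 0.35, 0.15))
    tid <- sprintf("T%02d", ti)
    along <- seq(0, L, by = config$fix_km)
    if (L - along[length(along)] > 1e-9) along <- c(along, L)
    t0 <- ti * 1e5
    eff[[length(eff) + 1]] <- tibble::tibble(
      transect_id = tid, timestamp = t0 + along * 60,
      x = a[1] + along * u[1], y = a[2] + along * u[2],
      on_effort = TRUE, seastate = seastate, subjective = subjective)
    if (nrow(groups) == 0) next
    relx <- groups$x - a[1]; rely <- groups$y - a[2]
    s_along <- relx * u[1] + rely * u[2]
    s_perp <- u[1] * rely - u[2] * relx          # >0 = left of travel
    side_ok <- if (config$both_sides) abs(s_perp) > 0 else s_perp > 0
    cand <- which(side_ok & s_along >= 0 & s_along <= L &
                    abs(s_perp) <= w_km)
    if (!length(cand)) next
    xm <- abs(s_perp[cand]) * 1000               # perp distance in m
    sigma_t <- det$sigma * exp(det$beta_seastate * seastate)
    g <- evaluate_detection(xm, sigma_t, det$key, det$shape,
                            truncation = det$truncation)
    seen <- cand[runif(length(cand)) < g]
    if (!length(seen)) next
    xm_seen <- abs(s_perp[seen]) * 1000
    sig[[length(sig) + 1]] <- tibble::tibble(
      transect_id = tid,
      timestamp = t0 + s_along[seen] * 60,
      perp_distance = xm_seen,
      declination_deg = atan2(det$altitude, xm_seen) * 180 / pi,
      group_size = groups$size[seen],
      seastate = seastate, subjective = subjective,
      x = groups$x[seen], y = groups$y[seen])
  }
  effort <- if (length(eff)) dplyr::bind_rows(eff) else
    stop("no transect intersected the domain")
  sightings <- if (length(sig)) dplyr::bind_rows(sig) else
    tibble::tibble(transect_id = character(), timestamp = numeric(),
                   perp_distance = numeric(), declination_deg = numeric(),
                   group_size = integer(), seastate = integer(),
                   subjective = character(), x = numeric(), y = numeric())
  structure(list(
    truth = list(groups = groups, n_groups = nrow(groups),
                 n_individuals = sum(groups$size),
                 surface = attr(groups, "surface")),
    effort = effort, sightings = sightings, config = config),
    class = "sim_survey")
}

#' Analytic expected number of detections
#'
#' For a homogeneous surface, the expected number of detected groups is
#' `D * esw * L` (one-sided coverage): the encounter-rate oracle used to
#' validate the simulator.
#'
#' @param config a [survey_config()] with a constant surface
#'   (`surface_beta = c(0, 0)`, no GRF noise).
#' @param esw_km analytic effective strip width (km).
#' @param total_effort_km total transect length; defaults to the nominal
#'   `n_transects * transect_km`.
#' @return expected detections (doubled for both-sides configs).
#' @export
expected_encounters <- function(config, esw_km, total_effort_km = NULL) {
  if (any(config$surface_beta != 0) || !is.null(config$grf))
    stop("analytic encounter rate is defined only for a homogeneous surface")
  L <- total_effort_km %||% (config$n_transects * config$transect_km)
  config$mean_density * esw_km * L * (if (config$both_sides) 2 else 1)
}

#' @export
print.sim_survey <- function(x, ...) {
  cat(sprintf("Simulated survey: %d true groups (%d individuals), %d sightings on %.0f km effort\n",
              x$truth$n_groups, x$truth$n_individuals, nrow(x$sightings),
              sum(vapply(split(x$effort, x$effort$transect_id), function(tr)
                sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), numeric(1)))))
  invisible(x)
}
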