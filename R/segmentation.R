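#' Convert declination angle to perpendicular distance
#'
#' Aerial observers record the declination angle from the horizontal down to
#' a sighting with an inclinometer; at flight altitude `h` the horizontal
#' distance to the sighting is `h / tan(declination)`.
#'
#' @param declination angle(s) in degrees below horizontal, in `(0, 90]`.
#' @param altitude flight altitude in metres (default 182.88 m = 600 ft).
#' @return horizontal distance(s) in metres.
#' @export
declination_to_distance <- function(declination, altitude = 182.88) {
  if (any(!is.finite(declination)) || any(declination <= 0) ||
      any(declination > 90))
    stop("declination must lie in (0, 90] degrees (horizon sightings have undefined distance)")
  if (any(altitude <= 0)) stop("altitude must be > 0")
  altitude / tan(declination * pi / 180)
}

# linear interpolation of (x, y[, t]) along cumulative length
interp_along <- function(cum, xs, ys, l, ts = NULL) {
  x <- approx(cum, xs, xout = l, rule = 2)$y
  y <- approx(cum, ys, xout = l, rule = 2)$y
  out <- list(x = x, y = y)
  if (!is.null(ts)) out$t <- approx(cum, as.numeric(ts), xout = l, rule = 2)$y
  out
}

#' Cut effort tracks into analysis segments
#'
#' Each contiguous on-effort run of GPS fixes is cut into consecutive
#' segments of `target_km`, with a shorter terminal remainder; remainders
#' below `min_km` are discarded.  Lengths are summed projected chord
#' lengths; the midpoint is the point at half the segment's along-track
#' length.  Segments never span an off-effort gap.
#'
#' @param effort data frame of GPS fixes with columns `transect_id`,
#'   `timestamp` (numeric or POSIXct), `x`, `y` (projected km) and logical
#'   `on_effort`.
#' @param target_km nominal segment length (default 5 km).
#' @param min_km minimum retained segment length (default 1 km).
#' @param sample_step_km spacing of the stored along-track sample points
#'   used later for covariate extraction (default 0.5 km).
#' @return a tibble with one row per segment: ids, along-run start/end (km),
#'   `length_km`, midpoint `x`, `y`, time span, and a `path` list-column of
#'   sample points.  The total discarded length is stored in the
#'   `discarded_km` attribute.
#' @export
split_effort <- function(effort, target_km = 5, min_km = 1,
                         sample_step_km = 0.5) {
  stopifnot(all(c("transect_id", "x", "y", "on_effort") %in% names(effort)))
  effort <- tibble::as_tibble(effort)
  if (!"timestamp" %in% names(effort)) effort$timestamp <- seq_len(nrow(effort))
  segs <- list(); discarded <- 0; seg_i <- 0L
  for (tid in unique(effort$transect_id)) {
    tr <- effort[effort$transect_id == tid, ]
    tr <- tr[order(as.numeric(tr$timestamp)), ]
    if (any(duplicated(as.numeric(tr$timestamp))))
      stop("timestamps must be strictly increasing within transect ", tid)
    run_id <- cumsum(c(TRUE, diff(tr$on_effort) != 0))
    for (rid in unique(run_id[tr$on_effort])) {
      run <- tr[run_id == rid & tr$on_effort, ]
      if (nrow(run) < 2) next
      d <- sqrt(diff(run$x)^2 + diff(run$y)^2)
      cum <- c(0, cumsum(d))
      L <- cum[length(cum)]
      if (L < min_km) { discarded <- discarded + L; next }
      brks <- seq(0, L, by = target_km)
      if (max(brks) < L) brks <- c(brks, L)
      for (j in seq_len(length(brks) - 1)) {
        a <- brks[j]; b <- brks[j + 1]; len <- b - a
        if (len < min_km) { discarded <- discarded + len; next }
        seg_i <- seg_i + 1L
        mid <- interp_along(cum, run$x, run$y, a + len / 2)
        tsp <- interp_along(cum, run$x, run$y, c(a, b),
                            ts = run$timestamp)$t
        ls <- unique(c(seq(a, b, by = sample_step_km), b))
        pts <- interp_along(cum, run$x, run$y, ls)
        segs[[seg_i]] <- tibble::tibble(
          segment_id = seg_i, transect_id = tid, run = paste(tid, rid, sep = ":"),
          start_km = a, end_km = b, length_km = len,
          x = mid$x, y = mid$y, t_start = tsp[1], t_end = tsp[2],
          path = list(tibble::tibble(x = pts$x, y = pts$y, along_km = ls - a)))
      }
    }
  }
  out <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble::tibble(segment_id = integer(), transect_id = character(),
                   run = character(), start_km = numeric(), end_km = numeric(),
                   length_km = numeric(), x = numeric(), y = numeric(),
                   t_start = numeric(), t_end = numeric(), path = list())
  attr(out, "discarded_km") <- discarded
  out
}

#' Assign sightings to segments
#'
#' Each on-effort sighting within the truncation distance increments exactly
#' one segment's group count and adds its group size to the individual
#' count.  Assignment is by the along-track time interval of the sighting's
#' recording time when the segments carry time spans; sightings without a
#' usable timestamp fall back to the nearest segment midpoint on the same
#' transect.  Sightings beyond the truncation distance or outside all effort
#' spans are excluded (the latter with a warning).
#'
#' @param segments output of [split_effort()].
#' @param sightings data frame with `transect_id`, `perp_distance`, and
#'   `group_size`; `timestamp` and/or `x`, `y` used for assignment.
#' @param truncation right truncation distance in metres (default 1750).
#' @return `segments` with `n_groups` and `n_individuals` columns.
#' @export
assign_sightings <- function(segments, sightings, truncation = 1750) {
  segments <- dplyr::mutate(segments, n_groups = 0L, n_individuals = 0L)
  if (is.null(sightings) || nrow(sightings) == 0) return(segments)
  sightings <- tibble::as_tibble(sightings)
  keep <- sightings$perp_distance <= truncation
  sightings <- sightings[keep, , drop = FALSE]
  n_out <- 0L
  for (i in seq_len(nrow(sightings))) {
    s <- sightings[i, ]
    idx <- NA_integer_
    if (!is.null(s$timestamp) && !is.na(s$timestamp)) {
      ts <- as.numeric(s$timestamp)
      hit <- which(segments$transect_id == s$transect_id &
                     segments$t_start <= ts & ts <= segments$t_end)
      if (length(hit)) idx <- hit[1]
    }
    if (is.na(idx) && !is.null(s$x) && !is.na(s$x)) {
      cand <- which(segments$transect_id == s$transect_id)
      if (!length(cand)) cand <- seq_len(nrow(segments))
      dd <- (segments$x[cand] - s$x)^2 + (segments$y[cand] - s$y)^2
      idx <- cand[which.min(dd)]
    }
    if (is.na(idx)) { n_out <- n_out + 1L; next }
    segments$n_groups[idx] <- segments$n_groups[idx] + 1L
    segments$n_individuals[idx] <- segments$n_individuals[idx] +
      as.integer(s$group_size)
  }
  if (n_out > 0)
    warning(n_out, " sighting(s) outside all effort spans were excluded")
  segments
}

#' Effective covered area per segment
#'
#' `A_seg = esw_km * L_seg`: the area effectively searched along a segment,
#' given the effective strip width from the detection function.  Coverage is
#' one-sided (observers searched one side of the track line), so no factor
#' of two appears.
#'
#' @param segments segments tibble with `length_km`.
#' @param esw_km effective strip width in kilometres (> 0).
#' @return `segments` with an `A_seg` column (km^2).
#' @export
effective_area <- function(segments, esw_km) {
  if (!is.numeric(esw_km) || esw_km <= 0) stop("esw must be > 0")
  dplyr::mutate(segments, A_seg = esw_km * .data$length_km)
}
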