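# ISO-8601 timestamps to numeric seconds, NA where unparseable
parse_time_utc <- function(x) {
  x <- sub(" ", "T", as.character(x))
  as.numeric(suppressWarnings(readr::parse_datetime(x)))
}

#' Read a sightings CSV
#'
#' Expected columns: `transect_id`, `datetime` (ISO-8601), `group_size`,
#' and either `perp_distance_m` (or `perp_distance`) or `declination_deg`;
#' optional `seastate`, `subjective`, `lat`/`lon` or `x`/`y`.  Declination
#' angles are converted to perpendicular distances at the given flight
#' altitude when no distance column is present (a recorded distance wins
#' when both exist).  Rows failing validation are never silently dropped:
#' they are collected, with reasons, into the `rejects` attribute.
#'
#' @param path CSV file path.
#' @param altitude flight altitude (m) for declination conversion.
#' @return tibble of validated sightings; rejected rows in
#'   `attr(, "rejects")`.
#' @export
read_sightings <- function(path, altitude = 182.88) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("transect_id", "group_size")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (!any(c("perp_distance", "perp_distance_m", "declination_deg") %in% names(raw)))
    stop("missing mandatory column: perp_distance_m or declination_deg")
  raw <- tibble::as_tibble(raw)
  if ("perp_distance_m" %in% names(raw) && !"perp_distance" %in% names(raw))
    raw$perp_distance <- raw$perp_distance_m
  if ("datetime" %in% names(raw))
    raw$timestamp <- parse_time_utc(raw$datetime)
  reason <- rep(NA_character_, nrow(raw))
  bad_size <- !is.finite(raw$group_size) | raw$group_size < 1 |
    raw$group_size != round(raw$group_size)
  reason[bad_size] <- "group_size must be an integer >= 1"
  if (!"perp_distance" %in% names(raw)) raw$perp_distance <- NA_real_
  no_dist <- !is.finite(raw$perp_distance)
  if ("declination_deg" %in% names(raw)) {
    conv <- no_dist & is.finite(raw$declination_deg) &
      raw$declination_deg > 0 & raw$declination_deg <= 90
    raw$perp_distance[conv] <- declination_to_distance(
      raw$declination_deg[conv], altitude)
    bad_dec <- no_dist & !conv
    reason[bad_dec & is.na(reason)] <- "no distance and invalid declination"
  } else {
    reason[no_dist & is.na(reason)] <- "missing perpendicular distance"
  }
  bad_d <- is.finite(raw$perp_distance) & raw$perp_distance < 0
  reason[bad_d & is.na(reason)] <- "negative perpendicular distance"
  if ("datetime" %in% names(raw)) {
    bad_t <- is.na(raw$timestamp)
    reason[bad_t & is.na(reason)] <- "unparseable timestamp"
  }
  ok <- is.na(reason)
  out <- raw[ok, , drop = FALSE]
  attr(out, "rejects") <- dplyr::mutate(raw[!ok, , drop = FALSE],
                                        reject_reason = reason[!ok])
  out
}

#' Read effort fixes from CSV or GPX 1.1
#'
#' CSV columns: `transect_id`, `datetime`, `on_effort`, and `x`/`y`
#' (projected km) or `lat`/`lon` (projected on read via [project_laea()]).
#' GPX tracks become one transect per `<trk>`, all fixes on effort.
#'
#' @param path file path (`.gpx` triggers the GPX parser).
#' @return tibble of fixes: `transect_id`, `timestamp`, `x`, `y`,
#'   `on_effort`.
#' @export
read_effort <- function(path) {
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) return(read_gpx(path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("transect_id", "datetime", "on_effort")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  raw$timestamp <- parse_time_utc(raw$datetime)
  if (any(is.na(raw$timestamp))) {
    warning(sum(is.na(raw$timestamp)), " effort fix(es) with unparseable ",
            "timestamps dropped")
    raw <- raw[!is.na(raw$timestamp), , drop = FALSE]
  }
  if (!all(c("x", "y") %in% names(raw))) {
    if (!all(c("lat", "lon") %in% names(raw)))
      stop("need x/y or lat/lon columns")
    raw <- project_laea(raw)
  }
  raw$on_effort <- as.logical(raw$on_effort)
  tibble::as_tibble(raw)
}

read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  out <- purrr::imap_dfr(trks, function(trk, i) {
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(nm) || nm == "") nm <- sprintf("trk%02d", i)
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    tibble::tibble(
      transect_id = nm,
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      datetime = xml2::xml_text(xml2::xml_find_first(pts, "./time")))
  })
  out$timestamp <- parse_time_utc(out$datetime)
  out <- project_laea(out)
  out$on_effort <- TRUE
  out
}

#' Write the detection-model comparison table
#'
#' CSV in the conventional survey-report column order: Key, Adj, Model,
#' Covariates, CvM, p0, SE, AIC, dAIC.
#'
#' @param tab output of [rank_detection_models()].
#' @param path output CSV path.
#' @export
write_detection_table <- function(tab, path) {
  out <- tibble::tibble(Key = tab$key, Adj = tab$adjustment,
                        Model = tab$model, Covariates = tab$covariates,
                        CvM = tab$cvm_p, p0 = tab$p0, SE = tab$p0_se,
                        AIC = tab$aic, dAIC = tab$delta_aic)
  readr::write_csv(out, path)
  invisible(out)
}

#' Write the DSM comparison table
#'
#' Columns: Model, Covariates, AIC, GCV, dAIC, dGCV, R2, DevianceExplained.
#'
#' @param tab output of [rank_dsm_models()].
#' @param path output CSV path.
#' @export
write_dsm_table <- function(tab, path) {
  out <- tibble::tibble(Model = tab$model, Covariates = tab$covariates,
                        AIC = tab$aic, GCV = tab$gcv, dAIC = tab$delta_aic,
                        dGCV = tab$delta_gcv, R2 = tab$r2,
                        DevianceExplained = tab$deviance_explained)
  readr::write_csv(out, path)
  invisible(out)
}

#' Write the abundance table
#'
#' Columns: Area, N, CI_lo, CI_hi, D_groups, D_individuals.
#'
#' @param estimates one or more [summarize_abundance()] rows (bind first).
#' @param path output CSV path.
#' @export
write_abundance_table <- function(estimates, path) {
  out <- tibble::tibble(Area = estimates$area,
                        N = estimates$n_individuals,
                        CI_lo = estimates$ci_lo, CI_hi = estimates$ci_hi,
                        D_groups = estimates$density_groups,
                        D_individuals = estimates$density_individuals)
  readr::write_csv(out, path)
  invisible(out)
}

#' Serialize a fitted DSM to JSON
#'
#' Versioned plain-text archive of everything needed to reproduce
#' predictions: coefficients, covariance, smoothing parameters, Tweedie
#' power and dispersion, and fit statistics.
#'
#' @param fit a `dsm_fit`.
#' @param path output path.
#' @export
write_dsm_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    format_version = 1L, label = fit$label,
    formula = deparse(fit$formula),
    beta = fit$beta, Vb = fit$Vb, lambda = as.list(fit$lambda),
    tweedie_power = fit$tweedie_power, phi = fit$phi,
    loglik = fit$loglik, aic = fit$aic, gcv = fit$gcv,
    deviance_explained = fit$deviance_explained, edf = fit$edf),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange (readable by standard GIS tools) for the
#' predicted density, SE and CV surfaces.
#'
#' @param raster a `cov_raster`.
#' @param path output path.
#' @export
write_ascii_grid <- function(raster, path) {
  z <- raster$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(z)), sprintf("nrows %d", nrow(z)),
               sprintf("xllcorner %g", raster$xmin),
               sprintf("yllcorner %g", raster$ymin),
               sprintf("cellsize %g", raster$cellsize),
               "NODATA_value -9999"), con)
  zz <- z; zz[is.na(zz)] <- -9999
  for (i in nrow(zz):1)                       # ASCII grids run north to south
    writeLines(paste(zz[i, ], collapse = " "), con)
  invisible(path)
}

#' Run the full abundance-estimation pipeline
#'
#' Executes the complete chain: right truncation, fitting and AIC ranking of
#' all candidate detection functions, effective strip width, group-size
#' estimation, effort segmentation with effective-area offsets, covariate
#' extraction, fitting and ranking of all candidate density surface models,
#' grid prediction, CV masking, and abundance summarization.  Every stage
#' logs its settings and row counts.  With identical inputs the run is fully
#' deterministic.
#'
#' @param sightings sightings tibble (see [read_sightings()]).
#' @param effort effort fixes tibble (see [read_effort()]).
#' @param det_configs list of [detection_config()] candidates.
#' @param dsm_formulas named list of candidate DSM formulas.
#' @param rasters named list of `cov_raster` covariates (names matching
#'   formula variables).
#' @param features named list of polyline features; each yields a
#'   distance-to-feature covariate under its name.
#' @param grid optional prediction grid; default: 2.5 km cells over the
#'   effort bounding box padded by the truncation distance.
#' @param cell_km prediction cell size (km).
#' @param cv_threshold CV masking threshold (percent).
#' @param segment_km,min_segment_km segmentation lengths.
#' @param exclude_hazard_rate drop hazard-rate models before selection
#'   (the near-zero spike exclusion is a caller decision).
#' @param alpha group-size regression significance level.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param quiet suppress progress messages.
#' @return list with the ranked tables, selected fits, segments, cells and
#'   the abundance estimate.
#' @export
run_pipeline <- function(sightings, effort,
                         det_configs = list(detection_config()),
                         dsm_formulas = list(g1 = n_groups ~ s(x, y, k = 30)),
                         rasters = list(), features = list(),
                         grid = NULL, cell_km = 2.5, cv_threshold = 100,
                         segment_km = 5, min_segment_km = 1,
                         exclude_hazard_rate = FALSE,
                         alpha = 0.15, out_dir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  w <- det_configs[[1]]$truncation
  say("stage detection: %d candidates, %d sightings, w = %g m",
      length(det_configs), nrow(sightings), w)
  fits <- lapply(det_configs, fit_detection, sightings = sightings)
  det_tab <- rank_detection_models(fits)
  sel_tab <- if (exclude_hazard_rate && any(det_tab$key != "hazard-rate"))
    det_tab[det_tab$key != "hazard-rate", ] else det_tab
  labels <- vapply(fits, function(f) f$config$label, character(1))
  det_fit <- fits[[match(sel_tab$model[1], labels)]]
  esw_km <- det_fit$esw / 1000
  gs <- expected_group_size(sightings, det_fit, alpha = alpha)
  say("selected %s: esw = %.0f m, E[s] = %.2f", det_fit$config$label,
      det_fit$esw, gs$expected_size)

  segs <- split_effort(effort, target_km = segment_km, min_km = min_segment_km)
  segs <- assign_sightings(segs, sightings, truncation = w)
  segs <- effective_area(segs, esw_km)
  for (nm in names(rasters)) segs <- extract_along_segments(segs, rasters[[nm]], nm)
  for (nm in names(features)) segs <- extract_along_segments(segs, features[[nm]], nm)
  say("stage segmentation: %d segments, %.0f km effort, %d groups assigned",
      nrow(segs), sum(segs$length_km), sum(segs$n_groups))

  dfits <- purrr::imap(dsm_formulas, function(f, nm)
    fit_dsm(segs, f, label = nm))
  dsm_tab <- rank_dsm_models(unname(dfits))
  dsm_fit_sel <- dfits[[match(dsm_tab$model[1], names(dfits))]]
  say("selected DSM %s: AIC %.1f, deviance explained %.1f%%",
      dsm_tab$model[1], dsm_fit_sel$aic, dsm_fit_sel$deviance_explained)

  if (is.null(grid)) {
    pad <- w / 1000
    grid <- make_prediction_grid(range(effort$x) + c(-pad, pad),
                                 range(effort$y) + c(-pad, pad), cell_km)
  }
  vars <- setdiff(unique(unlist(lapply(dsm_fit_sel$spec$terms, `[[`, "vars"))),
                  c("x", "y"))
  for (nm in vars) {
    if (nm %in% names(grid)) next
    if (nm %in% names(rasters))
      grid[[nm]] <- raster_interp(rasters[[nm]], grid$x, grid$y)
    else if (nm %in% names(features))
      grid[[nm]] <- distance_to_feature(grid, features[[nm]])
    else stop("no covariate source for grid variable ", nm)
  }
  cells <- predict_cells(dsm_fit_sel, grid)
  retained <- mask_by_cv(cells, cv_threshold)
  if (nrow(retained) == 0)
    stop("CV masking at threshold ", cv_threshold,
         " retained no cells; aborting at stage prediction")
  est <- summarize_abundance(retained, dsm_fit_sel, gs)
  say("stage prediction: %d/%d cells retained (%.0f km^2); N_ind = %.0f [%.0f, %.0f]",
      nrow(retained), nrow(cells), est$area, est$n_individuals,
      est$ci_lo, est$ci_hi)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_detection_table(det_tab, file.path(out_dir, "detection_models.csv"))
    write_dsm_table(dsm_tab, file.path(out_dir, "dsm_models.csv"))
    write_abundance_table(est, file.path(out_dir, "abundance.csv"))
    write_dsm_fit_json(dsm_fit_sel, file.path(out_dir, "dsm_fit.json"))
    readr::write_csv(dplyr::select(segs, -"path"),
                     file.path(out_dir, "segments.csv"))
    readr::write_csv(cells, file.path(out_dir, "prediction_cells.csv"))
  }
  list(detection_table = det_tab, detection_fit = det_fit,
       group_size = gs, segments = segs,
       dsm_table = dsm_tab, dsm_fit = dsm_fit_sel,
       cells = cells, retained = retained, abundance = est)
}
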