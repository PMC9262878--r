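test_that("population draws match their Poisson expectation", {
  # constant surface D = 0.01 over 10^4 km^2: expected 100 groups
  counts <- vapply(1:200, function(s) {
    cfg <- survey_config(extent = c(100, 100), mean_density = 0.01,
                         surface_beta = c(0, 0), seed = s)
    nrow(simulate_population(cfg))
  }, numeric(1))
  mc_se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 100), 3 * mc_se + 1e-9)
  # zero intensity -> no groups
  cfg0 <- survey_config(mean_density = 0, seed = 1)
  expect_equal(nrow(simulate_population(cfg0)), 0)
})

test_that("zero-truncated Poisson sizes have the closed-form mean", {
  set.seed(50)
  s <- transectdsm:::rztpois(1e5, 0.3)
  expect_true(all(s >= 1))
  expect_equal(mean(s), 0.3 / (1 - exp(-0.3)), tolerance = 0.01)
  # default size law approximates the observed mean group size ~1.3
  expect_equal(0.55 / (1 - exp(-0.55)), 1.30, tolerance = 1e-2)
})

test_that("simulation is deterministic given the seed", {
  cfg <- survey_config(seed = 99)
  a <- simulate_survey(simulate_population(cfg), cfg)
  b <- simulate_survey(simulate_population(cfg), cfg)
  expect_identical(a$sightings, b$sightings)
  expect_identical(a$effort, b$effort)
  expect_identical(a$truth$n_individuals, b$truth$n_individuals)
})

test_that("perfect detection sees every group in the one-sided strip", {
  cfg <- survey_config(detection = list(sigma = 1e9), n_transects = 4,
                       seed = 3)
  pop <- simulate_population(cfg)
  sv <- simulate_survey(pop, cfg)
  w_km <- cfg$detection$truncation / 1000
  expect_true(all(sv$sightings$perp_distance <= cfg$detection$truncation))
  # oracle: count groups left of each transect within w (straight transects)
  expected <- 0
  for (tid in unique(sv$effort$transect_id)) {
    tr <- sv$effort[sv$effort$transect_id == tid, ]
    a <- c(tr$x[1], tr$y[1]); b <- c(tr$x[nrow(tr)], tr$y[nrow(tr)])
    L <- sqrt(sum((b - a)^2)); u <- (b - a) / L
    al <- (pop$x - a[1]) * u[1] + (pop$y - a[2]) * u[2]
    pp <- u[1] * (pop$y - a[2]) - u[2] * (pop$x - a[1])
    expected <- expected + sum(al >= 0 & al <= L & pp > 0 & pp <= w_km)
  }
  expect_equal(nrow(sv$sightings), expected)
})

test_that("the analytic encounter rate matches simulation", {
  esw_km <- esw_hn_closed(600, 1750) / 1000
  cfg1 <- survey_config(mean_density = 0.02, surface_beta = c(0, 0), seed = 1)
  expect_equal(expected_encounters(survey_config(mean_density = 0.02,
                                                 surface_beta = c(0, 0)),
                                   0.5, total_effort_km = 1000), 10)
  expect_equal(expected_encounters(survey_config(mean_density = 0,
                                                 surface_beta = c(0, 0)),
                                   esw_km), 0)
  expect_error(expected_encounters(survey_config(surface_beta = c(1, 0)),
                                   esw_km), "homogeneous")
  # Monte-Carlo agreement using the realized effort of each replicate
  res <- vapply(1:120, function(s) {
    cfg <- survey_config(surface_beta = c(0, 0), seed = s)
    sv <- simulate_survey(simulate_population(cfg), cfg)
    L <- sum(vapply(split(sv$effort, sv$effort$transect_id), function(tr)
      sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), numeric(1)))
    c(n = nrow(sv$sightings),
      exp = expected_encounters(cfg, esw_km, total_effort_km = L))
  }, numeric(2))
  diff_mean <- mean(res["n", ] - res["exp", ])
  mc_se <- sd(res["n", ] - res["exp", ]) / sqrt(ncol(res))
  expect_lt(abs(diff_mean), 3 * mc_se)
})

test_that("detection thinning matches g(x) by distance bin", {
  set.seed(8)
  n <- 1e5
  x <- runif(n, 0, 1750)
  g <- evaluate_detection(x, 600)
  det <- runif(n) < g
  bins <- cut(x, seq(0, 1750, length.out = 11))
  obs_rate <- tapply(det, bins, mean)
  exp_rate <- tapply(g, bins, mean)
  nb <- tapply(det, bins, length)
  chi2 <- sum(nb * (obs_rate - exp_rate)^2 / (exp_rate * (1 - exp_rate)))
  expect_lt(chi2, qchisq(0.99, df = 10))
})

test_that("Horvitz-Thompson with the true detection function recovers N", {
  esw_km <- esw_hn_closed(600, 1750) / 1000
  w_km <- 1.75
  est <- vapply(1:60, function(s) {
    cfg <- survey_config(surface_beta = c(0, 0), seed = s)
    sv <- simulate_survey(simulate_population(cfg), cfg)
    L <- sum(vapply(split(sv$effort, sv$effort$transect_id), function(tr)
      sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), numeric(1)))
    ht_strip <- sum(1 / evaluate_detection(sv$sightings$perp_distance, 600))
    c(Nhat = ht_strip * prod(cfg$extent) / (w_km * L),
      N = sv$truth$n_groups)
  }, numeric(2))
  rel <- mean(est["Nhat", ]) / mean(est["N", ]) - 1
  expect_lt(abs(rel), 0.05)
})

test_that("aggregation clusters superimpose large groups", {
  cfg <- survey_config(aggregation = list(parent_rate = 3e-4,
                                          mean_size = 40, radius = 1),
                       seed = 12)
  pop <- simulate_population(cfg)
  expect_gt(max(pop$size), 14)   # aggregations are >= 15 animals
})

test_that("GRF noise perturbs the surface but keeps its mean density", {
  cfg <- survey_config(grf = list(range = 20, sd = 0.5), seed = 13)
  pop <- simulate_population(cfg)
  surf <- attr(pop, "surface")
  expect_equal(sum(surf$values), cfg$mean_density * prod(cfg$extent),
               tolerance = 1e-6)
  expect_gt(sd(log(surf$values)), 0.2)
})
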