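test_that("detection function evaluation matches analytic forms", {
  expect_equal(evaluate_detection(0, 600), 1.0)
  expect_equal(evaluate_detection(600, 600), exp(-0.5))
  expect_equal(evaluate_detection(500, 500, key = "hazard-rate", shape = 2),
               1 - exp(-1))
  # adjusted curve is rescaled to g(0) = 1 exactly
  g0 <- evaluate_detection(0, 600, adj_coeffs = 0.3, adj_orders = 2,
                           truncation = 1750)
  expect_identical(g0, 1.0)
  expect_error(evaluate_detection(-5, 600), "negative")
})

test_that("unadjusted keys are non-increasing and adjusted g stays valid", {
  xs <- seq(0, 1750, length.out = 400)
  for (spec in list(list(k = "half-normal", b = NULL),
                    list(k = "hazard-rate", b = 2.5))) {
    g <- evaluate_detection(xs, 600, spec$k, spec$b)
    expect_true(all(diff(g) <= 1e-12))
    expect_true(all(g > 0 & g <= 1))
  }
})

test_that("half-normal fit recovers the generating scale and esw identities hold", {
  set.seed(42)
  s <- sim_hn_sightings(500, sigma = 600)
  fit <- fit_detection(s, detection_config(truncation = 1750))
  sigma_hat <- exp(fit$beta[[1]])
  expect_lt(abs(sigma_hat - 600) / 600, 0.05)
  # identity esw = p_bar * w to 1e-9 relative
  expect_equal(fit$esw, fit$p_bar * 1750, tolerance = 1e-9)
  # package quadrature matches the closed form at the fitted scale
  expect_equal(fit$esw, esw_hn_closed(sigma_hat, 1750),
               tolerance = 1e-6)
  expect_equal(fit$aic, 2 * length(fit$par) - 2 * fit$loglik)
  expect_gt(fit$esw_se, 0)
})

test_that("quadrature matches the closed-form esw across scales", {
  w <- 1750
  for (sigma in c(100, 300, 600, 1000, 2000, 5000)) {
    quad <- integrate(function(x) evaluate_detection(x, sigma), 0, w,
                      rel.tol = 1e-10)$value
    expect_equal(quad, esw_hn_closed(sigma, w), tolerance = 1e-6)
  }
  # flat detection limit: esw -> w
  expect_equal(integrate(function(x) evaluate_detection(x, 1e9), 0, w)$value,
               w, tolerance = 1e-6)
})

test_that("covariate effects on log sigma are recovered", {
  set.seed(7)
  n <- 600
  ss <- sample(0:4, n, replace = TRUE)
  sig_i <- 500 * exp(0.2 * ss)
  x <- abs(rnorm(n, 0, sig_i))
  keep <- x <= 1750
  s <- tibble::tibble(perp_distance = x[keep], group_size = 1L,
                      seastate = ss[keep])
  fit <- fit_detection(s, detection_config(covariates = "seastate"))
  expect_lt(abs(fit$beta[["seastate"]] - 0.2), 0.1)
  expect_equal(fit$esw, fit$p_bar * 1750, tolerance = 1e-9)
})

test_that("degenerate inputs raise the documented errors", {
  one <- tibble::tibble(perp_distance = 100, group_size = 1L)
  expect_error(fit_detection(one), "fewer than 2")
  far <- tibble::tibble(perp_distance = c(1800, 2000, 100), group_size = 1L)
  expect_error(fit_detection(far, detection_config(truncation = 1750)),
               "fewer than 2")
  expect_error(detection_config(key = "hazard-rate", adjustment = "cosine"),
               "cosine")
  expect_error(detection_config(truncation = -1), "truncation")
})

test_that("CvM statistic attains its sample-size floor and null is calibrated", {
  # the statistic is bounded below by 1/(12n), attained when the ordered
  # PIT values sit exactly at (2i-1)/(2n)
  n <- 5
  u <- (2 * seq_len(n) - 1) / (2 * n)
  W2 <- 1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
  expect_equal(W2, 1 / 60)
  # asymptotic null quantile: P(W2 > 0.461) ~ 0.05
  expect_equal(1 - transectdsm:::pcvm_async(0.461), 0.05, tolerance = 0.01)
  expect_equal(1 - transectdsm:::pcvm_async(0.743), 0.01, tolerance = 0.005)
  set.seed(11)
  fit <- fit_detection(sim_hn_sightings(300), detection_config())
  gof <- cvm_goodness_of_fit(fit)
  expect_gte(gof$statistic, 1 / (12 * fit$n_used))
  expect_gt(gof$p_value, 0.01)
})

test_that("model ranking orders by AIC, is permutation invariant, and checks data", {
  set.seed(5)
  s <- sim_hn_sightings(250)
  fits <- list(fit_detection(s, detection_config(label = "m1")),
               fit_detection(s, detection_config(adjustment = "cosine",
                                                 label = "c1")),
               fit_detection(s, detection_config(key = "hazard-rate",
                                                 label = "h1")))
  tab <- rank_detection_models(fits)
  expect_equal(tab$aic, sort(tab$aic))
  expect_equal(tab$delta_aic[1], 0)
  tab2 <- rank_detection_models(fits[c(3, 1, 2)])
  expect_equal(tab$model, tab2$model)
  expect_equal(tab$aic, tab2$aic)
  # delta-AIC arithmetic on a frozen pair of AIC values
  expect_equal(diff(sort(c(1365.86, 1378.06))), 12.2)
  other <- fit_detection(sim_hn_sightings(100), detection_config())
  expect_error(rank_detection_models(list(fits[[1]], other)), "differing")
  expect_equal(rank_detection_models(list(fits[[1]]))$delta_aic, 0)
})

test_that("group size estimation uses the regression only when size bias is present", {
  set.seed(9)
  s <- sim_hn_sightings(200, lambda_size = 0)   # all singletons, no bias
  s$group_size <- rep(c(1L, 1L, 2L), length.out = 200)
  fit <- fit_detection(s, detection_config())
  gs <- expected_group_size(s, fit)
  expect_equal(gs$mean_observed, mean(s$group_size))
  expect_gte(gs$expected_size, 1)
  # arithmetic-mean branch on the toy example {1,1,2}
  expect_equal(mean(c(1, 1, 2)), 4 / 3)

  # size-biased detection: larger groups detectable farther out
  set.seed(10)
  n <- 4000
  size <- 1L + rpois(n, 0.8)
  sig_i <- 450 * exp(0.35 * (size - 1))
  x <- abs(rnorm(n, 0, sig_i))
  keep <- x <= 1750
  det <- runif(n) < exp(-x^2 / (2 * sig_i^2))
  obs <- tibble::tibble(perp_distance = x[keep & det],
                        group_size = size[keep & det])
  fitb <- fit_detection(obs, detection_config())
  gsb <- expected_group_size(obs, fitb)
  expect_equal(gsb$method, "size-bias-regression")
  expect_lt(gsb$expected_size, mean(obs$group_size))
})

test_that("tidiers summarise detection fits", {
  set.seed(2)
  fit <- fit_detection(sim_hn_sightings(150),
                       detection_config(adjustment = "cosine"))
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$par))
  gl <- glance(fit)
  expect_equal(gl$esw, fit$esw)
  expect_equal(gl$p0 * 1750, gl$esw, tolerance = 1e-9)
})
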