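test_that("thin-plate basis has a valid penalty and exact linear null space", {
  set.seed(21)
  x <- matrix(sort(runif(40, 0, 10)))
  b <- build_smoother_basis(x, k = 8)
  # penalty PSD
  ev <- eigen((b$S + t(b$S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
  # a straight line is reproduced exactly with zero penalty
  y <- 2 * x[, 1] + 1
  X <- cbind(1, b$X)
  beta <- qr.solve(X, y)
  expect_equal(as.vector(X %*% beta), y, tolerance = 1e-8)
  expect_lt(drop(t(beta[-1]) %*% b$S %*% beta[-1]), 1e-10)
  expect_error(build_smoother_basis(x, k = 100), "exceeds")
  expect_error(build_smoother_basis(x, k = 2), "k must be")
})

test_that("unpenalized full-rank basis interpolates like the exact thin plate", {
  set.seed(22)
  n <- 8
  x <- matrix(sort(runif(n, 0, 1)))
  y <- sin(2 * pi * x[, 1])
  # oracle: exact thin-plate interpolant (eta = r^3 radial + linear)
  E <- abs(outer(x[, 1], x[, 1], "-"))^3
  Tm <- cbind(1, x)
  A <- rbind(cbind(E, Tm), cbind(t(Tm), matrix(0, 2, 2)))
  sol <- solve(A, c(y, 0, 0))
  xs <- seq(0.05, 0.95, by = 0.1)
  oracle <- as.vector(abs(outer(xs, x[, 1], "-"))^3 %*% sol[1:n] +
                        cbind(1, xs) %*% sol[n + 1:2])
  # package: full-rank basis, near-zero smoothing via fit_dsm
  seg <- tibble::tibble(xx = x[, 1], n_groups = y + 2, A_seg = 1)
  f <- fit_dsm(seg, n_groups ~ s(xx, k = 8), p = 1.5, lambda = 1e-12)
  expect_equal(log(f$fitted), log(y + 2), tolerance = 1e-3)
})

test_that("intercept-only fit reproduces the offset-weighted mean", {
  set.seed(23)
  n <- 60
  seg <- tibble::tibble(n_groups = rpois(n, 1.2), A_seg = 2.5)
  f <- fit_dsm(seg, n_groups ~ 1, p = 1.5)
  expect_equal(f$fitted, rep(sum(seg$n_groups) / sum(seg$A_seg) * 2.5, n),
               tolerance = 1e-7)
  # with unequal areas the identity holds in the Poisson limit
  seg$A_seg <- runif(n, 1, 4)
  f2 <- fit_dsm(seg, n_groups ~ 1, p = 1.05)
  expect_equal(f2$fitted,
               sum(seg$n_groups) / sum(seg$A_seg) * seg$A_seg,
               tolerance = 1e-2)
})

test_that("the spatial smooth recovers a known intensity surface", {
  set.seed(24)
  n <- 600
  seg <- tibble::tibble(x = runif(n, 0, 150), y = runif(n, 0, 100),
                        A_seg = runif(n, 2, 3))
  mu_true <- exp(-1.2 + 0.015 * seg$x - 0.01 * seg$y +
                   0.7 * sin(seg$x / 20)) * seg$A_seg
  seg$n_groups <- rpois(n, mu_true)
  f <- fit_dsm(seg, n_groups ~ s(x, y, k = 25))
  expect_gt(cor(f$fitted, mu_true), 0.8)
  expect_true(f$tweedie_power > 1 && f$tweedie_power < 2)
  expect_true(f$deviance_explained >= 0 && f$deviance_explained <= 100)
  # covariance symmetric PSD
  expect_equal(f$Vb, t(f$Vb), tolerance = 1e-8)
  ev <- eigen(f$Vb, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * max(ev)))
})

test_that("fitted surfaces agree with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  withr::local_package("mgcv")
  set.seed(25)
  n <- 300
  seg <- tibble::tibble(x = runif(n, 0, 150), y = runif(n, 0, 100),
                        A_seg = runif(n, 2, 3))
  seg$n_groups <- rpois(n, exp(-1 + 0.02 * seg$x - 0.015 * seg$y) * seg$A_seg)
  ours <- fit_dsm(seg, n_groups ~ s(x, y, k = 25))
  ref <- mgcv::gam(n_groups ~ s(x, y, k = 25) + offset(log(A_seg)),
                   data = seg, family = mgcv::tw(), method = "GCV.Cp")
  expect_gt(cor(ours$fitted, fitted(ref)), 0.95)
  expect_lt(abs(ours$deviance_explained - 100 * summary(ref)$dev.expl), 8)
})

test_that("adding a pure-noise covariate rarely improves GCV", {
  set.seed(26)
  wins <- 0; nsim <- 30
  for (i in seq_len(nsim)) {
    n <- 150
    seg <- tibble::tibble(x = runif(n, 0, 100), y = runif(n, 0, 60),
                          junk = rnorm(n), A_seg = 2.5)
    seg$n_groups <- rpois(n, exp(-1.5 + 0.01 * seg$x) * seg$A_seg)
    f0 <- fit_dsm(seg, n_groups ~ s(x, y, k = 12), p = 1.3)
    f1 <- fit_dsm(seg, n_groups ~ s(x, y, k = 12) + s(junk, k = 6), p = 1.3)
    if (f1$gcv - f0$gcv >= -1e-6) wins <- wins + 1
  }
  expect_gte(wins / nsim, 0.8)
})

test_that("infinite smoothing collapses the 2-D smooth to a plane", {
  set.seed(27)
  n <- 200
  seg <- tibble::tibble(x = runif(n, 0, 100), y = runif(n, 0, 60), A_seg = 2.5)
  seg$n_groups <- rpois(n, exp(-1 + 0.02 * seg$x + 0.6 * sin(seg$y / 8)) * 2.5)
  f <- fit_dsm(seg, n_groups ~ s(x, y, k = 20), p = 1.3, lambda = 1e14)
  eta <- log(f$fitted) - log(seg$A_seg)
  plane <- lm(eta ~ x + y, data = seg)
  expect_lt(max(abs(residuals(plane))), 1e-3)
})

test_that("model ranking follows AIC with a parsimony tie-break", {
  set.seed(28)
  n <- 250
  seg <- tibble::tibble(x = runif(n, 0, 150), y = runif(n, 0, 100),
                        depth = runif(n, -800, -100), A_seg = 2.5)
  seg$n_groups <- rpois(n, exp(-1.6 + 0.012 * seg$x) * 2.5)
  f1 <- fit_dsm(seg, n_groups ~ s(x, y, k = 15), label = "g1")
  f2 <- fit_dsm(seg, n_groups ~ s(x, y, k = 15) + s(depth, k = 6), label = "g2")
  tab <- rank_dsm_models(list(f1, f2))
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(tab$delta_aic, sort(tab$delta_aic))
  # permutation invariance
  tab2 <- rank_dsm_models(list(f2, f1))
  expect_equal(tab$model, tab2$model)
  # parsimony: when both are within 2 AIC units the simpler model leads
  if (abs(f1$aic - f2$aic) < 2) expect_equal(tab$model[1], "g1")
  # delta arithmetic frozen on a printed-table pair
  expect_equal(891.11 - 890.25, 0.86)
  expect_equal(rank_dsm_models(list(f1))$delta_aic, 0)
  other <- fit_dsm(seg[1:100, ], n_groups ~ s(x, y, k = 10), label = "gx")
  expect_error(rank_dsm_models(list(f1, other)), "differing")
})

test_that("fits serialize to JSON and summarise via tidy/glance", {
  set.seed(29)
  n <- 120
  seg <- tibble::tibble(x = runif(n, 0, 80), y = runif(n, 0, 50), A_seg = 2.5)
  seg$n_groups <- rpois(n, 0.4)
  f <- fit_dsm(seg, n_groups ~ s(x, y, k = 10), label = "g1")
  path <- withr::local_tempfile(fileext = ".json")
  write_dsm_fit_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$beta, f$beta, tolerance = 1e-12)
  expect_equal(back$tweedie_power, f$tweedie_power)
  expect_equal(back$format_version, 1L)
  td <- tidy(f)
  expect_equal(td$term, "s(x, y, k = 10)")
  gl <- glance(f)
  expect_equal(gl$AIC, f$aic)
  expect_equal(gl$edf, f$edf)
})
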