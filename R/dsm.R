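# ---- low-rank thin-plate regression splines -------------------------------

tp_eta <- function(r, d) {
  if (d == 1) r^3 else ifelse(r == 0, 0, r^2 * log(r))
}

tp_dist <- function(A, B) {
  # Euclidean distance matrix between rows of A (n x d) and B (m x d)
  n <- nrow(A); m <- nrow(B)
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(D2, 0))
}

#' Low-rank thin-plate regression spline basis
#'
#' Builds the eigen-truncated thin-plate spline basis for 1-D or 2-D
#' covariates: the radial basis `eta(r)` (`r^3` in 1-D, `r^2 log r` in 2-D)
#' on the data points is eigen-decomposed and truncated to rank `k`; the
#' polynomial null space (intercept and linear terms) is appended
#' unpenalized, and the penalty is the truncated bending-energy matrix.
#' Identifiability within an additive model is obtained by sum-to-zero
#' centring of all columns (the intercept is carried globally by the model,
#' not by the smooth).
#'
#' @param points numeric matrix or data frame with 1 or 2 columns of
#'   covariate values at the data points.
#' @param k basis dimension (>= 3), including null-space columns.
#' @return list with `X` (centred design columns, penalized part first, then
#'   non-constant null-space columns), `S` (penalty for the full block, zero
#'   rows/columns on the null space), and the information needed to evaluate
#'   the basis at new points.
#' @export
build_smoother_basis <- function(points, k) {
  X0 <- as.matrix(points)
  storage.mode(X0) <- "double"
  d <- ncol(X0)
  if (!d %in% 1:2) stop("only 1-D and 2-D thin-plate terms are supported")
  uniq <- unique(X0)
  if (k > nrow(uniq)) stop("basis dimension k exceeds number of distinct points")
  if (k < 3) stop("k must be >= 3")
  M <- d + 1                                   # null space dimension
  E <- tp_eta(tp_dist(X0, X0), d)
  eg <- eigen((E + t(E)) / 2, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(k)]
  U <- eg$vectors[, ord, drop = FALSE]
  D <- eg$values[ord]
  Tm <- cbind(1, X0)
  C <- t(Tm) %*% U                             # M x k constraint
  qz <- qr(t(C))
  Z <- qr.Q(qz, complete = TRUE)[, (M + 1):k, drop = FALSE]
  UZ <- U %*% Z                                # n x (k - M)
  Xpen <- U %*% (D * Z)                        # = E %*% UZ
  Spen <- t(Z) %*% (D * Z)
  Spen <- (Spen + t(Spen)) / 2
  sc <- max(abs(Spen))
  if (sc > 0) Spen <- Spen / sc
  Xnull <- X0                                  # linear null-space columns
  Xb <- cbind(Xpen, Xnull)
  mns <- colMeans(Xb)
  Xb <- sweep(Xb, 2, mns)
  q <- ncol(Xb)
  S <- matrix(0, q, q)
  S[seq_len(ncol(Spen)), seq_len(ncol(Spen))] <- Spen
  list(X = Xb, S = S, knots = X0, UZ = UZ, d = d, k = k,
       col_means = mns, n_pen = ncol(Xpen))
}

# evaluate a stored basis at new points
tp_basis_predict <- function(basis, newpoints) {
  Xn <- as.matrix(newpoints)
  storage.mode(Xn) <- "double"
  Estar <- tp_eta(tp_dist(Xn, basis$knots), basis$d)
  Xb <- cbind(Estar %*% basis$UZ, Xn)
  sweep(Xb, 2, basis$col_means)
}

# ---- model specification ---------------------------------------------------

# parse a formula like n ~ s(x, y, k = 30) + s(depth) into term descriptors
parse_dsm_formula <- function(formula) {
  tf <- terms(formula)
  labs <- attr(tf, "term.labels")
  response <- as.character(attr(tf, "variables")[[2]])
  specs <- lapply(labs, function(lb) {
    cl <- str2lang(lb)
    if (!is.call(cl) || as.character(cl[[1]]) != "s")
      stop("every term must be a smooth s(...): ", lb)
    args <- as.list(cl)[-1]
    nm <- names(args) %||% rep("", length(args))
    vars <- vapply(args[nm == ""], as.character, character(1))
    k <- if ("k" %in% nm) eval(args[["k"]]) else if (length(vars) == 2) 30L else 10L
    if (length(vars) > 2) stop("smooths of more than 2 variables not supported")
    list(vars = vars, k = as.integer(k), label = lb)
  })
  n2d <- sum(vapply(specs, function(s) length(s$vars) == 2, TRUE))
  if (n2d > 1) stop("at most one 2-D smooth is supported")
  list(response = response, terms = specs)
}

# assemble full design matrix and penalty list from segments + parsed terms
dsm_design <- function(data, spec) {
  X <- matrix(1, nrow(data), 1)
  colnames(X) <- "(Intercept)"
  S_list <- list(); blocks <- list(); bases <- list()
  for (tm in spec$terms) {
    pts <- as.matrix(data[, tm$vars, drop = FALSE])
    b <- build_smoother_basis(pts, tm$k)
    i0 <- ncol(X)
    X <- cbind(X, b$X)
    idx <- (i0 + 1):(i0 + ncol(b$X))
    S_list[[tm$label]] <- b$S
    blocks[[tm$label]] <- idx
    bases[[tm$label]] <- b
  }
  list(X = X, S_list = S_list, blocks = blocks, bases = bases)
}

# embed per-term penalties into full-coefficient matrices scaled by lambda
penalty_total <- function(q, S_list, blocks, lambda) {
  S <- matrix(0, q, q)
  for (j in seq_along(S_list)) {
    idx <- blocks[[j]]
    S[idx, idx] <- S[idx, idx] + lambda[j] * S_list[[j]]
  }
  S
}

# ---- penalized IRLS --------------------------------------------------------

dsm_irls <- function(y, X, off, S, p, beta0 = NULL, max_iter = 60) {
  n <- length(y)
  mu <- if (is.null(beta0)) pmax(y, 0) + mean(y) * 0.5 + 1e-3
  else pmax(exp(pmin(X %*% beta0 + off, 30)), 1e-8)
  eta <- log(mu)
  beta <- beta0
  dev <- sum(tweedie_deviance(y, mu, p))
  for (it in seq_len(max_iter)) {
    w <- as.vector(mu^(2 - p))
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + S
    rank_def <- FALSE
    beta_new <- tryCatch(solve(A, XtW %*% z), error = function(e) {
      rank_def <<- TRUE
      MASS_ginv(A) %*% (XtW %*% z)
    })
    step <- 1
    repeat {
      b_try <- if (is.null(beta)) beta_new else beta + step * (beta_new - beta)
      eta_try <- pmin(pmax(as.vector(X %*% b_try) + off, -30), 30)
      mu_try <- exp(eta_try)
      dev_try <- sum(tweedie_deviance(y, mu_try, p))
      pen_try <- drop(t(b_try) %*% S %*% b_try)
      if (is.finite(dev_try + pen_try)) break
      step <- step / 2
      if (step < 1e-4) { b_try <- beta; eta_try <- eta; mu_try <- mu
        dev_try <- dev; break }
    }
    beta <- as.vector(b_try); eta <- eta_try; mu <- mu_try
    if (abs(dev - dev_try) < 1e-9 * (dev_try + 0.1) && it > 1) { dev <- dev_try; break }
    dev <- dev_try
  }
  w <- as.vector(mu^(2 - p))
  XtWX <- t(X * w) %*% X
  A <- XtWX + S
  Ainv <- tryCatch(solve(A), error = function(e) { rank_def <<- TRUE
    MASS_ginv(A) })
  edf <- sum(diag(Ainv %*% XtWX))
  list(beta = beta, mu = mu, eta = eta, dev = dev, edf = edf,
       Ainv = Ainv, XtWX = XtWX, rank_deficient = rank_def)
}

MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

dsm_gcv <- function(fitc, n) n * fitc$dev / (n - fitc$edf)^2

# coordinate-wise golden-section GCV minimization over log10(lambda)
select_lambda <- function(y, X, off, S_list, blocks, p, lambda,
                          lower = -4, upper = 7, sweeps = 2) {
  n <- length(y); q <- ncol(X)
  for (sw in seq_len(sweeps)) {
    for (j in seq_along(S_list)) {
      obj <- function(ll) {
        lam <- lambda; lam[j] <- 10^ll
        S <- penalty_total(q, S_list, blocks, lam)
        dsm_gcv(dsm_irls(y, X, off, S, p), n)
      }
      opt <- stats::optimize(obj, c(lower, upper), tol = 0.02)
      lambda[j] <- 10^opt$minimum
    }
  }
  lambda
}

#' Fit a Tweedie density surface model
#'
#' Penalized additive model of per-segment group counts with a log link and
#' `log(A_seg)` offset: thin-plate regression-spline smooths, smoothing
#' parameters chosen per term by minimizing GCV (`n D / (n - edf)^2` on the
#' deviance scale, golden-section search per term with outer iteration), the
#' Tweedie power `p` estimated by a 1-D profile over a grid (1.05 to 1.95,
#' step 0.05) maximizing the exact series log-likelihood, and the dispersion
#' by the Pearson estimator.  Fitting is by penalized IRLS with
#' step-halving; the whole procedure is deterministic.
#'
#' @param segments segments tibble with the response, covariates and
#'   effective-area column.
#' @param formula model formula of smooth terms, e.g.
#'   `n_groups ~ s(x, y, k = 30) + s(depth, k = 10)`.
#' @param offset_col name of the effective-area column (default `"A_seg"`).
#' @param p fixed Tweedie power; `NULL` (default) profiles it.
#' @param lambda fixed vector of smoothing parameters (one per term);
#'   `NULL` (default) selects them by GCV.
#' @param label optional short model label.
#' @return an object of class `dsm_fit`: coefficients with Bayesian
#'   covariance, per-term smoothing parameters, Tweedie power and
#'   dispersion, series log-likelihood, AIC, GCV, deviance explained (%),
#'   adjusted R^2 and effective degrees of freedom.
#' @export
fit_dsm <- function(segments, formula = n_groups ~ s(x, y, k = 30),
                    offset_col = "A_seg", p = NULL, lambda = NULL,
                    label = NULL) {
  spec <- parse_dsm_formula(formula)
  vars <- unique(c(unlist(lapply(spec$terms, `[[`, "vars")),
                   spec$response, offset_col))
  data <- tibble::as_tibble(segments)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- complete.cases(data[, vars])
  if (!all(ok)) {
    warning(sum(!ok), " segment(s) dropped for missing covariates")
    data <- data[ok, ]
  }
  y <- data[[spec$response]]
  A <- data[[offset_col]]
  if (any(A <= 0)) stop("offset areas must be > 0")
  off <- log(A)
  des <- dsm_design(data, spec)
  X <- des$X; q <- ncol(X); n <- length(y)

  fixed_p <- !is.null(p)
  p_cur <- p %||% 1.4
  lam <- lambda %||% rep(1, length(des$S_list))
  if (is.null(lambda) && length(des$S_list))
    lam <- select_lambda(y, X, off, des$S_list, des$blocks, p_cur, lam)
  S <- penalty_total(q, des$S_list, des$blocks, lam)
  fitc <- dsm_irls(y, X, off, S, p_cur)

  pearson_phi <- function(mu, pw, edf)
    max(sum((y - mu)^2 / mu^pw) / max(n - edf, 1), 1e-8)
  if (!fixed_p) {
    grid <- seq(1.05, 1.95, by = 0.05)
    ll <- vapply(grid, function(pp) {
      fc <- dsm_irls(y, X, off, S, pp, beta0 = fitc$beta)
      phi <- pearson_phi(fc$mu, pp, fc$edf)
      sum(tweedie_logdensity(y, fc$mu, pp, phi))
    }, numeric(1))
    p_cur <- grid[which.max(ll)]
    if (is.null(lambda) && length(des$S_list)) {
      lam <- select_lambda(y, X, off, des$S_list, des$blocks, p_cur, lam)
      S <- penalty_total(q, des$S_list, des$blocks, lam)
    }
    fitc <- dsm_irls(y, X, off, S, p_cur, beta0 = fitc$beta)
  }

  if (isTRUE(fitc$rank_deficient))
    warning("rank-deficient design; coefficients computed by pseudo-inverse")
  phi <- pearson_phi(fitc$mu, p_cur, fitc$edf)
  loglik <- sum(tweedie_logdensity(y, fitc$mu, p_cur, phi))
  aic <- -2 * loglik + 2 * (fitc$edf + 1)
  gcv <- dsm_gcv(fitc, n)
  # null (intercept + offset only) deviance at the same power
  null_fit <- dsm_irls(y, matrix(1, n, 1), off, matrix(0, 1, 1), p_cur)
  dev_expl <- 100 * (1 - fitc$dev / null_fit$dev)
  rss <- sum((y - fitc$mu)^2); tss <- sum((y - mean(y))^2)
  r2 <- 1 - (rss / max(n - fitc$edf, 1)) / (tss / (n - 1))
  Vb <- fitc$Ainv * phi                       # Bayesian posterior covariance

  structure(list(
    formula = formula, spec = spec, label = label %||% "dsm",
    offset_col = offset_col,
    beta = as.vector(fitc$beta), Vb = Vb, lambda = setNames(lam, names(des$S_list)),
    tweedie_power = p_cur, phi = phi, loglik = loglik, aic = aic, gcv = gcv,
    deviance = fitc$dev, null_deviance = null_fit$dev,
    deviance_explained = dev_expl, r2 = r2, edf = fitc$edf,
    fitted = as.vector(fitc$mu), y = y, n = n,
    bases = des$bases, blocks = des$blocks, data = data),
    class = "dsm_fit")
}

# design matrix for new data on the fitted basis
dsm_model_matrix <- function(fit, newdata) {
  X <- matrix(1, nrow(newdata), 1)
  for (tm in fit$spec$terms) {
    b <- fit$bases[[tm$label]]
    pts <- as.matrix(newdata[, tm$vars, drop = FALSE])
    X <- cbind(X, tp_basis_predict(b, pts))
  }
  X
}

#' Predict from a density surface model
#'
#' @param object a `dsm_fit`.
#' @param newdata data frame with the model covariates.
#' @param area offset area per row (km^2); default 1 gives density per km^2.
#' @param ... unused.
#' @return tibble with `mu` (expected groups), `se_eta` (link-scale SE),
#'   `se` (response-scale delta-method SE) and `cv` (percent).
#' @export
predict.dsm_fit <- function(object, newdata, area = 1, ...) {
  X <- dsm_model_matrix(object, newdata)
  eta <- as.vector(X %*% object$beta) + log(area)
  se_eta <- sqrt(pmax(rowSums((X %*% object$Vb) * X), 0))
  mu <- exp(eta)
  tibble::tibble(mu = mu, se_eta = se_eta, se = mu * se_eta,
                 cv = 100 * se_eta)
}

#' Rank candidate density surface models
#'
#' Comparison table in the conventional layout: model label, covariates,
#' AIC, GCV, delta-AIC, delta-GCV, R^2 and deviance explained, ranked by
#' AIC.  Models within 2 AIC units of the best are re-ordered to prefer the
#' one with fewer covariates (the parsimony tie-break).
#'
#' @param fits list of `dsm_fit` objects sharing segments and response.
#' @return a ranked tibble.
#' @export
rank_dsm_models <- function(fits) {
  if (inherits(fits, "dsm_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, TRUE, "dsm_fit")))
  ys <- lapply(fits, `[[`, "y")
  if (length(fits) > 1 &&
      !all(vapply(ys[-1], function(y) isTRUE(all.equal(y, ys[[1]])), TRUE)))
    stop("fits use differing segment data")
  tab <- purrr::map_dfr(fits, function(f) tibble::tibble(
    model = f$label,
    covariates = paste(vapply(f$spec$terms, `[[`, character(1), "label"),
                       collapse = " + "),
    n_terms = length(f$spec$terms),
    aic = f$aic, gcv = f$gcv, r2 = f$r2,
    deviance_explained = f$deviance_explained))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$delta_gcv <- tab$gcv - min(tab$gcv)
  near <- tab$delta_aic < 2
  tab <- tab[c(which(near)[order(tab$n_terms[near], tab$aic[near])],
               which(!near)[order(tab$aic[!near])]), ]
  tab$delta_aic <- tab$aic - min(tab$aic)
  dplyr::select(tab, -"n_terms")
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat("Tweedie density surface model:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d segments; edf = %.2f; p = %.2f; phi = %.3f\n",
              x$n, x$edf, x$tweedie_power, x$phi))
  cat(sprintf("  AIC = %.2f; GCV = %.3f; deviance explained = %.1f%%\n",
              x$aic, x$gcv, x$deviance_explained))
  invisible(x)
}
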