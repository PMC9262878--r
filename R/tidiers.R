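#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a detection-function fit
#'
#' One row per estimated parameter (log-scale coefficients, hazard shape,
#' cosine adjustment coefficients) with standard errors from the inverse
#' Hessian.
#'
#' @param x a `det_fit`.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.det_fit <- function(x, ...) {
  terms <- names(x$beta)
  if (!is.null(x$shape_b)) terms <- c(terms, "log(shape-1)")
  if (length(x$adj_coeffs))
    terms <- c(terms, paste0("cos", x$config$adj_orders))
  se <- if (all(is.finite(x$vcov))) sqrt(pmax(diag(x$vcov), 0))
  else rep(NA_real_, length(x$par))
  est <- x$par
  tibble::tibble(term = terms, estimate = est, std.error = se)
}

#' One-row summary of a detection-function fit
#'
#' @param x a `det_fit`.
#' @param ... unused.
#' @return tibble with n, esw, p0, logLik, AIC, CvM statistic and p-value.
#' @export
glance.det_fit <- function(x, ...) {
  tibble::tibble(n = x$n_used, esw = x$esw, esw_se = x$esw_se,
                 p0 = x$p_bar, p0_se = x$p_bar_se,
                 logLik = x$loglik, AIC = x$aic,
                 cvm_statistic = x$cvm_stat, cvm_p = x$cvm_p)
}

#' Tidy a density surface model fit
#'
#' One row per smooth term with its smoothing parameter; use
#' [glance.dsm_fit()] for whole-model statistics.
#'
#' @param x a `dsm_fit`.
#' @param ... unused.
#' @return tibble with `term`, `k`, `lambda`.
#' @export
tidy.dsm_fit <- function(x, ...) {
  tibble::tibble(
    term = vapply(x$spec$terms, `[[`, character(1), "label"),
    k = vapply(x$spec$terms, `[[`, integer(1), "k"),
    lambda = unname(x$lambda))
}

#' One-row summary of a density surface model fit
#'
#' @param x a `dsm_fit`.
#' @param ... unused.
#' @return tibble with edf, Tweedie power, dispersion, logLik, AIC, GCV,
#'   deviance explained (%) and adjusted R^2.
#' @export
glance.dsm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, edf = x$edf, tweedie_power = x$tweedie_power,
                 phi = x$phi, logLik = x$loglik, AIC = x$aic, GCV = x$gcv,
                 deviance_explained = x$deviance_explained, r2 = x$r2)
}
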