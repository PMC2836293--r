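# noncentral t quantile: library routine first (its "full precision"
# warnings are muffled), bisection on the CDF as fallback when the
# routine fails to converge at extreme noncentrality
qt_noncentral <- function(prob, df, ncp) {
  q <- withCallingHandlers(
    qt(prob, df = df, ncp = ncp),
    warning = function(w) invokeRestart("muffleWarning"))
  bad <- which(!is.finite(q))
  for (i in bad) {
    lo <- ncp[i] - 20 * (1 + ncp[i] / sqrt(df))
    hi <- ncp[i] + 20 * (1 + ncp[i] / sqrt(df))
    q[i] <- tryCatch(
      uniroot(function(t) suppressWarnings(pt(t, df, ncp[i])) - prob,
              c(lo, hi), extendInt = "upX", tol = 1e-10)$root,
      error = function(e) NaN)
  }
  q
}

#' Standard-error factor of a fitted mean in simple regression
#'
#' The factor `c(x) = sqrt(1/n + (x - x_bar)^2 / Sxx)` multiplying the
#' residual SD in the standard error of the fitted mean at covariate
#' value `x`. It also sets the noncentrality of the tolerance-bound
#' construction through `delta(x) = z_p / c(x)`.
#'
#' @param fit A [fit_simple_ols()] object.
#' @param x Covariate value(s).
#'
#' @return Numeric vector of factors.
#' @export
c_factor <- function(fit, x) {
  stopifnot(inherits(fit, "geotol_ols"))
  sqrt(1 / fit$n + (x - fit$x_bar)^2 / fit$Sxx)
}

#' Confidence interval for mean log error magnitude at a covariate value
#'
#' Two-sided 100(1 - alpha)% interval for the expected log magnitude at
#' `x`: `(alpha_hat + beta_hat x) +/- t_{alpha/2, n-2} * s * c(x)`.
#' Intervals are computed on the log scale and exponentiated to meters.
#'
#' @param fit A [fit_simple_ols()] object fitted to log magnitudes.
#' @param x Covariate value(s).
#' @param alpha Two-sided error level in (0, 1).
#'
#' @return Tibble, one row per `x`: `x`, `kind`, `level`, `fit_log`,
#'   `lower_log`, `upper_log`, `fit_m`, `lower_m`, `upper_m`.
#' @export
confidence_interval_mean <- function(fit, x, alpha = 0.05) {
  stopifnot(inherits(fit, "geotol_ols"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("alpha must be in (0, 1)")
  cx <- c_factor(fit, x)
  mid <- predict(fit, x)
  hw <- qt(1 - alpha / 2, fit$n - 2) * sqrt(fit$s2) * cx
  tibble(x = x, kind = "confidence", level = 1 - alpha,
         fit_log = mid, lower_log = mid - hw, upper_log = mid + hw,
         fit_m = exp(mid), lower_m = exp(mid - hw), upper_m = exp(mid + hw))
}

#' Upper tolerance bound for a proportion of error magnitudes
#'
#' One-sided upper 100(1 - alpha)% tolerance bound for the lower
#' 100(1 - p)% of the population of error magnitudes at covariate value
#' `x`:
#' `(alpha_hat + beta_hat x) + t_{1 - alpha; n - 2; delta(x)} * s * c(x)`
#' with noncentrality `delta(x) = z_p / c(x)`, where `z_p` is the
#' 100(1 - p)th standard normal percentile. Computed on the log scale
#' and exponentiated to meters.
#'
#' Unlike a confidence limit for the mean, the bound covers an entire
#' lower fraction `1 - p` of the conditional distribution, so it is much
#' larger than the upper confidence limit at the same levels.
#'
#' @param fit A [fit_simple_ols()] object fitted to log magnitudes.
#' @param x Covariate value(s).
#' @param alpha One-sided confidence error level in (0, 1).
#' @param p Excluded upper tail proportion in (0, 1); the bound covers
#'   the lower `1 - p` of the population.
#'
#' @return Tibble, one row per `x`: `x`, `kind`, `level`, `content`,
#'   `fit_log`, `bound_log`, `fit_m`, `bound_m`.
#' @export
tolerance_bound_upper <- function(fit, x, alpha = 0.05, p = 0.05) {
  stopifnot(inherits(fit, "geotol_ols"))
  if (alpha <= 0 || alpha >= 1 || p <= 0 || p >= 1)
    abort("alpha and p must be in (0, 1)")
  cx <- c_factor(fit, x)
  mid <- predict(fit, x)
  delta <- qnorm(1 - p) / cx
  tq <- qt_noncentral(1 - alpha, df = fit$n - 2, ncp = delta)
  if (any(!is.finite(tq)))
    abort("noncentral t quantile did not evaluate (extreme noncentrality)")
  bound <- mid + tq * sqrt(fit$s2) * cx
  tibble(x = x, kind = "tolerance", level = 1 - alpha, content = 1 - p,
         fit_log = mid, bound_log = bound,
         fit_m = exp(mid), bound_m = exp(bound))
}

#' Confidence limits and tolerance bounds at covariate percentiles
#'
#' For each rurality group, fits log error magnitude on the group's most
#' informative covariate (street segment length for municipal addresses,
#' street intersection density for rural ones), evaluates the two-sided
#' confidence interval for the mean and the one-sided upper tolerance
#' bound at chosen empirical percentiles of that covariate, and reports
#' everything in meters.
#'
#' @param data Tibble with columns `rurality`, `seg_length_m`,
#'   `density_per_sqmi`, `magnitude_m`.
#' @param alpha Error level for both interval kinds.
#' @param p Excluded upper tail proportion for the tolerance bound.
#' @param probs Covariate percentiles at which to evaluate.
#'
#' @return Tibble with columns `rurality`, `covariate`, `prob`,
#'   `covariate_value`, `ci_lower_m`, `ci_upper_m`, `tolerance_bound_m`.
#' @export
tolerance_report <- function(data, alpha = 0.05, p = 0.05,
                             probs = c(0.10, 0.50, 0.90)) {
  spec <- list(municipal = "seg_length_m", rural = "density_per_sqmi")
  out <- purrr::imap(spec, function(covar, g) {
    sub <- data[data$rurality == g, ]
    if (nrow(sub) < 3) return(NULL)
    xv <- sub[[covar]]
    fit <- fit_simple_ols(log(sub$magnitude_m), xv)
    at <- unname(quantile(xv, probs))
    ci <- confidence_interval_mean(fit, at, alpha)
    tb <- tolerance_bound_upper(fit, at, alpha, p)
    tibble(rurality = g,
           covariate = if (covar == "seg_length_m") "length" else "density",
           prob = probs, covariate_value = at,
           ci_lower_m = ci$lower_m, ci_upper_m = ci$upper_m,
           tolerance_bound_m = tb$bound_m)
  })
  bind_rows(out)
}
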