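#' Pearson correlation with a two-sided test
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#'
#' @return One-row tibble with columns `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Simple linear regression of log error magnitude on one covariate
#'
#' Ordinary least squares fit of `y = alpha + beta * x + e`, retaining
#' exactly the summaries the pointwise interval machinery needs: the
#' estimates, the mean squared error `s2` (denominator `n - 2`), `n`,
#' the covariate mean `x_bar` and the corrected sum of squares `Sxx`.
#'
#' @param y Response vector (log error magnitudes, log meters).
#' @param x Covariate vector (same length, non-constant).
#'
#' @return An object of class `geotol_ols` with fields `alpha_hat`,
#'   `beta_hat`, `s2`, `n`, `x_bar`, `Sxx`, `r_squared`, `residuals`.
#' @seealso [confidence_interval_mean()], [tolerance_bound_upper()]
#' @export
fit_simple_ols <- function(y, x) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(y)
  if (n < 3) abort("need at least 3 observations")
  Sxx <- sum((x - mean(x))^2)
  if (Sxx <= 0) abort("covariate is constant: singular design")
  fit <- lm.fit(cbind(`(Intercept)` = 1, x = x), y)
  res <- unname(fit$residuals)
  s2 <- sum(res^2) / (n - 2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(alpha_hat = unname(fit$coefficients[1]),
         beta_hat = unname(fit$coefficients[2]),
         s2 = s2, n = n, x_bar = mean(x), Sxx = Sxx,
         r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
         residuals = res),
    class = "geotol_ols")
}

#' @export
print.geotol_ols <- function(x, ...) {
  cat(sprintf("<geotol_ols> y = %.4f %+.6f x  (n = %d, s = %.4f, R2 = %.3f)\n",
              x$alpha_hat, x$beta_hat, x$n, sqrt(x$s2), x$r_squared))
  invisible(x)
}

#' Fitted mean of a simple OLS model at new covariate values
#'
#' @param object A [fit_simple_ols()] object.
#' @param x Covariate values.
#' @param ... Unused.
#' @return Fitted values `alpha_hat + beta_hat * x`.
#' @export
predict.geotol_ols <- function(object, x, ...) {
  object$alpha_hat + object$beta_hat * x
}

#' @export
tidy.geotol_ols <- function(x, ...) {
  se <- sqrt(x$s2 * c(1 / x$n + x$x_bar^2 / x$Sxx, 1 / x$Sxx))
  est <- c(x$alpha_hat, x$beta_hat)
  stat <- est / se
  tibble(term = c("(Intercept)", "x"), estimate = est, std.error = se,
         statistic = stat,
         p.value = 2 * stats::pt(abs(stat), x$n - 2, lower.tail = FALSE))
}

#' @export
glance.geotol_ols <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = sqrt(x$s2), nobs = x$n,
         df.residual = x$n - 2)
}

#' One-factor ANOVA of log error magnitude on rurality
#'
#' Partitions the variation of log positional error magnitude between and
#' within the rural/municipal groups. The fraction explained equals the
#' R-squared of the regression of log magnitude on a rurality indicator.
#'
#' @param data Tibble with columns `rurality` and `magnitude_m`.
#'
#' @return One-row tibble: `fraction_explained`, `statistic` (F), and
#'   `p_value`.
#' @export
anova_rurality <- function(data) {
  grp <- factor(data$rurality)
  if (nlevels(grp) < 2) abort("both rurality groups must be present")
  if (any(table(grp) < 2)) abort("each group needs at least 2 records")
  y <- log(data$magnitude_m)
  av <- summary(aov(y ~ grp))[[1]]
  ss <- av[["Sum Sq"]]
  tibble(fraction_explained = ss[1] / sum(ss),
         statistic = av[["F value"]][1],
         p_value = av[["Pr(>F)"]][1])
}

#' Partial correlation of y and x1 adjusted for x2
#'
#' Correlates the residuals of `y ~ x2` with the residuals of `x1 ~ x2`.
#'
#' @param y,x1,x2 Numeric vectors of equal length (>= 4).
#'
#' @return One-row tibble with `r_partial`, `p_value`, `n`. When `y` is
#'   (numerically) an exact linear function of `x2`, the residuals are
#'   degenerate and the result is flagged: `r_partial` is `NA` and
#'   `degenerate` is `TRUE`.
#' @export
partial_correlation <- function(y, x1, x2) {
  n <- length(y)
  if (length(x1) != n || length(x2) != n) abort("inputs must have equal length")
  if (n < 4) abort("need at least 4 observations")
  if (sd(x2) == 0) abort("adjustment covariate x2 is constant")
  r12 <- resid(lm(x1 ~ x2))
  if (sd(r12) < 1e-10 * sd(x1)) abort("x1 and x2 are collinear")
  ry2 <- resid(lm(y ~ x2))
  if (sd(ry2) < 1e-10 * max(sd(y), 1e-300))
    return(tibble(r_partial = NA_real_, p_value = NA_real_, n = n,
                  degenerate = TRUE))
  ct <- cor.test(ry2, r12)
  tibble(r_partial = unname(ct$estimate), p_value = ct$p.value, n = n,
         degenerate = FALSE)
}

#' Full interaction model for log error magnitude
#'
#' Fits log magnitude on rurality, street segment length and street
#' intersection density with all two-way interactions and the three-way
#' interaction (8 coefficients including the intercept), on raw covariate
#' scales.
#'
#' @param data Tibble with columns `rurality`, `seg_length_m`,
#'   `density_per_sqmi`, `magnitude_m`.
#'
#' @return An object of class `geotol_lm` wrapping the `lm` fit, with
#'   `r_squared`, `s2` and `n`.
#' @export
fit_interaction_model <- function(data) {
  if (length(unique(data$rurality)) < 2)
    abort("design is rank deficient: column rurality is constant")
  fit <- lm(log(magnitude_m) ~ rurality * seg_length_m * density_per_sqmi,
            data = data)
  ali <- is.na(coef(fit))
  if (any(ali))
    abort(sprintf("design is rank deficient: column %s is aliased",
                  names(coef(fit))[ali][1]))
  sm <- summary(fit)
  structure(list(fit = fit, r_squared = sm$r.squared,
                 s2 = sm$sigma^2, n = nrow(data)),
            class = "geotol_lm")
}

#' @export
print.geotol_lm <- function(x, ...) {
  cat(sprintf("<geotol_lm> interaction model, n = %d, R2 = %.3f\n",
              x$n, x$r_squared))
  invisible(x)
}

#' @export
tidy.geotol_lm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @export
glance.geotol_lm <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = sqrt(x$s2), nobs = x$n,
         df.residual = x$fit$df.residual)
}

#' Percent change in mean magnitude per covariate increment
#'
#' Translates a slope on the log scale into the percent change in (geometric)
#' mean error magnitude for an increment `delta` of the covariate:
#' `100 * (exp(beta * delta) - 1)`.
#'
#' @param beta Slope of log magnitude per covariate unit.
#' @param delta Covariate increment.
#'
#' @return Percent change (positive = increase).
#' @export
#' @examples
#' percent_effect(log(1.21) / 100, 100)  # 21
percent_effect <- function(beta, delta) {
  if (!all(is.finite(beta)) || !all(is.finite(delta)))
    abort("beta and delta must be finite")
  100 * (exp(beta * delta) - 1)
}
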