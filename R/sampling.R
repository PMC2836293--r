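# anisotropy: the generated error direction is (along, cross) =
# (k|Z1|, |Z2|) / norm with Z iid standard normal, so the direction
# depends only on the angle of an isotropic normal vector and the map
# from the half-normal scale ratio k to the realized ratio of mean
# component magnitudes has an exact one-dimensional integral form.
mean_component_ratio <- function(k) {
  Eu <- integrate(function(th) k * cos(th) / sqrt(k^2 * cos(th)^2 + sin(th)^2),
                  0, pi / 2, rel.tol = 1e-10)$value
  Ev <- integrate(function(th) sin(th) / sqrt(k^2 * cos(th)^2 + sin(th)^2),
                  0, pi / 2, rel.tol = 1e-10)$value
  Eu / Ev
}

.aniso_cache <- new.env(parent = emptyenv())

# invert mean_component_ratio (memoized; ratio 1 maps to k = 1)
aniso_scale <- function(ratio) {
  key <- sprintf("%.12g", ratio)
  if (!is.null(.aniso_cache[[key]])) return(.aniso_cache[[key]])
  k <- if (ratio <= 1 + 1e-12) 1 else
    uniroot(function(k) mean_component_ratio(k) - ratio,
            c(1 + 1e-9, 1e4), tol = 1e-9)$root
  .aniso_cache[[key]] <- k
  k
}

draw_covariate <- function(d, z) {
  if (d$kind == "point") rep(d$value, length(z))
  else d$shift + qlnorm(pnorm(z), d$meanlog, d$sdlog)
}

# latent Gaussian correlation that yields a target Pearson correlation
# between two (shifted) lognormal covariates; exact via the lognormal
# moment formula, identity for point masses
latent_rho <- function(target, d1, d2) {
  if (target == 0 || d1$kind == "point" || d2$kind == "point") return(target)
  s1 <- d1$sdlog; s2 <- d2$sdlog
  denom <- sqrt(expm1(s1^2) * expm1(s2^2))
  inner <- 1 + target * denom
  if (inner <= 0)
    abort("target covariate correlation is unattainable for these marginals")
  rho <- log(inner) / (s1 * s2)
  if (abs(rho) >= 1)
    abort("target covariate correlation is unattainable for these marginals")
  rho
}

#' Draw covariates for synthetic addresses
#'
#' Samples rurality-stratified covariates: street axial orientation
#' (group-specific proportions), street segment length and street
#' intersection density. Length and density are drawn through a Gaussian
#' copula calibrated so their Pearson correlation matches the group's
#' `cov_cor`, while their marginals come from the configured
#' distributions -- reproducing the weak negative association between
#' the two street network measures.
#'
#' Draws are taken from the current RNG state; use [generate_dataset()]
#' for a fully seeded dataset.
#'
#' @param config A [generator_config()].
#'
#' @return A tibble with columns `rurality`, `orientation`,
#'   `seg_length_m`, `density_per_sqmi`.
#' @export
sample_covariates <- function(config) {
  validate_generator_config(config)
  one_group <- function(g, n) {
    if (n == 0L)
      return(tibble(rurality = character(), orientation = character(),
                    seg_length_m = numeric(), density_per_sqmi = numeric()))
    rho <- latent_rho(config$cov_cor[[g]], config$length_dist[[g]],
                      config$density_dist[[g]])
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    len <- draw_covariate(config$length_dist[[g]], z1)
    den <- draw_covariate(config$density_dist[[g]], z2)
    pr <- config$orientation_probs[[g]][c("NS", "EW", "DIAG")]
    ori <- sample(c("NS", "EW", "DIAG"), n, replace = TRUE, prob = pr)
    tibble(rurality = g, orientation = ori,
           seg_length_m = len, density_per_sqmi = den)
  }
  bind_rows(one_group("rural", config$n_rural),
            one_group("municipal", config$n_municipal))
}

#' Attach positional error vectors to sampled covariates
#'
#' For each address, log error magnitude is drawn from the group's linear
#' model `log_intercept + beta_length * length + beta_density * density`
#' plus Normal(0, sigma^2) noise, truncated above at
#' `log(max_magnitude)` (errors cannot exceed the study region's spatial
#' extent). The magnitude `exp(L)` is then split into an along-street and
#' a cross-street component: a half-normal direction pair with scale
#' ratio chosen so mean along-street displacement is `anisotropy_ratio`
#' times mean cross-street displacement, renormalized so the vector norm
#' equals the magnitude exactly, with independent random signs. The
#' components map to (dx, dy) by street orientation (NS streets put the
#' along component on dy, EW on dx, DIAG at 45 degrees).
#'
#' @param covariates Tibble from [sample_covariates()] (non-empty).
#' @param config A [generator_config()].
#'
#' @return The covariate tibble with columns `id`, `dx_m`, `dy_m`,
#'   `magnitude_m` added.
#' @export
sample_positional_errors <- function(covariates, config) {
  validate_generator_config(config)
  if (nrow(covariates) == 0) abort("covariate table is empty")
  bad <- setdiff(unique(covariates$orientation), c("NS", "EW", "DIAG"))
  if (length(bad))
    abort(sprintf("unknown orientation label(s): %s",
                  paste(bad, collapse = ", ")))

  g <- covariates$rurality
  m <- unname(config$log_intercept[g] +
                config$beta_length[g] * covariates$seg_length_m +
                config$beta_density[g] * covariates$density_per_sqmi)
  sig <- unname(config$sigma[g])
  cap <- log(config$max_magnitude)
  nrec <- nrow(covariates)

  # truncated-normal noise by inverse CDF (one uniform per record)
  upper <- ifelse(sig > 0, pnorm((cap - m) / pmax(sig, 1e-300)), 1)
  if (any(upper <= 0))
    abort("magnitude cap is below the model mean for some records")
  eps <- ifelse(sig > 0, qnorm(runif(nrec) * upper) * sig, 0)
  L <- pmin(m + eps, cap)  # guard against qnorm rounding at the cap
  magnitude <- exp(L)

  k <- aniso_scale(config$anisotropy_ratio)
  a <- k * abs(rnorm(nrec))
  c_ <- abs(rnorm(nrec))
  nrm <- sqrt(a^2 + c_^2)
  along <- (a / nrm) * sign(runif(nrec) - 0.5) * magnitude
  cross <- (c_ / nrm) * sign(runif(nrec) - 0.5) * magnitude

  ori <- covariates$orientation
  dx <- ifelse(ori == "NS", cross,
               ifelse(ori == "EW", along, (along - cross) / sqrt(2)))
  dy <- ifelse(ori == "NS", along,
               ifelse(ori == "EW", cross, (along + cross) / sqrt(2)))

  out <- covariates
  out$dx_m <- dx
  out$dy_m <- dy
  out$magnitude_m <- magnitude
  out$id <- seq_len(nrec)
  out[, c("id", "rurality", "orientation", "seg_length_m",
          "density_per_sqmi", "dx_m", "dy_m", "magnitude_m")]
}

#' Generate a seeded synthetic geocoding-error dataset
#'
#' Draws covariates and positional error vectors for
#' `n_rural + n_municipal` addresses under the configured error model.
#' The run is fully determined by `config$seed`: the same configuration
#' always yields the identical table.
#'
#' @param config A [generator_config()]; the default reproduces the
#'   structure of a ground-truthed county address file with 6376
#'   addresses (1421 rural, 4955 municipal).
#'
#' @return A tibble with columns `id`, `rurality`, `orientation`,
#'   `seg_length_m`, `density_per_sqmi`, `dx_m`, `dy_m`, `magnitude_m`.
#' @export
#' @examples
#' errs <- generate_dataset(generator_config(n_rural = 50, n_municipal = 150))
#' dplyr::count(errs, rurality)
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  with_seed(config$seed, {
    cov <- sample_covariates(config)
    sample_positional_errors(cov, config)
  })
}
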