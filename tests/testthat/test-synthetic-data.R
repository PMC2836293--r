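test_that("generator configuration is validated", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_rural = -1), "non-negative")
  expect_error(generator_config(anisotropy_ratio = 0.5), "anisotropy")
  expect_error(generator_config(max_magnitude = 0), "max_magnitude")
  expect_error(
    generator_config(orientation_probs = list(
      rural = c(NS = 0.7, EW = 0.7, DIAG = 0),
      municipal = c(NS = 0.4, EW = 0.4, DIAG = 0.2))),
    "sum to 1")
  expect_error(generator_config(sigma = c(rural = -1, municipal = 0.7)),
               "sigma")
})

test_that("covariate distributions quantile correctly", {
  d <- dist_from_percentiles(0.64, 1.59, 7.00)
  expect_equal(quantile(d, c(0.1, 0.5, 0.9)), c(0.64, 1.59, 7.00),
               tolerance = 1e-10)
  expect_equal(quantile(dist_point(5), c(0.1, 0.9)), c(5, 5))
})

test_that("datasets are reproducible and schema-complete", {
  cfg <- tiny_config()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_named(d1, c("id", "rurality", "orientation", "seg_length_m",
                     "density_per_sqmi", "dx_m", "dy_m", "magnitude_m"))
  expect_equal(nrow(d1), 800)
  d3 <- generate_dataset(tiny_config(seed = 12L))
  expect_false(identical(d1$magnitude_m, d3$magnitude_m))
})

test_that("the default configuration yields the full address file size", {
  cfg <- generator_config()
  expect_equal(cfg$n_rural + cfg$n_municipal, 6376L)
  d <- generate_dataset(generator_config(seed = 5L))
  expect_equal(nrow(d), 6376L)
  expect_equal(sum(d$rurality == "rural"), 1421L)
  # rural addresses lie on axial streets only
  expect_true(all(d$orientation[d$rurality == "rural"] %in% c("NS", "EW")))
})

test_that("magnitude equals the Euclidean norm of the error vector", {
  d <- generate_dataset(tiny_config())
  expect_equal(sqrt(d$dx_m^2 + d$dy_m^2), d$magnitude_m, tolerance = 1e-12)
  expect_true(all(d$magnitude_m > 0))
})

test_that("degenerate configs hit the deterministic limit", {
  cfg <- degenerate_config()
  d <- generate_dataset(cfg)
  expect_true(all(d$seg_length_m %in% c(1600, 130)))
  expect_true(all(d$density_per_sqmi %in% c(1.6, 30)))
  lim <- exp(cfg$log_intercept)
  expect_equal(unique(d$magnitude_m[d$rurality == "rural"]),
               unname(lim["rural"]), tolerance = 1e-12)
  expect_equal(unique(d$magnitude_m[d$rurality == "municipal"]),
               unname(lim["municipal"]), tolerance = 1e-12)
})

test_that("unknown orientation labels are rejected", {
  cfg <- tiny_config()
  cov <- sample_covariates(cfg)
  cov$orientation[1] <- "NE"
  expect_error(sample_positional_errors(cov, cfg), "unknown orientation")
  expect_error(sample_positional_errors(cov[0, ], cfg), "empty")
})

test_that("covariate marginals reproduce their calibration percentiles", {
  set.seed(91)
  cov <- sample_covariates(generator_config(n_rural = 60000,
                                            n_municipal = 60000))
  mun_len <- cov$seg_length_m[cov$rurality == "municipal"]
  expect_equal(median(mun_len), 127.8, tolerance = 0.05)
  rur_den <- cov$density_per_sqmi[cov$rurality == "rural"]
  expect_equal(unname(quantile(rur_den, 0.9)), 7.00, tolerance = 0.10)
  expect_equal(median(rur_den), 1.59, tolerance = 0.05)
  # copula hits the target length-density correlation
  r <- cor(cov$seg_length_m[cov$rurality == "rural"], rur_den)
  expect_equal(r, -0.19, tolerance = 0.03 / 0.19)
})

test_that("group magnitude statistics match the calibration targets", {
  # x10 scale for stable means
  d <- generate_dataset(generator_config(n_rural = 14210,
                                         n_municipal = 49550, seed = 23L))
  rur <- d$magnitude_m[d$rurality == "rural"]
  mun <- d$magnitude_m[d$rurality == "municipal"]
  expect_equal(mean(rur), 333, tolerance = 0.05)
  expect_equal(mean(mun), 68, tolerance = 0.05)
  expect_equal(mean(d$magnitude_m), 127, tolerance = 0.05)
  # medians are close but not exactly reconcilable with the slope anchors
  expect_equal(median(rur), 168, tolerance = 0.15)
  expect_equal(median(mun), 53, tolerance = 0.15)
  expect_true(all(d$magnitude_m <= 3000))
})

test_that("errors cluster along the street axis at the calibrated ratio", {
  d <- generate_dataset(generator_config(n_rural = 30000,
                                         n_municipal = 30000, seed = 29L))
  for (g in c("rural", "municipal")) {
    ns <- d[d$rurality == g & d$orientation == "NS", ]
    ew <- d[d$rurality == g & d$orientation == "EW", ]
    rat_ns <- mean(abs(ns$dy_m)) / mean(abs(ns$dx_m))
    rat_ew <- mean(abs(ew$dx_m)) / mean(abs(ew$dy_m))
    expect_gt(rat_ns, 2); expect_lt(rat_ns, 3.5)
    expect_gt(rat_ew, 2); expect_lt(rat_ew, 3.5)
  }
  # rural N-S anchor: mean |dy| / mean |dx| near 3.1
  ns <- d[d$rurality == "rural" & d$orientation == "NS", ]
  expect_equal(mean(abs(ns$dy_m)) / mean(abs(ns$dx_m)), 3.1,
               tolerance = 0.05)
})

test_that("log magnitudes are normal about the model line per group", {
  cfg <- generator_config(n_rural = 20000, n_municipal = 20000, seed = 31L)
  d <- generate_dataset(cfg)
  for (g in c("rural", "municipal")) {
    sub <- d[d$rurality == g, ]
    mu <- cfg$log_intercept[[g]] +
      cfg$beta_length[[g]] * sub$seg_length_m +
      cfg$beta_density[[g]] * sub$density_per_sqmi
    z <- (log(sub$magnitude_m) - mu) / cfg$sigma[[g]]
    sk <- mean((z - mean(z))^3) / sd(z)^3
    ku <- mean((z - mean(z))^4) / sd(z)^4 - 3
    expect_lt(abs(sk), 0.15)   # cap truncation skews rural slightly
    expect_lt(abs(ku), 0.30)
  }
})

test_that("OLS on generated data recovers the generator slopes", {
  d <- generate_dataset(generator_config(n_rural = 25000,
                                         n_municipal = 25000, seed = 37L))
  cfg <- generator_config()
  rur <- d[d$rurality == "rural", ]
  fit_r <- fit_simple_ols(log(rur$magnitude_m), rur$density_per_sqmi)
  se_r <- sqrt(fit_r$s2 / fit_r$Sxx)
  expect_lt(abs(fit_r$beta_hat - cfg$beta_density[["rural"]]), 3 * se_r + 0.002)
  mun <- d[d$rurality == "municipal", ]
  fit_m <- fit_simple_ols(log(mun$magnitude_m), mun$seg_length_m)
  se_m <- sqrt(fit_m$s2 / fit_m$Sxx)
  expect_lt(abs(fit_m$beta_hat - cfg$beta_length[["municipal"]]), 3 * se_m)
})
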