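rmvn2 <- function(n, sd = c(1, 1), rho = 0) {
  z <- matrix(rnorm(2 * n), ncol = 2)
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  sweep(z, 2, sd, `*`)
}

test_that("the classical radius converges to the central chi-square limit", {
  r2 <- john_radius2(1e7, 0.05, 0.05, calibrate = FALSE)
  expect_equal(r2, qchisq(0.95, 2), tolerance = 2e-3)
  # finite-sample thresholds exceed the limit
  expect_gt(john_radius2(50, 0.05, 0.05, calibrate = FALSE), qchisq(0.95, 2))
})

test_that("normal mass of an ellipse integrates correctly", {
  # centered circle under the standard normal: chi-square df 2 content
  e <- geotol:::new_tolerance_ellipse(c(0, 0), diag(2), qchisq(0.9, 2),
                                      "john", 0.05, 0.05, 10)
  expect_equal(ellipse_normal_mass(e), 0.9, tolerance = 1e-6)
  # shifted circle: noncentral chi-square content
  e2 <- geotol:::new_tolerance_ellipse(c(1, 1), diag(2), 3, "john",
                                       0.05, 0.05, 10)
  expect_equal(ellipse_normal_mass(e2), pchisq(3, 2, ncp = 2),
               tolerance = 1e-6)
  # general sigma via Monte Carlo cross-check
  sh <- rbind(c(2, 0.5), c(0.5, 1))
  e3 <- geotol:::new_tolerance_ellipse(c(0.3, -0.2), sh, 4, "john",
                                       0.05, 0.05, 10)
  sig <- rbind(c(1.5, -0.3), c(-0.3, 0.8))
  set.seed(33)
  z <- rmvn2(2e5)
  ch <- chol(sig)
  pts <- z %*% ch
  expect_equal(ellipse_normal_mass(e3, c(0, 0), sig),
               mean(region_contains(e3, pts)), tolerance = 0.01)
})

test_that("normality-based regions hold their confidence coefficient", {
  n <- 50; reps <- 2000
  r2 <- john_radius2(n, 0.05, 0.05)      # calibrated threshold
  set.seed(55)
  hits <- 0
  for (i in seq_len(reps)) {
    y <- rmvn2(n)
    ell <- john_tolerance_region(y, 0.05, 0.05)
    if (ellipse_normal_mass(ell) >= 0.95) hits <- hits + 1
  }
  cover <- hits / reps
  mc_se <- sqrt(0.95 * 0.05 / reps)
  expect_lt(abs(cover - 0.95), 2 * mc_se)
  expect_equal(john_tolerance_region(rmvn2(n))$radius2, r2)
})

test_that("region orientation follows the data anisotropy", {
  set.seed(60)
  y <- rmvn2(600, sd = c(1, 3))          # major axis along the y-axis
  ell <- john_tolerance_region(y, n_calib = 500)
  td <- tidy(ell)
  expect_lt(min(abs(td$angle_deg - 90), abs(td$angle_deg - 270)), 10)
  expect_gt(td$semi_major / td$semi_minor, 2)
})

test_that("degenerate samples are rejected", {
  expect_error(john_tolerance_region(rbind(c(0, 0), c(1, 1))), "at least 3")
  line <- cbind(1:10, 2 * (1:10))
  expect_error(john_tolerance_region(line), "singular")
})

test_that("the normality-based region is affine equivariant", {
  set.seed(62)
  y <- rmvn2(80, sd = c(2, 1), rho = 0.4)
  A <- rbind(c(1.5, 0.7), c(-0.3, 1.1)); b <- c(5, -2)
  e1 <- john_tolerance_region(y, n_calib = 500)
  e2 <- john_tolerance_region(sweep(y %*% t(A), 2, b, `+`), n_calib = 500)
  expect_equal(e2$center, drop(A %*% e1$center + b), tolerance = 1e-8)
  expect_equal(e2$shape, A %*% e1$shape %*% t(A), tolerance = 1e-8)
  expect_equal(e2$radius2, e1$radius2)
  # membership verdicts transfer through the map
  set.seed(63)
  pts <- rmvn2(200, sd = c(3, 3))
  expect_equal(region_contains(e2, sweep(pts %*% t(A), 2, b, `+`)),
               region_contains(e1, pts))
})

test_that("the order-statistic count matches its closed form", {
  expect_equal(mve_count(600, 0.05, 0.05), 578L)
  # alpha = 0.5: z = 0, plain floor of n(1-p)
  expect_equal(mve_count(100, 0.5, 0.05), 95L)
  expect_equal(mve_count(101, 0.5, 0.10), floor(101 * 0.9))
  # p -> 0: all points required (capped at n)
  expect_equal(mve_count(50, 0.05, 1e-9), 50L)
  expect_error(mve_count(2, 0.05, 0.05), "n >= 3")
  expect_error(mve_count(4, 0.5, 0.9), "below 3")
})

test_that("points on a circle are recovered by the resampled ellipse", {
  # 48 evenly spaced points: equilateral 3-subsets exist, so the
  # subsample search can reproduce the circle (area pi) exactly
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  y <- cbind(cos(th), sin(th))
  ell <- mve_tolerance_region(y, alpha = 0.5, p = 1e-9,
                              n_resamples = choose(48, 3))
  expect_equal(ellipse_area(ell), pi, tolerance = 0.05)
  expect_true(all(region_contains(ell, y)))
})

test_that("small-sample search equals an exhaustive subsample oracle", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    for (n in c(10, 12)) {
      y <- rmvn2(n)
      m <- mve_count(n, 0.5, 0.2)
      ell <- mve_tolerance_region(y, alpha = 0.5, p = 0.2,
                                  n_resamples = choose(n, 3))
      # independent oracle: scan every 3-subset with full inflation
      best <- Inf
      for (cols in asplit(combn(n, 3), 2)) {
        P <- y[cols, , drop = FALSE]
        S <- cov(P)
        if (det(S) <= 1e-12) next
        d2 <- stats::mahalanobis(y, colMeans(P), S)
        r2 <- sort(d2)[m]
        best <- min(best, pi * sqrt(det(S)) * r2)
      }
      expect_equal(ellipse_area(ell), best, tolerance = 1e-10)
      expect_gte(empirical_content(ell, y), m / n)
    }
  }
})

test_that("longer resampling never yields a larger ellipse", {
  set.seed(71)
  y <- rmvn2(40)
  a1 <- ellipse_area(mve_tolerance_region(y, n_resamples = 150, seed = 9))
  a2 <- ellipse_area(mve_tolerance_region(y, n_resamples = 600, seed = 9))
  expect_lte(a2, a1)
  # same seed and length reproduce the same region
  e1 <- mve_tolerance_region(y, n_resamples = 300, seed = 4)
  e2 <- mve_tolerance_region(y, n_resamples = 300, seed = 4)
  expect_identical(e1, e2)
})

test_that("membership is closed at the boundary and matches the form", {
  sh <- rbind(c(2, 0.3), c(0.3, 1))
  ell <- geotol:::new_tolerance_ellipse(c(1, 2), sh, 3, "john", .05, .05, 10)
  expect_true(region_contains(ell, c(1, 2)))
  # a point exactly on the boundary is inside
  dirv <- c(1, 1) / sqrt(2)
  lam <- sqrt(3 / drop(t(dirv) %*% solve(sh) %*% dirv))
  expect_true(region_contains(ell, c(1, 2) + lam * dirv))
  expect_false(region_contains(ell, c(1, 2) + 1.01 * lam * dirv))
  set.seed(77)
  pts <- rmvn2(300, sd = c(3, 3))
  d2 <- stats::mahalanobis(pts, ell$center, ell$shape)
  expect_equal(region_contains(ell, pts), d2 <= 3 + 1e-9)
})

test_that("extreme outliers dilate the normal region but not the MVE", {
  # a concentration of extreme outliers (at a rate the order-statistic
  # count can exclude) inflates the sample covariance and hence the
  # normality-based region, while the minimum-volume ellipse stays close
  # to the clean-data region and ends up the smaller of the two
  smaller <- 0
  for (seed in 1:8) {
    set.seed(300 + seed)
    z <- rmvn2(600)
    out <- runif(600) < 0.03
    y <- z * ifelse(out, 8, 1)
    jo <- john_tolerance_region(y, n_calib = 500)
    jo_clean <- john_tolerance_region(z, n_calib = 500)
    mv <- mve_tolerance_region(y, n_resamples = 2000, seed = seed)
    expect_gt(ellipse_area(jo), 1.5 * ellipse_area(jo_clean))
    if (ellipse_area(mv) < ellipse_area(jo)) smaller <- smaller + 1
    expect_true(region_contains(jo, colMeans(y)))
    expect_true(region_contains(mv, colMeans(y)))
  }
  expect_gte(smaller, 4)
})

test_that("stratified regions skip undersized strata with a warning", {
  d <- generate_dataset(tiny_config(n_rural = 6, n_municipal = 200,
                                    seed = 13L))
  w <- capture_warnings(
    reg <- stratified_regions(d, n_resamples = 200, n_calib = 300))
  expect_length(w, 2)            # both undersized rural strata
  expect_true(all(grepl("skipped", w)))
  expect_true(all(reg$rurality == "municipal"))
  expect_setequal(reg$orientation, c("NS", "EW"))
  expect_s3_class(reg$john[[1]], "tolerance_ellipse")
  expect_s3_class(reg$mve[[1]], "tolerance_ellipse")
  i <- which(reg$orientation == "NS")
  expect_gte(empirical_content(
    reg$mve[[i]], d[d$rurality == "municipal" & d$orientation == "NS", ]),
    reg$mve[[i]]$n_points_required / reg$mve[[i]]$n)
})

test_that("plot helpers return well-formed objects", {
  set.seed(80)
  y <- rmvn2(50)
  ell <- john_tolerance_region(y, n_calib = 300)
  bd <- ellipse_boundary(ell, 73)
  expect_equal(nrow(bd), 73)
  # boundary points lie on the quadratic form surface
  d2 <- stats::mahalanobis(cbind(bd$x, bd$y), ell$center, ell$shape)
  expect_equal(d2, rep(ell$radius2, 73), tolerance = 1e-8)
  expect_s3_class(autoplot(ell, data = y), "ggplot")
})
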