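test_that("slab extraction keeps the breast-height band of a bare stem", {
  sl_cloud <- sample_cylinder_slab(z_range = c(0, 3), n = 5000,
                                   rng_seed = 51)
  slab <- extract_slab(sl_cloud, ground_z = 0)
  h <- slab$cloud$points$Z
  expect_true(all(h >= 1.0 & h <= 1.6))
  expect_gte(npoints(slab$cloud), 50)
  # translation covariance: shifting ground and cloud together is a no-op
  shifted <- sl_cloud
  shifted$points$Z <- shifted$points$Z + 1
  slab2 <- extract_slab(shifted, ground_z = 1)
  expect_equal(slab2$cloud$points$Z, slab$cloud$points$Z + 1)
  expect_equal(slab2$cloud$points$X, slab$cloud$points$X)
  expect_error(extract_slab(sample_cylinder_slab(n = 30, rng_seed = 1),
                            ground_z = 0, center = 10), "insufficient")
})

test_that("slab extraction drops a detached foliage blob", {
  stem <- sample_cylinder_slab(z_range = c(0.9, 1.7), n = 2000,
                               rng_seed = 52)
  set.seed(53)
  blob <- data.frame(X = rnorm(300, 0.5, 0.03), Y = rnorm(300, 0, 0.03),
                     Z = runif(300, 1.1, 1.5))
  mixed <- scan_cloud(rbind(stem$points[, c("X", "Y", "Z")], blob))
  slab <- extract_slab(mixed, ground_z = 0)
  expect_true(all(slab$cloud$points$X < 0.3))
  expect_equal(npoints(slab$cloud), sum(stem$points$Z >= 1.0 &
                                          stem$points$Z <= 1.6))
})

test_that("RANSAC recovers a noiseless cylinder almost exactly", {
  sl <- sample_cylinder_slab(radius = 0.0824, n = 2000, noise_sd = 0,
                             rng_seed = 54)
  fit <- ransac_cylinder(sl, seed = 1)
  expect_lt(abs(fit$radius - 0.0824), 1e-4)
  expect_lt(fit$sigma, 1e-4)
  expect_equal(fit$axis_direction, c(0, 0, 1))
})

test_that("RANSAC recovers radius and noise level on a half-visible stem", {
  sl <- sample_cylinder_slab(radius = 0.0824, n = 3000, noise_sd = 0.003,
                             arc_deg = 180, rng_seed = 55)
  fit <- ransac_cylinder(sl, seed = 2)
  expect_lt(abs(fit$radius - 0.0824), 0.001)
  expect_lt(abs(fit$sigma - 0.003), 0.001)
  # deterministic under a fixed seed
  fit2 <- ransac_cylinder(sl, seed = 2)
  expect_equal(fit2$radius, fit$radius)
  # covariant under rigid translation
  moved <- sl
  moved$points$X <- moved$points$X + 2
  moved$points$Y <- moved$points$Y - 1
  fit3 <- ransac_cylinder(moved, seed = 2)
  expect_equal(fit3$radius, fit$radius, tolerance = 1e-9)
  expect_equal(fit3$axis_point[1:2], fit$axis_point[1:2] + c(2, -1),
               tolerance = 1e-6)
})

test_that("RANSAC resists outliers where a plain least-squares fit fails", {
  sl <- sample_cylinder_slab(radius = 0.0824, n = 3000, noise_sd = 0.003,
                             outlier_frac = 0.2, rng_seed = 56)
  fit <- ransac_cylinder(sl, seed = 3)
  expect_lt(abs(fit$radius - 0.0824), 0.002)
  # oracle contrast: algebraic (Kasa) circle fit on all points, no consensus
  x <- sl$points$X
  y <- sl$points$Y
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  r_ls <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  expect_gt(abs(r_ls - 0.0824), 0.002)
})

test_that("imposed growth is recovered in order across epochs", {
  radii <- c(0.0824, 0.0827, 0.0834, 0.0837, 0.0842, 0.0856, 0.0861,
             0.0872)
  clouds <- lapply(seq_along(radii), function(i) {
    sample_cylinder_slab(radius = radii[i], z_range = c(0.9, 1.7), n = 2500,
                         noise_sd = 0.003, rng_seed = 100 + i)
  })
  series <- fit_dbh_series(clouds, dates = as.Date("2020-04-06") +
                             seq(0, 60, length.out = 8),
                           ground_z = 0, seed = 9)
  expect_equal(cor(series$radius_m, radii, method = "spearman"), 1)
  expect_lt(max(abs(series$radius_m - radii)), 0.001)
  expect_equal(series$dbh_mm, round(2000 * series$radius_m, 1))
})

test_that("DBH doubles the radius and reports in mm", {
  mk <- function(r) structure(list(radius = r), class = "stem_fit")
  expect_equal(dbh_from_fit(mk(0.0824)), 164.8)
  expect_equal(dbh_from_fit(mk(0.0872)), 174.4)
  expect_equal(dbh_from_fit(mk(0.1)), 200.0)
})

test_that("caliper comparison reports the mean and both dispersions", {
  series <- data.frame(date = as.Date("2020-06-05"), dbh_mm = 174.4)
  rep <- compare_to_reference(series, c(181, 166, 170, 175))
  expect_equal(rep$reference_mm, 173)
  expect_equal(rep$discrepancies$discrepancy_mm, 1.4)
  expect_equal(rep$caliper_sd_population_mm,
               sqrt(mean((c(181, 166, 170, 175) - 173)^2)))
  expect_equal(rep$caliper_sd_sample_mm, sd(c(181, 166, 170, 175)))
  single <- compare_to_reference(series, 170)
  expect_equal(single$reference_mm, 170)
  expect_true(is.na(single$caliper_sd_population_mm))
})
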