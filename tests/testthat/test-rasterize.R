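test_that("a single corner point fills exactly one pixel in its channel", {
  g <- test_geometry()
  # a hair inside the corner: the exact bound is half-open at float level
  p <- cartesian_from_spherical(data.frame(rho = 20,
                                           theta = g$theta_min + 1e-6,
                                           phi = g$phi_min + 1e-6))
  p$return_number <- 1L
  p$number_of_returns <- 1L
  cl <- enrich(scan_cloud(p), g)
  st <- rasterize(cl, g, "range")
  expect_equal(sum(is.finite(st$channels[[1]])), 1L)
  expect_equal(st$channels[[1]][1, 1], 20, tolerance = 1e-9)
  expect_true(all(!is.finite(st$channels[[2]])))
  expect_equal(sum(unlist(st$counts)), 1L)
})

test_that("the nearest-range reducer wins multi-point pixels consistently", {
  g <- test_geometry()
  sph <- data.frame(rho = c(12, 10), theta = g$theta_min + 0.1,
                    phi = g$phi_min + 0.1)
  p <- cartesian_from_spherical(sph)
  p$return_number <- 1L
  p$number_of_returns <- 1L
  p$reflectance <- c(-15, -3) # attribute of the nearer point must win
  cl <- enrich(scan_cloud(p), g)
  st <- rasterize(cl, g, "range")
  expect_equal(st$channels[[1]][1, 1], 10)
  expect_equal(st$counts[[1]][1, 1], 2L)
  sr <- rasterize(cl, g, "reflectance")
  expect_equal(sr$channels[[1]][1, 1], -3)
  expect_equal(rasterize(cl, g, "range", reducer = "mean")$channels[[1]][1, 1],
               11)
  expect_error(rasterize(cl, g, "no_such"), "absent")
})

test_that("point counts are conserved on a simulated scan", {
  scene <- build_scene(tree_spec(base = c(10, 2), height = 12,
                                 n_branches = 5), rng_seed = 4)
  cl <- scan_scene(scene, scanner_spec(alpha = 0.05), rng_seed = 4)
  gm <- cl$meta$geometry
  g <- raster_geometry(gm$alpha, gm$theta_min, gm$theta_max, gm$phi_min,
                       gm$phi_max)
  st <- rasterize(cl, g, "range")
  expect_equal(sum(unlist(st$counts)),
               sum(cl$points$in_window & cl$points$return_number <= 4))
  # per-channel tallies equal a brute-force count
  for (k in 1:2) {
    expect_equal(sum(st$counts[[k]]),
                 sum(cl$points$in_window & cl$points$return_number == k))
  }
})

test_that("TIFF round trip preserves values and the no-data mask", {
  g <- test_geometry(alpha = 2)
  cl <- radiometric_cloud(150, seed = 9, geom = g)
  st <- rasterize(cl, g, "deviation")
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(st, path)
  r <- read_raster_stack(path)
  expect_equal(length(r$channels), 4L)
  expect_equal(r$attribute, "deviation")
  for (k in 1:4) {
    expect_equal(is.finite(r$channels[[k]]), is.finite(st$channels[[k]]))
    fin <- is.finite(st$channels[[k]])
    if (any(fin)) {
      expect_lt(max(abs(r$channels[[k]][fin] - st$channels[[k]][fin])), 1e-4)
    }
    expect_identical(r$counts[[k]], st$counts[[k]])
  }
  expect_equal(unclass(r$geometry), unclass(st$geometry))
})

test_that("quicklooks map the display window linearly to 0..255", {
  g <- raster_geometry(1, 0, 2, 0, 2)
  st <- structure(list(
    geometry = g, attribute = "range", reducer = "nearest",
    max_return = 1L,
    channels = list(matrix(c(5, 139, 72, NaN), 2, 2)),
    counts = list(matrix(c(1L, 1L, 1L, 0L), 2, 2)), no_data = NaN),
    class = "raster_stack")
  ql <- quicklook(st, 5, 139)
  expect_equal(ql[1, 1], 0L)
  expect_equal(ql[2, 1], 255L)
  expect_true(ql[1, 2] %in% c(127L, 128L)) # documented half-way rounding
  expect_equal(ql[2, 2], 0L)               # no-data renders black
  expect_error(quicklook(st, 10, 5), "low")
})

test_that("radial range shifts change values but not occupancy", {
  g <- test_geometry()
  cl <- radiometric_cloud(400, seed = 13, geom = g)
  st1 <- rasterize(cl, g, "range")
  shifted <- cl
  f <- 1.05 # radial scaling preserves angles, hence pixels
  shifted$points$X <- cl$points$X * f
  shifted$points$Y <- cl$points$Y * f
  shifted$points$Z <- cl$points$Z * f
  st2 <- rasterize(enrich(shifted, g), g, "range")
  for (k in 1:4) {
    expect_identical(is.finite(st2$channels[[k]]),
                     is.finite(st1$channels[[k]]))
    expect_identical(st2$counts[[k]], st1$counts[[k]])
  }
})
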