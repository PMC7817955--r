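test_that("scene construction is seed-reproducible with known counts", {
  tr <- tree_spec(base = c(6, 2), n_branches = 5)
  s1 <- build_scene(tr, rng_seed = 10)
  s2 <- build_scene(tr, rng_seed = 10)
  expect_equal(s1$primitives, s2$primitives)
  # 1 stem + n branches + n foliage discs per tree
  expect_equal(nrow(s1$primitives), 1 + 2 * 5)
  bare <- build_scene(tree_spec(n_branches = 0), rng_seed = 1)
  expect_equal(nrow(bare$primitives), 1L)
  expect_equal(bare$primitives$material, "stem")
  s3 <- build_scene(list(tr, tree_spec(base = c(-4, 8), n_branches = 3)),
                    rng_seed = 2)
  expect_equal(nrow(s3$primitives), 11 + 7)
  expect_warning(build_scene(list(tr, tr), rng_seed = 3), "overlapping")
})

test_that("sprout scales deciduous foliage only and rejects pruning", {
  mixed <- build_scene(list(tree_spec(base = c(5, 5)),
                            tree_spec(base = c(-5, 5),
                                      species = "conifer")),
                       rng_seed = 4)
  s <- sprout(mixed, 1.5)
  pr0 <- mixed$primitives
  pr1 <- s$primitives
  dec <- pr0$material == "foliage" & pr0$species == "deciduous"
  con <- pr0$material == "foliage" & pr0$species == "conifer"
  expect_equal(pr1$density[dec], pr0$density[dec] * 1.5)
  expect_equal(pr1$density[con], pr0$density[con])
  expect_equal(sprout(mixed, 1)$primitives, pr0)
  expect_error(sprout(mixed, 0.9), ">= 1")
})

test_that("a wall at 100 m is sampled at the designed point spacing", {
  w <- add_wall(NULL, center = c(100, 0, 30), radius = 3)
  sc <- scanner_spec(alpha = 0.006, range_noise_sd = 0)
  cl <- scan_scene(w, sc, rng_seed = 1)
  expect_gt(npoints(cl), 100)
  p <- cl$points
  # nearest same-row neighbour spacing ~ range * alpha(rad) ~ 0.0105 m
  row0 <- p[p$row == p$row[which.min(abs(p$row - median(p$row)))], ]
  row0 <- row0[order(row0$col), ]
  gaps <- sqrt(diff(row0$X)^2 + diff(row0$Y)^2 + diff(row0$Z)^2)
  expect_equal(median(gaps), point_spacing_at_range(0.006, 100),
               tolerance = 0.02)
  expect_equal(round(median(gaps), 2), 0.01)
})

test_that("ray casting respects occlusion and the angular grid", {
  scene <- add_wall(NULL, center = c(60, 8, -10), radius = 15)
  scene <- add_wall(scene, center = c(30, 8, -5), radius = 1.5)
  cl <- scan_scene(scene, scanner_spec(alpha = 0.05, range_noise_sd = 0),
                   rng_seed = 2)
  tr <- attr(cl, "truth")
  # the scanner sits 30 m up: the occluder is ~47 m away, the wall ~73 m
  near <- cl$points[tr$true_range < 60, ]
  far <- cl$points[tr$true_range >= 60, ]
  expect_gt(nrow(near), 0)
  # no far-wall return shares a pixel with the occluding disc
  expect_equal(sum(paste(near$row, near$col) %in%
                     paste(far$row, far$col)), 0L)
  # each (pixel, return) is unique and in-window
  expect_false(anyDuplicated(
    cl$points[, c("row", "col", "return_number")]) > 0)
  expect_true(all(cl$points$in_window))
  # a scene entirely beyond the detection range gives an empty cloud
  e <- scan_scene(add_wall(NULL, center = c(500, 0, 0), radius = 1),
                  scanner_spec(alpha = 0.05, max_range = 100), rng_seed = 3)
  expect_equal(npoints(e), 0L)
})

test_that("scans are reproducible and foliage yields multiple returns", {
  scene <- build_scene(tree_spec(base = c(9, 4), height = 14,
                                 n_branches = 6), rng_seed = 11)
  sc <- scanner_spec(alpha = 0.04)
  a <- scan_scene(scene, sc, rng_seed = 5)
  b <- scan_scene(scene, sc, rng_seed = 5)
  expect_equal(a$points, b$points)
  expect_gt(max(a$points$number_of_returns), 1L)
  expect_true(all(a$points$return_number <= a$points$number_of_returns))
  expect_true(all(a$points$return_number <= sc$max_returns))
  tr <- attr(a, "truth")
  expect_equal(nrow(tr), npoints(a))
  # multi-returns come from porous foliage, opaque wood terminates rays
  expect_true(all(tr$material[a$points$return_number > 1] %in%
                    c("foliage", "stem", "branch")))
})

test_that("motion displaces branch and foliage returns by the imposed law", {
  scene <- build_scene(tree_spec(base = c(9, 4), height = 14,
                                 n_branches = 4), rng_seed = 12)
  sc <- scanner_spec(alpha = 0.05, range_noise_sd = 0)
  mo <- motion_spec(amplitude = 0.05, period_h = 24, phase = 0)
  at0 <- scan_scene(scene, sc, time_h = 0, motion = mo, rng_seed = 6)
  at6 <- scan_scene(scene, sc, time_h = 6, motion = mo, rng_seed = 6)
  tr6 <- attr(at6, "truth")
  expect_equal(unique(tr6$disp_z[tr6$material == "foliage"]), 0.05)
  expect_equal(unique(tr6$disp_z[tr6$material == "stem"]), 0)
  expect_equal(attr(at0, "truth")$disp_z, rep(0, npoints(at0)))
})

test_that("direct surface sampling is reproducible with Poisson counts", {
  scene <- build_scene(tree_spec(base = c(6, 3), foliage_density = 5000),
                       rng_seed = 13)
  a <- sample_scene_points(scene, rng_seed = 14)
  b <- sample_scene_points(scene, rng_seed = 14)
  expect_equal(a, b)
  expect_setequal(unique(a$material), c("stem", "branch", "foliage"))
  # expected count within 5 sd of the Poisson mean
  discs <- scene$primitives[scene$primitives$material == "foliage", ]
  lambda <- sum(discs$density * pi * discs$radius^2)
  n_fol <- sum(a$material == "foliage")
  expect_lt(abs(n_fol - lambda), 5 * sqrt(lambda))
  # scan sequences re-noise the same base points
  s1 <- simulate_scan_sequence(a, c(0, 1), noise_sd = 0.002, rng_seed = 15)
  s2 <- simulate_scan_sequence(a, c(0, 1), noise_sd = 0.002, rng_seed = 15)
  expect_equal(s1[[2]]$points, s2[[2]]$points)
  expect_false(isTRUE(all.equal(s1[[1]]$points$X, s1[[2]]$points$X)))
  expect_lt(max(abs(s1[[1]]$points$X - a$X)), 0.002 * 6)
})
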