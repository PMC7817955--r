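test_that("compact point groups seed the expected clusters", {
  set.seed(61)
  ball <- data.frame(X = runif(200, 0, 0.05), Y = runif(200, 0, 0.05),
                     Z = runif(200, 0, 0.05))
  m <- seed_clusters(scan_cloud(ball), min_size = 100, max_diameter = 0.15,
                     rng_seed = 1)
  expect_equal(nrow(m$seeds), 1L)
  expect_true(all(m$labels == 1L))

  two <- rbind(ball[1:150, ],
               data.frame(X = ball$X[1:150] + 1, Y = ball$Y[1:150],
                          Z = ball$Z[1:150]))
  m2 <- seed_clusters(scan_cloud(two), min_size = 100, rng_seed = 2)
  expect_equal(nrow(m2$seeds), 2L)
  # no cross-assignment between the two blobs
  expect_equal(length(unique(m2$labels[1:150])), 1L)
  expect_equal(length(unique(m2$labels[151:300])), 1L)
  expect_false(m2$labels[1] == m2$labels[151])
})

test_that("undersized clusters dissolve and their points detach", {
  set.seed(62)
  small <- data.frame(X = runif(99, 0, 0.04), Y = runif(99, 0, 0.04),
                      Z = runif(99, 0, 0.04))
  big <- data.frame(X = runif(150, 2, 2.04), Y = runif(150, 0, 0.04),
                    Z = runif(150, 0, 0.04))
  m <- seed_clusters(scan_cloud(rbind(small, big)), min_size = 100,
                     rng_seed = 3)
  expect_equal(nrow(m$seeds), 1L)
  expect_true(all(m$labels[1:99] == 0L))    # isolated 99-point group
  expect_true(all(m$labels[100:249] == 1L))
  # brute-force recount of the surviving cluster
  expect_gte(sum(m$labels == 1L), 100)
  expect_error(seed_clusters(scan_cloud(small), min_size = 100,
                             rng_seed = 4), "minimum size")
})

test_that("labels are a fixed point on identical consecutive clouds", {
  set.seed(63)
  cl <- scan_cloud(data.frame(X = runif(300, 0, 0.1),
                              Y = runif(300, 0, 0.1),
                              Z = runif(300, 0, 0.1)))
  m <- seed_clusters(cl, min_size = 100, rng_seed = 5)
  labs <- propagate_labels(m, list(cl, cl))
  expect_equal(labs[[2]], m$labels)
  expect_equal(labs[[3]], m$labels)
})

test_that("labels follow a rigid 1 cm shift and cap at the match radius", {
  set.seed(64)
  cl <- scan_cloud(data.frame(X = runif(400, 0, 0.12),
                              Y = runif(400, 0, 0.12),
                              Z = runif(400, 0, 0.12)))
  m <- seed_clusters(cl, min_size = 100, rng_seed = 6)
  shifted <- cl
  shifted$points$X <- shifted$points$X + 0.01
  labs <- propagate_labels(m, list(shifted))
  expect_equal(labs[[2]], m$labels) # same point order, labels preserved
  # a far point matches nothing and stays unassigned
  far <- scan_cloud(rbind(shifted$points, c(5, 5, 5)))
  labs2 <- propagate_labels(m, list(far))
  expect_equal(labs2[[2]][401], 0L)
  expect_error(propagate_labels(m, list(scan_cloud(
    data.frame(X = numeric(0), Y = numeric(0), Z = numeric(0))))),
    "empty scan")
})

test_that("medians and displacements match brute force and start at zero", {
  set.seed(65)
  cl <- scan_cloud(data.frame(X = runif(250, 0, 0.1),
                              Y = runif(250, 0, 0.1),
                              Z = runif(250, 0, 0.1)))
  m <- seed_clusters(cl, min_size = 100, rng_seed = 7)
  d <- c(0.02, -0.01, 0.03)
  moved <- cl
  moved$points$X <- moved$points$X + d[1]
  moved$points$Y <- moved$points$Y + d[2]
  moved$points$Z <- moved$points$Z + d[3]
  labs <- propagate_labels(m, list(moved))
  ds <- displacement_series(list(cl, moved), labs)
  first <- ds[ds$scan == 1, ]
  expect_true(all(first$amplitude == 0))
  second <- ds[ds$scan == 2, ]
  # exact recovery of a rigid, noiseless motion
  expect_lt(max(abs(second$dx - d[1])), 1e-9)
  expect_lt(max(abs(second$amplitude - sqrt(sum(d^2)))), 1e-9)
  # component-wise median equals the sort-based oracle
  for (k in seq_len(nrow(m$seeds))) {
    sel <- m$labels == k
    expect_equal(first$mx[first$cluster == k],
                 median(cl$points$X[sel]))
    expect_equal(first$mz[first$cluster == k],
                 median(cl$points$Z[sel]))
  }
})

test_that("tracking is equivariant under a global translation", {
  base <- blob_base_points()
  scans <- simulate_scan_sequence(base, c(0, 0.5, 1),
                                  motion = motion_spec(0.05),
                                  noise_sd = 0.001, rng_seed = 71)
  m <- seed_clusters(scans[[1]], rng_seed = 8)
  ds <- displacement_series(scans, propagate_labels(m, scans[-1]))

  off <- c(3, -2, 7)
  shifted <- lapply(scans, function(s) {
    s$points$X <- s$points$X + off[1]
    s$points$Y <- s$points$Y + off[2]
    s$points$Z <- s$points$Z + off[3]
    s
  })
  m2 <- seed_clusters(shifted[[1]], rng_seed = 8)
  ds2 <- displacement_series(shifted, propagate_labels(m2, shifted[-1]))
  expect_equal(ds2$mx, ds$mx + off[1], tolerance = 1e-9)
  expect_equal(ds2$mz, ds$mz + off[3], tolerance = 1e-9)
  expect_equal(ds2$dx, ds$dx, tolerance = 1e-9)
  expect_equal(ds2$amplitude, ds$amplitude, tolerance = 1e-9)
})

test_that("a vanished cluster yields flagged NA rows, not an error", {
  set.seed(66)
  a <- data.frame(X = runif(120, 0, 0.05), Y = runif(120, 0, 0.05),
                  Z = runif(120, 0, 0.05))
  b <- data.frame(X = runif(150, 1, 1.05), Y = runif(150, 0, 0.05),
                  Z = runif(150, 0, 0.05))
  cl <- scan_cloud(rbind(a, b))
  m <- seed_clusters(cl, min_size = 100, rng_seed = 9)
  # second scan drops blob a entirely
  cl2 <- scan_cloud(b)
  labs <- propagate_labels(m, list(cl2))
  ds <- displacement_series(list(cl, cl2), labs)
  gone <- ds[ds$scan == 2 & ds$n_points == 0, ]
  expect_equal(nrow(gone), 1L)
  expect_true(all(gone$flagged))
  expect_true(all(is.na(gone$mx)))
})
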