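test_that("enrich computes range/angles/pixels and is idempotent", {
  g <- test_geometry()
  cl <- enrich(scan_cloud(data.frame(X = 0, Y = 0, Z = 10)),
               raster_geometry(0.5, 0, 45, 0, 360))
  expect_equal(cl$points$range, 10)
  expect_equal(cl$points$theta, 0)

  cl2 <- radiometric_cloud(500, seed = 11, geom = g)
  again <- enrich(cl2, g)
  expect_equal(again$points, cl2$points)
  # elementwise oracle
  p <- cl2$points
  expect_equal(p$range, sqrt(p$X^2 + p$Y^2 + p$Z^2), tolerance = 1e-12)
  expect_error(scan_cloud(data.frame(X = 1, Y = 2)), "missing coordinate")
})

test_that("LAS 1.4 write/read round-trips every attribute", {
  g <- test_geometry()
  cl <- radiometric_cloud(300, seed = 5, geom = g)
  path <- withr::local_tempfile(fileext = ".las")
  write_las(cl, path)
  r <- read_las(path)
  p0 <- cl$points
  p1 <- r$points
  expect_equal(nrow(p1), nrow(p0))
  # coordinates at 1 mm storage scale
  expect_lt(max(abs(p1$X - p0$X)), 5e-4 + 1e-12)
  expect_lt(max(abs(p1$Z - p0$Z)), 5e-4 + 1e-12)
  # integer fields bit-exact
  expect_identical(p1$return_number, p0$return_number)
  expect_identical(p1$number_of_returns, p0$number_of_returns)
  expect_identical(p1$row, p0$row)
  expect_identical(p1$col, p0$col)
  # float32 extra bytes
  expect_lt(max(abs(p1$reflectance - p0$reflectance)), 1e-4)
  expect_lt(max(abs(p1$range - p0$range)), 1e-4)
  expect_lt(max(abs(p1$intensity - p0$intensity)), 1 / 65535)
  expect_equal(r$timestamp, cl$timestamp)
})

test_that("LAS handles empty clouds, old versions and missing extras", {
  e <- scan_cloud(data.frame(X = numeric(0), Y = numeric(0),
                             Z = numeric(0)))
  path <- withr::local_tempfile(fileext = ".las")
  expect_warning(write_las(e, path), regexp = NA)
  expect_warning(r <- read_las(path), "extra-byte")
  expect_equal(npoints(r), 0L)

  # bare cloud (no derived columns) reads back with a warning, not a crash
  cl <- random_cloud(10, seed = 2)
  write_las(cl, path)
  expect_warning(r2 <- read_las(path), "extra-byte")
  expect_equal(npoints(r2), 10L)

  # patch the version minor byte: explicit version error
  bytes <- readBin(path, raw(), file.info(path)$size)
  bytes[26] <- as.raw(2L)
  writeBin(bytes, path)
  expect_error(read_las(path), "version 1.2")
})

test_that("delineation equals a brute-force predicate filter", {
  cl <- enrich(random_cloud(2000, seed = 8), test_geometry())
  box <- delineate(cl, xlim = c(-2, 3), zlim = c(2, 8))
  p <- cl$points
  keep <- p$X >= -2 & p$X <= 3 & p$Z >= 2 & p$Z <= 8
  expect_equal(box$points$X, p$X[keep])
  expect_equal(npoints(box), sum(keep))
  # identity and disjoint boxes
  all_in <- delineate(cl, xlim = range(p$X))
  expect_equal(all_in$points$X, p$X)
  expect_warning(none <- delineate(cl, xlim = c(100, 101)), "no points")
  expect_equal(npoints(none), 0L)
  expect_error(delineate(cl), "threshold")
  # conjunction is order-independent
  a <- delineate(delineate(cl, xlim = c(-2, 3)), zlim = c(2, 8))
  expect_equal(a$points, box$points)
})

test_that("copy verification distinguishes size and content changes", {
  src <- withr::local_tempfile()
  writeBin(as.raw(sample(0:255, 4096, replace = TRUE)), src)
  dst <- withr::local_tempfile()
  file.copy(src, dst, overwrite = TRUE)
  expect_true(verify_copy(src, dst))
  # truncated copy
  writeBin(readBin(src, raw(), 4000), dst)
  expect_false(verify_copy(src, dst))
  # same size, different content: caught only by the checksum
  b <- readBin(src, raw(), 4096)
  b[1] <- xor(b[1], as.raw(255))
  writeBin(b, dst)
  expect_false(verify_copy(src, dst))
  expect_true(verify_copy(src, dst, checksum = FALSE))
  expect_error(verify_copy(src, "no-such-file"), "not found")
})

test_that("daily projects validate the naming convention", {
  d <- withr::local_tempdir()
  day <- file.path(d, "2020-05-01")
  dir.create(day)
  files <- file.path(day, c("0100.csv", "0000.csv"))
  file.create(files)
  pr <- scan_project("2020-05-01", files)
  expect_equal(format(pr$timestamps, "%H%M"), c("0000", "0100"))
  expect_error(scan_project("2020-05-02", files), "outside project day")
  expect_error(scan_project("2020-05-01", file.path(d, "scan1.csv")),
               "convention")
})
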