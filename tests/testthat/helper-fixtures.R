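# shared fixtures, all generated in code at test time

# uniform random cloud in a box, reproducible
random_cloud <- function(n, seed = 1, lo = c(-5, -5, 0), hi = c(5, 5, 10)) {
  set.seed(seed)
  scan_cloud(data.frame(X = runif(n, lo[1], hi[1]),
                        Y = runif(n, lo[2], hi[2]),
                        Z = runif(n, lo[3], hi[3])))
}

# small enriched cloud with radiometric columns, for I/O and raster tests
radiometric_cloud <- function(n = 200, seed = 3, geom = test_geometry()) {
  set.seed(seed)
  sph <- data.frame(rho = runif(n, 5, 50),
                    theta = runif(n, geom$theta_min, geom$theta_max),
                    phi = runif(n, geom$phi_min, geom$phi_max))
  p <- cartesian_from_spherical(sph)
  p$return_number <- sample(1:4, n, replace = TRUE)
  p$number_of_returns <- pmax(p$return_number, sample(1:4, n, replace = TRUE))
  p$intensity <- runif(n)
  p$reflectance <- runif(n, -20, 0)
  p$deviation <- runif(n, 0, 30)
  enrich(scan_cloud(p, timestamp = as.POSIXct("2020-05-01 01:00:00",
                                              tz = "UTC")), geom)
}

test_geometry <- function(alpha = 0.5) {
  raster_geometry(alpha, theta_min = 60, theta_max = 120,
                  phi_min = 10, phi_max = 70)
}

# compact-blob tree used by the tracker tests: isolated dense foliage discs
blob_base_points <- function(materials = "foliage") {
  scene <- build_scene(tree_spec(base = c(8, 3), height = 16,
                                 n_branches = 6, foliage_density = 60000,
                                 foliage_radius = c(0.065, 0.07)),
                       rng_seed = 2)
  sample_scene_points(scene, rng_seed = 3, materials = materials)
}

# per-minute weather frame with constant values, for direct gate tests
constant_weather <- function(hours = 2, wind = 2, precip = 0,
                             start = "2020-05-01 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  n <- hours * 60 + 1
  read_weather(data.frame(
    timestamp = t0 + (seq_len(n) - 1L) * 60,
    wind_speed = rep_len(wind, n),
    wind_direction = 180,
    temperature = 5,
    precipitation = rep_len(precip, n),
    relative_humidity = 70))
}
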