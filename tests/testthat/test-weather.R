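test_that("window statistics summarize the covered minutes", {
  w <- constant_weather(hours = 2, wind = 2)
  s <- window_stats(w, "2020-05-01 00:10:00", 21)
  expect_equal(s$wind_max, 2)
  expect_equal(s$wind_mean, 2)
  expect_equal(s$precip_total_mm, 0)
  # a single 5 m/s spike inside the window drives the max
  w2 <- constant_weather(hours = 2, wind = 2)
  w2$wind_speed[21] <- 5 # minute 20
  s2 <- window_stats(w2, "2020-05-01 00:10:00", 21)
  expect_equal(s2$wind_max, 5)
  expect_gt(s2$wind_mean, 2)
  expect_error(window_stats(w, "2020-05-01 01:50:00", 21), "not covered")
})

test_that("window maxima agree with a brute-force scan of the records", {
  set.seed(31)
  w <- constant_weather(hours = 24)
  w$wind_speed <- runif(nrow(w), 0, 6)
  for (start_min in c(0, 17, 303, 1000)) {
    t0 <- w$timestamp[1] + start_min * 60
    s <- window_stats(w, t0, 21)
    inside <- w$timestamp >= t0 & w$timestamp <= t0 + 21 * 60
    expect_equal(s$wind_max, max(w$wind_speed[inside]))
  }
})

test_that("the calm gate uses a strict wind bound and zero precipitation", {
  w <- constant_weather(hours = 4, wind = 2.9)
  t <- w$timestamp[c(1, 61, 121)]
  flags <- gate_scans(w, t)
  expect_true(all(flags$passed))
  # max wind exactly at the limit fails (strict inequality)
  w$wind_speed[] <- 3.0
  expect_false(any(gate_scans(read_weather(w), t)$passed))
  # any precipitation fails
  w$wind_speed[] <- 1
  w$precipitation[70] <- 0.4
  f <- gate_scans(read_weather(w), t)
  expect_equal(f$passed, c(TRUE, FALSE, TRUE))
  # relaxing the wind limit is monotone
  w2 <- constant_weather(hours = 4, wind = 3.5)
  strict <- gate_scans(w2, t, wind_limit = 3)$passed
  relaxed <- gate_scans(w2, t, wind_limit = 5)$passed
  expect_true(all(relaxed >= strict))
})

test_that("monthly summaries reproduce the published gating season", {
  # the four published monthly pass counts over 2,880 hourly scans
  passes <- c("2020-04" = 222L, "2020-05" = 316L, "2020-06" = 423L,
              "2020-07" = 275L)
  rows <- lapply(names(passes), function(m) {
    t0 <- as.POSIXct(paste0(m, "-01 00:00:00"), tz = "UTC")
    n <- 720L
    data.frame(scan_time = t0 + (seq_len(n) - 1L) * 3600,
               wind_max = ifelse(seq_len(n) <= passes[[m]], 2, 4),
               wind_mean = 2, wind_start = 2, precip_total_mm = 0)
  })
  flags <- do.call(rbind, rows)
  flags$passed <- flags$wind_max < 3 & flags$precip_total_mm == 0
  class(flags) <- c("scan_quality_flags", "data.frame")
  ms <- monthly_summary(flags)
  expect_equal(ms$passed, unname(passes))
  expect_equal(sum(ms$passed), 1236L)
  expect_equal(sum(ms$scans), 2880L)
  expect_equal(round(sum(ms$passed) / sum(ms$scans) * 100), 43)
  # brute-force group-by oracle on random flags
  set.seed(5)
  sub <- flags[sample(nrow(flags), 500), ]
  sub$passed <- runif(500) < 0.5
  class(sub) <- c("scan_quality_flags", "data.frame")
  ms2 <- monthly_summary(sub)
  key <- format(sub$scan_time, "%Y-%m")
  expect_equal(ms2$passed, as.vector(tapply(sub$passed, key, sum)[ms2$month]))
  expect_equal(ms2$scans, as.vector(table(key)[ms2$month]))
})

test_that("synthetic weather honours the calm fraction at the extremes", {
  t0 <- as.POSIXct("2020-04-01 00:00:00", tz = "UTC")
  times <- t0 + (0:22) * 3600
  all_calm <- synth_weather(1, rng_seed = 3, calm_fraction = 1)
  expect_true(all(gate_scans(all_calm, times)$passed))
  none <- synth_weather(1, rng_seed = 3, calm_fraction = 0)
  expect_false(any(gate_scans(none, times)$passed))
  # reproducibility
  a <- synth_weather(2, rng_seed = 8, calm_fraction = 0.5)
  b <- synth_weather(2, rng_seed = 8, calm_fraction = 0.5)
  expect_equal(a, b)
})
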