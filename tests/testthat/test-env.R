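test_that("profile smoothing preserves constants and removes single spikes", {
  depth <- seq(0, 100, by = 5)
  const <- rep(10, length(depth))
  sm <- smooth_profile(depth, const)
  expect_equal(sm$value, rep(10, nrow(sm)))

  for (spike_at in c(1, 3, 11, 21)) { # edge, near-edge, interior, far edge
    spiked <- const
    spiked[spike_at] <- spiked[spike_at] + 5
    sm2 <- smooth_profile(depth, spiked)
    expect_equal(sm2$value, rep(10, nrow(sm2)))
  }
})

test_that("a 5-point median matches hand evaluation around a spike", {
  # hand evaluation: median of (10,10,15,10,10) = 10 at every window
  x <- c(10, 10, 15, 10, 10, 10, 10)
  med <- frontfish:::roll_stat(x, 5, stats::median)
  expect_equal(med, rep(10, 7))
})

test_that("linear profiles pass through the interior of the smoother unchanged", {
  depth <- seq(0, 200, by = 5)
  lin <- 20 - 0.05 * depth
  sm <- smooth_profile(depth, lin)
  interior <- 5:(nrow(sm) - 4)
  expect_equal(sm$value[interior], lin[interior], tolerance = 1e-12)
  # monotonicity is preserved everywhere
  expect_true(all(diff(sm$value) <= 1e-12))
})

test_that("profiles that are too short or too shallow are rejected", {
  expect_error(smooth_profile(c(0, 5, 10, 15), c(1, 2, 3, 4)), "5 valid levels")
  expect_error(smooth_profile(c(0, 5, 10, 15, 20), 1:5), "at least 25")
})

test_that("zonal profile differences recover the prescribed offset", {
  labs <- straight_labels()
  prof <- sample_profiles(
    profile_spec(n_warm = 12, n_cold = 12, depth_range = c(0, 400),
                 temp_offset = 1, noise_sd = 0),
    labs, seed = 3)
  d <- zonal_env_difference(prof, labs, depth_m = 200, cell_deg = 4)
  expect_gt(nrow(d), 0)
  expect_equal(d$difference, rep(1, nrow(d)), tolerance = 1e-9)

  noisy <- sample_profiles(
    profile_spec(n_warm = 40, n_cold = 40, depth_range = c(0, 400),
                 temp_offset = 0, noise_sd = 0.1),
    labs, seed = 4)
  d0 <- zonal_env_difference(noisy, labs, depth_m = 200, cell_deg = 4)
  pooled <- sum(d0$difference * pmin(d0$n_warm, d0$n_cold)) /
    sum(pmin(d0$n_warm, d0$n_cold))
  expect_lt(abs(pooled), 3 * 0.1 * sqrt(2 / 40))
})

test_that("cells with a single zone are no-data and swapping zones flips the sign", {
  labs <- straight_labels()
  prof <- sample_profiles(
    profile_spec(n_warm = 8, n_cold = 8, depth_range = c(0, 400),
                 temp_offset = 1, noise_sd = 0),
    labs, seed = 5)
  warm_only <- prof[prof$zone == "warm", ]
  d_warm_only <- zonal_env_difference(warm_only, labs, depth_m = 200,
                                      cell_deg = 4)
  expect_identical(nrow(d_warm_only), 0L)
  d <- zonal_env_difference(prof, labs, depth_m = 200, cell_deg = 4)
  swapped <- prof
  swapped$temp <- swapped$temp - ifelse(swapped$zone == "warm", 1, -1)
  d2 <- zonal_env_difference(swapped, labs, depth_m = 200, cell_deg = 4)
  expect_equal(d2$difference, -d$difference, tolerance = 1e-9)
})

test_that("relative chlorophyll differences match direct arithmetic", {
  lab <- matrix(ZONE_CODES[["non_frontal"]], 10, 10)
  lab[6:10, ] <- ZONE_CODES[["warm_zone"]]
  lab[1:5, ] <- ZONE_CODES[["cold_zone"]]
  labs <- manual_labels(lab, matrix(15, 10, 10))

  uniform <- sst_grid(matrix(0.8, 10, 10), labs$lon, labs$lat, labs$date)
  d_u <- zonal_chl_relative_difference(uniform, labs, cell_deg = 1)
  expect_equal(d_u$relative_difference, rep(0, nrow(d_u)))

  chl <- matrix(1, 10, 10); chl[6:10, ] <- 2
  two <- sst_grid(chl, labs$lon, labs$lat, labs$date)
  d2 <- zonal_chl_relative_difference(two, labs, cell_deg = 1)
  expect_equal(d2$relative_difference, rep((2 - 1) / 1.5 * 100, nrow(d2)),
               tolerance = 1e-12)

  cold_rich <- matrix(2, 10, 10); cold_rich[6:10, ] <- 1.2
  d3 <- zonal_chl_relative_difference(
    sst_grid(cold_rich, labs$lon, labs$lat, labs$date), labs, cell_deg = 1)
  expect_true(all(d3$relative_difference < 0))
})
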