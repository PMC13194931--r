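test_that("tanh front saturates to T_cold and T_cold + delta_T away from the axis", {
  g <- straight_field()
  far_cold <- g$values[1, ]           # ~1.5 deg (>160 km) south of the axis
  far_warm <- g$values[nrow(g$values), ]
  expect_equal(far_cold, rep(12, length(far_cold)), tolerance = 1e-6)
  expect_equal(far_warm, rep(14, length(far_warm)), tolerance = 1e-6)
})

test_that("row of maximum meridional gradient coincides with the straight axis", {
  g <- straight_field()
  # brute-force column-wise gradient over the generated grid
  axis_rows <- apply(g$values, 2, function(col) which.max(abs(diff(col))))
  true_axis <- which(g$truth[, 1] == "axis")
  expect_true(all(abs(axis_rows - mean(true_axis)) <= 1))
})

test_that("ground-truth labels partition unmasked pixels into warm/cold/axis", {
  g <- std_field()
  expect_true(all(g$truth %in% c("warm", "cold", "axis")))
  expect_equal(sum(table(g$truth)), length(g$values))
})

test_that("generated fields and fisheries are reproducible under a fixed seed", {
  dom <- list(lon = c(150, 152), lat = c(38, 40), res = 0.1)
  fr <- front_spec(delta_T = 2, width_km = 10, T_cold = 12)
  g1 <- make_sst_field(dom, fr, noise_sd = 0.2, seed = 11)
  g2 <- make_sst_field(dom, fr, noise_sd = 0.2, seed = 11)
  expect_identical(g1$values, g2$values)
  r1 <- sample_fishing_records(g1, fishery_spec(200, seed = 5))
  r2 <- sample_fishing_records(g2, fishery_spec(200, seed = 5))
  expect_identical(r1, r2)
})

test_that("degenerate domains and out-of-domain axes are rejected", {
  fr <- front_spec()
  expect_error(make_sst_field(list(lon = c(150, 150.2), lat = c(38, 38.2), res = 0.1),
                              fr), "degenerate")
  bad_axis <- front_spec(axis = cbind(c(140, 141), c(38.5, 38.5)))
  expect_error(make_sst_field(list(lon = c(150, 152), lat = c(38, 40), res = 0.1),
                              bad_axis), "outside the domain")
})

test_that("an indifferent fishery occupies the warm side in proportion to its area", {
  g <- straight_field()
  rec <- sample_fishing_records(g, fishery_spec(1000, seed = 2))
  px <- locate_pixels(g, rec$lon, rec$lat)
  on_warm <- g$truth[cbind(px$row, px$col)] == "warm"
  p_area <- mean(g$truth == "warm")
  se <- sqrt(p_area * (1 - p_area) / 1000)
  expect_lt(abs(mean(on_warm) - p_area), 3 * se)
})

test_that("a sharp warm preference places > 90% of records on the true warm side", {
  g <- straight_field() # delta_T = 2, noise 0
  rec <- sample_fishing_records(
    g, fishery_spec(1000, mu_pref = 14, sigma_pref = 0.5, seed = 3))
  px <- locate_pixels(g, rec$lon, rec$lat)
  frac_warm <- mean(g$truth[cbind(px$row, px$col)] == "warm")
  expect_gt(frac_warm, 0.9)
})

test_that("record count is exact and impossible preferences fail loudly", {
  g <- straight_field()
  rec <- sample_fishing_records(g, fishery_spec(500, seed = 4))
  expect_identical(nrow(rec), 500L)
  expect_error(
    sample_fishing_records(g, fishery_spec(10, mu_pref = 1000, sigma_pref = 0.5,
                                           seed = 1)),
    "zero everywhere")
})

test_that("mean record SST converges to the thermal mode on a flat background", {
  g <- ramp_field()
  rec <- sample_fishing_records(
    g, fishery_spec(10000, mu_pref = 15, sigma_pref = 1, seed = 6))
  expect_lt(abs(mean(sst_at(g, rec$lon, rec$lat)) - 15), 0.1)
})

test_that("synthetic profiles honour the prescribed warm-minus-cold offset", {
  labs <- straight_labels()
  prof <- sample_profiles(
    profile_spec(n_warm = 5, n_cold = 5, depth_range = c(0, 400),
                 temp_offset = 1, noise_sd = 0),
    labs, seed = 1)
  at200 <- prof[prof$depth == 200, ]
  expect_equal(mean(at200$temp[at200$zone == "warm"]) -
                 mean(at200$temp[at200$zone == "cold"]), 1, tolerance = 1e-12)

  noisy <- sample_profiles(
    profile_spec(n_warm = 30, n_cold = 30, depth_range = c(0, 400),
                 temp_offset = 0, noise_sd = 0.1),
    labs, seed = 2)
  at200 <- noisy[noisy$depth == 200, ]
  diff200 <- mean(at200$temp[at200$zone == "warm"]) -
    mean(at200$temp[at200$zone == "cold"])
  expect_lt(abs(diff200), 3 * 0.1 * sqrt(2 / 30))

  expect_error(sample_profiles(profile_spec(n_warm = 5, n_cold = 0), labs),
               "cold")
})
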