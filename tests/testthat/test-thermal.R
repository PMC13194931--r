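test_that("catch is binned and normalized by the maximum bin total", {
  one <- data.frame(date = as.Date("2020-01-01"), lon = 1, lat = 1,
                    catch = 3, sst = 15.2)
  h1 <- bin_catch_by_sst(one)
  expect_identical(nrow(h1[h1$C > 0, ]), 1L)
  expect_equal(h1$bin_lo[h1$C > 0], 15.0)
  expect_equal(h1$C_n[h1$C > 0], 1)

  two <- data.frame(date = as.Date("2020-01-01"), lon = 1:3, lat = 1,
                    catch = c(6, 4, 5), sst = c(15.2, 15.3, 16.1))
  h2 <- bin_catch_by_sst(two)
  expect_equal(h2$C[h2$C > 0], c(10, 5))
  expect_equal(h2$C_n[h2$C > 0], c(1.0, 0.5))

  zero <- data.frame(date = as.Date("2020-01-01"), lon = 1, lat = 1,
                     catch = 0, sst = 15)
  expect_error(bin_catch_by_sst(zero), "zero")
})

test_that("the argmax bin brackets the generative optimum at large n", {
  g <- ramp_field()
  rec <- sample_fishing_records(
    g, fishery_spec(10000, mu_pref = 16, sigma_pref = 1.5, seed = 41))
  h <- bin_catch_by_sst(rec, grid = g)
  top <- h[which.max(h$C), ]
  expect_lte(top$bin_lo - 0.5, 16) # within one bin of 16 degC
  expect_gte(top$bin_hi + 0.5, 16)
})

test_that("least squares recovers an exact Gaussian histogram to 1e-6", {
  T_mid <- seq(6, 22, by = 0.5) # includes the true optimum as a bin centre
  h <- data.frame(bin_lo = T_mid - 0.25, bin_mid = T_mid, bin_hi = T_mid + 0.25,
                  C = exp(-(T_mid - 14)^2 / (2 * 4)))
  h$C_n <- h$C / max(h$C)
  class(h) <- c("sst_histogram", "data.frame")
  fit <- fit_thermal_gaussian(h)
  expect_equal(fit$mu, 14, tolerance = 1e-6)
  expect_equal(fit$sigma, 2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)

  # symmetric histogram: mu at the axis of symmetry
  h2 <- h
  h2$C <- h$C + rev(h$C)
  h2$C_n <- h2$C / max(h2$C)
  fit2 <- fit_thermal_gaussian(h2)
  expect_equal(fit2$mu, 14, tolerance = 1e-6)

  expect_error(fit_thermal_gaussian(h[13:16, ]), "non-empty bins")
})

test_that("the fit is equivariant under a temperature shift", {
  g <- ramp_field()
  rec <- sample_fishing_records(
    g, fishery_spec(5000, mu_pref = 15, sigma_pref = 1.5, seed = 42))
  rec$sst <- sst_at(g, rec$lon, rec$lat)
  f1 <- fit_thermal_gaussian(bin_catch_by_sst(rec))
  rec2 <- rec
  rec2$sst <- rec$sst + 3 # a whole number of 0.5-degC bins
  f2 <- fit_thermal_gaussian(bin_catch_by_sst(rec2))
  expect_equal(f2$mu, f1$mu + 3, tolerance = 1e-6)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-6)
})

test_that("THSI takes its closed-form values and is monotone in |T - mu|", {
  fit <- structure(list(mu = 14, sigma = 2), class = "thermal_fit")
  expect_equal(predict_thsi(fit, 14), 1)
  expect_equal(predict_thsi(fit, c(12, 16)), rep(exp(-0.5), 2))
  expect_equal(predict_thsi(fit, c(8, 20)), rep(exp(-4.5), 2))
  Ts <- seq(14, 24, by = 0.5)
  expect_true(all(diff(predict_thsi(fit, Ts)) < 0))
  expect_true(all(predict_thsi(fit, seq(-10, 40, 0.5)) <= 1))
  # literal density form differs by the normal prefactor
  expect_equal(predict_thsi(fit, 14, density_form = TRUE),
               1 / (2 * sqrt(2 * pi)))
})

test_that("zone thermal comparison separates aligned and displaced zones", {
  fit <- structure(list(mu = 14, sigma = 1), class = "thermal_fit")
  set.seed(43)
  sst_w <- rnorm(60, 14, 0.3)       # warm zone centred on mu
  sst_c <- rnorm(60, 11, 0.3)       # cold zone 3 sigma below
  rec <- data.frame(date = as.Date("2020-01-01"), lon = 0, lat = 0,
                    catch = 1, cpue = rep(rlnorm(60), 2),
                    zone = rep(c("warm_zone", "cold_zone"), each = 60),
                    wc_side = NA, sst = c(sst_w, sst_c))
  cmp <- compare_zone_thermal(rec, fit = fit, top_fraction = 0.5)
  expect_lt(cmp$p_value, 0.01)
  expect_identical(cmp$higher_thsi_zone, "warm")
  expect_lt(cmp$warm$deviation[["median"]], cmp$cold$deviation[["median"]])

  # identical SST distributions: no separation
  rec2 <- rec
  rec2$sst <- rep(sst_w, 2)
  cmp2 <- compare_zone_thermal(rec2, fit = fit, top_fraction = 0.5)
  expect_gt(cmp2$p_value, 0.9)

  # top_fraction = 1 keeps every record
  cmp3 <- compare_zone_thermal(rec, fit = fit, top_fraction = 1)
  expect_identical(cmp3$warm$n, 60L)
  expect_identical(cmp3$cold$n, 60L)

  few <- rec[c(1:5, 61:120), ]
  expect_error(compare_zone_thermal(few, fit = fit), "qualifying")
})

test_that("date stratification splits records at the pivot", {
  rec <- data.frame(date = as.Date(c("2020-06-01", "2020-07-31", "2020-08-01",
                                     "2020-09-10")),
                    lon = 1, lat = 1, catch = 1)
  sp <- split_by_date(rec, "2020-08-01")
  expect_identical(nrow(sp$before), 2L)
  expect_identical(nrow(sp$after), 2L)
})
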