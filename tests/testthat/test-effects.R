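test_that("record-to-zone assignment matches a brute-force point-in-cell count", {
  labs <- straight_labels()
  set.seed(7)
  n <- 100
  rec <- data.frame(date = labs$date,
                    lon = runif(n, 150, 153), lat = runif(n, 38, 41),
                    catch = 1)
  ass <- assign_records_to_zones(rec, labs)

  # independent oracle: explicit half-open cell search per record
  oracle <- sapply(seq_len(n), function(i) {
    r <- which(rec$lat[i] >= labs$lat - labs$res / 2 &
                 rec$lat[i] < labs$lat + labs$res / 2)
    cc <- which(rec$lon[i] >= labs$lon - labs$res / 2 &
                  rec$lon[i] < labs$lon + labs$res / 2)
    labs$label[r, cc]
  })
  expect_identical(sum(ass$records$zone == "warm_zone"),
                   sum(oracle == ZONE_CODES[["warm_zone"]]))
  expect_identical(sum(ass$records$zone == "cold_zone"),
                   sum(oracle == ZONE_CODES[["cold_zone"]]))
  expect_identical(sum(ass$records$zone == "non_frontal"),
                   sum(oracle == ZONE_CODES[["non_frontal"]]))
  # frontal total = warm + cold + line catch
  Ft <- ass$totals$F
  expect_equal(Ft[["frontal"]], Ft[["warm"]] + Ft[["cold"]] + Ft[["line"]])
  expect_equal(Ft[["all"]], Ft[["frontal"]] + Ft[["non_frontal"]])
  At <- ass$totals$A
  expect_equal(At[["all"]], At[["frontal"]] + At[["non_frontal"]])
})

test_that("records outside the grid are excluded with a message", {
  labs <- straight_labels()
  rec <- data.frame(date = labs$date, lon = c(151, 10), lat = c(39, 0),
                    catch = c(2, 3))
  expect_message(ass <- assign_records_to_zones(rec, labs), "excluded 1")
  expect_identical(nrow(ass$records), 1L)
})

test_that("FRAD reproduces its arithmetic reference cases", {
  obs <- manual_totals(F_warm = 10, F_cold = 10, F_non = 30)
  nulls <- replicate(25, manual_totals(F_warm = 10, F_cold = 10, F_non = 30),
                     simplify = FALSE)
  e0 <- frad(obs, nulls, "warm", "cold")
  expect_equal(e0$estimate, 0, tolerance = 1e-12)

  obs15 <- manual_totals(F_warm = 15, F_cold = 10, F_non = 30)
  e50 <- frad(obs15, nulls, "warm", "cold")
  expect_equal(e50$estimate, 50, tolerance = 1e-12)
  expect_equal(unique(e50$null_values), 50, tolerance = 1e-12)
})

test_that("FRAD and RD_FPA are antisymmetric and scale invariant", {
  obs <- manual_totals(F_warm = 22, F_cold = 7, F_non = 55,
                       A_warm = 3, A_cold = 5, A_non = 40)
  nulls <- lapply(1:30, function(r) {
    manual_totals(F_warm = 10 + r / 10, F_cold = 9 + r / 7, F_non = 50,
                  A_warm = 3, A_cold = 5, A_non = 40)
  })
  eij <- frad(obs, nulls, "warm", "cold")
  eji <- frad(obs, nulls, "cold", "warm")
  expect_equal(eij$null_values, -eji$null_values, tolerance = 1e-12)
  expect_equal(eij$estimate, -eji$estimate, tolerance = 1e-12)
  expect_equal(rd_fpa(obs, "warm", "cold"), -rd_fpa(obs, "cold", "warm"),
               tolerance = 1e-12)

  scale_tot <- function(t, k) {
    t$F <- t$F * k
    t
  }
  k <- 17.3
  eij_s <- frad(scale_tot(obs, k), lapply(nulls, scale_tot, k = k),
                "warm", "cold")
  expect_equal(eij_s$null_values, eij$null_values, tolerance = 1e-12)
  expect_equal(rd_fpa(scale_tot(obs, k), "warm", "cold"),
               rd_fpa(obs, "warm", "cold"), tolerance = 1e-12)
})

test_that("RD_FPA reproduces its arithmetic reference cases and errors", {
  equal_density <- manual_totals(F_warm = 2, F_cold = 2, F_non = 2,
                                 A_warm = 1, A_cold = 1, A_non = 1)
  expect_equal(rd_fpa(equal_density, "warm", "cold"), 0, tolerance = 1e-12)

  # F(i)/A(i) = 2k, F(j)/A(j) = k, overall density k  ->  +100%
  tot <- manual_totals(F_warm = 2, F_cold = 1, F_non = 5,
                       A_warm = 1, A_cold = 1, A_non = 6)
  expect_equal(rd_fpa(tot, "warm", "cold"), 100, tolerance = 1e-12)

  zero_area <- manual_totals(F_warm = 1, F_cold = 1, F_non = 1,
                             A_warm = 0, A_cold = 1, A_non = 1)
  expect_error(rd_fpa(zero_area, "warm", "cold"), "zero-area")
})

test_that("RD_FPA matches an independent brute-force oracle on random labeled grids", {
  km <- pi * 6371 / 180
  for (s in 1:100) {
    set.seed(s)
    lab <- matrix(sample(0:3, 100, replace = TRUE, prob = c(.5, .1, .2, .2)),
                  10, 10)
    sstm <- matrix(rnorm(100, 15), 10, 10)
    labs <- manual_labels(lab, sstm)
    n <- 30
    rec <- data.frame(date = labs$date,
                      lon = runif(n, min(labs$lon) - 0.05, max(labs$lon) + 0.05),
                      lat = runif(n, min(labs$lat) - 0.05, max(labs$lat) + 0.05),
                      catch = rlnorm(n))
    tot <- suppressMessages(assign_records_to_zones(rec, labs))$totals

    # oracle: direct Eq-style arithmetic from first principles
    cellarea <- outer(0.1 * km * cos(labs$lat * pi / 180) * 0.1 * km,
                      rep(1, 10))
    px_r <- floor((rec$lat - 40) / 0.1) + 1
    px_c <- floor((rec$lon - 150) / 0.1) + 1
    F_of <- function(codes) {
      sum(rec$catch[px_r >= 1 & px_r <= 10 & px_c >= 1 & px_c <= 10 &
                      lab[cbind(pmin(pmax(px_r, 1), 10),
                                pmin(pmax(px_c, 1), 10))] %in% codes])
    }
    A_of <- function(codes) sum(cellarea[lab %in% codes])
    # manual_labels assigns line pixels to the warm side
    Fi <- F_of(c(2, 1)); Fj <- F_of(3)
    Ai <- A_of(c(2, 1)); Aj <- A_of(3)
    Fall <- F_of(0:3); Aall <- A_of(0:3)
    if (Ai == 0 || Aj == 0 || Fall == 0) next
    oracle <- ((Fi / Ai - Fj / Aj) / (Fall / Aall)) * 100
    expect_equal(rd_fpa(tot, "warm", "cold"), oracle, tolerance = 1e-12)
  }
})

test_that("the underestimation rate reproduces its reference cases", {
  expect_equal(underestimation_rate(50, -50, 0)$UR, 100)
  expect_equal(underestimation_rate(50, 50, 50)$UR, 0)
  expect_equal(underestimation_rate(40, 10, 80)$UR, -50)
  expect_message(z <- underestimation_rate(0, 0, 0), "0")
  expect_equal(z$UR, 0)
  expect_true(all(abs(underestimation_rate(rnorm(50, 40, 5),
                                           rnorm(50, -40, 5),
                                           rnorm(50, 0, 5))$values) <= 100))
})

test_that("replicates with zero simulated catch are dropped or fail loudly", {
  obs <- manual_totals(F_warm = 10, F_cold = 10, F_non = 30)
  nulls <- replicate(30, manual_totals(F_warm = 10, F_cold = 10, F_non = 30),
                     simplify = FALSE)
  nulls[[1]] <- manual_totals(F_warm = 0, F_cold = 10, F_non = 30)
  expect_message(e <- frad(obs, nulls, "warm", "cold"), "dropped 1")
  expect_identical(e$n_dropped, 1L)
  bad <- replicate(30, manual_totals(F_warm = 0, F_cold = 10, F_non = 30),
                   simplify = FALSE)
  expect_error(frad(obs, bad, "warm", "cold"), "zero simulated")
})

test_that("a spatially constant density yields a zero RD_FPA map, and smoothing conserves mass", {
  labs <- straight_labels()
  # one record per pixel centre with catch = pixel area: constant density
  centres <- expand.grid(lat = labs$lat, lon = labs$lon)
  rec <- data.frame(date = labs$date, lon = centres$lon, lat = centres$lat,
                    catch = as.vector(pixel_areas(labs)))
  m <- spatial_rd_fpa(rec, labs, cell_deg = 1, smooth_fwhm_deg = 3,
                      min_records = 1)
  vals <- m$value[!is.na(m$value)]
  expect_gt(length(vals), 0)
  expect_equal(max(abs(vals)), 0, tolerance = 1e-9)
  expect_equal(max(abs(m$smoothed), na.rm = TRUE), 0, tolerance = 1e-9)

  # linear-filter property on a synthetic one-hot map, away from edges
  hot <- matrix(0, 17, 17); hot[9, 9] <- 100
  sm <- frontfish:::gaussian_smooth(hot, fwhm = 3)
  expect_lt(sm[9, 9], 100)
  expect_gt(min(sm[8:10, 8:10]), 0)
  expect_equal(sum(sm), 100, tolerance = 1e-9)
})
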