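test_that("normalized distance is 0 on the front line and +/-1 at zone boundaries", {
  labs <- straight_labels()
  nr <- nrow(labs$label)
  px_tol <- labs$res * pi * 6371 / 180 # one-pixel quantization, km

  # a record exactly on a frontal pixel centre
  fidx <- which(!is.na(labs$front_id))[10]
  rec0 <- data.frame(date = labs$date,
                     lon = labs$lon[((fidx - 1) %/% nr) + 1],
                     lat = labs$lat[((fidx - 1) %% nr) + 1],
                     catch = 1)
  nd0 <- normalized_distance(rec0, labs)
  expect_equal(nd0$nd, 0, tolerance = 1e-9)

  # records on warm / cold boundary pixels: |nd| = 1 within quantization
  for (side in c("warm", "cold")) {
    b_idx <- zone_boundary_pixels(labs, side)
    pick <- b_idx[seq(1, length(b_idx), length.out = 5)]
    rec <- data.frame(date = labs$date,
                      lon = labs$lon[((pick - 1) %/% nr) + 1],
                      lat = labs$lat[((pick - 1) %% nr) + 1],
                      catch = 1)
    nd <- normalized_distance(rec, labs)
    expect_true(all(nd$usable))
    sgn <- if (side == "warm") 1 else -1
    expect_true(all(sign(nd$nd) == sgn))
    expect_true(all(abs(abs(nd$nd) - 1) <= px_tol / nd$width_km + 1e-9))
  }
})

test_that("a record midway between front and cold boundary has nd near -0.5", {
  labs <- wide_labels()
  nr <- nrow(labs$label)
  # straight east-west front: pick a column, find its front row and cold
  # boundary row, place a record halfway along the meridian
  col <- 30
  f_rows <- which(!is.na(labs$front_id[, col]))
  b_cold <- zone_boundary_pixels(labs, "cold")
  b_rows <- ((b_cold - 1) %% nr) + 1
  b_cols <- ((b_cold - 1) %/% nr) + 1
  brow <- b_rows[b_cols == col]
  expect_gt(length(brow), 0)
  expect_gt(length(f_rows), 0)
  f_row <- min(f_rows) # cold-side edge of the front line
  b_row <- min(brow)
  rec <- data.frame(date = labs$date, lon = labs$lon[col],
                    lat = (labs$lat[f_row] + labs$lat[b_row]) / 2, catch = 1)
  nd <- normalized_distance(rec, labs)
  n_px <- abs(f_row - b_row)
  expect_lt(abs(nd$nd - (-0.5)), 1 / n_px + 0.05) # grid-quantization tolerance
})

test_that("nd sign is consistent with zone labels for in-zone records", {
  labs <- straight_labels()
  set.seed(21)
  rec <- data.frame(date = labs$date, lon = runif(400, 150, 153),
                    lat = runif(400, 38, 41), catch = 1)
  ass <- assign_records_to_zones(rec, labs)
  nd <- normalized_distance(ass$records, labs)
  in_warm <- ass$records$zone == "warm_zone"
  in_cold <- ass$records$zone == "cold_zone"
  expect_true(all(nd$nd[in_warm & nd$usable] > 0))
  expect_true(all(nd$nd[in_cold & nd$usable] < 0))
})

test_that("bin populations sum to the number of usable in-range records", {
  labs <- wide_labels()
  set.seed(22)
  rec <- data.frame(date = labs$date, lon = runif(500, 150, 153),
                    lat = runif(500, 38, 41), catch = rlnorm(500))
  nul <- randomize_records(rec, window_deg = 2, R = 30, seed = 23)
  prof <- composite_profile(rec, labs, nul)
  ndr <- frontfish:::nd_raster(labs, cap = 3)
  px <- locate_pixels(labs, rec$lon, rec$lat)
  nd <- ndr[cbind(px$row, px$col)]
  usable <- sum(!is.na(nd) & abs(nd) <= 3)
  expect_identical(sum(prof$n_obs), usable)
})

test_that("records confined to one nd bin put observed mass only there", {
  labs <- wide_labels()
  nr <- nrow(labs$label)
  ndr <- frontfish:::nd_raster(labs, cap = 3)
  sel <- which(ndr >= 0.30 & ndr < 0.45)
  expect_gte(length(sel), 5)
  sel <- sel[1:5]
  rec <- data.frame(date = labs$date,
                    lon = labs$lon[((sel - 1) %/% nr) + 1],
                    lat = labs$lat[((sel - 1) %% nr) + 1],
                    catch = 1)
  nd <- normalized_distance(rec, labs)
  expect_true(all(nd$nd >= 0.30 & nd$nd < 0.45))
  nul <- randomize_records(rec, window_deg = 2, R = 25, seed = 5)
  prof <- composite_profile(rec, labs, nul)
  expect_identical(sum(prof$n_obs[prof$bin_lo < 0.29 | prof$bin_lo > 0.44]), 0L)
  expect_identical(sum(prof$n_obs), 5L)
})

test_that("a held-out null replicate produces a profile whose envelope covers 0", {
  labs <- straight_labels()
  g <- straight_field()
  rec <- sample_fishing_records(g, fishery_spec(1500, seed = 31))
  ens <- randomize_records(rec, window_deg = 2, R = 41, mask = g, seed = 32)
  obs <- ens$replicates[[1]]
  nul <- structure(list(replicates = ens$replicates[-1], window_deg = 2,
                        R = 40L, seed = 32, center = "record"),
                   class = "null_ensemble")
  prof <- composite_profile(obs, labs, nul)
  have <- !is.na(prof$median_anomaly) & prof$n_obs >= 3
  expect_gt(sum(have), 5)
  expect_true(all(prof$q05[have] <= 0 & prof$q95[have] >= 0))
})

test_that("a cold-preferring fishery peaks in negative-nd bins", {
  g <- straight_field()
  labs <- straight_labels()
  rec <- sample_fishing_records(
    g, fishery_spec(2000, mu_pref = 12.6, sigma_pref = 0.25, seed = 33))
  nul <- randomize_records(rec, window_deg = 2, R = 60, mask = g, seed = 34)
  prof <- composite_profile(rec, labs, nul)
  peak <- prof$bin_mid[which.max(prof$median_anomaly)]
  expect_lt(peak, 0)
})
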