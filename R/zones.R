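#' Zone label codes
#'
#' Integer codes used in front label maps: `non_frontal = 0`,
#' `frontal_line = 1`, `warm_zone = 2`, `cold_zone = 3`, `masked = 4`.
#' @export
ZONE_CODES <- c(non_frontal = 0L, frontal_line = 1L, warm_zone = 2L,
                cold_zone = 3L, masked = 4L)

#' Partition pixels around detected fronts into warm and cold zones
#'
#' Defines the frontal zone around each front and splits it by temperature.
#' In `"relative"` mode the zone is grown (8-connectivity) outward from each
#' frontal pixel over unmasked non-frontal pixels whose gradient magnitude is
#' at least `threshold_frac` times the magnitude at the seeding frontal
#' pixel, stopping `max_extent_km` from the seed; in `"fixed_width"` mode the
#' zone is all pixels within `fixed_width_km` of any frontal pixel. Every
#' zone pixel is then attached to its nearest frontal pixel by great-circle
#' distance (ties broken by smallest row then column; when several fronts
#' compete, the nearest frontal pixel decides) and labelled `warm_zone` if
#' strictly warmer than that pixel, `cold_zone` if strictly colder; an exact
#' SST tie is assigned to the warm zone so every pixel is labelled.
#'
#' @param sst an [sst_grid].
#' @param grad its [gradient field][compute_gradient]; computed when `NULL`.
#' @param fronts a [front_set][detect_fronts].
#' @param mode `"relative"` (gradient threshold relative to the seed) or
#'   `"fixed_width"`.
#' @param threshold_frac fraction of the seed gradient magnitude (default
#'   1/2; 1/4 and 3/4 are the conventional sensitivity settings).
#' @param fixed_width_km zone half-width for `"fixed_width"` mode (40 or 80
#'   km are the conventional settings).
#' @param max_extent_km hard cap on zone growth distance from the seed.
#' @param log_space threshold the base-10 logarithm of the gradient magnitude
#'   instead of the magnitude itself.
#' @param despike classify warm/cold against a 3x3 median-despiked SST field
#'   (the same preprocessing used before histogram analysis); the despiked
#'   field is the one stored in the result and referenced by the warm/cold
#'   invariants.
#' @return list of class `front_labels`: `label` (integer matrix of
#'   [ZONE_CODES]), `front_id`, `nearest_front` (linear index of the nearest
#'   frontal pixel, defined for zone pixels), `dist_to_front_km`,
#'   `line_side` (for frontal-line pixels: `"warm"`/`"cold"` by comparison
#'   with the mean of their 4-neighbours), `threshold_used` (per-front
#'   data.frame), plus the grid axes (`lon`, `lat`, `res`, `date`), the SST
#'   matrix `sst` and gradient `grad_mag`.
#' @export
partition_zones <- function(sst, grad = NULL, fronts,
                            mode = c("relative", "fixed_width"),
                            threshold_frac = 0.5, fixed_width_km = 40,
                            max_extent_km = 100, log_space = FALSE,
                            despike = TRUE) {
  mode <- match.arg(mode)
  stopifnot(threshold_frac > 0, fixed_width_km > 0, max_extent_km > 0)
  if (is.null(grad)) grad <- compute_gradient(sst)
  nr <- length(sst$lat); nc <- length(sst$lon)
  v <- sst$values
  v[sst$mask] <- NA
  if (isTRUE(despike)) v <- median_filter3(v)
  gmag <- grad$magnitude

  label <- matrix(ZONE_CODES[["non_frontal"]], nr, nc)
  label[sst$mask] <- ZONE_CODES[["masked"]]
  fid <- fronts$front_id
  is_front <- !is.na(fid)
  label[is_front] <- ZONE_CODES[["frontal_line"]]

  nearest_front <- matrix(NA_integer_, nr, nc)
  dist_to_front <- matrix(NA_real_, nr, nc)

  if (any(is_front)) {
    f_idx <- which(is_front)
    # order frontal pixels by (row, col) so ties resolve to the smallest index
    f_rows <- ((f_idx - 1L) %% nr) + 1L
    f_cols <- ((f_idx - 1L) %/% nr) + 1L
    o <- order(f_rows, f_cols)
    f_idx <- f_idx[o]; f_rows <- f_rows[o]; f_cols <- f_cols[o]
    f_lon <- sst$lon[f_cols]; f_lat <- sst$lat[f_rows]

    zone <- if (mode == "relative") {
      grow_zone(gmag, is_front, sst$mask, f_idx, f_lon, f_lat,
                threshold_frac, max_extent_km, log_space,
                lon = sst$lon, lat = sst$lat)
    } else {
      within_width(sst, is_front, f_lon, f_lat, fixed_width_km)
    }

    z_idx <- which(zone)
    if (length(z_idx)) {
      z_rows <- ((z_idx - 1L) %% nr) + 1L
      z_cols <- ((z_idx - 1L) %/% nr) + 1L
      dmat <- cross_dist_km(sst$lon[z_cols], sst$lat[z_rows], f_lon, f_lat)
      nf <- max.col(-dmat, ties.method = "first")
      nearest_front[z_idx] <- f_idx[nf]
      dist_to_front[z_idx] <- dmat[cbind(seq_along(nf), nf)]
      warmer <- v[z_idx] >= v[f_idx[nf]] # tie -> warm
      label[z_idx[warmer]] <- ZONE_CODES[["warm_zone"]]
      label[z_idx[!warmer]] <- ZONE_CODES[["cold_zone"]]
    }
  } else if (mode == "relative") {
    stop("front set is empty; no zones to grow")
  }

  structure(list(
    label = label, front_id = fid, nearest_front = nearest_front,
    dist_to_front_km = dist_to_front,
    line_side = line_side(v, is_front),
    threshold_used = threshold_table(fronts, gmag, mode, threshold_frac,
                                     fixed_width_km),
    lon = sst$lon, lat = sst$lat, res = sst$res, date = sst$date,
    sst = v, grad_mag = gmag, mask = sst$mask, mode = mode
  ), class = "front_labels")
}

# Frontier-batch BFS growth of the relative-threshold zone. Each frontier
# entry carries its seed; a neighbour joins if unvisited, unmasked,
# non-frontal, its gradient >= frac * gradient(seed) (optionally in log10
# space) and it lies within max_extent_km of that seed.
grow_zone <- function(gmag, is_front, mask, f_idx, f_lon, f_lat,
                      frac, max_extent_km, log_space, lon, lat) {
  nr <- nrow(gmag); nc <- ncol(gmag)
  thr <- if (log_space) {
    g <- log10(pmax(gmag[f_idx], .Machine$double.xmin))
    frac * g
  } else {
    frac * gmag[f_idx]
  }
  gtest <- if (log_space) log10(pmax(gmag, .Machine$double.xmin)) else gmag
  visited <- is_front | mask
  zone <- matrix(FALSE, nr, nc)
  frontier_px <- f_idx
  frontier_seed <- seq_along(f_idx)
  nbr <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  while (length(frontier_px)) {
    rows <- ((frontier_px - 1L) %% nr) + 1L
    cols <- ((frontier_px - 1L) %/% nr) + 1L
    cand_px <- integer(0); cand_seed <- integer(0)
    for (k in seq_len(nrow(nbr))) {
      r2 <- rows + nbr[k, 1]; c2 <- cols + nbr[k, 2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      if (!any(ok)) next
      p2 <- (c2[ok] - 1L) * nr + r2[ok]
      s2 <- frontier_seed[ok]
      ok2 <- !visited[p2] & !is.na(gtest[p2]) & gtest[p2] >= thr[s2]
      if (!any(ok2)) next
      p2 <- p2[ok2]; s2 <- s2[ok2]
      d <- haversine_km(lon[((p2 - 1L) %/% nr) + 1L],
                        lat[((p2 - 1L) %% nr) + 1L],
                        f_lon[s2], f_lat[s2])
      ok3 <- d <= max_extent_km
      cand_px <- c(cand_px, p2[ok3])
      cand_seed <- c(cand_seed, s2[ok3])
    }
    if (!length(cand_px)) break
    first <- !duplicated(cand_px)
    cand_px <- cand_px[first]; cand_seed <- cand_seed[first]
    new <- !visited[cand_px]
    cand_px <- cand_px[new]; cand_seed <- cand_seed[new]
    visited[cand_px] <- TRUE
    zone[cand_px] <- TRUE
    frontier_px <- cand_px
    frontier_seed <- cand_seed
  }
  zone
}

# Pixels within fixed_width_km of any frontal pixel (excluding the front
# line and masked pixels), via a pixel-dilation prefilter plus exact
# great-circle distances.
within_width <- function(sst, is_front, f_lon, f_lat, width_km) {
  nr <- nrow(is_front); nc <- ncol(is_front)
  px_km <- sst$res * KM_PER_DEG * min(cos(sst$lat * pi / 180))
  steps <- ceiling(width_km / (sst$res * KM_PER_DEG * min(cos(sst$lat * pi / 180)))) + 1L
  cand <- dilate(is_front, steps)
  cand <- cand & !is_front & !sst$mask
  idx <- which(cand)
  if (!length(idx)) return(cand & FALSE)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  dmat <- cross_dist_km(sst$lon[cols], sst$lat[rows], f_lon, f_lat)
  keep <- apply(dmat, 1, min) <= width_km
  out <- matrix(FALSE, nr, nc)
  out[idx[keep]] <- TRUE
  out
}

# Chebyshev dilation of a logical matrix by `steps` pixels.
dilate <- function(m, steps) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (s in seq_len(steps)) {
    grown <- out
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
      rs <- seq_len(nr) + d[1]; cs <- seq_len(nc) + d[2]
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      grown[ok_r, ok_c] <- grown[ok_r, ok_c] | out[rs[ok_r], cs[ok_c]]
    }
    if (identical(grown, out)) break
    out <- grown
  }
  out
}

# Warm/cold sub-side of frontal-line pixels: warm when the pixel is warmer
# than the mean of its valid 4-neighbours (ties -> warm).
line_side <- function(v, is_front) {
  nr <- nrow(v); nc <- ncol(v)
  ssum <- matrix(0, nr, nc); cnt <- matrix(0L, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + d[1]; cs <- seq_len(nc) + d[2]
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    nb[ok_r, ok_c] <- v[rs[ok_r], cs[ok_c]]
    has <- !is.na(nb)
    ssum[has] <- ssum[has] + nb[has]
    cnt <- cnt + has
  }
  side <- matrix(NA_character_, nr, nc)
  ok <- is_front & cnt > 0
  side[ok] <- ifelse(v[ok] >= ssum[ok] / cnt[ok], "warm", "cold")
  side[is_front & cnt == 0] <- "warm"
  side
}

threshold_table <- function(fronts, gmag, mode, frac, width_km) {
  if (nrow(fronts$pixels) == 0) {
    return(data.frame(front_id = integer(0), n_pixels = integer(0),
                      median_seed_gradient = numeric(0)))
  }
  sp <- split(seq_len(nrow(fronts$pixels)), fronts$pixels$front_id)
  data.frame(
    front_id = as.integer(names(sp)),
    n_pixels = lengths(sp),
    median_seed_gradient = vapply(sp, function(i) {
      stats::median(gmag[cbind(fronts$pixels$row[i], fronts$pixels$col[i])],
                    na.rm = TRUE)
    }, numeric(1)),
    mode = mode,
    parameter = if (mode == "relative") frac else width_km,
    row.names = NULL
  )
}

#' @export
print.front_labels <- function(x, ...) {
  tab <- table(factor(names(ZONE_CODES)[match(x$label, ZONE_CODES)],
                      levels = names(ZONE_CODES)))
  cat(sprintf("<front_labels> %s, %d x %d px (%s mode)\n",
              format(x$date), length(x$lat), length(x$lon), x$mode))
  print(tab)
  invisible(x)
}

#' Boundary pixels of the frontal zones
#'
#' Zone pixels (warm or cold) having at least one 4-neighbour outside the
#' frontal zone (non-frontal, masked, or off-grid). These are the pixels
#' that define the local frontal-zone width for normalized distances.
#'
#' @param labels a [front_labels][partition_zones] object.
#' @param side `"warm"` or `"cold"`.
#' @return integer vector of linear pixel indices.
#' @export
zone_boundary_pixels <- function(labels, side = c("warm", "cold")) {
  side <- match.arg(side)
  code <- ZONE_CODES[[paste0(side, "_zone")]]
  lab <- labels$label
  nr <- nrow(lab); nc <- ncol(lab)
  inzone <- lab == ZONE_CODES[["warm_zone"]] | lab == ZONE_CODES[["cold_zone"]] |
    lab == ZONE_CODES[["frontal_line"]]
  outside <- matrix(FALSE, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- matrix(TRUE, nr, nc) # off-grid counts as outside
    rs <- seq_len(nr) + d[1]; cs <- seq_len(nc) + d[2]
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    nb[ok_r, ok_c] <- !inzone[rs[ok_r], cs[ok_c]]
    outside <- outside | nb
  }
  which(lab == code & outside)
}

#' Write a label map to CSV / front polylines to GeoJSON
#'
#' The label raster is written in long form (`lon,lat,label,front_id`), with
#' the integer codes documented in [ZONE_CODES]. Front lines are written as
#' one GeoJSON `MultiPoint` feature per front (pixel centres in reading
#' order) with a `front_id` property.
#'
#' @param labels a [front_labels][partition_zones] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  idx <- which(labels$label != ZONE_CODES[["masked"]], arr.ind = TRUE)
  df <- data.frame(
    date = format(labels$date),
    lon = labels$lon[idx[, 2]], lat = labels$lat[idx[, 1]],
    label = labels$label[idx], front_id = labels$front_id[idx]
  )
  utils::write.csv(df[order(df$lat, df$lon), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
write_fronts_geojson <- function(labels, path) {
  ids <- sort(unique(labels$front_id[!is.na(labels$front_id)]))
  feats <- lapply(ids, function(id) {
    px <- which(labels$front_id == id, arr.ind = TRUE)
    coords <- cbind(labels$lon[px[, 2]], labels$lat[px[, 1]])
    list(type = "Feature",
         properties = list(front_id = id, n_pixels = nrow(coords)),
         geometry = list(type = "MultiPoint", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
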