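# Zonal environmental contrasts: vertical profile smoothing and
# warm-minus-cold differences of profile variables and surface chlorophyll.

#' Regrid and smooth a vertical profile
#'
#' Interpolates a profile linearly to a regular 5 m depth grid within its
#' observed span (no extrapolation), then applies a 25 m (5-level) running
#' median followed by a running mean of the same window; windows are
#' truncated at the profile ends. The median stage removes single-level
#' spikes, the mean stage smooths residual noise.
#'
#' @param depth depth levels, m (strictly increasing within 0-2000).
#' @param values variable at those levels (temperature, oxygen, ...).
#' @param step regridding interval, m.
#' @param window_m filter window length, m (converted to levels).
#' @param mean_window_m mean-filter window length, m (defaults to
#'   `window_m`).
#' @return data.frame with `depth` and `value` on the 5 m grid.
#' @export
smooth_profile <- function(depth, values, step = 5, window_m = 25,
                           mean_window_m = window_m) {
  ok <- is.finite(depth) & is.finite(values)
  depth <- depth[ok]; values <- values[ok]
  if (length(depth) < 5) stop("need at least 5 valid levels")
  if (is.unsorted(depth, strictly = TRUE)) stop("depths must be strictly increasing")
  if (diff(range(depth)) < window_m) {
    stop(sprintf("profile spans %.0f m; need at least %.0f m", diff(range(depth)), window_m))
  }
  grid <- seq(ceiling(min(depth) / step) * step,
              floor(max(depth) / step) * step, by = step)
  v <- stats::approx(depth, values, xout = grid)$y
  k_med <- max(1L, round(window_m / step)) %/% 2L * 2L + 1L
  k_mean <- max(1L, round(mean_window_m / step)) %/% 2L * 2L + 1L
  v <- roll_stat(v, k_med, stats::median)
  v <- roll_stat(v, k_mean, mean)
  data.frame(depth = grid, value = v)
}

#' Warm-minus-cold environmental differences from profiles
#'
#' Matches each profile to the zone of the pixel containing it on the label
#' map of its date, smooths it with [smooth_profile()], extracts the value
#' at the requested depth, and contrasts warm- and cold-zone means within
#' coarse cells (default 2 degrees) per calendar month. Cells represented by
#' only one zone are no-data (dropped).
#'
#' @param profiles long-format data.frame: `profile_id`, `lon`, `lat`,
#'   `date`, `depth`, and the variable column.
#' @param labels a single [front_labels][partition_zones] object or a list
#'   of them keyed by `format(date)`.
#' @param depth_m target depth, m.
#' @param variable column name to contrast (default `"temp"`).
#' @param cell_deg contrast cell size, degrees.
#' @param smooth apply [smooth_profile()] before extracting the level.
#' @return data.frame: `cell_lon`, `cell_lat`, `month`, `n_warm`, `n_cold`,
#'   `warm_mean`, `cold_mean`, `difference` (warm minus cold).
#' @export
zonal_env_difference <- function(profiles, labels, depth_m, variable = "temp",
                                 cell_deg = 2, smooth = TRUE) {
  stopifnot(variable %in% names(profiles))
  lab_for <- function(date) {
    if (inherits(labels, "front_labels")) return(labels)
    labels[[format(as.Date(date))]]
  }
  ids <- unique(profiles$profile_id)
  rows <- lapply(ids, function(id) {
    p <- profiles[profiles$profile_id == id, , drop = FALSE]
    lm <- lab_for(p$date[1])
    if (is.null(lm)) return(NULL)
    px <- locate_pixels(lm, p$lon[1], p$lat[1])
    if (is.na(px$row)) return(NULL)
    code <- lm$label[px$row, px$col]
    zone <- if (code == ZONE_CODES[["warm_zone"]]) "warm"
            else if (code == ZONE_CODES[["cold_zone"]]) "cold"
            else return(NULL)
    val <- if (smooth) {
      sm <- smooth_profile(p$depth, p[[variable]])
      stats::approx(sm$depth, sm$value, xout = depth_m)$y
    } else {
      stats::approx(p$depth, p[[variable]], xout = depth_m)$y
    }
    if (!is.finite(val)) return(NULL)
    data.frame(lon = p$lon[1], lat = p$lat[1],
               month = format(as.Date(p$date[1]), "%Y-%m"),
               zone = zone, value = val)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no profiles fall inside warm or cold zones")
  }
  rows$cell_lon <- (floor(rows$lon / cell_deg) + 0.5) * cell_deg
  rows$cell_lat <- (floor(rows$lat / cell_deg) + 0.5) * cell_deg
  sp <- split(rows, interaction(rows$cell_lon, rows$cell_lat, rows$month,
                                drop = TRUE))
  out <- lapply(sp, function(g) {
    w <- g$value[g$zone == "warm"]; cz <- g$value[g$zone == "cold"]
    if (!length(w) || !length(cz)) return(NULL) # one-zone cell: no-data
    data.frame(cell_lon = g$cell_lon[1], cell_lat = g$cell_lat[1],
               month = g$month[1], n_warm = length(w), n_cold = length(cz),
               warm_mean = mean(w), cold_mean = mean(cz),
               difference = mean(w) - mean(cz))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(cell_lon = numeric(0), cell_lat = numeric(0),
                      month = character(0), n_warm = integer(0),
                      n_cold = integer(0), warm_mean = numeric(0),
                      cold_mean = numeric(0), difference = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Relative chlorophyll difference between frontal warm and cold zones
#'
#' Per coarse cell (default 1 degree), the difference of mean chlorophyll
#' between warm- and cold-zone pixels divided by the cell's overall mean,
#' in percent: `(mean_warm - mean_cold) / mean_all * 100`. Cells lacking
#' either zone, or with a zero overall mean, are no-data.
#'
#' @param chl an [sst_grid]-shaped raster of chlorophyll co-registered with
#'   the label map (same axes).
#' @param labels a [front_labels][partition_zones] object.
#' @param cell_deg cell size, degrees.
#' @return data.frame: `cell_lon`, `cell_lat`, `n_warm`, `n_cold`,
#'   `relative_difference` (%).
#' @export
zonal_chl_relative_difference <- function(chl, labels, cell_deg = 1) {
  if (!isTRUE(all.equal(chl$lon, labels$lon)) ||
      !isTRUE(all.equal(chl$lat, labels$lat))) {
    stop("chlorophyll grid must be co-registered with the label map")
  }
  idx <- which(!chl$mask & labels$label != ZONE_CODES[["masked"]], arr.ind = TRUE)
  df <- data.frame(
    lon = chl$lon[idx[, 2]], lat = chl$lat[idx[, 1]],
    chl = chl$values[idx], code = labels$label[idx]
  )
  df$cell_lon <- (floor(df$lon / cell_deg) + 0.5) * cell_deg
  df$cell_lat <- (floor(df$lat / cell_deg) + 0.5) * cell_deg
  sp <- split(df, interaction(df$cell_lon, df$cell_lat, drop = TRUE))
  out <- lapply(sp, function(g) {
    w <- g$chl[g$code == ZONE_CODES[["warm_zone"]]]
    cz <- g$chl[g$code == ZONE_CODES[["cold_zone"]]]
    if (!length(w) || !length(cz)) return(NULL)
    m_all <- mean(g$chl)
    if (!is.finite(m_all) || m_all == 0) return(NULL)
    data.frame(cell_lon = g$cell_lon[1], cell_lat = g$cell_lat[1],
               n_warm = length(w), n_cold = length(cz),
               relative_difference = (mean(w) - mean(cz)) / m_all * 100)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
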