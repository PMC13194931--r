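#' Specification of a synthetic SST front
#'
#' Describes a single mesoscale front as a parametric axis with a smooth
#' (tanh) cross-front temperature transition. When `axis` is `NULL` the axis
#' is built inside [make_sst_field()] as a west-to-east curve through the
#' domain centre with a sinusoidal meander; the warm side is then the
#' northern side (in general, the left side of the vertex order).
#'
#' @param delta_T cross-front temperature contrast, degrees Celsius (> 0).
#' @param width_km transition half-width, km (> 0); the tanh transition
#'   saturates within roughly +/- 2 widths.
#' @param T_cold cold-side base temperature, degrees Celsius.
#' @param axis optional two-column matrix (lon, lat) of axis vertices.
#' @param meander_amplitude_km,meander_wavelength_km amplitude and wavelength
#'   of the sinusoidal meander used when `axis` is `NULL`.
#' @param n_vertices number of vertices used for the generated axis.
#' @return An object of class `front_spec`.
#' @export
front_spec <- function(delta_T = 2, width_km = 10, T_cold = 12,
                       axis = NULL, meander_amplitude_km = 0,
                       meander_wavelength_km = 200, n_vertices = 200L) {
  stopifnot(delta_T > 0, width_km > 0, meander_amplitude_km >= 0,
            meander_wavelength_km > 0, n_vertices >= 2)
  structure(list(delta_T = delta_T, width_km = width_km, T_cold = T_cold,
                 axis = axis, meander_amplitude_km = meander_amplitude_km,
                 meander_wavelength_km = meander_wavelength_km,
                 n_vertices = as.integer(n_vertices)),
            class = "front_spec")
}

#' Specification of a synthetic fishery
#'
#' Generative model for fishing records: locations are drawn from a smooth
#' large-scale background intensity multiplied by a Gaussian thermal
#' preference weight `exp(-(SST - mu_pref)^2 / (2 sigma_pref^2))`, and
#' optionally by an antisymmetric zone-occupancy weight (`1 + zone_amp` on
#' the true warm side of the front, `1 - zone_amp` on the cold side, within
#' `zone_band_km` of the axis) used to emulate fisheries that prefer one side
#' of a front without any net frontal-zone enrichment. Catches are drawn from
#' a log-normal, the conventional right-skewed model for positive catches.
#'
#' @param n_records number of records to draw (>= 1).
#' @param mu_pref preferred SST, degrees Celsius, or `NULL` for a thermally
#'   indifferent fishery (uniform thermal weight).
#' @param sigma_pref thermal niche breadth, degrees Celsius (> 0 when
#'   `mu_pref` is given).
#' @param background `NULL` for a flat background, or `function(lon, lat)`
#'   returning a non-negative intensity.
#' @param catch_meanlog,catch_sdlog log-normal catch parameters (tons).
#' @param zone_amp occupancy amplitude `a` in `[0, 1)` for the antisymmetric
#'   side preference; 0 disables it.
#' @param zone_band_km half-width of the band around the front axis within
#'   which the side preference applies.
#' @param seed integer seed; draws are reproducible under a fixed seed.
#' @return An object of class `fishery_spec`.
#' @export
fishery_spec <- function(n_records, mu_pref = NULL, sigma_pref = NULL,
                         background = NULL, catch_meanlog = 0,
                         catch_sdlog = 0.5, zone_amp = 0,
                         zone_band_km = Inf, seed = 1L) {
  stopifnot(n_records >= 1, zone_amp >= 0, zone_amp < 1, zone_band_km > 0)
  if (!is.null(mu_pref)) {
    stopifnot(is.numeric(sigma_pref), sigma_pref > 0)
  }
  if (!is.null(background)) stopifnot(is.function(background))
  structure(list(n_records = as.integer(n_records), mu_pref = mu_pref,
                 sigma_pref = sigma_pref, background = background,
                 catch_meanlog = catch_meanlog, catch_sdlog = catch_sdlog,
                 zone_amp = zone_amp, zone_band_km = zone_band_km,
                 seed = seed),
            class = "fishery_spec")
}

#' Specification of synthetic vertical profiles
#'
#' Emulates paired float profiles in frontal warm and cold zones: a smooth
#' climatological base profile, a prescribed warm-minus-cold offset as a
#' function of depth (temperature and optionally oxygen), and independent
#' per-level noise.
#'
#' @param n_warm,n_cold number of profiles per zone.
#' @param depth_range depth span in metres, within 0-2000.
#' @param temp_offset,oxygen_offset warm-minus-cold offsets: a constant or a
#'   `function(depth_m)`.
#' @param noise_sd per-level observation noise SD (same units as variable).
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(n_warm = 20L, n_cold = 20L,
                         depth_range = c(0, 1000), temp_offset = 1,
                         oxygen_offset = -10, noise_sd = 0) {
  stopifnot(depth_range[1] >= 0, depth_range[2] <= 2000,
            depth_range[2] > depth_range[1], noise_sd >= 0)
  structure(list(n_warm = as.integer(n_warm), n_cold = as.integer(n_cold),
                 depth_range = depth_range, temp_offset = temp_offset,
                 oxygen_offset = oxygen_offset, noise_sd = noise_sd),
            class = "profile_spec")
}

# Build the axis polyline (lon/lat) for a front within a domain, and the
# planar-km transform used for signed distances.
build_axis <- function(front, domain) {
  lat0 <- mean(domain$lat)
  coslat <- cos(lat0 * pi / 180)
  if (is.null(front$axis)) {
    lons <- seq(domain$lon[1], domain$lon[2], length.out = front$n_vertices)
    x_km <- (lons - domain$lon[1]) * KM_PER_DEG * coslat
    lat_off <- front$meander_amplitude_km *
      sin(2 * pi * x_km / front$meander_wavelength_km) / KM_PER_DEG
    axis <- cbind(lon = lons, lat = lat0 + lat_off)
  } else {
    axis <- front$axis
  }
  if (any(axis[, 1] < domain$lon[1] - 1e-9) || any(axis[, 1] > domain$lon[2] + 1e-9) ||
      any(axis[, 2] < domain$lat[1] - 1e-9) || any(axis[, 2] > domain$lat[2] + 1e-9)) {
    stop("front axis lies outside the domain bounding box")
  }
  list(axis = axis, lat0 = lat0, coslat = coslat,
       lon0 = domain$lon[1], latmin = domain$lat[1])
}

to_plane_km <- function(ax, lon, lat) {
  list(x = (lon - ax$lon0) * KM_PER_DEG * ax$coslat,
       y = (lat - ax$latmin) * KM_PER_DEG)
}

#' Generate a synthetic SST field with a known front
#'
#' Builds a dated SST raster containing one meandering front:
#' `SST(p) = T_cold + delta_T * (1 + tanh(d(p)/width)) / 2 + noise`, where
#' `d(p)` is the signed cross-axis distance in km (positive on the warm
#' side). The returned grid carries the generative ground truth: the signed
#' distance raster and a per-pixel label among warm side, cold side, and
#' axis (pixels whose centre lies within half a pixel of the axis).
#'
#' @param domain list with `lon = c(min, max)`, `lat = c(min, max)` and
#'   `res` (grid step, degrees); the step must divide the spans evenly.
#' @param front a [front_spec()].
#' @param noise_sd SD of i.i.d. Gaussian observation noise, degrees Celsius.
#' @param seed integer seed for the noise.
#' @param date date stamp for the field.
#' @return An [sst_grid] with extra elements `truth` (character matrix:
#'   `"warm"`, `"cold"`, `"axis"`), `dist_km` (signed distance raster) and
#'   `front` (the spec, with the realized axis).
#' @examples
#' dom <- list(lon = c(150, 152), lat = c(38, 40), res = 0.1)
#' g <- make_sst_field(dom, front_spec(delta_T = 2, width_km = 10), noise_sd = 0)
#' table(g$truth)
#' @export
make_sst_field <- function(domain, front, noise_sd = 0, seed = 1L,
                           date = "2019-10-15") {
  stopifnot(noise_sd >= 0)
  res <- domain$res
  n_lon <- round(diff(domain$lon) / res)
  n_lat <- round(diff(domain$lat) / res)
  if (abs(n_lon * res - diff(domain$lon)) > 1e-6 ||
      abs(n_lat * res - diff(domain$lat)) > 1e-6) {
    stop("resolution must divide the domain spans evenly")
  }
  if (n_lon <= 2 || n_lat <= 2) stop("degenerate domain: need > 2 pixels per side")
  lon <- domain$lon[1] + (seq_len(n_lon) - 0.5) * res
  lat <- domain$lat[1] + (seq_len(n_lat) - 0.5) * res

  ax <- build_axis(front, domain)
  g <- expand.grid(lat = lat, lon = lon) # row-major in lat: matches matrix fill
  p <- to_plane_km(ax, g$lon, g$lat)
  v <- to_plane_km(ax, ax$axis[, 1], ax$axis[, 2])
  d <- signed_dist_polyline_km(p$x, p$y, v$x, v$y)
  dist_km <- matrix(d, nrow = n_lat, ncol = n_lon)

  sst <- front$T_cold + front$delta_T * (1 + tanh(dist_km / front$width_km)) / 2
  sst <- with_seed(seed, sst + matrix(stats::rnorm(length(sst), 0, noise_sd),
                                      n_lat, n_lon))

  half_px_km <- res * KM_PER_DEG / 2
  truth <- matrix(ifelse(abs(dist_km) <= half_px_km, "axis",
                         ifelse(dist_km > 0, "warm", "cold")),
                  n_lat, n_lon)

  out <- sst_grid(sst, lon, lat, date = date)
  out$truth <- truth
  out$dist_km <- dist_km
  front$axis <- ax$axis
  out$front <- front
  out
}

#' Sample fishing records over a synthetic SST field
#'
#' Draws record locations by rejection sampling from the unnormalized density
#' `background(lon, lat) * thermal(SST(lon, lat)) * side_weight`, with SST
#' evaluated by bilinear interpolation. The thermal term is the unit-peak
#' Gaussian preference (or 1 for an indifferent fishery); the side weight is
#' the optional antisymmetric occupancy factor of [fishery_spec()]. Catches
#' are log-normal; every record is stamped with the grid's date and carries
#' `cpue = catch / effort_days` with one fishing day per record.
#'
#' @param sst an [sst_grid]; for `zone_amp > 0` it must be a synthetic field
#'   from [make_sst_field()] (the side weight needs the ground-truth signed
#'   distance).
#' @param spec a [fishery_spec()].
#' @return data.frame with columns `date`, `lon`, `lat`, `catch`,
#'   `effort_days`, `cpue`.
#' @export
sample_fishing_records <- function(sst, spec) {
  stopifnot(inherits(spec, "fishery_spec"))
  if (any(!is.finite(sst$values[!sst$mask]))) {
    stop("SST grid has missing values inside the domain")
  }
  if (spec$zone_amp > 0 && is.null(sst$dist_km)) {
    stop("zone_amp > 0 requires a synthetic field with ground-truth distances")
  }
  lon_rng <- range(sst$lon) + c(-0.5, 0.5) * sst$res
  lat_rng <- range(sst$lat) + c(-0.5, 0.5) * sst$res

  thermal_w <- function(T) {
    if (is.null(spec$mu_pref)) rep(1, length(T))
    else exp(-(T - spec$mu_pref)^2 / (2 * spec$sigma_pref^2))
  }
  bg_w <- function(lon, lat) {
    if (is.null(spec$background)) rep(1, length(lon))
    else spec$background(lon, lat)
  }
  side_w <- function(lon, lat) {
    if (spec$zone_amp == 0) return(rep(1, length(lon)))
    px <- locate_pixels(sst, lon, lat)
    d <- sst$dist_km[cbind(px$row, px$col)]
    w <- rep(1, length(lon))
    in_band <- abs(d) <= spec$zone_band_km
    w[in_band & d > 0] <- 1 + spec$zone_amp
    w[in_band & d < 0] <- 1 - spec$zone_amp
    w
  }

  # Bound the density: bilinear SST stays within grid values, so the grid
  # maximum of the full weight (with a small safety factor for the smooth
  # background between nodes) bounds the interpolated weight.
  gl <- expand.grid(lat = sst$lat, lon = sst$lon)
  wmax <- max(bg_w(gl$lon, gl$lat) * thermal_w(as.vector(sst$values)) *
                side_w(gl$lon, gl$lat), na.rm = TRUE) * 1.05
  if (!is.finite(wmax) || wmax <= 0) {
    stop("acceptance probability is zero everywhere; ",
         "is mu_pref far outside the field's SST range?")
  }
  if (any(bg_w(gl$lon, gl$lat) < 0)) stop("background intensity must be >= 0")

  n <- spec$n_records
  with_seed(spec$seed, {
    got_lon <- numeric(0); got_lat <- numeric(0)
    attempts <- 0L
    max_attempts <- 1000L * n
    while (length(got_lon) < n) {
      m <- min(max(4L * (n - length(got_lon)), 1000L),
               max_attempts - attempts)
      if (m <= 0L) {
        stop(sprintf("rejection sampling failed after %d attempts", attempts))
      }
      attempts <- attempts + m
      clon <- stats::runif(m, lon_rng[1], lon_rng[2])
      clat <- stats::runif(m, lat_rng[1], lat_rng[2])
      Tc <- sst_at(sst, clon, clat)
      w <- bg_w(clon, clat) * thermal_w(Tc) * side_w(clon, clat)
      w[is.na(w)] <- 0
      keep <- stats::runif(m) * wmax < w
      got_lon <- c(got_lon, clon[keep])
      got_lat <- c(got_lat, clat[keep])
    }
    catch <- stats::rlnorm(n, spec$catch_meanlog, spec$catch_sdlog)
    data.frame(date = sst$date, lon = got_lon[seq_len(n)],
               lat = got_lat[seq_len(n)], catch = catch,
               effort_days = 1, cpue = catch)
  })
}

#' Sample synthetic vertical profiles in frontal zones
#'
#' Places profiles at random unmasked pixels of the warm and cold zones of a
#' front label map and generates temperature/oxygen against depth as a smooth
#' base profile plus the prescribed warm-minus-cold offset (applied to the
#' warm zone) and i.i.d. noise.
#'
#' @param spec a [profile_spec()].
#' @param labels a [front label map][partition_zones] with nonempty warm and
#'   cold zones.
#' @param seed integer seed.
#' @param by depth step of the generated levels, metres.
#' @return data.frame in long form: `profile_id`, `lon`, `lat`, `date`,
#'   `zone`, `depth`, `temp`, `oxygen`.
#' @export
sample_profiles <- function(spec, labels, seed = 1L, by = 5) {
  stopifnot(inherits(spec, "profile_spec"))
  for (z in c("warm", "cold")) {
    n <- if (z == "warm") spec$n_warm else spec$n_cold
    if (n < 1) stop(sprintf("n_profiles must be >= 1 for the %s zone", z))
    if (!any(labels$label == ZONE_CODES[paste0(z, "_zone")])) {
      stop(sprintf("the %s zone is empty; cannot place profiles", z))
    }
  }
  off_fun <- function(off) if (is.function(off)) off else function(z) rep(off, length(z))
  t_off <- off_fun(spec$temp_offset)
  o_off <- off_fun(spec$oxygen_offset)
  depth <- seq(spec$depth_range[1], spec$depth_range[2], by = by)
  base_t <- 18 * exp(-depth / 350) + 2          # thermocline-like base, degC
  base_o <- 180 + 80 * exp(-depth / 250)        # oxygen base, umol/kg

  with_seed(seed, {
    out <- list(); id <- 0L
    for (z in c("warm", "cold")) {
      n <- if (z == "warm") spec$n_warm else spec$n_cold
      px <- which(labels$label == ZONE_CODES[paste0(z, "_zone")], arr.ind = TRUE)
      pick <- px[sample.int(nrow(px), n, replace = TRUE), , drop = FALSE]
      for (k in seq_len(n)) {
        id <- id + 1L
        tt <- base_t + if (z == "warm") t_off(depth) else 0
        oo <- base_o + if (z == "warm") o_off(depth) else 0
        out[[id]] <- data.frame(
          profile_id = id,
          lon = labels$lon[pick[k, 2]], lat = labels$lat[pick[k, 1]],
          date = labels$date, zone = z, depth = depth,
          temp = tt + stats::rnorm(length(depth), 0, spec$noise_sd),
          oxygen = oo + stats::rnorm(length(depth), 0, spec$noise_sd)
        )
      }
    }
    do.call(rbind, out)
  })
}
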