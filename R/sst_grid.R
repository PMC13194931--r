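#' Gridded SST field
#'
#' Container for one dated sea-surface temperature raster on a regular
#' longitude/latitude grid, with an optional land/invalid mask. Values are
#' stored as a matrix with rows indexing latitude (south to north) and columns
#' indexing longitude (west to east); `lon` and `lat` hold the cell-centre
#' coordinates. Each cell covers the half-open box
#' `[lon - res/2, lon + res/2) x [lat - res/2, lat + res/2)`.
#'
#' @param values numeric matrix of SST in degrees Celsius,
#'   `length(lat)` rows by `length(lon)` columns.
#' @param lon,lat numeric vectors of cell-centre coordinates in decimal
#'   degrees, strictly increasing with constant step.
#' @param date a `Date` (or string coercible to one) stamping the field.
#' @param mask logical matrix of the same shape; `TRUE` marks land/invalid
#'   pixels. Default: no masked pixels.
#' @return An object of class `sst_grid`: a list with elements `values`,
#'   `lon`, `lat`, `res` (grid step, degrees), `date`, `mask`.
#' @examples
#' g <- sst_grid(matrix(15, 4, 5), lon = seq(150, 151, by = 0.25),
#'               lat = seq(40, 40.75, by = 0.25), date = "2019-10-15")
#' dim(g$values)
#' @export
sst_grid <- function(values, lon, lat, date, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    stop("`values` must be length(lat) x length(lon)")
  }
  check_axis(lon, "lon")
  check_axis(lat, "lat")
  res_lon <- diff(lon)[1]
  res_lat <- diff(lat)[1]
  if (length(lon) > 1 && length(lat) > 1 &&
      abs(res_lon - res_lat) > 1e-8 * max(res_lon, res_lat)) {
    stop("grid must have equal lon and lat spacing")
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  mask <- mask | !is.finite(values)
  if (any(!is.finite(values[!mask]))) stop("non-finite SST on unmasked pixels")
  structure(
    list(values = values, lon = lon, lat = lat,
         res = if (length(lat) > 1) res_lat else res_lon,
         date = as.Date(date), mask = mask),
    class = "sst_grid"
  )
}

check_axis <- function(x, name) {
  if (length(x) < 1) stop(sprintf("empty axis `%s`", name))
  if (length(x) > 1) {
    d <- diff(x)
    if (any(d <= 0)) stop(sprintf("axis `%s` must be strictly increasing", name))
    if (max(d) - min(d) > 1e-6 * mean(d)) {
      stop(sprintf("axis `%s` must have constant spacing", name))
    }
  }
  invisible(TRUE)
}

#' @export
print.sst_grid <- function(x, ...) {
  cat(sprintf("<sst_grid> %d x %d pixels at %.3f deg, %s\n",
              length(x$lat), length(x$lon), x$res, format(x$date)))
  cat(sprintf("  lon [%.3f, %.3f]  lat [%.3f, %.3f]  masked %d px\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat), sum(x$mask)))
  rng <- range(x$values[!x$mask])
  cat(sprintf("  SST range %.2f .. %.2f degC\n", rng[1], rng[2]))
  invisible(x)
}

#' Pixel areas of a grid
#'
#' Area of each grid cell in km^2, cosine-latitude weighted.
#'
#' @param grid an [sst_grid] (or any list with `lon`, `lat`, `res`).
#' @return numeric matrix of cell areas, km^2.
#' @export
pixel_areas <- function(grid) {
  dy <- grid$res * KM_PER_DEG
  dx <- grid$res * KM_PER_DEG * cos(grid$lat * pi / 180)
  matrix(dx * dy, nrow = length(grid$lat), ncol = length(grid$lon))
}

#' Locate records in grid cells
#'
#' Maps lon/lat points to row/column indices of the half-open grid cells that
#' contain them. Points outside the grid get `NA` indices.
#'
#' @param grid an [sst_grid] or front label map.
#' @param lon,lat point coordinates, decimal degrees.
#' @return data.frame with columns `row`, `col` (NA when outside the grid).
#' @export
locate_pixels <- function(grid, lon, lat) {
  res <- grid$res
  col <- floor((lon - (grid$lon[1] - res / 2)) / res) + 1
  row <- floor((lat - (grid$lat[1] - res / 2)) / res) + 1
  col[col < 1 | col > length(grid$lon)] <- NA
  row[row < 1 | row > length(grid$lat)] <- NA
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Bilinear SST at arbitrary locations
#'
#' Interpolates the gridded field bilinearly at point locations; points
#' outside the convex hull of cell centres are clamped to the nearest edge
#' value. Masked pixels are treated as missing and yield `NA`.
#'
#' @inheritParams locate_pixels
#' @return numeric vector of interpolated SST, degrees Celsius.
#' @export
sst_at <- function(grid, lon, lat) {
  if (length(lon) == 0) return(numeric(0))
  if (anyNA(lon) || anyNA(lat)) {
    ok <- !is.na(lon) & !is.na(lat)
    out <- rep(NA_real_, length(lon))
    out[ok] <- sst_at(grid, lon[ok], lat[ok])
    return(out)
  }
  v <- grid$values
  v[grid$mask] <- NA
  lonc <- pmin(pmax(lon, grid$lon[1]), grid$lon[length(grid$lon)])
  latc <- pmin(pmax(lat, grid$lat[1]), grid$lat[length(grid$lat)])
  if (length(grid$lon) < 2 || length(grid$lat) < 2) {
    px <- locate_pixels(grid, lonc, latc)
    return(v[cbind(px$row, px$col)])
  }
  # pracma::interp2 expects x along columns, y along rows
  pracma::interp2(x = grid$lon, y = grid$lat, Z = v,
                  xp = lonc, yp = latc, method = "linear")
}

#' Read and write gridded fields as CSV
#'
#' Plain-text interchange for gridded rasters: a long-format CSV with columns
#' `lon,lat,value` plus a `date` column, one row per unmasked pixel.
#'
#' @param grid an [sst_grid].
#' @param path file path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv` returns
#'   an [sst_grid] (pixels absent from the file are masked).
#' @export
write_grid_csv <- function(grid, path) {
  keep <- !grid$mask
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(
    date = format(grid$date),
    lon = grid$lon[idx[, 2]],
    lat = grid$lat[idx[, 1]],
    value = grid$values[keep]
  )
  utils::write.csv(df[order(df$lat, df$lon), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("date", "lon", "lat", "value") %in% names(df)))
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  vals <- matrix(NA_real_, length(lat), length(lon))
  vals[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  sst_grid(vals, lon, lat, date = df$date[1])
}

#' Read and write fishing record tables
#'
#' Fishing records travel as CSV with header `date,lon,lat,catch` (ISO-8601
#' dates, decimal degrees, tons); extra columns such as `cpue` are preserved.
#'
#' @param records data.frame of fishing records.
#' @param path file path.
#' @return `read_fishing_csv` returns a validated data.frame.
#' @export
write_fishing_csv <- function(records, path) {
  stopifnot(all(c("date", "lon", "lat", "catch") %in% names(records)))
  out <- records
  out$date <- format(as.Date(out$date))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fishing_csv
#' @export
read_fishing_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("date", "lon", "lat", "catch") %in% names(df)))
  df$date <- as.Date(df$date)
  validate_fishing_table(df)
  df
}

validate_fishing_table <- function(records) {
  if (any(!is.finite(records$lon)) || any(!is.finite(records$lat))) {
    stop("fishing records contain missing coordinates")
  }
  if (any(records$catch < 0, na.rm = TRUE)) stop("negative catch/effort")
  invisible(TRUE)
}
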