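#' SST gradient field
#'
#' Computes the horizontal SST gradient in degrees Celsius per km: central
#' differences in the interior, one-sided differences next to grid edges and
#' mask boundaries. The zonal (east-west) step is scaled by the cosine of
#' the local latitude; masked pixels propagate to a masked gradient.
#'
#' @param sst an [sst_grid].
#' @return list of class `gradient_field` with matrices `zonal`,
#'   `meridional` and `magnitude` (all degC/km; `NA` where masked).
#' @examples
#' g <- sst_grid(outer(1:5, rep(1, 5)), lon = seq(0, 1, 0.25) + 150,
#'               lat = seq(0, 1, 0.25) + 40, date = "2020-01-01")
#' range(compute_gradient(g)$zonal, na.rm = TRUE)
#' @export
compute_gradient <- function(sst) {
  v <- sst$values
  v[sst$mask] <- NA
  if (all(is.na(v))) stop("all pixels are masked; no gradient to compute")
  nr <- nrow(v); nc <- ncol(v)
  dy_km <- sst$res * KM_PER_DEG
  dx_km <- sst$res * KM_PER_DEG * cos(sst$lat * pi / 180) # per row

  shift <- function(m, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  fd <- function(fwd, bwd, ctr, h) {
    g <- (fwd - bwd) / (2 * h)                 # central
    one_f <- (fwd - ctr) / h                   # forward where backward missing
    one_b <- (ctr - bwd) / h                   # backward where forward missing
    g[is.na(g)] <- one_f[is.na(g)]
    g[is.na(g)] <- one_b[is.na(g)]
    g
  }
  east <- shift(v, 0, 1); west <- shift(v, 0, -1)
  north <- shift(v, 1, 0); south <- shift(v, -1, 0)
  hx <- matrix(dx_km, nr, nc)
  zonal <- fd(east, west, v, hx)
  meridional <- fd(north, south, v, dy_km)
  zonal[is.na(v)] <- NA
  meridional[is.na(v)] <- NA
  magnitude <- sqrt(zonal^2 + meridional^2)
  structure(list(zonal = zonal, meridional = meridional,
                 magnitude = magnitude),
            class = "gradient_field")
}
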