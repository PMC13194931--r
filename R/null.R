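#' Build a spatially randomized background null for fishing records
#'
#' Generates an ensemble of replicate record tables in which each record is
#' relocated uniformly at random within a square window of side `window_deg`
#' centred on its observed position (`center = "record"`, the default) or
#' within the fixed `window_deg` tile containing it (`center = "tile"`).
#' Dates and catches are untouched, so each replicate preserves the
#' large-scale distribution and the total catch exactly while erasing
#' mesoscale structure. Draws falling outside the analysis domain, or on
#' invalid water when a mask is supplied, are redrawn (never clamped).
#'
#' @param obs data.frame of fishing records (`date`, `lon`, `lat`, `catch`,
#'   other columns preserved).
#' @param window_deg randomization window side, degrees (default 2).
#' @param R number of replicates (default 1000).
#' @param mask optional [sst_grid]-like object whose `mask` marks invalid
#'   water; draws on masked pixels are redrawn.
#' @param domain optional `list(lon = c(min, max), lat = c(min, max))`
#'   bounding box for redraw clipping; defaults to the mask's extent, or no
#'   clipping.
#' @param seed integer seed.
#' @param center `"record"` or `"tile"` (see Details above).
#' @param max_redraws per-record cap on redraws before failing.
#' @return list of class `null_ensemble`: `replicates` (list of R
#'   data.frames), `window_deg`, `R`, `seed`, `center`.
#' @export
randomize_records <- function(obs, window_deg = 2, R = 1000L, mask = NULL,
                              domain = NULL, seed = 1L,
                              center = c("record", "tile"),
                              max_redraws = 1000L) {
  center <- match.arg(center)
  stopifnot(window_deg > 0, R >= 1)
  validate_fishing_table(obs)
  if (is.null(domain) && !is.null(mask)) {
    domain <- list(lon = range(mask$lon) + c(-0.5, 0.5) * mask$res,
                   lat = range(mask$lat) + c(-0.5, 0.5) * mask$res)
  }
  n <- nrow(obs)
  half <- window_deg / 2
  ctr_lon <- if (center == "record") obs$lon else
    (floor(obs$lon / window_deg) + 0.5) * window_deg
  ctr_lat <- if (center == "record") obs$lat else
    (floor(obs$lat / window_deg) + 0.5) * window_deg

  ok_draw <- function(lon, lat) {
    ok <- rep(TRUE, length(lon))
    if (!is.null(domain)) {
      ok <- ok & lon >= domain$lon[1] & lon < domain$lon[2] &
        lat >= domain$lat[1] & lat < domain$lat[2]
    }
    if (!is.null(mask)) {
      px <- locate_pixels(mask, lon, lat)
      inb <- !is.na(px$row) & !is.na(px$col)
      okm <- rep(FALSE, length(lon))
      okm[inb] <- !mask$mask[cbind(px$row[inb], px$col[inb])]
      ok <- ok & okm
    }
    ok
  }

  replicates <- with_seed(seed, lapply(seq_len(R), function(r) {
    lon <- stats::runif(n, ctr_lon - half, ctr_lon + half)
    lat <- stats::runif(n, ctr_lat - half, ctr_lat + half)
    bad <- which(!ok_draw(lon, lat))
    tries <- 0L
    while (length(bad)) {
      tries <- tries + 1L
      if (tries > max_redraws) {
        stop(sprintf("record %d: window contains no valid water after %d redraws",
                     bad[1], max_redraws))
      }
      lon[bad] <- stats::runif(length(bad), ctr_lon[bad] - half, ctr_lon[bad] + half)
      lat[bad] <- stats::runif(length(bad), ctr_lat[bad] - half, ctr_lat[bad] + half)
      bad <- bad[!ok_draw(lon[bad], lat[bad])]
    }
    rep_tab <- obs
    rep_tab$lon <- lon
    rep_tab$lat <- lat
    rep_tab
  }))
  structure(list(replicates = replicates, window_deg = window_deg,
                 R = as.integer(R), seed = seed, center = center),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d replicates of %d records, %.1f deg %s-centred windows (seed %s)\n",
              x$R, nrow(x$replicates[[1]]), x$window_deg, x$center,
              format(x$seed)))
  invisible(x)
}

#' Monte-Carlo percentile significance of an observed statistic
#'
#' Locates an observed statistic in a null distribution. Reports the
#' one-sided exceedance fractions, a standard two-sided Monte-Carlo p-value
#' `p = 2 * min(r_above + 1, r_below + 1) / (R + 1)` (capped at 1), the
#' percentile rule used in frontal-effect studies (significant when the
#' observed value exceeds the null's 95th percentile or falls below its
#' 5th), and a 5%-nominal flag `significant = p_value < 0.05`.
#'
#' @param observed observed statistic (length 1).
#' @param null_stats numeric vector of the statistic under the null
#'   (length >= 20).
#' @return list with `p_value`, `frac_above`, `frac_below`,
#'   `significant_percentile`, `significant`.
#' @export
percentile_pvalue <- function(observed, null_stats) {
  null_stats <- null_stats[is.finite(null_stats)]
  R <- length(null_stats)
  if (R < 20) stop("need at least 20 null statistics")
  r_above <- sum(null_stats >= observed)
  r_below <- sum(null_stats <= observed)
  p <- min(1, 2 * min(r_above + 1, r_below + 1) / (R + 1))
  q <- stats::quantile(null_stats, c(0.05, 0.95), names = FALSE, type = 7)
  flag_pct <- observed > q[2] || observed < q[1]
  list(p_value = p,
       frac_above = r_above / R,
       frac_below = r_below / R,
       significant_percentile = flag_pct,
       significant = p < 0.05)
}
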