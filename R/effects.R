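#' Assign fishing records to front-zone labels and accumulate zone totals
#'
#' Each record takes the label of the half-open grid cell containing it.
#' Records falling on frontal-line pixels count toward the frontal zone and
#' are additionally split to a warm/cold side by the line pixel's
#' 4-neighbour temperature rule, so warm-versus-cold contrasts lose no
#' records. Records outside the grid are excluded (their count is attached
#' as the `n_excluded` attribute and reported via a message).
#'
#' @param records data.frame of fishing records (`lon`, `lat`, `catch`).
#' @param labels a [front_labels][partition_zones] object for the records'
#'   date.
#' @param quiet suppress the exclusion message.
#' @return list of class `zone_assignment`: `records` (the kept records plus
#'   `zone` and `wc_side` columns) and `totals`, a `zone_totals` list with
#'   named vectors `F` (catch, tons), `A` (area, km^2) and `n` (records) over
#'   zones `frontal`, `line`, `line_warm`, `line_cold`, `warm`, `cold`,
#'   `non_frontal`, `all`.
#' @export
assign_records_to_zones <- function(records, labels, quiet = FALSE) {
  px <- locate_pixels(labels, records$lon, records$lat)
  inside <- !is.na(px$row) & !is.na(px$col)
  if (any(inside)) {
    code <- labels$label[cbind(px$row[inside], px$col[inside])]
    inside[inside] <- code != ZONE_CODES[["masked"]]
  }
  n_excl <- sum(!inside)
  if (n_excl > 0 && !quiet) {
    message(sprintf("excluded %d record(s) outside the labelled grid", n_excl))
  }
  rec <- records[inside, , drop = FALSE]
  px <- px[inside, , drop = FALSE]
  code <- labels$label[cbind(px$row, px$col)]
  zone <- names(ZONE_CODES)[match(code, ZONE_CODES)]
  wc_side <- ifelse(zone == "warm_zone", "warm",
                    ifelse(zone == "cold_zone", "cold", NA))
  on_line <- zone == "frontal_line"
  wc_side[on_line] <- labels$line_side[cbind(px$row[on_line], px$col[on_line])]
  rec$zone <- zone
  rec$wc_side <- wc_side
  totals <- zone_totals(rec, labels)
  attr(totals, "n_excluded") <- n_excl
  structure(list(records = rec, totals = totals), class = "zone_assignment")
}

# Catch totals, areas (cos-latitude weighted km^2) and record counts per zone.
zone_totals <- function(rec, labels) {
  areas <- pixel_areas(labels)
  lab <- labels$label
  a_line <- sum(areas[lab == ZONE_CODES[["frontal_line"]]])
  line_warm_px <- lab == ZONE_CODES[["frontal_line"]] & labels$line_side == "warm"
  a_line_warm <- sum(areas[which(line_warm_px)])
  a_warm <- sum(areas[lab == ZONE_CODES[["warm_zone"]]])
  a_cold <- sum(areas[lab == ZONE_CODES[["cold_zone"]]])
  a_non <- sum(areas[lab == ZONE_CODES[["non_frontal"]]])

  s <- function(cond) sum(rec$catch[cond])
  f_line <- s(rec$zone == "frontal_line")
  f_line_warm <- s(rec$zone == "frontal_line" & rec$wc_side == "warm")
  f_warm <- s(rec$zone == "warm_zone")
  f_cold <- s(rec$zone == "cold_zone")
  f_non <- s(rec$zone == "non_frontal")

  cnt <- function(cond) sum(cond)
  structure(list(
    F = c(frontal = f_warm + f_cold + f_line,
          line = f_line, line_warm = f_line_warm,
          line_cold = f_line - f_line_warm,
          warm = f_warm, cold = f_cold, non_frontal = f_non,
          all = f_warm + f_cold + f_line + f_non),
    A = c(frontal = a_warm + a_cold + a_line,
          line = a_line, line_warm = a_line_warm,
          line_cold = a_line - a_line_warm,
          warm = a_warm, cold = a_cold, non_frontal = a_non,
          all = a_warm + a_cold + a_line + a_non),
    n = c(frontal = cnt(rec$zone %in% c("warm_zone", "cold_zone", "frontal_line")),
          line = cnt(rec$zone == "frontal_line"),
          line_warm = cnt(rec$zone == "frontal_line" & rec$wc_side == "warm"),
          line_cold = cnt(rec$zone == "frontal_line" & rec$wc_side == "cold"),
          warm = cnt(rec$zone == "warm_zone"),
          cold = cnt(rec$zone == "cold_zone"),
          non_frontal = cnt(rec$zone == "non_frontal"),
          all = nrow(rec))
  ), class = "zone_totals")
}

# Effective totals for a contrast zone: records/area on the front line join
# the warm/cold side they were split to.
zone_value <- function(totals, zone, what = c("F", "A")) {
  what <- match.arg(what)
  x <- totals[[what]]
  switch(zone,
         frontal = x[["frontal"]],
         warm = x[["warm"]] + x[["line_warm"]],
         cold = x[["cold"]] + x[["line_cold"]],
         non_frontal = x[["non_frontal"]],
         all = x[["all"]],
         stop(sprintf("unknown zone '%s'", zone)))
}

#' Fishing catch/effort relative anomaly difference (FRAD)
#'
#' For zones i and j, the relative anomaly of observed catch against one
#' background replicate is `(OF - SF_r)/SF_r`, and FRAD is the difference of
#' the two zones' anomalies in percent:
#' `FRAD_r(i, j) = ((OF(i) - SF_r(i))/SF_r(i) - (OF(j) - SF_r(j))/SF_r(j)) * 100`.
#' The function evaluates FRAD against every replicate, reporting the median
#' as the point estimate with the 25th-75th percentile spread, a two-sided
#' Monte-Carlo p-value for FRAD != 0 from the replicate distribution, and
#' two flags: `significant_90` (zero outside the central 90% of the
#' distribution) and `significant` (p < 0.05). Replicates with a zero
#' simulated total in either zone are dropped; more than 10% dropped is an
#' error. With `per_replicate = FALSE` a single FRAD is computed against the
#' ensemble-mean simulated totals instead.
#'
#' @param obs_totals `zone_totals` of the observed table
#'   (from [assign_records_to_zones()]).
#' @param null_totals list of `zone_totals`, one per null replicate.
#' @param i,j zone names among `"frontal"`, `"warm"`, `"cold"`,
#'   `"non_frontal"`.
#' @param per_replicate distributional FRAD (default) or ensemble-mean FRAD.
#' @return list of class `effect_estimate` with elements `index`, `zones`,
#'   `estimate` (%), `q25`, `q75`, `null_values` (the per-replicate FRADs),
#'   `p_value`, `significant`, `significant_90`, `n_dropped`.
#' @export
frad <- function(obs_totals, null_totals, i, j, per_replicate = TRUE) {
  OFi <- zone_value(obs_totals, i); OFj <- zone_value(obs_totals, j)
  SFi <- vapply(null_totals, zone_value, numeric(1), zone = i)
  SFj <- vapply(null_totals, zone_value, numeric(1), zone = j)
  if (!per_replicate) {
    SFi <- mean(SFi); SFj <- mean(SFj)
  }
  ok <- SFi > 0 & SFj > 0
  n_drop <- sum(!ok)
  if (n_drop > 0.1 * length(ok)) {
    stop(sprintf("%d of %d replicates have zero simulated catch in zone %s or %s",
                 n_drop, length(ok), i, j))
  }
  if (n_drop > 0) message(sprintf("dropped %d replicate(s) with zero simulated catch", n_drop))
  vals <- ((OFi - SFi[ok]) / SFi[ok] - (OFj - SFj[ok]) / SFj[ok]) * 100
  est <- stats::median(vals)
  qq <- stats::quantile(vals, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  p <- min(1, 2 * min(sum(vals <= 0) + 1, sum(vals >= 0) + 1) / (length(vals) + 1))
  structure(list(index = "FRAD", zones = c(i = i, j = j), estimate = est,
                 q25 = qq[2], q75 = qq[3],
                 null_values = vals, p_value = p,
                 significant = p < 0.05,
                 significant_90 = (0 < qq[1] || 0 > qq[4]),
                 n_dropped = n_drop),
            class = "effect_estimate")
}

#' Relative difference in fishing catch/effort per unit area (RD_FPA)
#'
#' `RD_FPA(i, j) = ((F(i)/A(i) - F(j)/A(j)) / (F(all)/A(all))) * 100`, where
#' `all` aggregates the frontal and non-frontal zones. Positive values mean
#' a higher catch density in zone i than zone j relative to the overall
#' density.
#'
#' @param totals a `zone_totals` list.
#' @param i,j zone names (see [frad()]).
#' @return RD_FPA in percent (length-1 numeric).
#' @export
rd_fpa <- function(totals, i, j) {
  Ai <- zone_value(totals, i, "A"); Aj <- zone_value(totals, j, "A")
  Aall <- zone_value(totals, "all", "A")
  Fall <- zone_value(totals, "all", "F")
  if (Ai <= 0 || Aj <= 0 || Aall <= 0) {
    stop("zero-area zone: RD_FPA undefined")
  }
  if (Fall <= 0) stop("no catch anywhere: RD_FPA undefined")
  Fi <- zone_value(totals, i, "F"); Fj <- zone_value(totals, j, "F")
  ((Fi / Ai - Fj / Aj) / (Fall / Aall)) * 100
}

#' RD_FPA with bootstrap significance
#'
#' Evaluates [rd_fpa()] on the observed totals and on each null replicate's
#' totals, then locates the observed value in the null distribution with
#' [percentile_pvalue()].
#'
#' @inheritParams frad
#' @return list of class `effect_estimate` with `estimate` (%),
#'   `null_values`, `p_value`, `significant`, `significant_percentile`.
#' @export
rd_fpa_estimate <- function(obs_totals, null_totals, i, j) {
  obs <- rd_fpa(obs_totals, i, j)
  nulls <- vapply(null_totals, rd_fpa, numeric(1), i = i, j = j)
  pv <- percentile_pvalue(obs, nulls)
  structure(c(list(index = "RD_FPA", zones = c(i = i, j = j),
                   estimate = obs, null_values = nulls), pv),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s(%s, %s) = %.2f%%  (p = %.4g%s)\n",
              x$index, x$zones[["i"]], x$zones[["j"]], x$estimate,
              x$p_value, if (isTRUE(x$significant)) ", significant" else ""))
  invisible(x)
}

#' Underestimation rate of frontal fishery effects
#'
#' How much the hotspot contrast (frontal vs non-frontal, `FE`) understates
#' the larger of the two single-side contrasts (warm vs non-frontal `WZ`,
#' cold vs non-frontal `CZ`):
#' `UR = (max(|WZ|, |CZ|) - |FE|) / max(max(|WZ|, |CZ|), |FE|) * 100`.
#' Positive UR means the barrier effect is underestimated when only the
#' hotspot contrast is examined. Inputs may be vectors (e.g. per-replicate
#' values), in which case UR is evaluated elementwise and the spread
#' summarizes the uncertainty.
#'
#' @param WZ,CZ,FE contrasts in percent (FRAD or RD_FPA values).
#' @return list of class `ur_result`: `UR` (median over elements, %),
#'   `values` (elementwise UR), `q25`, `q75`, and the inputs.
#' @export
underestimation_rate <- function(WZ, CZ, FE) {
  stopifnot(all(is.finite(WZ)), all(is.finite(CZ)), all(is.finite(FE)))
  big <- pmax(abs(WZ), abs(CZ))
  den <- pmax(big, abs(FE))
  ur <- ifelse(den == 0, 0, (big - abs(FE)) / den * 100)
  if (any(den == 0)) message("UR defined as 0 where all contrasts are 0")
  qq <- stats::quantile(ur, c(0.25, 0.75), names = FALSE)
  structure(list(UR = stats::median(ur), values = ur,
                 q25 = qq[1], q75 = qq[2],
                 WZ = WZ, CZ = CZ, FE = FE),
            class = "ur_result")
}

#' @export
print.ur_result <- function(x, ...) {
  cat(sprintf("<ur_result> UR = %.1f%% [%.1f, %.1f]\n", x$UR, x$q25, x$q75))
  invisible(x)
}

#' Gridded RD_FPA map with Gaussian smoothing and per-cell significance
#'
#' Evaluates RD_FPA between two zones within coarse cells (default 1 degree)
#' using each cell's own totals and areas, smooths the map with a Gaussian
#' kernel whose full width at half maximum equals `smooth_fwhm_deg`, and
#' flags per-cell significance against the null ensemble with the
#' percentile rule. Cells with fewer than `min_records` observed records are
#' no-data.
#'
#' @param records observed fishing records.
#' @param labels a [front_labels][partition_zones] object.
#' @param null a [null_ensemble][randomize_records] (optional; omit for a
#'   map without significance).
#' @param i,j zone names (see [frad()]).
#' @param cell_deg evaluation cell size, degrees.
#' @param smooth_fwhm_deg Gaussian kernel FWHM, degrees (0 disables).
#' @param min_records minimum observed records per evaluated cell.
#' @return list of class `rd_fpa_map`: `lon`, `lat` (cell centres), `value`
#'   (raw RD_FPA %), `smoothed`, `p_value`, `significant` (matrices; `NA`
#'   where no data).
#' @export
spatial_rd_fpa <- function(records, labels, null = NULL,
                           i = "frontal", j = "non_frontal",
                           cell_deg = 1, smooth_fwhm_deg = 3,
                           min_records = 5L) {
  res <- labels$res
  lon0 <- labels$lon[1] - res / 2
  lat0 <- labels$lat[1] - res / 2
  n_clon <- ceiling((max(labels$lon) + res / 2 - lon0) / cell_deg - 1e-9)
  n_clat <- ceiling((max(labels$lat) + res / 2 - lat0) / cell_deg - 1e-9)
  cell_lon <- lon0 + (seq_len(n_clon) - 0.5) * cell_deg
  cell_lat <- lat0 + (seq_len(n_clat) - 0.5) * cell_deg

  cell_of <- function(lon, lat) {
    ci <- floor((lon - lon0) / cell_deg) + 1
    ri <- floor((lat - lat0) / cell_deg) + 1
    ok <- ci >= 1 & ci <= n_clon & ri >= 1 & ri <= n_clat
    ci[!ok] <- NA; ri[!ok] <- NA
    cbind(row = ri, col = ci)
  }

  # pixel -> cell mapping, precomputed once
  px_idx <- which(labels$label != ZONE_CODES[["masked"]], arr.ind = TRUE)
  px_cell <- cell_of(labels$lon[px_idx[, 2]], labels$lat[px_idx[, 1]])

  cell_value <- function(tab) {
    ass <- assign_records_to_zones(tab, labels, quiet = TRUE)
    rc <- cell_of(ass$records$lon, ass$records$lat)
    out <- matrix(NA_real_, n_clat, n_clon)
    nrec <- matrix(0L, n_clat, n_clon)
    for (r in seq_len(n_clat)) for (cc in seq_len(n_clon)) {
      in_cell_px <- px_cell[, 1] == r & px_cell[, 2] == cc
      if (!any(in_cell_px, na.rm = TRUE)) next
      in_cell_rec <- !is.na(rc[, 1]) & rc[, 1] == r & rc[, 2] == cc
      nrec[r, cc] <- sum(in_cell_rec)
      sub_lab <- labels
      keep <- matrix(FALSE, nrow(labels$label), ncol(labels$label))
      keep[px_idx[which(in_cell_px), , drop = FALSE]] <- TRUE
      sub_lab$label <- ifelse(keep, labels$label, ZONE_CODES[["masked"]])
      tot <- zone_totals(ass$records[in_cell_rec, , drop = FALSE], sub_lab)
      val <- tryCatch(rd_fpa(tot, i, j), error = function(e) NA_real_)
      out[r, cc] <- val
    }
    list(value = out, nrec = nrec)
  }

  obs <- cell_value(records)
  value <- obs$value
  value[obs$nrec < min_records] <- NA

  p_value <- significant <- NULL
  if (!is.null(null)) {
    null_vals <- lapply(null$replicates, function(tab) cell_value(tab)$value)
    p_value <- matrix(NA_real_, n_clat, n_clon)
    significant <- matrix(NA, n_clat, n_clon)
    for (r in seq_len(n_clat)) for (cc in seq_len(n_clon)) {
      if (is.na(value[r, cc])) next
      nv <- vapply(null_vals, function(m) m[r, cc], numeric(1))
      nv <- nv[is.finite(nv)]
      if (length(nv) < 20) next
      pv <- percentile_pvalue(value[r, cc], nv)
      p_value[r, cc] <- pv$p_value
      significant[r, cc] <- pv$significant_percentile
    }
  }
  smoothed <- if (smooth_fwhm_deg > 0) {
    gaussian_smooth(value, smooth_fwhm_deg / cell_deg)
  } else value
  structure(list(lon = cell_lon, lat = cell_lat, value = value,
                 smoothed = smoothed, p_value = p_value,
                 significant = significant, cell_deg = cell_deg,
                 zones = c(i = i, j = j)),
            class = "rd_fpa_map")
}

# NA-aware Gaussian smoothing; `fwhm` in cell units. Kernel weights are
# renormalized over available cells so interior mass is conserved.
gaussian_smooth <- function(m, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  ker <- outer(stats::dnorm(-half:half, sd = sigma),
               stats::dnorm(-half:half, sd = sigma))
  ker <- ker / sum(ker)
  nr <- nrow(m); nc <- ncol(m)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    w <- ker[dr + half + 1L, dc + half + 1L]
    nb <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    nb[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    has <- !is.na(nb)
    num[has] <- num[has] + w * nb[has]
    den[has] <- den[has] + w
  }
  out <- num / den
  out[is.na(m) & den == 0] <- NA
  out
}
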