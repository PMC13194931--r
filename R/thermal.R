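# Gaussian thermal niche model: catch-vs-SST histogram, least-squares
# Gaussian fit (thermal optimum mu, niche breadth sigma), and the thermal
# habitat suitability index THSI.

#' Aggregate catch into SST bins
#'
#' Total catch per SST interval (default 0.5 degrees Celsius), normalized to
#' a 0-1 scale by the maximum bin total: `C_n(i) = C(i) / max(C)`. SST at
#' each record is taken from an `sst` column when present, otherwise
#' interpolated bilinearly from the supplied daily grid.
#'
#' @param records fishing records with `catch` and either an `sst` column or
#'   coordinates on `grid`.
#' @param grid optional [sst_grid] used to interpolate record SSTs.
#' @param bin_width SST bin width, degrees Celsius.
#' @return data.frame of class `sst_histogram`: `bin_lo`, `bin_mid`,
#'   `bin_hi`, `C` (tons), `C_n`.
#' @export
bin_catch_by_sst <- function(records, grid = NULL, bin_width = 0.5) {
  sstv <- record_sst(records, grid)
  ok <- is.finite(sstv)
  sstv <- sstv[ok]
  catch <- records$catch[ok]
  if (!length(catch) || all(catch == 0)) {
    stop("all catches are zero; nothing to normalize")
  }
  lo <- floor(min(sstv))
  hi <- ceiling(max(sstv))
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  b <- pmin(findInterval(sstv, edges, left.open = FALSE), length(edges) - 1L)
  C <- as.numeric(rowsum(c(catch, rep(0, length(edges) - 1L)),
                         c(b, seq_len(length(edges) - 1L)))[, 1])
  out <- data.frame(bin_lo = edges[-length(edges)],
                    bin_mid = edges[-length(edges)] + bin_width / 2,
                    bin_hi = edges[-1],
                    C = C, C_n = C / max(C))
  class(out) <- c("sst_histogram", "data.frame")
  out
}

record_sst <- function(records, grid) {
  if (!is.null(records$sst)) return(records$sst)
  if (is.null(grid)) stop("records have no `sst` column and no grid was given")
  sst_at(grid, records$lon, records$lat)
}

#' Fit the Gaussian thermal niche
#'
#' Nonlinear least squares of the normalized catch histogram against a
#' Gaussian of SST, `C_n(T) ~ A * exp(-(T - mu)^2 / (2 sigma^2))`,
#' initialized at the catch-weighted mean and SD of the bin centres with
#' unit amplitude. `mu` is the thermal optimum and `sigma` the niche
#' breadth, both in degrees Celsius.
#'
#' @param hist an [sst_histogram][bin_catch_by_sst].
#' @return list of class `thermal_fit`: `mu`, `sigma`, `amplitude`,
#'   `r_squared`, `rss`, `n_bins`.
#' @export
fit_thermal_gaussian <- function(hist) {
  nz <- hist[hist$C > 0, , drop = FALSE]
  if (nrow(nz) < 4 || diff(range(nz$bin_mid)) <= 2) {
    stop("need at least 4 non-empty bins spanning more than 2 degC")
  }
  T_i <- hist$bin_mid
  y <- hist$C_n
  w <- nz$C / sum(nz$C)
  mu0 <- sum(w * nz$bin_mid)
  s0 <- sqrt(max(sum(w * (nz$bin_mid - mu0)^2), 0.25))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(T_i - mu)^2 / (2 * sigma^2)),
      start = list(A = 1, mu = mu0, sigma = s0),
      control = minpack.lm::nls.lm.control(ptol = 1e-8, ftol = 1e-12,
                                           maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf(paste0("Gaussian fit did not converge (%s); ",
                          "initialization mu0 = %.2f, sigma0 = %.2f"),
                   conditionMessage(e), mu0, s0))
    }
  )
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
                 amplitude = unname(cf["A"]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 rss = rss, n_bins = length(y),
                 init = c(mu0 = mu0, sigma0 = s0)),
            class = "thermal_fit")
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("<thermal_fit> mu = %.2f degC, sigma = %.2f degC, A = %.3f (R2 = %.3f)\n",
              x$mu, x$sigma, x$amplitude, x$r_squared))
  invisible(x)
}

#' Thermal habitat suitability index
#'
#' `THSI(T) = exp(-(T - mu)^2 / (2 sigma^2))`: the fitted thermal niche
#' rescaled to peak 1 at the thermal optimum, so the index lies in (0, 1].
#' `density_form = TRUE` instead evaluates the normal density
#' `1/(sigma sqrt(2 pi)) * exp(...)`.
#'
#' @param fit a [thermal_fit][fit_thermal_gaussian].
#' @param sst temperatures, degrees Celsius (vectorized).
#' @param density_form evaluate the density form instead of the unit-peak
#'   suitability.
#' @return numeric vector of suitabilities.
#' @examples
#' f <- structure(list(mu = 14, sigma = 2), class = "thermal_fit")
#' predict_thsi(f, c(14, 16)) # 1 and exp(-0.5)
#' @export
predict_thsi <- function(fit, sst, density_form = FALSE) {
  g <- exp(-(sst - fit$mu)^2 / (2 * fit$sigma^2))
  if (density_form) g / (fit$sigma * sqrt(2 * pi)) else g
}

#' Compare thermal proximity of high-CPUE records between warm and cold zones
#'
#' Selects records at or above the (1 - `top_fraction`) CPUE quantile within
#' each of the frontal warm and cold zones (the top 50% by default) and
#' compares their SST, absolute deviation from the thermal optimum
#' `|SST - mu|`, and predicted THSI, with a two-sided t-test on the
#' deviations.
#'
#' @param records records carrying `cpue` and an `sst` column (or supply
#'   `grid`).
#' @param assignment a [zone_assignment][assign_records_to_zones] for the
#'   records, or `NULL` if `records` already has a `zone` column.
#' @param fit a [thermal_fit][fit_thermal_gaussian].
#' @param top_fraction CPUE fraction retained per zone (1 keeps all).
#' @param grid optional [sst_grid] for record SSTs.
#' @param min_records refuse the comparison when either zone has fewer
#'   qualifying records.
#' @return list of class `zone_thermal_comparison`: per-zone summaries
#'   (`median`, `q25`, `q75` of SST, deviation, THSI; `n`), `p_value` of the
#'   t-test on deviations, `higher_thsi_zone`.
#' @export
compare_zone_thermal <- function(records, assignment = NULL, fit,
                                 top_fraction = 0.5, grid = NULL,
                                 min_records = 10L) {
  if (!is.null(assignment)) records <- assignment$records
  if (is.null(records$zone)) stop("records need zone labels (see assign_records_to_zones)")
  if (is.null(records$cpue)) stop("records need a `cpue` column")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  records$sst <- record_sst(records, grid)

  pick <- function(side) {
    z <- records[records$zone == paste0(side, "_zone") |
                   (records$zone == "frontal_line" & records$wc_side %in% side), ,
                 drop = FALSE]
    thr <- stats::quantile(z$cpue, 1 - top_fraction, names = FALSE)
    z[z$cpue >= thr, , drop = FALSE]
  }
  summ <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(q25 = q[1], median = q[2], q75 = q[3])
  }
  res <- list()
  for (side in c("warm", "cold")) {
    z <- pick(side)
    if (nrow(z) < min_records) {
      stop(sprintf("only %d qualifying record(s) in the %s zone (need >= %d)",
                   nrow(z), side, min_records))
    }
    dev <- abs(z$sst - fit$mu)
    res[[side]] <- list(n = nrow(z), sst = summ(z$sst), deviation = summ(dev),
                        thsi = summ(predict_thsi(fit, z$sst)),
                        dev_values = dev)
  }
  tt <- stats::t.test(res$warm$dev_values, res$cold$dev_values)
  structure(list(
    warm = res$warm[c("n", "sst", "deviation", "thsi")],
    cold = res$cold[c("n", "sst", "deviation", "thsi")],
    p_value = tt$p.value,
    mean_dev_warm = mean(res$warm$dev_values),
    mean_dev_cold = mean(res$cold$dev_values),
    higher_thsi_zone = if (res$warm$thsi[["median"]] >= res$cold$thsi[["median"]])
      "warm" else "cold",
    top_fraction = top_fraction
  ), class = "zone_thermal_comparison")
}

#' @export
print.zone_thermal_comparison <- function(x, ...) {
  cat(sprintf("<zone_thermal_comparison> top %.0f%% CPUE: |SST - mu| warm %.2f vs cold %.2f (p = %.3g)\n",
              100 * x$top_fraction, x$warm$deviation[["median"]],
              x$cold$deviation[["median"]], x$p_value))
  cat(sprintf("  higher THSI in the %s zone\n", x$higher_thsi_zone))
  invisible(x)
}

#' Stratify records by a date predicate
#'
#' Splits a record table into named strata with an arbitrary date predicate;
#' the conventional seasonal split contrasts records before and after a
#' pivot date (e.g. 1 August).
#'
#' @param records data.frame with a `date` column.
#' @param split_date pivot date; records strictly before it go to `before`.
#' @return named list `before` / `after` of data.frames.
#' @export
split_by_date <- function(records, split_date) {
  d <- as.Date(records$date)
  sd <- as.Date(split_date)
  list(before = records[d < sd, , drop = FALSE],
       after = records[d >= sd, , drop = FALSE])
}
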