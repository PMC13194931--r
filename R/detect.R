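# Windowed histogram (bimodality) front detection, in the single-image
# edge-detection tradition: per window, split the SST histogram at the
# threshold maximizing between-population variance, test bimodality and
# spatial cohesion of the two populations, mark pixels adjacent to the
# opposite population as frontal candidates, take the union over overlapping
# windows, and prune short components.

# Optimal histogram split: threshold tau maximizing the between-population
# variance, plus the ratio of that variance to the total (theta statistic).
# Values are binned at `bin_width`; tau is the midpoint of the maximizing
# edge plateau.
histogram_split <- function(values, bin_width = 0.1) {
  values <- values[is.finite(values)]
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width + 1e-9) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 3) return(list(tau = NA_real_, theta = 0))
  cnt <- tabulate(pmin(findInterval(values, edges, left.open = FALSE),
                       length(edges) - 1L), nbins = length(edges) - 1L)
  mids <- edges[-length(edges)] + bin_width / 2
  n <- sum(cnt)
  mu <- sum(cnt * mids) / n
  tot_var <- sum(cnt * (mids - mu)^2) / n
  if (tot_var == 0) return(list(tau = NA_real_, theta = 0))
  # candidate thresholds: each interior bin edge
  w1 <- cumsum(cnt)[-length(cnt)] / n
  s1 <- cumsum(cnt * mids)[-length(cnt)] / n
  m1 <- ifelse(w1 > 0, s1 / w1, 0)
  m2 <- ifelse(w1 < 1, (mu - s1) / (1 - w1), 0)
  sb <- w1 * (1 - w1) * (m1 - m2)^2
  best <- which(sb > max(sb) - 1e-12)
  tau <- mean(edges[c(min(best), max(best)) + 1L]) # midpoint of plateau
  list(tau = tau, theta = max(sb) / tot_var)
}

# Fraction of each population's pixels whose valid 4-neighbours are majority
# same-population. `pop` is a logical matrix (TRUE = above tau), NA = invalid.
cohesion_stats <- function(pop) {
  nr <- nrow(pop); nc <- ncol(pop)
  same <- matrix(0L, nr, nc); valid <- matrix(0L, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- matrix(NA, nr, nc)
    rs <- seq_len(nr) + d[1]; cs <- seq_len(nc) + d[2]
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    nb[ok_r, ok_c] <- pop[rs[ok_r], cs[ok_c]]
    has <- !is.na(nb) & !is.na(pop)
    valid <- valid + has
    same <- same + (has & nb == pop)
  }
  cohesive <- !is.na(pop) & valid > 0 & same * 2L > valid
  c(cold = if (any(pop %in% FALSE)) mean(cohesive[pop %in% FALSE]) else NA_real_,
    warm = if (any(pop %in% TRUE)) mean(cohesive[pop %in% TRUE]) else NA_real_)
}

# 3x3 median despiking filter (NA-aware; masked pixels stay NA).
median_filter3 <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  stack <- array(NA_real_, c(nr, nc, 9L))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    stack[ok_r, ok_c, k] <- v[rs[ok_r], cs[ok_c]]
  }
  out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  out[is.na(v)] <- NA
  out
}

#' Detect mesoscale SST fronts by windowed histogram analysis
#'
#' Slides a square window over the grid; within each window the SST histogram
#' is split at the threshold maximizing the between-population variance, the
#' window is accepted when the between/total variance ratio reaches
#' `theta_crit` (bimodality) and both populations are spatially cohesive, and
#' unmasked pixels with at least one 4-neighbour on the opposite side of the
#' threshold become frontal candidates. Candidates are pooled across
#' overlapping windows, and 8-connected components shorter than
#' `min_length_px` pixels are pruned. Aimed at mesoscale fronts: with the
#' default 32-pixel window on a 0.05-degree grid the detection scale is
#' about 160 km, excluding basin-scale and submesoscale structure.
#'
#' @param sst an [sst_grid].
#' @param window_px window side, pixels (default 32).
#' @param stride_px window stride, pixels (default `window_px / 2`).
#' @param theta_crit minimum between/total variance ratio for bimodality.
#' @param cohesion_crits length-2 vector: minimum cohesion for the cold and
#'   warm populations.
#' @param min_length_px minimum component size (pixels) kept after pruning.
#' @param bin_width SST histogram bin width, degrees Celsius.
#' @param median_filter despike with a 3x3 median filter before analysis?
#' @param min_valid_frac windows with a smaller unmasked fraction are skipped.
#' @return list of class `front_set`: `pixels` (data.frame `row`, `col`,
#'   `front_id`), `front_id` (integer matrix, `NA` off-front), `n_fronts`,
#'   and `windows` (per-window diagnostics: `tau`, `theta`, accepted).
#' @export
detect_fronts <- function(sst, window_px = 32L, stride_px = window_px %/% 2L,
                          theta_crit = 0.70, cohesion_crits = c(0.90, 0.90),
                          min_length_px = 15L, bin_width = 0.1,
                          median_filter = TRUE, min_valid_frac = 0.25) {
  nr <- length(sst$lat); nc <- length(sst$lon)
  if (window_px > min(nr, nc)) stop("window_px exceeds the grid dimensions")
  if (stride_px > window_px) stop("stride_px must not exceed window_px")
  v <- sst$values
  v[sst$mask] <- NA
  if (isTRUE(median_filter)) v <- median_filter3(v)

  starts <- function(n) {
    s <- seq(1L, max(n - window_px + 1L, 1L), by = stride_px)
    if (s[length(s)] != n - window_px + 1L) s <- c(s, n - window_px + 1L)
    s
  }
  cand <- matrix(FALSE, nr, nc)
  wlog <- list()
  for (r0 in starts(nr)) for (c0 in starts(nc)) {
    rows <- r0:(r0 + window_px - 1L); cols <- c0:(c0 + window_px - 1L)
    w <- v[rows, cols]
    if (mean(is.finite(w)) < min_valid_frac) next
    hs <- histogram_split(w, bin_width)
    acc <- FALSE
    if (is.finite(hs$tau) && hs$theta >= theta_crit) {
      pop <- w >= hs$tau
      coh <- cohesion_stats(pop)
      if (!any(is.na(coh)) &&
          coh["cold"] >= cohesion_crits[1] && coh["warm"] >= cohesion_crits[2]) {
        acc <- TRUE
        # frontal candidates: pixels with a 4-neighbour across tau, thinned
        # to the pixel of each crossing whose SST is closer to tau (ties go
        # to the cold side) so the front line stays ~1 pixel wide
        opp <- matrix(FALSE, window_px, window_px)
        dtau <- abs(w - hs$tau)
        opp_min <- matrix(Inf, window_px, window_px)
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          nb <- matrix(NA, window_px, window_px)
          nbd <- matrix(Inf, window_px, window_px)
          rs <- seq_len(window_px) + d[1]; cs <- seq_len(window_px) + d[2]
          ok_r <- rs >= 1 & rs <= window_px; ok_c <- cs >= 1 & cs <= window_px
          nb[ok_r, ok_c] <- pop[rs[ok_r], cs[ok_c]]
          x <- dtau[rs[ok_r], cs[ok_c]]
          x[is.na(x)] <- Inf
          nbd[ok_r, ok_c] <- x
          cross <- !is.na(nb) & !is.na(pop) & nb != pop
          opp <- opp | cross
          opp_min[cross] <- pmin(opp_min[cross], nbd[cross])
        }
        keep <- opp & !is.na(pop) &
          (dtau < opp_min | (dtau == opp_min & !pop))
        cand[rows, cols] <- cand[rows, cols] | keep
      }
    }
    wlog[[length(wlog) + 1L]] <- data.frame(row0 = r0, col0 = c0,
                                            tau = hs$tau, theta = hs$theta,
                                            accepted = acc)
  }
  if (length(wlog) == 0L) {
    warning("no window had enough valid pixels; empty front set")
  }
  windows <- if (length(wlog)) do.call(rbind, wlog) else NULL

  front_id <- matrix(NA_integer_, nr, nc)
  pix <- which(cand, arr.ind = TRUE)
  if (nrow(pix) > 0) {
    comp <- label_components(cand)
    keep_sizes <- table(comp[cand])
    keep <- as.integer(names(keep_sizes))[keep_sizes >= min_length_px]
    # deterministic ids: order surviving components by smallest linear index
    firsts <- vapply(keep, function(k) min(which(comp == k)), integer(1))
    keep <- keep[order(firsts)]
    for (i in seq_along(keep)) front_id[comp == keep[i]] <- i
  }
  pix <- which(!is.na(front_id), arr.ind = TRUE)
  pixels <- data.frame(row = pix[, 1], col = pix[, 2],
                       front_id = front_id[pix])
  pixels <- pixels[order(pixels$row, pixels$col), , drop = FALSE]
  rownames(pixels) <- NULL
  if (nrow(pixels) == 0 && length(wlog) > 0) {
    message("no fronts detected")
  }
  structure(list(pixels = pixels, front_id = front_id,
                 n_fronts = length(unique(pixels$front_id)),
                 windows = windows),
            class = "front_set")
}

# 8-connected component labelling of a logical matrix via igraph.
label_components <- function(m) {
  idx <- which(m)
  nr <- nrow(m)
  lab <- matrix(NA_integer_, nr, ncol(m))
  if (length(idx) == 0) return(lab)
  pos <- match(idx, idx)
  edges <- integer(0)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  key <- function(r, c) (c - 1L) * nr + r
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(m)
    nb <- match(key(r2[ok], c2[ok]), idx)
    has <- !is.na(nb)
    edges <- c(edges, rbind(pos[ok][has], nb[has]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' @export
print.front_set <- function(x, ...) {
  cat(sprintf("<front_set> %d fronts, %d frontal pixels\n",
              x$n_fronts, nrow(x$pixels)))
  invisible(x)
}
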