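# Internal helpers shared across modules.

# Kilometres per degree of latitude (sphere of radius 6371 km).
KM_PER_DEG <- pi * 6371 / 180

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic entry points go through this so a
# seed argument never leaks into (or depends on) the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Haversine distance in km between point sets (lon/lat degrees). Thin wrapper
# so all great-circle arithmetic shares one radius.
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371) # km
}

# Cross distances (n x m, km) between two point sets, chunked to bound memory.
cross_dist_km <- function(lon1, lat1, lon2, lat2, chunk = 2000L) {
  n <- length(lon1)
  out <- matrix(NA_real_, n, length(lon2))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j, ] <- geosphere::distm(cbind(lon1[i:j], lat1[i:j]),
                                   cbind(lon2, lat2),
                                   fun = geosphere::distHaversine) / 1000
    i <- j + 1L
  }
  out
}

# Signed distance (km) from points to a polyline given in planar km
# coordinates. Sign is positive on the left of the vertex order. Returns km.
signed_dist_polyline_km <- function(px, py, vx, vy) {
  nseg <- length(vx) - 1L
  stopifnot(nseg >= 1L)
  best_d2 <- rep(Inf, length(px))
  best_side <- rep(0, length(px))
  for (s in seq_len(nseg)) {
    ax <- vx[s]; ay <- vy[s]
    dx <- vx[s + 1L] - ax; dy <- vy[s + 1L] - ay
    L2 <- dx * dx + dy * dy
    if (L2 == 0) next
    t <- ((px - ax) * dx + (py - ay) * dy) / L2
    t <- pmin(1, pmax(0, t))
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    cross <- dx * (py - ay) - dy * (px - ax)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_side[upd] <- sign(cross[upd])
  }
  best_side[best_side == 0] <- 1
  best_side * sqrt(best_d2)
}

# Rolling windowed statistic with edge truncation (window = full width, odd).
roll_stat <- function(x, window, fun) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- fun(x[lo:hi])
  }
  out
}

# md5 of an arbitrary R object (used for run manifests).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
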