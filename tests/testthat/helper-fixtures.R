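# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Mid-latitude 10 x 10 degree domain at 0.05 degrees (200 x 200 pixels).
koe_domain <- function() list(lon = c(150, 160), lat = c(35, 45), res = 0.05)

# Meandering front, 2 degC contrast, 10 km width, 0.1 degC noise.
std_field <- function() fixture("std_field", function() {
  make_sst_field(koe_domain(),
                 front_spec(delta_T = 2, width_km = 10, T_cold = 12,
                            meander_amplitude_km = 60,
                            meander_wavelength_km = 300),
                 noise_sd = 0.1, seed = 1)
})

std_fronts <- function() fixture("std_fronts", function() detect_fronts(std_field()))

std_labels <- function() fixture("std_labels", function() {
  partition_zones(std_field(), fronts = std_fronts())
})

# Small straight noise-free front (60 x 60 pixels) for geometric tests.
straight_field <- function() fixture("straight_field", function() {
  make_sst_field(list(lon = c(150, 153), lat = c(38, 41), res = 0.05),
                 front_spec(delta_T = 2, width_km = 10, T_cold = 12),
                 noise_sd = 0, seed = 1)
})

straight_labels <- function() fixture("straight_labels", function() {
  partition_zones(straight_field(), fronts = detect_fronts(straight_field()))
})

# Broad straight front (30 km width): zones span several pixels, giving a
# finely resolved normalized-distance raster.
wide_field <- function() fixture("wide_field", function() {
  make_sst_field(list(lon = c(150, 153), lat = c(38, 41), res = 0.05),
                 front_spec(delta_T = 3, width_km = 30, T_cold = 12),
                 noise_sd = 0, seed = 1)
})

wide_labels <- function() fixture("wide_labels", function() {
  partition_zones(wide_field(), fronts = detect_fronts(wide_field()))
})

# Linear north-south SST ramp (flat availability per SST bin), no front.
ramp_field <- function(lo = 10, hi = 20) {
  lonv <- seq(150.025, 159.975, by = 0.05)
  latv <- seq(35.025, 44.975, by = 0.05)
  sst_grid(matrix(rep(seq(lo, hi, length.out = length(latv)), length(lonv)),
                  length(latv), length(lonv)),
           lonv, latv, date = "2019-07-01")
}

# Hand-built tiny label map (no detection involved) for arithmetic tests.
manual_labels <- function(label, sst, res = 0.1, lon0 = 150, lat0 = 40) {
  nr <- nrow(label); nc <- ncol(label)
  structure(list(
    label = label,
    front_id = ifelse(label == ZONE_CODES[["frontal_line"]], 1L, NA_integer_),
    nearest_front = matrix(NA_integer_, nr, nc),
    dist_to_front_km = matrix(NA_real_, nr, nc),
    line_side = matrix(ifelse(label == ZONE_CODES[["frontal_line"]], "warm", NA),
                       nr, nc),
    threshold_used = NULL,
    lon = lon0 + (seq_len(nc) - 0.5) * res,
    lat = lat0 + (seq_len(nr) - 0.5) * res,
    res = res, date = as.Date("2020-01-01"),
    sst = sst, grad_mag = matrix(0, nr, nc),
    mask = matrix(FALSE, nr, nc), mode = "manual"
  ), class = "front_labels")
}

# Minimal zone_totals constructor for identity tests.
manual_totals <- function(F_warm, F_cold, F_non, A_warm = 1, A_cold = 1,
                          A_non = 1, F_line = 0, A_line = 0,
                          F_line_warm = 0, A_line_warm = 0) {
  structure(list(
    F = c(frontal = F_warm + F_cold + F_line, line = F_line,
          line_warm = F_line_warm, line_cold = F_line - F_line_warm,
          warm = F_warm, cold = F_cold, non_frontal = F_non,
          all = F_warm + F_cold + F_line + F_non),
    A = c(frontal = A_warm + A_cold + A_line, line = A_line,
          line_warm = A_line_warm, line_cold = A_line - A_line_warm,
          warm = A_warm, cold = A_cold, non_frontal = A_non,
          all = A_warm + A_cold + A_line + A_non),
    n = c(frontal = NA, line = NA, line_warm = NA, line_cold = NA,
          warm = NA, cold = NA, non_frontal = NA, all = NA)
  ), class = "zone_totals")
}

expect_no_na <- function(x) expect_false(anyNA(x))
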