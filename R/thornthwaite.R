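#' Feddema legend (36 types)
#'
#' Six thermal types crossed with six moisture types, thermal-major in
#' table order: Torrid, Hot, Warm, Cool, Cold, Frigid by annual potential
#' evapotranspiration; Saturated, Wet, Moist, Dry, Semiarid, Arid by
#' moisture index.
#'
#' @return data.frame with `id` (1-36), `code` (e.g. `"Torrid/Saturated"`),
#'   `name`, `thermal`, `moisture`.
#' @export
feddema_legend <- function() {
  thermal <- c("Torrid", "Hot", "Warm", "Cool", "Cold", "Frigid")
  moisture <- c("Saturated", "Wet", "Moist", "Dry", "Semiarid", "Arid")
  g <- expand.grid(moisture = moisture, thermal = thermal,
                   stringsAsFactors = FALSE)[, c("thermal", "moisture")]
  data.frame(id = 1:36,
             code = paste(g$thermal, g$moisture, sep = "/"),
             name = paste(g$thermal, g$moisture),
             thermal = g$thermal, moisture = g$moisture,
             stringsAsFactors = FALSE)
}

# days per month (climatological, non-leap) and mid-month day-of-year
MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
MONTH_MID_DOY <- cumsum(c(0, MONTH_DAYS[-12])) + MONTH_DAYS / 2

#' Mean daylight hours per month
#'
#' Day length from solar declination at the month's middle day:
#' delta = 0.409 sin(2 pi J / 365 - 1.39), sunset hour angle
#' omega_s = acos(-tan(phi) tan(delta)) (clamped for polar day/night),
#' day length 24 omega_s / pi.
#'
#' @param lat latitude in degrees (vector).
#' @return Matrix `12 x length(lat)` of mean daylight hours.
#' @export
daylight_hours <- function(lat) {
  phi <- lat * pi / 180
  delta <- 0.409 * sin(2 * pi * MONTH_MID_DOY / 365 - 1.39)
  x <- -outer(delta, tan(phi), function(d, tp) tan(d) * tp)
  x <- pmin(pmax(x, -1), 1)
  24 / pi * acos(x)
}

#' Monthly potential evapotranspiration (classic Thornthwaite)
#'
#' The classic temperature-based estimate: annual heat index
#' `I = sum (T/5)^1.514` over months with `T > 0`; exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`; unadjusted
#' monthly PET `16 (10 T / I)^a` mm for `0 < T <= 26.5`, the standard
#' high-temperature quadratic `-415.85 + 32.24 T - 0.43 T^2` above
#' 26.5 degC, and 0 at or below freezing. Each month is then scaled by the
#' day-length correction `(daylight/12) * (days/30)`. When every month is
#' at or below 0 degC (`I = 0`), PET is 0 throughout.
#'
#' @param monthly_ts numeric vector of 12 monthly-mean temperatures (degC),
#'   or a matrix `12 x n` for n locations.
#' @param lat latitude (degrees) of the location(s); length 1 or n.
#' @return Matrix `12 x n` of monthly PET (mm).
#' @export
thornthwaite_pet_monthly <- function(monthly_ts, lat) {
  x <- as.matrix(monthly_ts)
  if (nrow(x) != 12L) stop("monthly_ts must have 12 months on rows")
  n <- ncol(x)
  if (length(lat) == 1L) lat <- rep(lat, n)
  stopifnot(length(lat) == n, all(abs(lat) <= 90))
  Tpos <- pmax(x, 0)
  I <- colSums((Tpos / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  e <- matrix(0, 12L, n)
  ok <- I > 0
  if (any(ok)) {
    Ti <- x[, ok, drop = FALSE]
    Ia <- rep(I[ok], each = 12L)
    aa <- rep(a[ok], each = 12L)
    em <- 16 * (10 * pmax(Ti, 0) / Ia)^aa
    hot <- Ti > 26.5
    em[hot] <- -415.85 + 32.24 * Ti[hot] - 0.43 * Ti[hot]^2
    em[Ti <= 0] <- 0
    e[, ok] <- em
  }
  K <- daylight_hours(lat) / 12 * (MONTH_DAYS / 30)
  pmax(e * K, 0)
}

#' Annual potential evapotranspiration
#'
#' @inheritParams thornthwaite_pet_monthly
#' @return Numeric vector of annual PET (mm yr^-1), the sum of the 12
#'   corrected monthly values.
#' @export
thornthwaite_pe_annual <- function(monthly_ts, lat) {
  colSums(thornthwaite_pet_monthly(monthly_ts, lat))
}

#' Willmott-Feddema moisture index
#'
#' A symmetric aridity/humidity index in `[-1, 1]`:
#' `Im = r/PE - 1` when `r < PE` and `Im = 1 - PE/r` when `r >= PE`.
#' Both branches meet at 0 when `r = PE`.
#'
#' @param r annual rainfall (mm yr^-1).
#' @param PE annual potential evapotranspiration (mm yr^-1).
#' @return `Im`; pixels with `r = PE = 0` are assigned 0 and their count is
#'   recorded in the `"undefined"` attribute (a QC flag, not a silent
#'   default).
#' @export
moisture_index <- function(r, PE) {
  stopifnot(all(r >= 0, na.rm = TRUE), all(PE >= 0, na.rm = TRUE))
  im <- ifelse(r < PE, r / PE - 1, 1 - PE / r)
  undef <- r == 0 & PE == 0
  im[undef] <- 0
  attr(im, "undefined") <- sum(undef, na.rm = TRUE)
  im
}

#' Feddema climate type from annual PE and moisture index
#'
#' Thermal type from annual PE bands (mm): Frigid 0-300, Cold 300-600,
#' Cool 600-900, Warm 900-1200, Hot 1200-1500, Torrid above 1500.
#' Moisture type from Im bands: Arid -1 to -0.66, Semiarid -0.66 to -0.33,
#' Dry -0.33 to 0, Moist 0 to 0.33, Wet 0.33 to 0.66, Saturated 0.66 to 1.
#' Bands are lower-inclusive, upper-exclusive, except the top band of each
#' axis which is closed above, so the two axes are partitions.
#'
#' @param PE annual potential evapotranspiration (mm yr^-1), non-negative.
#' @param Im moisture index in `[-1, 1]`.
#' @return data.frame with `id` (1-36, see [feddema_legend()]), `thermal`,
#'   `moisture`.
#' @export
classify_feddema <- function(PE, Im) {
  if (any(PE < 0, na.rm = TRUE)) stop("PE must be non-negative")
  if (any(Im < -1 - 1e-9 | Im > 1 + 1e-9, na.rm = TRUE))
    stop("Im must lie in [-1, 1]")
  # ascending band index via findInterval, then map to table-order id
  th_breaks <- c(300, 600, 900, 1200, 1500)
  th_asc <- findInterval(PE, th_breaks) + 1L       # 1 = Frigid ... 6 = Torrid
  th <- 7L - th_asc                                 # 1 = Torrid ... 6 = Frigid
  mo_breaks <- c(-0.66, -0.33, 0, 0.33, 0.66)
  mo_asc <- findInterval(Im, mo_breaks) + 1L        # 1 = Arid ... 6 = Saturated
  mo <- 7L - mo_asc                                 # 1 = Saturated ... 6 = Arid
  id <- (th - 1L) * 6L + mo
  leg <- feddema_legend()
  data.frame(id = id, thermal = leg$thermal[id], moisture = leg$moisture[id],
             stringsAsFactors = FALSE)
}

#' Thornthwaite-Feddema classification of a gridded climatology
#'
#' Computes annual PET per pixel (classic Thornthwaite with day-length
#' correction at the cell-center latitude), the moisture index from annual
#' precipitation, and the 36-type Feddema assignment.
#'
#' @param clim a [monthly_climatology()].
#' @return A [class_map()] (scheme `"thornthwaite"`, 36-class legend) with
#'   auxiliary rasters `PE` (mm yr^-1) and `Im` for NetCDF export.
#' @export
classify_map_thornthwaite <- function(clim) {
  stopifnot(inherits(clim, "monthly_climatology"))
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  idx <- which(clim$land_mask)
  latm <- matrix(clim$lat, nlat, nlon)
  tsm <- matrix(clim$ts, nrow = 12L)  # 12 x (nlat*nlon), column-major cells
  pe_all <- thornthwaite_pe_annual(tsm[, idx, drop = FALSE], latm[idx])
  app <- apply(clim$pr, c(2, 3), sum)
  im <- moisture_index(app[idx], pe_all)
  cls <- classify_feddema(pe_all, as.numeric(im))
  codes <- matrix(NA_integer_, nlat, nlon)
  codes[idx] <- cls$id
  pe_m <- matrix(NA_real_, nlat, nlon); pe_m[idx] <- pe_all
  im_m <- matrix(NA_real_, nlat, nlon); im_m[idx] <- as.numeric(im)
  class_map(codes, legend = feddema_legend()[, c("id", "code", "name")],
            scheme = "thornthwaite",
            lat = clim$lat, lon = clim$lon, land_mask = clim$land_mask,
            scenario = clim$meta$scenario, period = clim$meta$period,
            aux = list(PE = pe_m, Im = im_m))
}
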