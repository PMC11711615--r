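#' Monthly gridded climatology
#'
#' Container for a 12-month climatology of near-surface temperature and
#' precipitation on a regular latitude-longitude grid with a land mask.
#' This is the universal input of every classifier in the package.
#'
#' @param ts numeric array `c(12, nlat, nlon)`, monthly-mean temperature (degC).
#' @param pr numeric array `c(12, nlat, nlon)`, monthly precipitation
#'   (mm month^-1), non-negative on land.
#' @param lat numeric vector of cell-center latitudes (degrees north),
#'   strictly monotone with constant spacing. The conventional raster order
#'   runs north to south (89.5 to -89.5 at 1 degree).
#' @param lon numeric vector of cell-center longitudes (degrees east),
#'   constant spacing (default 1 degree, -179.5 to 179.5).
#' @param land_mask logical matrix `nlat x nlon`; `TRUE` on land. Masked
#'   (ocean/Antarctica) cells are excluded from every downstream statistic.
#' @param scenario,period free-text labels attached to output filenames
#'   (e.g. `"historical"`, `"1980-2014"`).
#'
#' @return An object of class `monthly_climatology`.
#' @export
monthly_climatology <- function(ts, pr, lat, lon, land_mask,
                                scenario = "historical",
                                period = "1980-2014") {
  ts <- as_month_array(ts, "ts")
  pr <- as_month_array(pr, "pr")
  if (!identical(dim(ts), dim(pr)))
    stop("ts and pr must have identical dimensions")
  nlat <- dim(ts)[2L]; nlon <- dim(ts)[3L]
  if (length(lat) != nlat || length(lon) != nlon)
    stop("lat/lon lengths do not match field dimensions")
  dl <- diff(lat)
  if (length(dl) && (any(dl == 0) || length(unique(sign(dl))) != 1L))
    stop("lat must be strictly monotone")
  if (missing(land_mask) || is.null(land_mask))
    land_mask <- matrix(TRUE, nlat, nlon)
  land_mask <- matrix(as.logical(land_mask), nlat, nlon)
  obj <- structure(
    list(ts = ts, pr = pr, lat = as.numeric(lat), lon = as.numeric(lon),
         land_mask = land_mask,
         meta = list(scenario = scenario, period = period)),
    class = "monthly_climatology")
  validate_climatology(obj)
  obj
}

as_month_array <- function(x, name) {
  x <- unname(as.array(x))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L || dim(x)[1L] != 12L)
    stop(sprintf("%s must be a (12, nlat, nlon) array; got dimensions [%s]",
                 name, paste(dim(x), collapse = ", ")))
  storage.mode(x) <- "double"
  x
}

validate_climatology <- function(clim) {
  land <- clim$land_mask
  for (m in 1:12) {
    tsm <- clim$ts[m, , ]; prm <- clim$pr[m, , ]
    if (any(!is.finite(tsm[land])))
      stop("ts must be finite on land")
    if (any(!is.finite(prm[land])) || any(prm[land] < 0))
      stop("pr must be finite and non-negative on land")
  }
  invisible(clim)
}

#' @export
print.monthly_climatology <- function(x, ...) {
  cat(sprintf("<monthly_climatology> %d x %d grid, %d land cells (%.1f%%)\n",
              length(x$lat), length(x$lon), sum(x$land_mask),
              100 * mean(x$land_mask)))
  cat(sprintf("  scenario: %s   period: %s\n", x$meta$scenario, x$meta$period))
  cat(sprintf("  lat %s..%s  lon %s..%s\n", x$lat[1], x$lat[length(x$lat)],
              x$lon[1], x$lon[length(x$lon)]))
  invisible(x)
}

#' Month indices of the summer half-year
#'
#' Summer is Apr-Sep in the northern hemisphere and Oct-Mar in the southern;
#' winter is the complement. Cells with center latitude >= 0 count as
#' northern. This convention is the one commonly used to evaluate the
#' Koeppen precipitation-seasonality rules; it is exposed so alternative
#' half-years can be substituted.
#'
#' @param northern logical; `TRUE` for the northern hemisphere.
#' @return Integer vector of 6 month indices.
#' @export
summer_months <- function(northern = TRUE) {
  if (northern) 4:9 else c(10:12, 1:3)
}

#' Per-pixel annual and seasonal climate statistics
#'
#' Reduces a monthly climatology to the per-pixel summaries consumed by the
#' classifiers: annual precipitation total, annual-mean / coldest-month /
#' hottest-month temperature, driest-month precipitation, and the min/max
#' monthly precipitation within the hemisphere-dependent summer and winter
#' half-years, together with the fraction of the annual total falling in
#' each half-year.
#'
#' @param clim a [monthly_climatology()].
#' @return An object of class `derived_climatology`: a list of `nlat x nlon`
#'   matrices `P_annual` (mm yr^-1), `T_avg`, `T_min`, `T_max` (degC),
#'   `P_min`, `P_smin`, `P_smax`, `P_wmin`, `P_wmax` (mm month^-1),
#'   `winter_frac`, `summer_frac`, plus the grid and mask.
#' @export
derive_climatology <- function(clim) {
  stopifnot(inherits(clim, "monthly_climatology"))
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  out <- list(
    P_annual = apply(clim$pr, c(2, 3), sum),
    T_avg    = apply(clim$ts, c(2, 3), mean),
    T_min    = apply(clim$ts, c(2, 3), min),
    T_max    = apply(clim$ts, c(2, 3), max),
    P_min    = apply(clim$pr, c(2, 3), min))

  nh <- clim$lat >= 0
  # computed per hemisphere: summer/winter month sets swap across the equator
  smin <- smax <- wmin <- wmax <- psum <- matrix(NA_real_, nlat, nlon)
  for (hemi in c(TRUE, FALSE)) {
    rows <- which(nh == hemi)
    if (!length(rows)) next
    sm <- summer_months(hemi); wm <- setdiff(1:12, sm)
    sub <- clim$pr[, rows, , drop = FALSE]
    smin[rows, ] <- apply(sub[sm, , , drop = FALSE], c(2, 3), min)
    smax[rows, ] <- apply(sub[sm, , , drop = FALSE], c(2, 3), max)
    wmin[rows, ] <- apply(sub[wm, , , drop = FALSE], c(2, 3), min)
    wmax[rows, ] <- apply(sub[wm, , , drop = FALSE], c(2, 3), max)
    psum[rows, ] <- apply(sub[sm, , , drop = FALSE], c(2, 3), sum)
  }
  out$P_smin <- smin; out$P_smax <- smax
  out$P_wmin <- wmin; out$P_wmax <- wmax
  sf <- ifelse(out$P_annual > 0, psum / out$P_annual, 0.5)
  out$summer_frac <- sf
  out$winter_frac <- 1 - sf
  out$lat <- clim$lat; out$lon <- clim$lon; out$land_mask <- clim$land_mask
  class(out) <- "derived_climatology"
  out
}

#' Area weights on the grid
#'
#' Per-pixel weights proportional to cell area (cosine of the center
#' latitude on a regular grid), zeroed on masked cells and normalized to
#' sum to one over the unmasked domain. Used by every area-weighted metric.
#'
#' @param clim a [monthly_climatology()] (or any list with `lat`, `lon`,
#'   `land_mask`).
#' @return `nlat x nlon` matrix of weights summing to 1 over land.
#' @export
area_weights <- function(clim) {
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  w <- matrix(cos(clim$lat * pi / 180), nlat, nlon)
  w[w < 0] <- 0
  w[!clim$land_mask] <- 0
  s <- sum(w)
  if (s <= 0) stop("empty domain: no unmasked cells with positive area")
  w / s
}

#' Bilinear regridding on regular latitude-longitude grids
#'
#' Interpolates a field from one regular grid of cell centers to another.
#' Longitude is treated as periodic (360 degrees), so interpolation works
#' across the dateline; latitudes outside the source cell-center range are
#' an error (no extrapolation).
#'
#' @param field numeric matrix `length(src_lat) x length(src_lon)`.
#' @param src_lat,src_lon source cell-center coordinates.
#' @param dst_lat,dst_lon destination cell-center coordinates.
#' @return Matrix `length(dst_lat) x length(dst_lon)`.
#' @export
regrid_bilinear <- function(field, src_lat, src_lon, dst_lat, dst_lon) {
  field <- as.matrix(field)
  stopifnot(nrow(field) == length(src_lat), ncol(field) == length(src_lon))
  olat <- order(src_lat)
  latv <- src_lat[olat]
  f <- field[olat, , drop = FALSE]
  if (any(dst_lat < latv[1] - 1e-9) || any(dst_lat > latv[length(latv)] + 1e-9))
    stop("destination latitude outside source coverage; refusing to extrapolate")

  # periodic longitude: unwrap to increasing, pad one wrap column each side
  lonv <- src_lon %% 360
  olon <- order(lonv)
  lonv <- lonv[olon]
  f <- f[, olon, drop = FALSE]
  nlon <- length(lonv)
  lon_ext <- c(lonv[nlon] - 360, lonv, lonv[1] + 360)
  f_ext <- cbind(f[, nlon], f, f[, 1])

  ilat <- findInterval(pmin(pmax(dst_lat, latv[1]), latv[length(latv)]), latv,
                       all.inside = TRUE)
  tlat <- (dst_lat - latv[ilat]) / (latv[ilat + 1] - latv[ilat])
  dlon <- dst_lon %% 360
  ilon <- findInterval(dlon, lon_ext, all.inside = TRUE)
  tlon <- (dlon - lon_ext[ilon]) / (lon_ext[ilon + 1] - lon_ext[ilon])

  out <- matrix(NA_real_, length(dst_lat), length(dst_lon))
  for (j in seq_along(dst_lon)) {
    c0 <- f_ext[ilat, ilon[j]]     + tlat * (f_ext[ilat + 1, ilon[j]]     - f_ext[ilat, ilon[j]])
    c1 <- f_ext[ilat, ilon[j] + 1] + tlat * (f_ext[ilat + 1, ilon[j] + 1] - f_ext[ilat, ilon[j] + 1])
    out[, j] <- c0 + tlon[j] * (c1 - c0)
  }
  out
}
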