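#' Categorical class-map raster
#'
#' The universal classifier output: an integer-coded categorical raster on
#' the climatology grid, with a legend resolving every code, the scheme
#' name, and optional auxiliary continuous rasters (e.g. the climate
#' variables exported alongside the class layer).
#'
#' @param codes integer matrix `nlat x nlon`; `NA` on masked cells.
#' @param legend data.frame with columns `id`, `code`, `name` covering every
#'   code present.
#' @param scheme one of `"holdridge"`, `"koppen"`, `"thornthwaite"`,
#'   `"whittaker"` (or a consensus layer name).
#' @param lat,lon cell-center coordinates.
#' @param land_mask logical matrix; codes must be `NA` off-land.
#' @param scenario,period free-text labels used in output filenames.
#' @param varname variable kind: `"class"`, `"confidence"` or `"modvar"`.
#' @param aux named list of numeric matrices carried into NetCDF output.
#' @return Object of class `class_map`.
#' @export
class_map <- function(codes, legend, scheme, lat, lon, land_mask,
                      scenario = "historical", period = "1980-2014",
                      varname = "class", aux = list()) {
  codes <- matrix(as.integer(codes), length(lat), length(lon))
  stopifnot(is.data.frame(legend), all(c("id", "code", "name") %in% names(legend)))
  present <- unique(codes[!is.na(codes)])
  if (!all(present %in% legend$id))
    stop("class codes present that the legend does not resolve")
  if (any(!is.na(codes[!land_mask])))
    stop("masked cells must carry NA codes")
  structure(list(codes = codes, legend = legend, scheme = scheme,
                 varname = varname, lat = lat, lon = lon,
                 land_mask = land_mask,
                 meta = list(scenario = scenario, period = period),
                 aux = aux),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$codes[!is.na(x$codes)], levels = x$legend$id))
  cat(sprintf("<class_map> scheme %s (%s), %d x %d, %d classified cells\n",
              x$scheme, x$varname, length(x$lat), length(x$lon),
              sum(!is.na(x$codes))))
  cat(sprintf("  %d/%d legend classes present; scenario %s, period %s\n",
              sum(tab > 0), nrow(x$legend), x$meta$scenario, x$meta$period))
  invisible(x)
}

#' Classify a climatology under one or all schemes
#'
#' Dispatcher over the four classification systems.
#'
#' @param clim a [monthly_climatology()].
#' @param scheme `"holdridge"`, `"koppen"`, `"thornthwaite"`, `"whittaker"`
#'   or `"all"`.
#' @return A [class_map()], or a named list of them for `"all"`.
#' @export
classify_climatology <- function(clim, scheme = c("all", "holdridge", "koppen",
                                                  "thornthwaite", "whittaker")) {
  scheme <- match.arg(scheme)
  fns <- list(holdridge = classify_map_holdridge,
              koppen = classify_map_koppen,
              thornthwaite = classify_map_thornthwaite,
              whittaker = classify_map_whittaker)
  if (scheme == "all") lapply(fns, function(f) f(clim)) else fns[[scheme]](clim)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}
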