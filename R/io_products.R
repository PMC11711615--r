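#' Product filename convention
#'
#' Distribution filenames follow `classification_varname_scenario_period.ext`,
#' e.g. `koppen_class_historical_1980-2014.tif` or
#' `holdridge_consensus_ssp585_2021-2050.nc`.
#'
#' @param scheme classification scheme.
#' @param varname `"class"`, `"confidence"`, `"modvar"` or `"consensus"`.
#' @param scenario,period labels (no underscores).
#' @param ext file extension without dot.
#' @return Filename string.
#' @export
product_filename <- function(scheme, varname, scenario, period, ext) {
  parts <- c(scheme, varname, scenario, period)
  if (any(grepl("_", parts)))
    stop("scheme/varname/scenario/period tokens must not contain underscores")
  sprintf("%s_%s_%s_%s.%s", scheme, varname, scenario, period, ext)
}

#' Parse a product filename back into its tokens
#'
#' @param filename a name produced by [product_filename()].
#' @return List with `scheme`, `varname`, `scenario`, `period`, `ext`.
#' @export
parse_product_filename <- function(filename) {
  base <- basename(filename)
  ext <- sub(".*\\.", "", base)
  stem <- sub("\\.[^.]*$", "", base)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("filename does not follow classification_varname_scenario_period: ",
         base)
  list(scheme = parts[1], varname = parts[2], scenario = parts[3],
       period = parts[4], ext = ext)
}

#' Write a legend file
#'
#' @param legend data.frame with `id`, `code`, `name`.
#' @param path output path (conventionally `legend.txt`).
#' @return `path`, invisibly.
#' @export
write_legend <- function(legend, path) {
  writeLines(c("id\tcode\tname",
               sprintf("%d\t%s\t%s", legend$id, legend$code, legend$name)),
             path)
  invisible(path)
}

legend_attr_string <- function(legend) {
  paste(sprintf("%d: %s (%s)", legend$id, legend$code, legend$name),
        collapse = "; ")
}

# scheme -> auxiliary variables accompanying the class layer in NetCDF.
# Koeppen class files carry no auxiliary climate variables.
NETCDF_AUX_VARS <- list(
  holdridge = c("ABT", "APP", "PER"),
  koppen = character(0),
  thornthwaite = c("PE", "Im"),
  whittaker = c("AT", "APP"))

# class variable name in NetCDF: Holdridge life-zone files use HLZ,
# the other schemes a plain "class" layer
netcdf_class_var <- function(scheme) if (scheme == "holdridge") "HLZ" else "class"

#' Write a class map to NetCDF
#'
#' Class files carry the scheme's key climate variables alongside the class
#' layer (Whittaker: `AT`, `APP`; Holdridge: `ABT`, `APP`, `PER`, class as
#' `HLZ`; Thornthwaite-Feddema: `PE`, `Im`, `class`; Koeppen: the class
#' layer only). Legend codes are embedded in the file's global attributes.
#'
#' @param map a [class_map()] whose `aux` slot holds the required key
#'   variables (writing is refused if any is missing).
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_class_netcdf <- function(map, path) {
  stopifnot(inherits(map, "class_map"))
  needed <- NETCDF_AUX_VARS[[map$scheme]] %||% character(0)
  miss <- setdiff(needed, names(map$aux))
  if (length(miss))
    stop("missing key variable(s) for ", map$scheme, " NetCDF: ",
         paste(miss, collapse = ", "))
  dims <- c(lat = length(map$lat), lon = length(map$lon))
  flat <- function(m) as.double(t(m))           # row-major (lat slowest)
  vars <- list(
    list(name = "lat", dims = "lat", type = NC_DOUBLE, values = map$lat,
         attrs = list(units = "degrees_north")),
    list(name = "lon", dims = "lon", type = NC_DOUBLE, values = map$lon,
         attrs = list(units = "degrees_east")))
  for (nm in needed) {
    units <- switch(nm, ABT = "degC", AT = "degC",
                    APP = if (map$scheme == "whittaker") "cm year-1"
                    else "mm year-1",
                    PE = "mm year-1", PER = "1", Im = "1")
    v <- map$aux[[nm]]
    v[is.na(v)] <- -9999
    vars[[length(vars) + 1L]] <-
      list(name = nm, dims = c("lat", "lon"), type = NC_DOUBLE,
           values = flat(v),
           attrs = list(units = units, missing_value = -9999))
  }
  cls <- map$codes
  cls[is.na(cls)] <- 0L
  vars[[length(vars) + 1L]] <-
    list(name = netcdf_class_var(map$scheme), dims = c("lat", "lon"),
         type = NC_SHORT, values = as.integer(t(cls)),
         attrs = list(long_name = paste(map$scheme, "climate classification"),
                      missing_value = 0L,
                      legend = legend_attr_string(map$legend)))
  write_netcdf_raw(path, dims, vars, global_attrs = list(
    title = paste(map$scheme, "climate classification"),
    scheme = map$scheme, varname = map$varname,
    scenario = map$meta$scenario, period = map$meta$period,
    legend = legend_attr_string(map$legend)))
  invisible(path)
}

#' Write a consensus product to NetCDF
#'
#' Stores the variables `confidence` (percent, continuous) and `modvar`
#' (distinct-class count), with the class legend and reference provenance
#' in the global attributes.
#'
#' @param cp a `consensus_product` from [build_consensus_product()].
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_consensus_netcdf <- function(cp, path) {
  stopifnot(inherits(cp, "consensus_product"))
  dims <- c(lat = length(cp$lat), lon = length(cp$lon))
  conf <- cp$confidence; conf[is.na(conf)] <- -9999
  mv <- cp$modvar; mv[is.na(mv)] <- 0L
  vars <- list(
    list(name = "lat", dims = "lat", type = NC_DOUBLE, values = cp$lat,
         attrs = list(units = "degrees_north")),
    list(name = "lon", dims = "lon", type = NC_DOUBLE, values = cp$lon,
         attrs = list(units = "degrees_east")),
    list(name = "confidence", dims = c("lat", "lon"), type = NC_DOUBLE,
         values = as.double(t(conf)),
         attrs = list(units = "percent", missing_value = -9999,
                      long_name = "percent of members matching the reference class")),
    list(name = "modvar", dims = c("lat", "lon"), type = NC_SHORT,
         values = as.integer(t(mv)),
         attrs = list(units = "count", missing_value = 0L,
                      long_name = "number of distinct classes among members")))
  write_netcdf_raw(path, dims, vars, global_attrs = list(
    title = paste(cp$scheme, "consensus product"),
    scheme = cp$scheme, varname = "consensus",
    scenario = cp$meta$scenario, period = cp$meta$period,
    n_members = as.integer(cp$n_members),
    reference = cp$meta$reference,
    legend = legend_attr_string(cp$legend)))
  invisible(path)
}

#' Export a class map in the distribution formats
#'
#' Writes the class raster under the standard filename convention as
#' GeoTIFF, NetCDF and/or BIL (+ `legend.txt`), with nodata code 0 for the
#' integer formats.
#'
#' @param map a [class_map()].
#' @param outdir output directory (created if needed).
#' @param formats subset of `c("tif", "nc", "bil")`.
#' @return Character vector of files written.
#' @export
export_class_map <- function(map, outdir, formats = c("tif", "nc", "bil")) {
  formats <- match.arg(formats, c("tif", "nc", "bil"), several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fn <- function(ext) file.path(outdir, product_filename(
    map$scheme, map$varname, map$meta$scenario, map$meta$period, ext))
  out <- character(0)
  if ("tif" %in% formats)
    out <- c(out, write_geotiff_raw(fn("tif"), map$codes, map$lat, map$lon))
  if ("nc" %in% formats)
    out <- c(out, write_class_netcdf(map, fn("nc")))
  if ("bil" %in% formats)
    out <- c(out, write_bil_raw(fn("bil"), map$codes, map$lat, map$lon))
  leg <- file.path(outdir, "legend.txt")
  legend_block <- c(paste0("# ", map$scheme),
                    sprintf("%d\t%s\t%s", map$legend$id, map$legend$code,
                            map$legend$name))
  cat(legend_block, file = leg, sep = "\n", append = file.exists(leg))
  c(out, leg)
}

#' Export a consensus product in the distribution formats
#'
#' GeoTIFF/BIL carry the 8-bit confidence *category* (1-5, nodata 0) and
#' the modvar count; the continuous percent-confidence layer travels in
#' the NetCDF file together with modvar.
#'
#' @param cp a `consensus_product`.
#' @param outdir output directory.
#' @param formats subset of `c("tif", "nc", "bil")`.
#' @return Character vector of files written.
#' @export
export_consensus <- function(cp, outdir, formats = c("tif", "nc", "bil")) {
  formats <- match.arg(formats, c("tif", "nc", "bil"), several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fn <- function(varname, ext) file.path(outdir, product_filename(
    cp$scheme, varname, cp$meta$scenario, cp$meta$period, ext))
  cat_codes <- cp$confidence_category
  out <- character(0)
  if ("tif" %in% formats) {
    out <- c(out,
             write_geotiff_raw(fn("confidence", "tif"), cat_codes, cp$lat, cp$lon),
             write_geotiff_raw(fn("modvar", "tif"), cp$modvar, cp$lat, cp$lon))
  }
  if ("nc" %in% formats)
    out <- c(out, write_consensus_netcdf(cp, fn("consensus", "nc")))
  if ("bil" %in% formats) {
    out <- c(out,
             write_bil_raw(fn("confidence", "bil"), cat_codes, cp$lat, cp$lon),
             write_bil_raw(fn("modvar", "bil"), cp$modvar, cp$lat, cp$lon))
  }
  out
}

#' Write a monthly climatology to NetCDF
#'
#' Stores `ts` (degC) and `pr` (mm month-1) on `(month, lat, lon)` plus the
#' land mask, readable back with [read_climatology_netcdf()].
#'
#' @param clim a [monthly_climatology()].
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_climatology_netcdf <- function(clim, path) {
  stopifnot(inherits(clim, "monthly_climatology"))
  dims <- c(month = 12L, lat = length(clim$lat), lon = length(clim$lon))
  # row-major flattening: month slowest, then lat, then lon
  flat3 <- function(a) as.double(aperm(a, c(3, 2, 1)))
  vars <- list(
    list(name = "lat", dims = "lat", type = NC_DOUBLE, values = clim$lat,
         attrs = list(units = "degrees_north")),
    list(name = "lon", dims = "lon", type = NC_DOUBLE, values = clim$lon,
         attrs = list(units = "degrees_east")),
    list(name = "month", dims = "month", type = NC_INT, values = 1:12,
         attrs = list(units = "month of climatological year")),
    list(name = "ts", dims = c("month", "lat", "lon"), type = NC_DOUBLE,
         values = flat3(clim$ts), attrs = list(units = "degC")),
    list(name = "pr", dims = c("month", "lat", "lon"), type = NC_DOUBLE,
         values = flat3(clim$pr), attrs = list(units = "mm month-1")),
    list(name = "land_mask", dims = c("lat", "lon"), type = NC_SHORT,
         values = as.integer(t(clim$land_mask)),
         attrs = list(long_name = "1 on land, 0 masked")))
  write_netcdf_raw(path, dims, vars, global_attrs = list(
    title = "monthly climatology",
    scenario = clim$meta$scenario, period = clim$meta$period))
  invisible(path)
}

#' Read a monthly climatology from NetCDF
#'
#' Reads a classic-format NetCDF file holding 12-month temperature and
#' precipitation fields. Temperature in kelvin (by `units` attribute) is
#' converted to degC; precipitation in kg m-2 s-1 is converted to
#' mm month-1 using climatological days per month. An optional `land_mask`
#' variable (nonzero = land) is honoured.
#'
#' @param path NetCDF-3 file with variables on dimensions
#'   `(month, lat, lon)` (or `(time, lat, lon)` with 12 steps).
#' @param ts_var,pr_var variable names (default `ts`, `pr`).
#' @param scenario,period labels for the result.
#' @return A [monthly_climatology()].
#' @export
read_climatology_netcdf <- function(path, ts_var = "ts", pr_var = "pr",
                                    scenario = "historical",
                                    period = "1980-2014") {
  nc <- read_netcdf_raw(path)
  getv <- function(nm) {
    if (!nm %in% names(nc$vars)) stop("variable not found: ", nm)
    nc$vars[[nm]]
  }
  ts <- getv(ts_var); pr <- getv(pr_var)
  lat <- as.numeric(getv("lat")$values)
  lon <- as.numeric(getv("lon")$values)
  ts_a <- month_first(ts$values, dim_order(ts$dims))
  pr_a <- month_first(pr$values, dim_order(pr$dims))
  units_of <- function(v) tolower(trimws(v$attrs$units %||% ""))
  if (units_of(ts) %in% c("k", "kelvin")) ts_a <- ts_a - 273.15
  if (units_of(pr) %in% c("kg m-2 s-1", "kg/m2/s", "kg m^-2 s^-1")) {
    for (m in 1:12) pr_a[m, , ] <- pr_a[m, , ] * 86400 * MONTH_DAYS[m]
  }
  mask <- if ("land_mask" %in% names(nc$vars))
    nc$vars$land_mask$values != 0 else NULL
  monthly_climatology(ts_a, pr_a, lat, lon, mask,
                      scenario = scenario, period = period)
}

dim_order <- function(dims) {
  m <- match(c("month", "time", "lat", "lon"), dims)
  c(if (!is.na(m[1])) m[1] else m[2], m[3], m[4])
}

month_first <- function(arr, ord) {
  if (anyNA(ord)) stop("variable must have month/time, lat and lon dimensions")
  out <- aperm(arr, ord)
  if (dim(out)[1] != 12L) stop("expected 12 months")
  out
}
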