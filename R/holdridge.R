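#' Holdridge life-zone centroid table
#'
#' The 33 life-zone centroids in (annual precipitation, biotemperature,
#' PET-ratio) space, grouped into 13 major biomes. Shipped as a plain-text
#' file; the file, not code, is the source of truth. Centroid coordinates
#' form sqrt(2) geometric progressions on all three axes, reflecting the
#' logarithmic layout of the Holdridge chart.
#'
#' @return data.frame with columns `biome_id` (1-13), `biome_code`,
#'   `biome_name`, `life_zone`, `APP` (mm yr^-1), `ABT` (degC), `PER`.
#' @export
holdridge_centroids <- function() {
  path <- system.file("extdata", "holdridge_centroids.tsv",
                      package = "climclass", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 33L) stop("centroid table must have exactly 33 rows")
  if (length(unique(tab$biome_id)) != 13L)
    stop("centroid table must group into exactly 13 biomes")
  tab
}

#' Holdridge biome legend (13 classes)
#' @return data.frame with `id`, `code`, `name`.
#' @export
holdridge_legend <- function() {
  tab <- holdridge_centroids()
  u <- !duplicated(tab$biome_id)
  data.frame(id = tab$biome_id[u], code = tab$biome_code[u],
             name = tab$biome_name[u], stringsAsFactors = FALSE)
}

#' Mean annual biotemperature
#'
#' Monthly mean temperatures are clamped to the 0-30 degC range before
#' averaging: months above 30 degC count as 30, months below 0 degC as 0.
#'
#' @param monthly_ts numeric vector of 12 monthly means, or an array with
#'   months on the first dimension.
#' @return Biotemperature (degC), same shape as the input minus the month
#'   dimension.
#' @export
biotemperature <- function(monthly_ts) {
  x <- as.array(monthly_ts)
  d <- dim(x)
  if (is.null(d) || length(d) == 1L || d[1L] != 12L) {
    if (length(x) == 12L) { dim(x) <- c(12L, 1L); d <- dim(x) }
    else stop("monthly_ts must have 12 months on the first dimension")
  }
  x <- pmin(pmax(x, 0), 30)
  out <- apply(x, seq_along(d)[-1L], mean)
  if (length(out) == 1L) out <- as.numeric(out)
  out
}

#' Holdridge PET ratio
#'
#' Potential-evapotranspiration ratio: biotemperature times 58.93 divided
#' by annual precipitation (the Holdridge aridity axis).
#'
#' @param ABT biotemperature (degC).
#' @param APP annual precipitation (mm yr^-1), positive.
#' @return `PER = 58.93 * ABT / APP`; `NaN` where `APP == 0` (such pixels
#'   are classified by the remaining two axes after the PER floor).
#' @export
pet_ratio <- function(ABT, APP) {
  out <- 58.93 * ABT / APP
  out[APP == 0] <- NaN
  out
}

# log2 transform of one Holdridge axis with a small floor so the ABT = 0
# centroids (Polar Desert) and hyper-arid APP = 0 pixels stay finite
holdridge_transform <- function(x, floor) log2(pmax(x, floor))

#' Classify states into Holdridge life zones
#'
#' Nearest-centroid assignment over the 33 life zones: each state is mapped
#' to the centroid minimizing Euclidean distance in base-2 logarithms of
#' (APP, ABT, PER). The log space is the natural metric for the Holdridge
#' chart, whose class boundaries are geometric (factor sqrt 2) on all three
#' axes; a linear-space distance is available via `space = "linear"`.
#' Ties go to the lower-index (table-order) centroid.
#'
#' @param ABT,APP,PER equal-length numeric vectors (degC, mm yr^-1,
#'   dimensionless). `NaN` PER values (APP = 0) are floored like zeros.
#' @param centroids the centroid table, by default [holdridge_centroids()].
#' @param space `"log2"` (default) or `"linear"`.
#' @return data.frame with `zone` (1-33 row index), `life_zone`,
#'   `biome_id` (1-13), `biome_code`.
#' @export
classify_holdridge <- function(ABT, APP, PER = pet_ratio(ABT, APP),
                               centroids = holdridge_centroids(),
                               space = c("log2", "linear")) {
  space <- match.arg(space)
  if (nrow(centroids) == 0L) stop("empty centroid table")
  n <- length(ABT)
  stopifnot(length(APP) == n, length(PER) == n)
  eps <- 2^-6
  if (space == "log2") {
    P <- cbind(holdridge_transform(APP, 1),
               holdridge_transform(ABT, eps),
               holdridge_transform(ifelse(is.nan(PER), 0, PER), eps))
    Cm <- cbind(holdridge_transform(centroids$APP, 1),
                holdridge_transform(centroids$ABT, eps),
                holdridge_transform(centroids$PER, eps))
  } else {
    P <- cbind(APP, ABT, ifelse(is.nan(PER), 0, PER))
    Cm <- cbind(centroids$APP, centroids$ABT, centroids$PER)
  }
  # squared distances, n x 33; max.col on the negative keeps first-min ties
  d2 <- outer(rowSums(P^2), rep(1, nrow(Cm))) -
    2 * P %*% t(Cm) + outer(rep(1, n), rowSums(Cm^2))
  zone <- max.col(-d2, ties.method = "first")
  data.frame(zone = zone,
             life_zone = centroids$life_zone[zone],
             biome_id = centroids$biome_id[zone],
             biome_code = centroids$biome_code[zone],
             stringsAsFactors = FALSE)
}

#' Holdridge classification of a gridded climatology
#'
#' Derives biotemperature, annual precipitation and PET ratio per pixel and
#' assigns the 13 major Holdridge biomes by nearest life-zone centroid.
#'
#' @param clim a [monthly_climatology()].
#' @inheritParams classify_holdridge
#' @return A [class_map()] (scheme `"holdridge"`, 13-class legend) whose
#'   `aux` slot carries the `ABT`, `APP` and `PER` rasters exported to
#'   NetCDF alongside the class layer.
#' @export
classify_map_holdridge <- function(clim, space = "log2") {
  stopifnot(inherits(clim, "monthly_climatology"))
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  abt <- biotemperature(clim$ts)
  app <- apply(clim$pr, c(2, 3), sum)
  per <- pet_ratio(abt, app)
  idx <- which(clim$land_mask)
  res <- classify_holdridge(abt[idx], app[idx], per[idx], space = space)
  codes <- matrix(NA_integer_, nlat, nlon)
  codes[idx] <- res$biome_id
  mask_na <- function(m) { m[!clim$land_mask] <- NA_real_; m }
  class_map(codes, legend = holdridge_legend(), scheme = "holdridge",
            lat = clim$lat, lon = clim$lon, land_mask = clim$land_mask,
            scenario = clim$meta$scenario, period = clim$meta$period,
            aux = list(ABT = mask_na(abt), APP = mask_na(app),
                       PER = mask_na(per)))
}
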