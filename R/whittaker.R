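#' Whittaker-Ricklefs biome polygons
#'
#' Loads the bundled biome-diagram polygons: nine simple closed polygons in
#' (annual mean temperature degC, annual precipitation cm yr^-1) space.
#' The bundled file is our own approximate digitization of the classic
#' Whittaker diagram in Ricklefs's rendering (hence the `_synthetic`
#' filename); the file, not code, is the source of truth, so an alternative
#' digitization can be dropped in.
#'
#' @param path polygon file (tab-separated `biome_id`, `biome_name`,
#'   `vertex`, `MAT`, `APP_cm`); default the bundled file.
#' @return List of 9 elements, each `list(id, name, xy)` with `xy` an
#'   `n x 2` vertex matrix (MAT, APP_cm) in ring order.
#' @export
whittaker_polygons <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "whittaker_polygons_synthetic.tsv",
                        package = "climclass", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- sort(unique(tab$biome_id))
  polys <- lapply(ids, function(i) {
    sub <- tab[tab$biome_id == i, ]
    sub <- sub[order(sub$vertex), ]
    xy <- cbind(sub$MAT, sub$APP_cm)
    if (nrow(xy) < 3L || anyDuplicated(xy))
      stop("degenerate polygon for biome ", i)
    if (!polygon_is_simple(xy))
      stop("self-intersecting polygon for biome ", i)
    list(id = i, name = sub$biome_name[1], xy = xy)
  })
  if (length(polys) != 9L) stop("expected exactly 9 biome polygons")
  polys
}

#' Whittaker biome legend (9 classes)
#' @param polys polygon set from [whittaker_polygons()].
#' @return data.frame with `id`, `code`, `name`.
#' @export
whittaker_legend <- function(polys = whittaker_polygons()) {
  data.frame(id = vapply(polys, `[[`, 0, "id"),
             code = vapply(polys, `[[`, "", "name"),
             name = vapply(polys, `[[`, "", "name"),
             stringsAsFactors = FALSE)
}

# segment properly intersects another (shared endpoints allowed)
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  cross <- function(o, p, q)
    (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
    d1 <- cross(a[i, ], b[i, ], a[j, ]); d2 <- cross(a[i, ], b[i, ], b[j, ])
    d3 <- cross(a[j, ], b[j, ], a[i, ]); d4 <- cross(a[j, ], b[j, ], b[i, ])
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
  }
  TRUE
}

# vectorized even-odd ray casting; points on an edge count as inside
point_in_polygon <- function(x, y, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in 1:n) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    # boundary test: collinear and within bounding box of the edge
    d <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on_seg <- abs(d) < 1e-9 &
      x >= pmin(xi, xj) - 1e-9 & x <= pmax(xi, xj) + 1e-9 &
      y >= pmin(yi, yj) - 1e-9 & y <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | on_seg
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# min distance from points to a polygon boundary, axes pre-scaled
dist_to_polygon <- function(x, y, xy) {
  n <- nrow(xy)
  d2 <- rep(Inf, length(x))
  j <- n
  for (i in 1:n) {
    x1 <- xy[j, 1]; y1 <- xy[j, 2]; x2 <- xy[i, 1]; y2 <- xy[i, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(pmax(((x - x1) * dx + (y - y1) * dy) / len2, 0), 1) else 0
    px <- x1 + t * dx; py <- y1 + t * dy
    d2 <- pmin(d2, (x - px)^2 + (y - py)^2)
    j <- i
  }
  sqrt(d2)
}

# chart ranges used to scale the two axes before outlier distances
WHITTAKER_MAT_RANGE <- 70   # degC
WHITTAKER_APP_RANGE <- 450  # cm yr^-1

#' Classify points into Whittaker biomes
#'
#' Point-in-polygon assignment over the nine biome polygons; on a shared
#' boundary the first polygon in file order wins. Points falling inside no
#' polygon (climate-space outliers) are assigned the biome whose polygon
#' boundary is nearest, with Euclidean distance computed after scaling each
#' axis by the diagram's range (70 degC, 450 cm) so neither axis dominates.
#' Assignment is therefore total.
#'
#' @param MAT annual mean temperature (degC), vector.
#' @param APP_cm annual precipitation (cm yr^-1), vector.
#' @param polys polygon set from [whittaker_polygons()].
#' @return Integer vector of biome ids (1-9); attribute `"outliers"` counts
#'   points assigned by the nearest-biome fallback.
#' @export
classify_whittaker <- function(MAT, APP_cm, polys = whittaker_polygons()) {
  stopifnot(length(MAT) == length(APP_cm))
  out <- rep(NA_integer_, length(MAT))
  for (p in polys) {
    hit <- is.na(out) & point_in_polygon(MAT, APP_cm, p$xy)
    out[hit] <- p$id
  }
  miss <- which(is.na(out) & is.finite(MAT) & is.finite(APP_cm))
  if (length(miss)) {
    xs <- MAT[miss] / WHITTAKER_MAT_RANGE
    ys <- APP_cm[miss] / WHITTAKER_APP_RANGE
    dmat <- vapply(polys, function(p) {
      dist_to_polygon(xs, ys, cbind(p$xy[, 1] / WHITTAKER_MAT_RANGE,
                                    p$xy[, 2] / WHITTAKER_APP_RANGE))
    }, numeric(length(miss)))
    dmat <- matrix(dmat, nrow = length(miss))
    out[miss] <- vapply(polys, `[[`, 0L, "id")[max.col(-dmat, "first")]
  }
  attr(out, "outliers") <- length(miss)
  out
}

#' Whittaker classification of a gridded climatology
#'
#' Converts annual precipitation to cm yr^-1 (the unit conversion lives in
#' this module only) and assigns biomes by polygon membership with
#' nearest-biome fallback.
#'
#' @param clim a [monthly_climatology()].
#' @param polys polygon set from [whittaker_polygons()].
#' @return A [class_map()] (scheme `"whittaker"`, 9-class legend) with
#'   auxiliary rasters `AT` (degC) and `APP` (cm yr^-1).
#' @export
classify_map_whittaker <- function(clim, polys = whittaker_polygons()) {
  stopifnot(inherits(clim, "monthly_climatology"))
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  mat <- apply(clim$ts, c(2, 3), mean)
  app_cm <- apply(clim$pr, c(2, 3), sum) / 10
  idx <- which(clim$land_mask)
  cls <- classify_whittaker(mat[idx], app_cm[idx], polys)
  codes <- matrix(NA_integer_, nlat, nlon)
  codes[idx] <- cls
  mask_na <- function(m) { m[!clim$land_mask] <- NA_real_; m }
  class_map(codes, legend = whittaker_legend(polys), scheme = "whittaker",
            lat = clim$lat, lon = clim$lon, land_mask = clim$land_mask,
            scenario = clim$meta$scenario, period = clim$meta$period,
            aux = list(AT = mask_na(mat), APP = mask_na(app_cm)))
}
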