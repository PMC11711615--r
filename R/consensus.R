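#' Per-pixel percent confidence against a reference map
#'
#' For each pixel, the percentage of ensemble members whose climate class
#' matches the reference map:
#' `confidence = 100 * coincident_members / n_members`. Pixels where the
#' reference is masked or unclassifiable are masked (confidence against an
#' undefined truth is meaningless).
#'
#' @param member_maps list of [class_map()] on a shared grid and legend.
#' @param reference a [class_map()] on the same grid/legend (observations
#'   for the present; the top-10 ensemble-mean map for future scenarios).
#' @return Numeric matrix of percentages in `[0, 100]`, `NA` off-reference.
#' @export
confidence_map <- function(member_maps, reference) {
  check_member_maps(member_maps, reference)
  n <- length(member_maps)
  agree <- matrix(0, length(reference$lat), length(reference$lon))
  for (m in member_maps)
    agree <- agree + (!is.na(m$codes) & !is.na(reference$codes) &
                        m$codes == reference$codes)
  out <- 100 * agree / n
  out[is.na(reference$codes)] <- NA_real_
  out
}

#' Five-level confidence categories
#'
#' Discretizes percent confidence into the five standard levels:
#' very high (>= 80), high (60-79), moderate (40-59), low (20-39) and
#' very low (< 20). Bins are lower-inclusive (`[60, 80)` style), matching
#' the printed integer ranges; with 10 members confidence only takes
#' multiples of 10 and the closure choice is immaterial.
#'
#' @param confidence numeric (percent, 0-100); `NA` passes through.
#' @return Integer categories 1 (very high) to 5 (very low), with a
#'   `"labels"` attribute.
#' @export
confidence_category <- function(confidence) {
  if (any(confidence < -1e-9 | confidence > 100 + 1e-9, na.rm = TRUE))
    stop("confidence must be a percentage in [0, 100]")
  cat <- 5L - findInterval(confidence, c(20, 40, 60, 80))
  if (is.matrix(confidence)) cat <- matrix(cat, nrow(confidence))
  attr(cat, "labels") <- c("very high", "high", "moderate", "low", "very low")
  cat
}

#' Inter-model class-agreement counts
#'
#' For each pixel, the number of distinct climate classes identified by the
#' ensemble members. Two or fewer distinct classes indicates low
#' inter-model variability; three or more flags high variability.
#'
#' @param member_maps list of [class_map()] on a shared grid and legend.
#' @return List with `modvar` (integer count matrix, `NA` where no member
#'   classifies) and `high_variability` (logical, `modvar >= 3`).
#' @export
modvar_map <- function(member_maps) {
  check_member_maps(member_maps)
  nlat <- length(member_maps[[1]]$lat); nlon <- length(member_maps[[1]]$lon)
  nleg <- max(member_maps[[1]]$legend$id)
  seen <- array(FALSE, c(nlat, nlon, nleg))
  for (m in member_maps) {
    idx <- which(!is.na(m$codes))
    seen[cbind(arrayInd(idx, c(nlat, nlon)), m$codes[idx])] <- TRUE
  }
  cnt <- apply(seen, c(1, 2), sum)
  cnt[cnt == 0L] <- NA_integer_
  list(modvar = cnt, high_variability = !is.na(cnt) & cnt >= 3L)
}

check_member_maps <- function(member_maps, reference = NULL) {
  if (!length(member_maps)) stop("at least one member map required")
  first <- member_maps[[1]]
  all_maps <- c(member_maps, if (!is.null(reference)) list(reference))
  for (m in all_maps) {
    if (!inherits(m, "class_map")) stop("members must be class_map objects")
    if (!same_grid(m, first)) stop("member maps must share one grid")
    if (!identical(m$legend$id, first$legend$id))
      stop("member maps must share one legend")
  }
  invisible(TRUE)
}

#' Build the paired consensus product
#'
#' Bundles the two complementary uncertainty metrics for an ensemble of
#' class maps: percent confidence against a reference (accuracy -- depends
#' on the reference) and inter-model class-agreement counts (precision --
#' independent of any reference), plus the five-level confidence category
#' and the high-variability mask.
#'
#' @param member_maps list of [class_map()] on a shared grid and legend.
#' @param reference a [class_map()] used as truth.
#' @return Object of class `consensus_product`: `confidence`,
#'   `confidence_category`, `modvar`, `high_variability`, `n_members`,
#'   grid, scheme, and reference provenance in `meta`.
#' @export
build_consensus_product <- function(member_maps, reference) {
  conf <- confidence_map(member_maps, reference)
  mv <- modvar_map(member_maps)
  mv$modvar[is.na(reference$codes)] <- NA_integer_
  mv$high_variability[is.na(reference$codes)] <- NA
  structure(list(
    confidence = conf,
    confidence_category = confidence_category(conf),
    modvar = mv$modvar,
    high_variability = mv$high_variability,
    n_members = length(member_maps),
    scheme = reference$scheme,
    lat = reference$lat, lon = reference$lon,
    land_mask = reference$land_mask & !is.na(reference$codes),
    legend = reference$legend,
    meta = list(scenario = reference$meta$scenario,
                period = reference$meta$period,
                reference = sprintf("%s %s %s", reference$scheme,
                                    reference$meta$scenario,
                                    reference$meta$period))),
    class = "consensus_product")
}

#' @export
print.consensus_product <- function(x, ...) {
  cat(sprintf("<consensus_product> scheme %s, %d members, %d x %d\n",
              x$scheme, x$n_members, length(x$lat), length(x$lon)))
  cat(sprintf("  mean confidence %.1f%%; high-variability area: %.1f%% of pixels\n",
              mean(x$confidence, na.rm = TRUE),
              100 * mean(x$high_variability, na.rm = TRUE)))
  cat(sprintf("  reference: %s\n", x$meta$reference))
  invisible(x)
}
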