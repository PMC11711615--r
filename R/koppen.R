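#' Koeppen legend (11 classes, early-Koeppen scheme)
#'
#' The 11-class rule set after Lohmann et al.: tropical (Af, Aw), dry
#' (BS, BW), mesothermal (Cs, Cw, Cf), microthermal (Dw, Df) and polar
#' (ET, EF) types.
#'
#' @return data.frame with `id` (1-11), `code`, `name`.
#' @export
koppen_legend <- function() {
  data.frame(
    id = 1:11,
    code = c("Af", "Aw", "BS", "BW", "Cs", "Cw", "Cf", "Dw", "Df", "ET", "EF"),
    name = c("Tropical rainforest", "Tropical savanna", "Steppe", "Desert",
             "Warm climate dry summer", "Warm climate dry winter",
             "Humid temperate", "Cold climate dry winter",
             "Cold climate moist winter", "Tundra", "Permafrost"),
    stringsAsFactors = FALSE)
}

#' Koeppen aridity threshold
#'
#' The precipitation threshold separating dry (B) climates, dependent on
#' annual-mean temperature and the seasonal concentration of precipitation:
#' if at least 70% of the annual total falls in winter, `2 * T_avg`; if at
#' least 70% falls in summer, `2 * T_avg + 28`; otherwise `2 * T_avg + 14`.
#'
#' @param T_avg annual-mean temperature (degC).
#' @param winter_frac,summer_frac fractions of annual precipitation in the
#'   winter and summer half-years.
#' @return Threshold in mm yr^-1 (can be negative for very cold climates,
#'   in which case the B test never fires since precipitation is
#'   non-negative).
#' @export
koppen_p_threshold <- function(T_avg, winter_frac, summer_frac) {
  ifelse(winter_frac >= 0.7, 2 * T_avg,
         ifelse(summer_frac >= 0.7, 2 * T_avg + 28, 2 * T_avg + 14))
}

#' Koeppen classification rule cascade
#'
#' Applies the 11-class rules in the prescribed order: the aridity
#' threshold is evaluated first (B climates), then thermal types A, C, D
#' and E in sequence. Evaluating B first is what keeps arid-climate
#' identification consistent when observations are in play.
#'
#' Rules (boundaries inclusive exactly as printed in the defining table):
#' B when `P_annual <= P_threshold` (BS if `P_annual >= P_threshold/2`,
#' else BW); A when `T_min >= 18` (Af if `P_min >= 60`, else Aw); C when
#' `-3 <= T_min < 18` (Cs if `P_wmax >= 3 P_smin`, else Cw if
#' `P_smax >= 10 P_wmin`, else Cf); D when `T_min < -3` and `T_max > 10`
#' (Dw if `P_smax >= 10 P_wmin`, else Df); E when `T_max <= 10` (ET if
#' `T_max >= 0`, else EF). The E test is extended from `< 10` to `<= 10`
#' to close the boundary the D rule (`> 10`) leaves open.
#'
#' @param inputs list or data.frame with numeric elements `T_min`, `T_max`,
#'   `T_avg`, `P_annual`, `P_min`, `P_smin`, `P_smax`, `P_wmin`, `P_wmax`,
#'   `winter_frac`, `summer_frac` (equal lengths).
#' @return Integer vector of class ids (1-11, see [koppen_legend()]).
#'   `NA` marks unclassifiable inputs (non-finite); the count is reported
#'   in the `"unclassified"` attribute rather than silently defaulted.
#' @export
classify_koppen <- function(inputs) {
  need <- c("T_min", "T_max", "T_avg", "P_annual", "P_min",
            "P_smin", "P_smax", "P_wmin", "P_wmax",
            "winter_frac", "summer_frac")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing inputs: ", paste(miss, collapse = ", "))
  e <- lapply(inputs[need], as.numeric)
  n <- length(e$T_min)
  pt <- koppen_p_threshold(e$T_avg, e$winter_frac, e$summer_frac)
  out <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  assign_cls <- function(cond, id) {
    sel <- !done & !is.na(cond) & cond
    out[sel] <<- id
    done[sel] <<- TRUE
  }
  # B first
  isB <- e$P_annual <= pt
  assign_cls(isB & e$P_annual >= pt / 2, 3L)  # BS
  assign_cls(isB, 4L)                         # BW
  # A
  isA <- e$T_min >= 18
  assign_cls(isA & e$P_min >= 60, 1L)         # Af
  assign_cls(isA, 2L)                         # Aw
  # C
  isC <- e$T_min >= -3 & e$T_min < 18
  assign_cls(isC & e$P_wmax >= 3 * e$P_smin, 5L)   # Cs
  assign_cls(isC & e$P_smax >= 10 * e$P_wmin, 6L)  # Cw
  assign_cls(isC, 7L)                              # Cf
  # D
  isD <- e$T_min < -3 & e$T_max > 10
  assign_cls(isD & e$P_smax >= 10 * e$P_wmin, 8L)  # Dw
  assign_cls(isD, 9L)                              # Df
  # E (boundary T_max == 10 folded into ET/EF)
  isE <- e$T_max <= 10
  assign_cls(isE & e$T_max >= 0, 10L)              # ET
  assign_cls(isE, 11L)                             # EF
  attr(out, "unclassified") <- sum(!done & !is.na(e$T_min))
  out
}

#' Koeppen classification of a gridded climatology
#'
#' @param clim a [monthly_climatology()].
#' @return A [class_map()] (scheme `"koppen"`, 11-class legend). Per the
#'   distribution convention, no auxiliary climate rasters accompany the
#'   Koeppen class layer.
#' @export
classify_map_koppen <- function(clim) {
  stopifnot(inherits(clim, "monthly_climatology"))
  d <- derive_climatology(clim)
  idx <- which(clim$land_mask)
  fields <- c("T_min", "T_max", "T_avg", "P_annual", "P_min",
              "P_smin", "P_smax", "P_wmin", "P_wmax",
              "winter_frac", "summer_frac")
  inp <- lapply(d[fields], function(m) m[idx])
  cls <- classify_koppen(inp)
  codes <- matrix(NA_integer_, length(clim$lat), length(clim$lon))
  codes[idx] <- cls
  class_map(codes, legend = koppen_legend(), scheme = "koppen",
            lat = clim$lat, lon = clim$lon, land_mask = clim$land_mask,
            scenario = clim$meta$scenario, period = clim$meta$period)
}
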