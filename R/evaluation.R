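#' Area-weighted Cohen's kappa between two class maps
#'
#' Chance-corrected categorical agreement
#' `kappa = (P0 - Pe) / (1 - Pe)`, where `P0` is the area-weighted
#' proportion of cells on which the maps agree and `Pe` the chance
#' agreement implied by the two maps' area-weighted class frequencies.
#' Grid boxes are weighted by area; masked cells carry zero weight.
#'
#' @param map_a,map_b [class_map()] objects on identical grids with
#'   identical legends, or plain integer matrices/vectors of class codes.
#' @param w area weights from [area_weights()] (normalized over the
#'   compared domain). Required when maps are plain codes.
#' @return kappa (1 = perfect agreement). Degenerate cases: two identical
#'   constant maps give 1; two constant maps with different classes have
#'   `P0 = Pe = 0` and give 0.
#' @export
cohen_kappa <- function(map_a, map_b, w = NULL) {
  if (inherits(map_a, "class_map")) {
    if (!inherits(map_b, "class_map") || !same_grid(map_a, map_b))
      stop("maps must share an identical grid")
    if (!identical(map_a$legend$id, map_b$legend$id))
      stop("maps must share an identical legend")
    if (is.null(w)) w <- area_weights(map_a)
    a <- map_a$codes; b <- map_b$codes
  } else {
    a <- map_a; b <- map_b
    if (is.null(w)) stop("weights required for plain code inputs")
  }
  ok <- !is.na(a) & !is.na(b) & w > 0
  if (!any(ok)) stop("no jointly classified cells to compare")
  a <- a[ok]; b <- b[ok]; w <- w[ok] / sum(w[ok])
  p0 <- sum(w[a == b])
  cls <- union(a, b)
  fa <- vapply(cls, function(c) sum(w[a == c]), 0)
  fb <- vapply(cls, function(c) sum(w[b == c]), 0)
  pe <- sum(fa * fb)
  if (pe >= 1 - 1e-12) {
    if (p0 >= 1 - 1e-12) return(1)
    warning("both maps constant with different classes; kappa undefined, returning 0")
    return(0)
  }
  (p0 - pe) / (1 - pe)
}

#' Area-weighted coefficient of determination
#'
#' Skill of a model field against a reference field. The default is the
#' skill-score form `R2 = 1 - sum w (m - o)^2 / sum w (o - o_bar)^2`
#' (`o_bar` the area-weighted reference mean), which penalizes bias; the
#' squared area-weighted Pearson correlation is available via
#' `method = "corr"`.
#'
#' @param model_field,ref_field numeric matrices on the same grid.
#' @param w area weights (masked cells zero).
#' @param method `"nse"` (default, skill-score form) or `"corr"`.
#' @return R-squared (at most 1 for `"nse"`).
#' @export
weighted_r2 <- function(model_field, ref_field, w,
                        method = c("nse", "corr")) {
  method <- match.arg(method)
  ok <- is.finite(model_field) & is.finite(ref_field) & w > 0
  m <- model_field[ok]; o <- ref_field[ok]; ww <- w[ok] / sum(w[ok])
  obar <- sum(ww * o)
  ss_tot <- sum(ww * (o - obar)^2)
  if (ss_tot <= 0) stop("zero reference variance; R2 undefined")
  if (method == "nse") {
    1 - sum(ww * (m - o)^2) / ss_tot
  } else {
    mbar <- sum(ww * m)
    sum(ww * (m - mbar) * (o - obar))^2 /
      (sum(ww * (m - mbar)^2) * ss_tot)
  }
}

#' Score an ensemble of climatologies against a reference
#'
#' Builds the per-model scorecard used for ranking: area-weighted kappa of
#' the model's class map against the reference class map (for a chosen
#' scheme), plus area-weighted R2 of annual-total precipitation
#' (mm yr^-1) and annual-mean temperature (degC).
#'
#' @param members named list of [monthly_climatology()] objects.
#' @param reference a [monthly_climatology()] on the same grid.
#' @param scheme classification scheme for the kappa score.
#' @param r2_method passed to [weighted_r2()].
#' @param ref_map,member_maps optional precomputed [class_map()] objects
#'   (the reference's and one per member) to avoid re-classifying.
#' @return data.frame (one row per model) with `model`, `kappa`, `r2_pr`,
#'   `r2_ts`, `in_quadrant`, `rank` (by kappa, 1 = best), `selected`.
#' @export
rank_models <- function(members, reference,
                        scheme = c("whittaker", "holdridge", "koppen",
                                   "thornthwaite"),
                        r2_method = "nse",
                        ref_map = NULL, member_maps = NULL) {
  scheme <- match.arg(scheme)
  if (!length(members)) stop("empty model cohort")
  if (is.null(names(members)) || any(names(members) == ""))
    names(members) <- sprintf("model_%02d", seq_along(members))
  w <- area_weights(reference)
  if (is.null(ref_map)) ref_map <- classify_climatology(reference, scheme)
  ref_pr <- apply(reference$pr, c(2, 3), sum)
  ref_ts <- apply(reference$ts, c(2, 3), mean)
  rows <- lapply(names(members), function(nm) {
    mem <- members[[nm]]
    if (!same_grid(mem, reference)) stop("member grids must match the reference")
    mmap <- member_maps[[nm]] %||% classify_climatology(mem, scheme)
    data.frame(
      model = nm,
      kappa = cohen_kappa(mmap, ref_map, w),
      r2_pr = weighted_r2(apply(mem$pr, c(2, 3), sum), ref_pr, w,
                          method = r2_method),
      r2_ts = weighted_r2(apply(mem$ts, c(2, 3), mean), ref_ts, w,
                          method = r2_method),
      stringsAsFactors = FALSE)
  })
  cards <- do.call(rbind, rows)
  cards$in_quadrant <- cards$kappa >= stats::median(cards$kappa) &
    cards$r2_pr >= stats::median(cards$r2_pr)
  cards$rank <- rank(-cards$kappa, ties.method = "first")
  cards$selected <- cards$model %in% select_top10(cards)
  cards
}

#' Median-quadrant top-10 selection
#'
#' Implements the two-stage screen used to form the top-10 ensemble: keep
#' models in the upper-right quadrant of the (kappa, precipitation-R2)
#' plane -- both metrics at or above the cohort medians (inclusive, so
#' borderline models stay) -- then take the `n` highest-kappa members of
#' that quadrant. If the quadrant holds fewer than `n`, all of it is
#' returned with a warning.
#'
#' @param cards scorecard data.frame with `model`, `kappa`, `r2_pr`.
#' @param n ensemble size (default 10).
#' @return Character vector of selected model names, ordered by decreasing
#'   kappa (ties by cohort order).
#' @export
select_top10 <- function(cards, n = 10L) {
  if (!nrow(cards)) stop("empty model cohort")
  quad <- cards$kappa >= stats::median(cards$kappa) &
    cards$r2_pr >= stats::median(cards$r2_pr)
  qc <- cards[quad, , drop = FALSE]
  if (nrow(qc) < n)
    warning(sprintf("median quadrant holds only %d models (< %d); returning all",
                    nrow(qc), n))
  qc <- qc[order(-qc$kappa), , drop = FALSE]
  utils::head(qc$model, n)
}

#' Ensemble-mean climatology
#'
#' Per-pixel, per-month unweighted mean of temperature and precipitation
#' across members. Classification happens downstream on the averaged
#' climatology (the consensus products, not this mean, are where per-member
#' class votes enter).
#'
#' @param members list of [monthly_climatology()] on identical grids.
#' @param scenario,period labels for the result (default: first member's).
#' @return A [monthly_climatology()]; the land mask is the intersection of
#'   member masks.
#' @export
ensemble_mean <- function(members, scenario = NULL, period = NULL) {
  if (!length(members)) stop("empty member list")
  ref <- members[[1]]
  ts <- ref$ts * 0; pr <- ref$pr * 0; mask <- ref$land_mask
  for (m in members) {
    if (!same_grid(m, ref) || !identical(dim(m$ts), dim(ref$ts)))
      stop("mixed grids in ensemble")
    ts <- ts + m$ts; pr <- pr + m$pr; mask <- mask & m$land_mask
  }
  monthly_climatology(ts / length(members), pr / length(members),
                      ref$lat, ref$lon, mask,
                      scenario = scenario %||% ref$meta$scenario,
                      period = period %||% ref$meta$period)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent of land area per climate class
#'
#' Area-weighted percentage of the classified domain covered by each legend
#' class; classes absent from the map report 0 and the percentages sum
#' to 100.
#'
#' @param map a [class_map()].
#' @param w area weights (default computed from the map's grid/mask).
#' @return Named numeric vector (legend codes), percentages.
#' @export
class_area_fractions <- function(map, w = area_weights(map)) {
  ok <- !is.na(map$codes) & w > 0
  ww <- w[ok] / sum(w[ok])
  cl <- map$codes[ok]
  out <- vapply(map$legend$id, function(id) 100 * sum(ww[cl == id]), 0)
  names(out) <- map$legend$code
  out
}
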