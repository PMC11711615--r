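# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# small uniform climatology: every month the same ts/pr at every cell
uniform_clim <- function(ts_val = 20, pr_val = 100,
                         lat = c(30.5, 29.5, -29.5, -30.5),
                         lon = c(-0.5, 0.5, 1.5),
                         mask = NULL) {
  nlat <- length(lat); nlon <- length(lon)
  ts <- array(ts_val, c(12, nlat, nlon))
  pr <- array(pr_val, c(12, nlat, nlon))
  monthly_climatology(ts, pr, lat, lon, mask)
}

# climatology with per-month vectors applied at every cell
monthly_series_clim <- function(ts_series, pr_series,
                                lat = c(45.5, -45.5), lon = c(0.5, 1.5)) {
  nlat <- length(lat); nlon <- length(lon)
  ts <- array(rep(ts_series, nlat * nlon), c(12, nlat, nlon))
  pr <- array(rep(pr_series, nlat * nlon), c(12, nlat, nlon))
  monthly_climatology(ts, pr, lat, lon)
}

# small class_map on a near-equatorial grid (weights effectively equal)
toy_map <- function(codes, nclass = max(codes, na.rm = TRUE),
                    lat = NULL, lon = NULL, varname = "class") {
  codes <- as.matrix(codes)
  if (is.null(lat)) lat <- seq(0.5, by = -1e-7, length.out = nrow(codes))
  if (is.null(lon)) lon <- seq(0.5, by = 1, length.out = ncol(codes))
  legend <- data.frame(id = seq_len(nclass),
                       code = paste0("C", seq_len(nclass)),
                       name = paste0("Class ", seq_len(nclass)))
  class_map(codes, legend, scheme = "toy", lat = lat, lon = lon,
            land_mask = !is.na(codes), varname = varname)
}

# fast synthetic config for pipeline-level tests
test_cfg <- function(seed = 11, n_members = 6, res = 8, ...) {
  synthetic_config(seed = seed, n_members = n_members, res = res, ...)
}

# straight-line scalar rule-by-rule Koeppen oracle (independent of the
# vectorized cascade in the package)
koppen_oracle <- function(T_min, T_max, T_avg, P_annual, P_min,
                          P_smin, P_smax, P_wmin, P_wmax,
                          winter_frac, summer_frac) {
  pt <- if (winter_frac >= 0.7) 2 * T_avg
  else if (summer_frac >= 0.7) 2 * T_avg + 28 else 2 * T_avg + 14
  if (P_annual <= pt) {
    if (P_annual >= pt / 2) return("BS") else return("BW")
  }
  if (T_min >= 18) {
    if (P_min >= 60) return("Af") else return("Aw")
  }
  if (T_min >= -3 && T_min < 18) {
    if (P_wmax >= 3 * P_smin) return("Cs")
    if (P_smax >= 10 * P_wmin) return("Cw")
    return("Cf")
  }
  if (T_min < -3 && T_max > 10) {
    if (P_smax >= 10 * P_wmin) return("Dw") else return("Df")
  }
  if (T_max <= 10) {
    if (T_max >= 0) return("ET") else return("EF")
  }
  NA_character_
}

# explicit-loop Holdridge oracle in the same log2 metric
holdridge_oracle <- function(ABT, APP, PER, centroids) {
  eps <- 2^-6
  tr <- function(app, abt, per)
    c(log2(max(app, 1)), log2(max(abt, eps)), log2(max(per, eps)))
  p <- tr(APP, ABT, if (is.nan(PER)) 0 else PER)
  best <- 1L; bestd <- Inf
  for (i in seq_len(nrow(centroids))) {
    q <- tr(centroids$APP[i], centroids$ABT[i], centroids$PER[i])
    d <- sum((p - q)^2)
    if (d < bestd - 1e-15) { bestd <- d; best <- i }
  }
  best
}

# random Koeppen-style rule inputs with internally consistent seasonal
# precipitation statistics
random_koppen_inputs <- function(n, seed = 1) {
  set.seed(seed)
  mk <- function() {
    pr <- stats::rexp(12, rate = 1 / stats::runif(1, 2, 200))
    ts <- stats::runif(12, -45, 35)
    sm <- 4:9; wm <- c(10:12, 1:3)
    list(T_min = min(ts), T_max = max(ts), T_avg = mean(ts),
         P_annual = sum(pr), P_min = min(pr),
         P_smin = min(pr[sm]), P_smax = max(pr[sm]),
         P_wmin = min(pr[wm]), P_wmax = max(pr[wm]),
         winter_frac = sum(pr[wm]) / sum(pr),
         summer_frac = sum(pr[sm]) / sum(pr))
  }
  recs <- replicate(n, mk(), simplify = FALSE)
  out <- lapply(stats::setNames(names(recs[[1]]), names(recs[[1]])),
                function(f) vapply(recs, `[[`, 0, f))
  out
}

# scalar reference implementation of the classic Thornthwaite monthly PET
# (independent straight-line code path, used as the oracle)
thornthwaite_oracle <- function(ts, lat) {
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mid <- cumsum(c(0, days[-12])) + days / 2
  I <- sum(sapply(ts, function(t) if (t > 0) (t / 5)^1.514 else 0))
  if (I == 0) return(rep(0, 12))
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  sapply(1:12, function(m) {
    t <- ts[m]
    e <- if (t <= 0) 0
    else if (t > 26.5) -415.85 + 32.24 * t - 0.43 * t^2
    else 16 * (10 * t / I)^a
    delta <- 0.409 * sin(2 * pi * mid[m] / 365 - 1.39)
    x <- max(min(-tan(lat * pi / 180) * tan(delta), 1), -1)
    L <- 24 / pi * acos(x)
    max(e * (L / 12) * (days[m] / 30), 0)
  })
}
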