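#' Synthetic-ensemble configuration
#'
#' Parameters of the synthetic climate generator. Defaults emulate the
#' study conditions the pipeline is built for: a 52-member model cohort on
#' the 1-degree grid, with precipitation errors much larger (in relative
#' terms) than temperature errors -- relative precipitation errors beyond
#' 100% do occur under the lognormal default, as they do for real models.
#'
#' @param seed integer seed; every random draw in a run derives from it.
#' @param n_members ensemble size (study cohort: 52).
#' @param res grid spacing in degrees (1 for production; coarser, e.g. 4,
#'   for fast tests).
#' @param temp_bias_sd s.d. (degC) of each member's smooth, spatially
#'   correlated temperature bias field.
#' @param precip_bias_rel_sd s.d. of the log of each member's multiplicative
#'   precipitation bias field (0.35 means typical biases around +-35%, with
#'   a heavy upper tail).
#' @param pixel_noise_sd_t s.d. (degC) of white per-pixel temperature noise.
#' @param pixel_noise_rel_sd_p s.d. of log-multiplicative per-pixel
#'   precipitation noise.
#' @param skill_spread range (min, max) of per-member bias multipliers; a
#'   spread above/below 1 makes the cohort span a skill range so ranking
#'   has something to rank.
#' @param warming_delta global-mean warming (degC) applied by
#'   [apply_scenario()].
#' @param precip_scaling fractional precipitation increase per degC of
#'   warming.
#' @param land_fraction target fraction of the globe covered by synthetic
#'   continents (before Antarctica masking).
#' @param scenario,period labels attached to generated climatologies.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_members = 52L, res = 1,
                             temp_bias_sd = 1.5, precip_bias_rel_sd = 0.35,
                             pixel_noise_sd_t = 0.75,
                             pixel_noise_rel_sd_p = 0.15,
                             skill_spread = c(0.4, 1.8),
                             warming_delta = 0, precip_scaling = 0.02,
                             land_fraction = 0.35,
                             scenario = "historical", period = "1980-2014") {
  stopifnot(n_members >= 1L, res > 0, temp_bias_sd >= 0,
            precip_bias_rel_sd >= 0, pixel_noise_sd_t >= 0,
            pixel_noise_rel_sd_p >= 0, warming_delta >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# smooth random field: iid normal on a coarse grid (~scale_deg spacing),
# bilinearly upsampled to the target grid; longitude periodic
smooth_random_field <- function(lat, lon, sd = 1, scale_deg = 20) {
  nc_lat <- max(3L, ceiling(180 / scale_deg) + 1L)
  nc_lon <- max(4L, ceiling(360 / scale_deg))
  clat <- seq(90, -90, length.out = nc_lat)
  clon <- seq(-180, 180 - 360 / nc_lon, length.out = nc_lon)
  coarse <- matrix(stats::rnorm(nc_lat * nc_lon, sd = sd), nc_lat, nc_lon)
  regrid_bilinear(coarse, clat, clon, lat, lon)
}

#' Generate the synthetic reference climatology
#'
#' Builds a deterministic (given the seed) reference climate with the
#' large-scale structure the classifiers feed on: an equator-to-pole
#' annual-mean temperature profile with a seasonal cycle whose amplitude
#' grows poleward and whose phase flips across the equator; precipitation
#' with a tropical maximum, subtropical dry belts and mid-latitude storm
#' tracks, modulated by multiplicative lognormal texture (high spatial
#' variability, deserts included); and a smooth pseudo-continental land
#' mask with Antarctica (latitudes south of -60) excluded.
#'
#' @param cfg a [synthetic_config()].
#' @return A [monthly_climatology()].
#' @export
make_reference <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  lat <- seq(90 - cfg$res / 2, -90 + cfg$res / 2, by = -cfg$res)
  lon <- seq(-180 + cfg$res / 2, 180 - cfg$res / 2, by = cfg$res)
  nlat <- length(lat); nlon <- length(lon)
  sin2 <- sin(lat * pi / 180)^2

  # annual-mean temperature: ~27 degC at the equator, ~-25 at the poles,
  # plus smooth "continentality" texture
  t_ann <- matrix(27 - 52 * sin2, nlat, nlon) +
    smooth_random_field(lat, lon, sd = 3, scale_deg = 25)
  amp <- matrix(2 + 18 * sin2, nlat, nlon) *
    (1 + 0.25 * smooth_random_field(lat, lon, sd = 1, scale_deg = 30))
  hemi <- matrix(ifelse(lat >= 0, 1, -1), nlat, nlon)

  # annual precipitation: ITCZ peak and mid-latitude storm tracks, carved
  # by subtropical dry belts and multiplicative lognormal texture (the
  # texture is what produces hyper-arid deserts and very wet coasts)
  abs_lat <- abs(lat)
  p_ann_prof <- 60 + 1900 * exp(-(lat / 12)^2) +
    700 * exp(-((abs_lat - 47) / 13)^2)
  dry_belt <- 1 - 0.85 * exp(-((abs_lat - 25) / 9)^2)
  texture <- exp(smooth_random_field(lat, lon, sd = 0.9, scale_deg = 22) +
                   0.3 * smooth_random_field(lat, lon, sd = 1, scale_deg = 60))
  p_ann <- matrix(p_ann_prof * dry_belt, nlat, nlon) * texture

  # monthly split: seasonality amplitude strongest in the tropics, with a
  # regionally varying phase -- most regions are wet-summer (monsoonal),
  # patches are wet-winter (mediterranean-like)
  seas <- matrix(0.7 * exp(-(abs_lat / 25)^2) + 0.25, nlat, nlon) *
    (1 + 0.3 * smooth_random_field(lat, lon, sd = 1, scale_deg = 30))
  seas <- pmin(pmax(seas, 0), 0.95)
  regime <- ifelse(smooth_random_field(lat, lon, sd = 1, scale_deg = 40) >
                     -0.55, 1, -1)   # 1 wet-summer, -1 wet-winter
  ts <- array(0, c(12L, nlat, nlon))
  pr <- array(0, c(12L, nlat, nlon))
  for (m in 1:12) {
    phase <- cos(2 * pi * (m - 7) / 12)   # +1 in July, -1 in January
    ts[m, , ] <- t_ann + hemi * amp * phase
    wgt <- (1 + seas * regime * hemi * phase) / 12
    pr[m, , ] <- p_ann * wgt
  }
  pr[pr < 0] <- 0

  # pseudo-continents: smooth field thresholded at the target land fraction
  gm <- smooth_random_field(lat, lon, sd = 1, scale_deg = 35) +
    0.5 * smooth_random_field(lat, lon, sd = 1, scale_deg = 70)
  mask <- gm >= stats::quantile(gm, 1 - cfg$land_fraction)
  mask[lat < -60, ] <- FALSE  # Antarctica excluded from the analysis domain
  monthly_climatology(ts, pr, lat, lon, mask,
                      scenario = cfg$scenario, period = cfg$period)
}

#' Generate a perturbed model ensemble
#'
#' Each member is the reference plus a smooth, spatially correlated bias
#' field plus white pixel noise: temperature perturbed additively,
#' precipitation multiplicatively (lognormal, so fields stay non-negative
#' and relative errors can be large). A per-member bias multiplier drawn
#' from `cfg$skill_spread` makes the cohort span a range of skill, which
#' the top-10 selection needs.
#'
#' @param ref reference [monthly_climatology()] from [make_reference()].
#' @param cfg a [synthetic_config()]; `cfg$n_members` members are drawn,
#'   each from an independent stream derived from `cfg$seed`.
#' @return Named list (`model_01`, ...) of [monthly_climatology()].
#' @export
make_ensemble <- function(ref, cfg = synthetic_config()) {
  stopifnot(inherits(ref, "monthly_climatology"),
            inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_members)
  skills <- stats::runif(cfg$n_members, cfg$skill_spread[1], cfg$skill_spread[2])
  nlat <- length(ref$lat); nlon <- length(ref$lon)
  members <- vector("list", cfg$n_members)
  for (k in seq_len(cfg$n_members)) {
    set.seed(member_seeds[k])
    s <- skills[k]
    t_bias <- smooth_random_field(ref$lat, ref$lon,
                                  sd = cfg$temp_bias_sd * s, scale_deg = 25)
    p_bias <- smooth_random_field(ref$lat, ref$lon,
                                  sd = cfg$precip_bias_rel_sd * s, scale_deg = 25)
    ts <- ref$ts; pr <- ref$pr
    for (m in 1:12) {
      ts[m, , ] <- ts[m, , ] + t_bias +
        stats::rnorm(nlat * nlon, sd = cfg$pixel_noise_sd_t)
      pr[m, , ] <- pr[m, , ] * exp(p_bias +
        stats::rnorm(nlat * nlon, sd = cfg$pixel_noise_rel_sd_p))
    }
    members[[k]] <- monthly_climatology(ts, pr, ref$lat, ref$lon,
                                        ref$land_mask,
                                        scenario = ref$meta$scenario,
                                        period = ref$meta$period)
  }
  names(members) <- sprintf("model_%02d", seq_len(cfg$n_members))
  members
}

#' Apply an idealized warming scenario
#'
#' Emulates a scenario-labelled future climatology: temperature shifted by
#' `warming_delta` amplified poleward (polar amplification factor up to
#' 1.8x at the poles); precipitation scaled up by
#' `precip_scaling * warming_delta` globally with an additional drying
#' factor in the subtropical belts. `warming_delta = 0` is the identity.
#'
#' @param ref a [monthly_climatology()].
#' @param cfg a [synthetic_config()] supplying `warming_delta`,
#'   `precip_scaling`, and the `scenario`/`period` labels of the result.
#' @return A [monthly_climatology()].
#' @export
apply_scenario <- function(ref, cfg) {
  stopifnot(inherits(ref, "monthly_climatology"), cfg$warming_delta >= 0)
  lat <- ref$lat
  nlat <- length(lat); nlon <- length(ref$lon)
  dT <- matrix(cfg$warming_delta * (1 + 0.8 * sin(lat * pi / 180)^2),
               nlat, nlon)
  dry <- matrix(1 - pmin(0.04 * cfg$warming_delta, 0.4) *
                  exp(-((abs(lat) - 25) / 8)^2), nlat, nlon)
  wet <- 1 + cfg$precip_scaling * cfg$warming_delta
  ts <- ref$ts; pr <- ref$pr
  for (m in 1:12) {
    ts[m, , ] <- ts[m, , ] + dT
    pr[m, , ] <- pmax(pr[m, , ] * wet * dry, 0)
  }
  monthly_climatology(ts, pr, ref$lat, ref$lon, ref$land_mask,
                      scenario = cfg$scenario, period = cfg$period)
}

# save/restore the global RNG state so generator calls do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
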