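test_that("generation is deterministic in the seed and leaves global RNG state alone", {
  cfg <- test_cfg(seed = 17, n_members = 3)
  r1 <- make_reference(cfg)
  set.seed(999); before <- .Random.seed
  r2 <- make_reference(cfg)
  expect_identical(before, .Random.seed)   # generator restored the RNG state
  expect_identical(r1$ts, r2$ts)
  expect_identical(r1$pr, r2$pr)
  expect_identical(r1$land_mask, r2$land_mask)
  e1 <- make_ensemble(r1, cfg)
  e2 <- make_ensemble(r2, cfg)
  expect_identical(e1, e2)
  r3 <- make_reference(test_cfg(seed = 18, n_members = 3))
  expect_false(identical(r1$ts, r3$ts))
})

test_that("the reference climate has Earth-like zonal structure", {
  ref <- make_reference(test_cfg(seed = 2))
  t_ann <- apply(ref$ts, c(2, 3), mean)
  zonal_t <- rowMeans(t_ann)
  eq <- which.min(abs(ref$lat))
  np <- which.max(ref$lat)
  expect_gt(zonal_t[eq], 20)              # warm tropics
  expect_lt(zonal_t[np], 0)               # frozen high Arctic
  expect_gt(zonal_t[eq], zonal_t[np] + 25)
  # seasonal range grows poleward within the NH
  t_range <- apply(ref$ts, c(2, 3), function(v) diff(range(v)))
  nh <- ref$lat > 0
  expect_gt(stats::cor(ref$lat[nh], rowMeans(t_range)[nh, drop = FALSE]), 0.9)
  # precipitation peaks near the equator, with drier subtropics
  p_ann <- apply(ref$pr, c(2, 3), sum)
  zonal_p <- rowMeans(p_ann)
  subtrop <- which.min(abs(ref$lat - 25))
  expect_gt(zonal_p[eq], zonal_p[subtrop])
})

test_that("seasons flip phase across the equator", {
  ref <- make_reference(test_cfg(seed = 3))
  i45n <- which.min(abs(ref$lat - 45))
  i45s <- which.min(abs(ref$lat + 45))
  jul_minus_jan_n <- mean(ref$ts[7, i45n, ] - ref$ts[1, i45n, ])
  jul_minus_jan_s <- mean(ref$ts[7, i45s, ] - ref$ts[1, i45s, ])
  expect_gt(jul_minus_jan_n, 5)
  expect_lt(jul_minus_jan_s, -5)
})

test_that("the land mask honors the requested fraction and excludes the polar cap", {
  cfg <- test_cfg(seed = 4)
  ref <- make_reference(cfg)
  south_cap <- ref$lat < -60
  expect_false(any(ref$land_mask[south_cap, ]))
  # the threshold quantile targets the fraction of the full grid; removing
  # the polar cap afterwards can only shrink it
  frac <- mean(ref$land_mask)
  expect_lte(frac, cfg$land_fraction + 0.01)
  expect_gte(frac, 0.2)
})

test_that("a noise-free ensemble reproduces the reference exactly", {
  cfg <- test_cfg(seed = 5, n_members = 2,
                  temp_bias_sd = 0, precip_bias_rel_sd = 0,
                  pixel_noise_sd_t = 0, pixel_noise_rel_sd_p = 0)
  ref <- make_reference(cfg)
  ens <- make_ensemble(ref, cfg)
  expect_equal(ens$model_01$ts, ref$ts)
  expect_equal(ens$model_01$pr, ref$pr, tolerance = 1e-12)
  m <- classify_climatology(ref, "koppen")
  expect_equal(cohen_kappa(classify_climatology(ens$model_02, "koppen"), m), 1)
})

test_that("ranking skill degrades monotonically with injected error amplitude", {
  kappas <- vapply(c(0.25, 1, 4), function(mult) {
    cfg <- test_cfg(seed = 6, n_members = 5,
                    temp_bias_sd = 1.5 * mult,
                    precip_bias_rel_sd = 0.35 * mult,
                    pixel_noise_sd_t = 0.75 * mult,
                    pixel_noise_rel_sd_p = 0.15 * mult)
    ref <- make_reference(cfg)
    cards <- suppressWarnings(rank_models(make_ensemble(ref, cfg), ref,
                                          scheme = "koppen"))
    mean(cards$kappa)
  }, 0)
  expect_true(all(diff(kappas) < 0))
  expect_gt(kappas[1], 0.8)
})

test_that("the ensemble mean converges to the reference temperature", {
  cfg <- test_cfg(seed = 7, n_members = 200)
  ref <- make_reference(cfg)
  ens <- make_ensemble(ref, cfg)
  em <- ensemble_mean(ens)
  w <- area_weights(ref)
  t_ref <- apply(ref$ts, c(2, 3), mean)
  t_em <- apply(em$ts, c(2, 3), mean)
  rmse <- sqrt(sum(w * (t_em - t_ref)^2))
  # biases are zero-mean across members, so the mean error shrinks ~1/sqrt(n)
  expect_lt(rmse, 0.4)
})

test_that("scenario forcing warms everywhere with polar amplification", {
  cfg0 <- test_cfg(seed = 8, warming_delta = 0)
  ref <- make_reference(cfg0)
  expect_identical(apply_scenario(ref, cfg0)$ts, ref$ts)
  cfg4 <- test_cfg(seed = 8, warming_delta = 4, scenario = "ssp585",
                   period = "2070-2099")
  fut <- apply_scenario(ref, cfg4)
  dts <- fut$ts - ref$ts
  expect_true(all(dts >= 4 - 1e-9))
  eq <- which.min(abs(ref$lat))
  np <- which.max(ref$lat)
  expect_gt(mean(dts[, np, ]), mean(dts[, eq, ]))
  expect_equal(fut$meta$scenario, "ssp585")
  expect_true(all(fut$pr >= 0))
})

test_that("at study resolution the generator exercises most of every legend", {
  ref <- make_reference(synthetic_config(seed = 1))
  maps <- classify_climatology(ref, "all")
  n_classes <- vapply(maps, function(m)
    length(unique(m$codes[!is.na(m$codes)])), 0L)
  expect_gte(n_classes[["koppen"]], 8L)
  expect_gte(n_classes[["holdridge"]], 9L)
  expect_gte(n_classes[["thornthwaite"]], 20L)
  expect_gte(n_classes[["whittaker"]], 7L)
})
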