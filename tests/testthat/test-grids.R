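test_that("derived statistics of a uniform climatology equal the uniform value", {
  clim <- uniform_clim(ts_val = 20, pr_val = 100)
  d <- derive_climatology(clim)
  expect_equal(unique(as.vector(d$P_annual)), 1200)
  expect_equal(unique(as.vector(d$T_min)), 20)
  expect_equal(unique(as.vector(d$T_max)), 20)
  expect_equal(unique(as.vector(d$T_avg)), 20)
  expect_equal(unique(as.vector(d$P_min)), 100)
  for (f in c("P_smin", "P_smax", "P_wmin", "P_wmax"))
    expect_equal(unique(as.vector(d[[f]])), 100, info = f)
  expect_equal(unique(as.vector(d$summer_frac)), 0.5)
})

test_that("half-year fractions follow the stated month sets", {
  pr <- rep(10, 12); pr[4:9] <- 90                 # Apr-Sep wet
  clim <- monthly_series_clim(rep(15, 12), pr, lat = c(45.5, -45.5))
  d <- derive_climatology(clim)
  nh <- 1; sh <- 2
  expect_equal(d$summer_frac[nh, 1], 540 / 600)    # NH summer = Apr-Sep
  expect_equal(d$winter_frac[nh, 1], 60 / 600)
  expect_equal(d$summer_frac[sh, 1], 60 / 600)     # SH summer = Oct-Mar
  expect_equal(d$winter_frac[sh, 1], 540 / 600)
})

test_that("an SH pixel with an NH pixel's series swaps summer and winter stats", {
  set.seed(3)
  pr <- stats::runif(12, 5, 120)
  clim <- monthly_series_clim(rep(10, 12), pr, lat = c(30.5, -30.5))
  d <- derive_climatology(clim)
  expect_equal(d$P_smax[2, 1], d$P_wmax[1, 1])
  expect_equal(d$P_smin[2, 1], d$P_wmin[1, 1])
  expect_equal(d$summer_frac[2, 1], d$winter_frac[1, 1])
})

test_that("flipping latitude and rolling months by six swaps the half-years", {
  set.seed(9)
  nlat <- 4; nlon <- 3
  lat <- c(40.5, 10.5, -10.5, -40.5)
  ts <- array(stats::runif(12 * nlat * nlon, -10, 25), c(12, nlat, nlon))
  pr <- array(stats::runif(12 * nlat * nlon, 0, 200), c(12, nlat, nlon))
  clim <- monthly_climatology(ts, pr, lat, lon = c(0.5, 1.5, 2.5))
  rows_rev <- rev(seq_len(nlat))
  d1 <- derive_climatology(clim)

  # latitude flip alone: the half-year month sets swap
  clim_flip <- monthly_climatology(ts[, rows_rev, ], pr[, rows_rev, ],
                                   lat, lon = c(0.5, 1.5, 2.5))
  d_flip <- derive_climatology(clim_flip)
  expect_equal(d_flip$P_smax, d1$P_wmax[rows_rev, ])
  expect_equal(d_flip$P_wmin, d1$P_smin[rows_rev, ])
  expect_equal(d_flip$summer_frac, d1$winter_frac[rows_rev, ])

  # latitude flip plus a six-month roll: two swaps cancel exactly
  roll <- c(7:12, 1:6)
  clim2 <- monthly_climatology(ts[roll, rows_rev, ], pr[roll, rows_rev, ],
                               lat, lon = c(0.5, 1.5, 2.5))
  d2 <- derive_climatology(clim2)
  expect_equal(d2$P_smax, d1$P_smax[rows_rev, ])
  expect_equal(d2$summer_frac, d1$summer_frac[rows_rev, ])
})

test_that("area weights are cosine-latitude, masked, and normalized", {
  clim <- uniform_clim(lat = c(60.5, -60.5), lon = c(0.5, 1.5))
  w <- area_weights(clim)
  expect_equal(sum(w), 1)
  expect_equal(w[1, 1], w[2, 2])                    # equal |lat| -> equal w

  mask <- matrix(FALSE, 2, 2); mask[1, 1] <- TRUE
  clim1 <- uniform_clim(lat = c(60.5, -60.5), lon = c(0.5, 1.5), mask = mask)
  expect_equal(area_weights(clim1)[1, 1], 1)        # single unmasked cell

  clim2 <- uniform_clim(lat = c(0, 60), lon = c(0.5, 1.5))
  w2 <- area_weights(clim2)
  expect_equal(w2[1, 1] / w2[2, 1], cos(0) / cos(60 * pi / 180))

  mask_none <- matrix(FALSE, 2, 2)
  expect_error(area_weights(uniform_clim(lat = c(10.5, -10.5),
                                         lon = c(0.5, 1.5),
                                         mask = mask_none)),
               "empty domain")
})

test_that("climatology validation rejects malformed input", {
  expect_error(monthly_climatology(array(0, c(11, 2, 2)), array(0, c(11, 2, 2)),
                                   c(1, -1), c(0, 1)), "12")
  ts <- array(0, c(12, 2, 2)); pr <- array(0, c(12, 2, 2))
  pr[1, 1, 1] <- -5
  expect_error(monthly_climatology(ts, pr, c(1, -1), c(0, 1)), "non-negative")
})

test_that("bilinear regridding is exact on identity, constants, and midpoints", {
  lat <- seq(80.5, -80.5, by = -1)[1:20]
  lon <- seq(-10.5, 10.5, by = 1)
  set.seed(4)
  f <- matrix(stats::rnorm(length(lat) * length(lon)), length(lat))
  expect_lt(max(abs(regrid_bilinear(f, lat, lon, lat, lon) - f)), 1e-12)

  g <- regrid_bilinear(matrix(3.7, length(lat), length(lon)), lat, lon,
                       lat[3:10], lon[2:5])
  expect_true(all(abs(g - 3.7) < 1e-12))

  # 2x2 corners {0,1;1,2}: the cell-center midpoint interpolates to 1
  h <- regrid_bilinear(matrix(c(0, 1, 1, 2), 2, 2), c(1, 0), c(0, 1),
                       0.5, 0.5)
  expect_equal(as.numeric(h), 1.0)

  expect_error(regrid_bilinear(f, lat, lon, c(85, 0), lon[1:2]),
               "extrapolate")
})

test_that("regridding agrees with an independent interpolator away from the seam", {
  skip_if_not_installed("pracma")
  src_lat <- seq(40, 20, by = -2)
  src_lon <- seq(10, 40, by = 2)
  set.seed(12)
  f <- matrix(stats::rnorm(length(src_lat) * length(src_lon)), length(src_lat))
  dst_lat <- seq(38.3, 21.7, length.out = 9)
  dst_lon <- seq(11.2, 38.8, length.out = 11)
  got <- regrid_bilinear(f, src_lat, src_lon, dst_lat, dst_lon)
  # pracma::interp2 wants ascending coordinates
  ref <- pracma::interp2(src_lon, rev(src_lat), f[rev(seq_along(src_lat)), ],
                         rep(dst_lon, each = length(dst_lat)),
                         rep(dst_lat, times = length(dst_lon)),
                         method = "linear")
  expect_equal(as.vector(got), ref, tolerance = 1e-10)
})

test_that("regridding interpolates across the dateline seam", {
  src_lat <- c(10, -10)
  src_lon <- c(-179.5, -178.5, 178.5, 179.5)
  f <- matrix(c(1, 1, 3, 3, 5, 5, 7, 7), 2, 4)
  # halfway between lon 179.5 and -179.5 (i.e. at 180): mean of cols 4 and 1
  g <- regrid_bilinear(f, src_lat, src_lon, c(10, -10), 180)
  expect_equal(as.vector(g), c((7 + 1) / 2, (7 + 1) / 2))
})
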