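test_that("kappa of a map against itself is exactly 1", {
  set.seed(41)
  m <- toy_map(matrix(sample(1:5, 48, replace = TRUE), 6, 8), nclass = 5)
  expect_equal(cohen_kappa(m, m), 1)
})

test_that("kappa matches the hand-computed four-pixel example", {
  a <- toy_map(matrix(c(1, 1, 2, 2), 2, 2), nclass = 2)
  b <- toy_map(matrix(c(1, 1, 2, 1), 2, 2), nclass = 2)
  # P0 = 3/4; class frequencies give Pe = 0.5*0.75 + 0.5*0.25 = 0.5
  expect_equal(cohen_kappa(a, b), (0.75 - 0.5) / (1 - 0.5), tolerance = 1e-9)
})

test_that("kappa is symmetric and invariant under a joint relabeling", {
  set.seed(42)
  ca <- matrix(sample(1:4, 60, replace = TRUE), 6, 10)
  cb <- matrix(sample(1:4, 60, replace = TRUE), 6, 10)
  a <- toy_map(ca, 4); b <- toy_map(cb, 4)
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  perm <- c(3L, 1L, 4L, 2L)
  a2 <- toy_map(matrix(perm[ca], 6, 10), 4)
  b2 <- toy_map(matrix(perm[cb], 6, 10), 4)
  expect_equal(cohen_kappa(a2, b2), cohen_kappa(a, b))
})

test_that("independent random maps score near zero kappa", {
  set.seed(7)
  n <- 20000
  a <- sample(1:2, n, replace = TRUE)
  b <- sample(1:2, n, replace = TRUE)
  k <- cohen_kappa(a, b, w = rep(1 / n, n))
  expect_lt(abs(k), 0.05)
})

test_that("degenerate constant maps follow the documented conventions", {
  a <- toy_map(matrix(2L, 2, 2), nclass = 3)
  expect_equal(cohen_kappa(a, a), 1)
  # two constant maps with different classes: P0 = Pe = 0, so kappa = 0
  b <- toy_map(matrix(3L, 2, 2), nclass = 3)
  expect_equal(cohen_kappa(a, b), 0)
})

test_that("weighted R2 reproduces hand-worked values in both forms", {
  w <- rep(1 / 3, 3)
  o <- c(0, 1, 2)
  expect_equal(weighted_r2(o, o, w), 1)
  # constant-at-the-mean model has zero skill
  expect_equal(weighted_r2(rep(1, 3), o, w), 0)
  # one unit error on one of three cells: 1 - (1/3)/(2/3) = 0.5
  expect_equal(weighted_r2(c(0, 1, 1), o, w), 0.5)
  # a biased but perfectly correlated model: corr form 1, skill form negative
  expect_equal(weighted_r2(o + 5, o, w, method = "corr"), 1)
  expect_lt(weighted_r2(o + 5, o, w), 0)
  expect_error(weighted_r2(o, rep(4, 3), w), "variance")
})

test_that("weighted R2 ignores zero-weight cells", {
  o <- c(0, 1, 2, 100)
  m <- c(0, 1, 1, -999)
  w <- c(1, 1, 1, 0) / 3
  expect_equal(weighted_r2(m, o, w), 0.5)
})

test_that("median-quadrant selection matches a brute-force oracle", {
  set.seed(13)
  for (trial in 1:5) {
    nmod <- 24
    cards <- data.frame(model = sprintf("m%02d", 1:nmod),
                        kappa = stats::runif(nmod),
                        r2_pr = stats::runif(nmod),
                        stringsAsFactors = FALSE)
    got <- suppressWarnings(select_top10(cards))
    quad <- cards[cards$kappa >= stats::median(cards$kappa) &
                    cards$r2_pr >= stats::median(cards$r2_pr), ]
    want <- utils::head(quad$model[order(-quad$kappa)], 10)
    expect_equal(got, want)
    # shuffling the cohort rows must not change the selected set
    got2 <- suppressWarnings(select_top10(cards[sample(nmod), ]))
    expect_setequal(got2, got)
  }
})

test_that("selection is inclusive at the medians and warns on small quadrants", {
  # all models identical: everyone is on both medians, all are kept
  cards <- data.frame(model = letters[1:10], kappa = 0.5, r2_pr = 0.5)
  expect_equal(select_top10(cards), letters[1:10])
  small <- data.frame(model = letters[1:4], kappa = c(1, 2, 3, 4) / 10,
                      r2_pr = c(1, 2, 3, 4) / 10)
  expect_warning(sel <- select_top10(small), "quadrant")
  expect_equal(sel, c("d", "c"))   # upper-right pair, by decreasing kappa
})

test_that("a member equal to the reference ranks first with kappa 1", {
  cfg <- test_cfg(seed = 5, n_members = 4)
  ref <- make_reference(cfg)
  members <- c(list(truth = ref), make_ensemble(ref, cfg))
  cards <- suppressWarnings(rank_models(members, ref, scheme = "whittaker"))
  expect_equal(cards$kappa[cards$model == "truth"], 1)
  expect_equal(cards$rank[cards$model == "truth"], 1L)
  expect_true(cards$selected[cards$model == "truth"])
  expect_true(all(cards$kappa <= 1))
  expect_equal(cards$r2_pr[cards$model == "truth"], 1)
  expect_equal(cards$r2_ts[cards$model == "truth"], 1)
})

test_that("ranking reuses precomputed class maps unchanged", {
  cfg <- test_cfg(seed = 6, n_members = 3)
  ref <- make_reference(cfg)
  members <- make_ensemble(ref, cfg)
  ref_map <- classify_climatology(ref, "koppen")
  member_maps <- lapply(members, classify_climatology, scheme = "koppen")
  c1 <- suppressWarnings(rank_models(members, ref, scheme = "koppen"))
  c2 <- suppressWarnings(rank_models(members, ref, scheme = "koppen",
                                     ref_map = ref_map,
                                     member_maps = member_maps))
  expect_equal(c1, c2)
})

test_that("ensemble mean averages fields and intersects land masks", {
  a <- uniform_clim(ts_val = 10, pr_val = 50)
  b <- uniform_clim(ts_val = 20, pr_val = 150)
  m <- ensemble_mean(list(a, b))
  expect_equal(unique(as.vector(m$ts)), 15)
  expect_equal(unique(as.vector(m$pr)), 100)
  mask <- matrix(TRUE, 4, 3); mask[1, 1] <- FALSE
  b2 <- uniform_clim(ts_val = 20, pr_val = 150, mask = mask)
  m2 <- ensemble_mean(list(a, b2))
  expect_identical(m2$land_mask, mask)
})

test_that("class area fractions are cosine-weighted and sum to 100", {
  codes <- matrix(c(1L, 2L), 2, 1)
  m <- toy_map(codes, nclass = 3, lat = c(0, 60), lon = 0.5)
  f <- class_area_fractions(m)
  expect_equal(sum(f), 100)
  expect_equal(unname(f[1] / f[2]), cos(0) / cos(60 * pi / 180))
  expect_equal(unname(f[3]), 0)
  expect_named(f, c("C1", "C2", "C3"))
})
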