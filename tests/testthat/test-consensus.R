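make_vote_stack <- function(ref_codes, member_codes_list, nclass = 5) {
  ref <- toy_map(ref_codes, nclass)
  members <- lapply(member_codes_list, toy_map, nclass = nclass)
  list(ref = ref, members = members)
}

test_that("confidence is the percentage of members voting with the reference", {
  ref_codes <- matrix(c(1L, 2L), 1, 2)
  # pixel 1: 8 of 10 members agree; pixel 2: 3 of 10
  members <- lapply(1:10, function(i)
    matrix(c(if (i <= 8) 1L else 3L, if (i <= 3) 2L else 4L), 1, 2))
  vs <- make_vote_stack(ref_codes, members)
  conf <- confidence_map(vs$members, vs$ref)
  expect_equal(as.vector(conf), c(80, 30))
})

test_that("confidence bins follow the five published categories", {
  conf <- c(100, 80, 79.9, 60, 59.9, 40, 39.9, 20, 19.9, 0)
  got <- confidence_category(conf)
  expect_equal(as.integer(got), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_equal(attr(got, "labels"),
               c("very high", "high", "moderate", "low", "very low"))
  expect_error(confidence_category(120), "percentage")
})

test_that("model variability counts distinct classes with a threshold of three", {
  members <- list(matrix(c(1L, 1L), 1, 2),
                  matrix(c(1L, 2L), 1, 2),
                  matrix(c(1L, 3L), 1, 2))
  vs <- make_vote_stack(matrix(c(1L, 1L), 1, 2), members)
  mv <- modvar_map(vs$members)
  expect_equal(as.vector(mv$modvar), c(1L, 3L))
  expect_equal(as.vector(mv$high_variability), c(FALSE, TRUE))
})

test_that("confidence is invariant to member order and grows when agreeing members join", {
  set.seed(23)
  ref_codes <- matrix(sample(1:4, 20, replace = TRUE), 4, 5)
  members <- lapply(1:7, function(i)
    matrix(sample(1:4, 20, replace = TRUE), 4, 5))
  vs <- make_vote_stack(ref_codes, members, nclass = 4)
  c1 <- confidence_map(vs$members, vs$ref)
  c2 <- confidence_map(rev(vs$members), vs$ref)
  expect_equal(c1, c2)
  # add a copy of the reference: every pixel's confidence cannot drop
  c3 <- confidence_map(c(vs$members, list(vs$ref)), vs$ref)
  expect_true(all(c3 >= c1 - 1e-9))
  expect_true(all(c3 > 0))
})

test_that("confidence against complementary references sums to 100 for binary votes", {
  set.seed(29)
  members <- lapply(1:9, function(i)
    matrix(sample(1:2, 12, replace = TRUE), 3, 4))
  ones <- toy_map(matrix(1L, 3, 4), 2)
  twos <- toy_map(matrix(2L, 3, 4), 2)
  vs <- lapply(members, toy_map, nclass = 2)
  expect_equal(confidence_map(vs, ones) + confidence_map(vs, twos),
               matrix(100, 3, 4))
})

test_that("confidence recovers a known corruption rate", {
  set.seed(31)
  n <- 2500; p <- 0.3; nmem <- 40
  ref_codes <- matrix(sample(1:5, n, replace = TRUE), 50, 50)
  members <- lapply(seq_len(nmem), function(i) {
    cc <- ref_codes
    flip <- stats::runif(n) < p
    cc[flip] <- ((cc[flip] + sample(1:4, sum(flip), replace = TRUE) - 1L) %% 5L) + 1L
    cc
  })
  vs <- make_vote_stack(ref_codes, members)
  conf <- confidence_map(vs$members, vs$ref)
  expect_equal(mean(conf), 100 * (1 - p), tolerance = 0.02)
})

test_that("the consensus product bundles all layers consistently", {
  set.seed(37)
  ref_codes <- matrix(sample(1:3, 24, replace = TRUE), 4, 6)
  members <- lapply(1:6, function(i) {
    cc <- ref_codes
    flip <- stats::runif(24) < 0.25
    cc[flip] <- sample(1:3, sum(flip), replace = TRUE)
    cc
  })
  vs <- make_vote_stack(ref_codes, members, nclass = 3)
  cp <- build_consensus_product(vs$members, vs$ref)
  expect_s3_class(cp, "consensus_product")
  expect_equal(cp$n_members, 6L)
  expect_equal(cp$confidence_category,
               confidence_category(cp$confidence), ignore_attr = TRUE)
  expect_equal(cp$high_variability, !is.na(cp$modvar) & cp$modvar >= 3L,
               ignore_attr = TRUE)
  expect_output(print(cp), "consensus")
})

test_that("member maps on mismatched grids or legends are rejected", {
  a <- toy_map(matrix(1L, 2, 2), 2)
  b <- toy_map(matrix(1L, 3, 3), 2)
  expect_error(build_consensus_product(list(a, b), a), "grid")
  c3 <- toy_map(matrix(1L, 2, 2), 3)
  expect_error(build_consensus_product(list(a, c3), a), "legend")
  expect_error(build_consensus_product(list(), a), "at least one")
})
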