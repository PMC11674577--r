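test_that("noiseless frames from orthogonal templates are recovered exactly", {
  tpl <- orthogonal_templates(3, block = 10L)
  lab <- rep(1:3, each = 20)
  fm <- frames_of(tpl[lab, ])
  fit <- cap_fit(fm, 3, seed = 1, n_init = 5, row_standardize = FALSE)
  expect_equal(adjusted_rand(fit$assignments, lab), 1)
  m <- match_states(fit$centers, tpl)
  expect_lt(max(abs(fit$centers - tpl[m$mapping, ])), 1e-8)
  # assignment sets are exactly the planted partition
  expect_true(all(table(fit$assignments) == 20))
})

test_that("the fit is deterministic and seed-stable up to relabeling", {
  set.seed(10)
  x <- orthogonal_templates(3, 8)[rep(1:3, 30), ] +
    matrix(rnorm(90 * 24, 0, 0.3), 90, 24)
  f1 <- cap_fit(x, 3, seed = 7, n_init = 5, row_standardize = FALSE)
  f2 <- cap_fit(x, 3, seed = 7, n_init = 5, row_standardize = FALSE)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$centers, f2$centers)
  f3 <- cap_fit(x, 3, seed = 8, n_init = 5, row_standardize = FALSE)
  expect_lt(abs(f1$sse - f3$sse) / f1$sse, 1e-10)
})

test_that("planted states are recovered under noise (adjusted agreement > 0.9)", {
  cfg <- small_config(seed = 2L, n_parcels = 120L)
  tpl <- make_templates(cfg)
  set.seed(42)
  lab <- sample(1:6, 2000, replace = TRUE)
  x <- tpl$templates[lab, ] + matrix(rnorm(2000 * 120, 0, 0.5), 2000, 120)
  fit <- cap_fit(x, 6, seed = 1, n_init = 10)
  expect_gt(adjusted_rand(fit$assignments, lab), 0.9)
})

test_that("SSE matches stats::kmeans and an independent recomputation", {
  set.seed(3)
  x <- orthogonal_templates(4, 6)[rep(1:4, 100), ] * 2 +
    matrix(rnorm(400 * 24, 0, 0.6), 400, 24)
  fit <- cap_fit(x, 4, seed = 2, n_init = 10, row_standardize = FALSE,
                 search_n = Inf)
  # independent oracle: sum of squared distances to assigned centers
  sse_oracle <- sum((x - fit$centers[fit$assignments, ])^2)
  expect_lt(abs(fit$sse - sse_oracle), 1e-6)
  set.seed(2)
  ref <- kmeans(x, 4, nstart = 10, iter.max = 100)
  expect_lt(abs(fit$sse - ref$tot.withinss) / ref$tot.withinss, 1e-6)
  # centers are the means of their member frames
  recomp <- rowsum(x, fit$assignments) / as.vector(table(fit$assignments))
  expect_lt(max(abs(recomp - fit$centers)), 1e-8)
})

test_that("Z maps divide centers by the population within-cluster sd", {
  # cluster members {center + e, center - e} with e = 0.5 on parcel 1,
  # center value 0.2 -> z = 0.2 / 0.5 = 0.4
  a <- rbind(c(0.7, 5, 5), c(-0.3, 5, 5))
  b <- rbind(c(10, -5, -5), c(10.2, -5.2, -5))
  fit <- cap_fit(rbind(a, b), 2, seed = 1, n_init = 2,
                 row_standardize = FALSE)
  ca <- which.max(fit$centers[, 2])   # the cluster built from block a
  zm <- normalize_tns(fit)
  expect_equal(zm$z[ca, 1], 0.4, tolerance = 1e-12)
  # scale invariance: doubling all member values leaves z unchanged
  fit2 <- cap_fit(rbind(2 * a, 2 * b), 2, seed = 1, n_init = 2,
                  row_standardize = FALSE)
  map <- match_states(fit$centers, fit2$centers)$mapping
  expect_equal(normalize_tns(fit2)$z[map, ], zm$z, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("near-zero within-cluster spread is flagged", {
  a <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3.4))
  b <- rbind(c(-9, 4, 0), c(-9.4, 4, 0), c(-9, 4.4, 0))
  fit <- cap_fit(rbind(a, b), 2, seed = 1, n_init = 2,
                 row_standardize = FALSE)
  zm <- normalize_tns(fit)
  expect_true(any(zm$flagged))
  expect_true(all(zm$z[zm$flagged] == 0))
})

test_that("threshold masks use strict inequalities", {
  zm <- structure(list(z = matrix(c(0.5, -0.5, 0.1), 1),
                       parcel_ids = c("a", "b", "c")),
                  class = "cap_zmaps")
  m <- threshold_map(zm, 0.4)
  expect_identical(as.vector(m$mask), c(1L, -1L, 0L))
  m2 <- threshold_map(zm, 0.5)
  expect_identical(as.vector(m2$mask), c(0L, 0L, 0L))
  zm$z[] <- 0
  expect_true(all(threshold_map(zm, 0.4)$mask == 0L))
  expect_error(threshold_map(zm, 0), "positive")
})

test_that("state matching recovers permutations and survives noise", {
  set.seed(5)
  a <- matrix(rnorm(6 * 400), 6, 400)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  m <- match_states(a, a[perm, ])
  expect_identical(perm[m$mapping], 1:6)
  expect_equal(m$similarity, rep(1, 6), tolerance = 1e-12)
  b <- a[perm, ] + matrix(rnorm(6 * 400, 0, 0.1), 6, 400)
  m2 <- match_states(a, b)
  expect_identical(m2$mapping, m$mapping)
  expect_true(all(m2$similarity > 0.9))
  # negation: still a bijection, similarities near -1, sign not forced
  m3 <- match_states(a, -a)
  expect_identical(sort(m3$mapping), 1:6)
  expect_true(all(m3$similarity < -0.99))
  expect_error(match_states(a, a[1:5, ]), "mismatch")
})

test_that("mirror pairing finds constructed mirrors and flags orthogonal maps", {
  set.seed(6)
  A <- rnorm(50); B <- rnorm(50)
  mp <- find_mirror_pairs(rbind(A, -A, B, -B))
  expect_equal(mp$pairs, rbind(c(1L, 2L), c(3L, 4L)), ignore_attr = TRUE)
  expect_equal(mp$r, c(-1, -1), tolerance = 1e-12)
  expect_false(any(mp$flagged))
  orth <- orthogonal_templates(4, 12)
  mp2 <- find_mirror_pairs(orth)
  expect_true(all(mp2$flagged))
  # planted templates pair up exactly as constructed
  cfg <- small_config(seed = 2L, n_parcels = 120L)
  tpl <- make_templates(cfg)$templates
  mp3 <- find_mirror_pairs(tpl)
  expect_equal(mp3$pairs, rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
               ignore_attr = TRUE)
  expect_equal(mp3$r, rep(-1, 3), tolerance = 1e-12)
})

test_that("spatial similarity matrices are symmetric with unit diagonal", {
  set.seed(7)
  z <- matrix(rnorm(5 * 60), 5, 60)
  s <- spatial_similarity_matrix(z)
  expect_equal(diag(s), rep(1, 5), tolerance = 1e-12)
  expect_lt(max(abs(s - t(s))), 1e-12)
  s2 <- spatial_similarity_matrix(rbind(z[1, ], -z[1, ]))
  expect_equal(s2[1, 2], -1, tolerance = 1e-12)
})

test_that("elbow selection flags a structureless cloud and keeps SSE monotone", {
  set.seed(8)
  x <- matrix(rnorm(3000 * 20), 3000, 20)
  expect_warning(el <- select_k_elbow(x, c(2L, 4L, 6L, 8L), seed = 1,
                                      row_standardize = FALSE),
                 "no clear elbow")
  expect_true(el$no_elbow)
  expect_identical(el$k, 2L)
  expect_true(all(diff(el$sse) <= 1e-8))
  expect_error(select_k_elbow(x, c(2L, 4L)), "at least 3")
  expect_error(select_k_elbow(x, c(4L, 2L, 6L)), "increasing")
})

test_that("elbow finds the planted state count on a small cohort", {
  cfg <- small_config(seed = 9L, n_parcels = 100L)
  tpl <- make_templates(cfg)
  set.seed(9)
  lab <- sample(1:6, 4000, replace = TRUE)
  x <- tpl$templates[lab, ] + matrix(rnorm(4000 * 100, 0, 1.0), 4000, 100)
  el <- select_k_elbow(x, c(2L, 4L, 6L, 8L, 10L), seed = 2)
  expect_identical(el$k, 6L)
  expect_false(el$no_elbow)
})

test_that("predict assigns new frames to the nearest state", {
  tpl <- orthogonal_templates(3, 10)
  fm <- frames_of(tpl[rep(1:3, 10), ])
  fit <- cap_fit(fm, 3, seed = 1, n_init = 3, row_standardize = FALSE)
  pred <- predict(fit, tpl + matrix(rnorm(90, 0, 0.05), 3, 30))
  expect_identical(pred, predict(fit, tpl))
  expect_identical(sort(pred), 1:3)
  # residuals of the training frames vanish in the noiseless case
  expect_lt(max(abs(residuals(fit, fm))), 1e-10)
})
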