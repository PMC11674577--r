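test_that("frame distance is 1 - Pearson r and lives in [0, 2]", {
  v <- rnorm(20)
  expect_equal(frame_distance(v, v), 0, tolerance = 1e-12)
  expect_equal(frame_distance(v, -v), 2, tolerance = 1e-12)
  # cor(c(1,0,-1), c(0,1,-1)) = 0.5 -> d = 0.5
  expect_equal(frame_distance(c(1, 0, -1), c(0, 1, -1)), 0.5,
               tolerance = 1e-12)
  expect_error(frame_distance(rep(1, 5), rnorm(5)), "constant")
})

test_that("subject mean distances match a brute-force oracle and flag absent states", {
  cfg <- small_config(seed = 21L, n = 2L, n_parcels = 60L)
  sim <- simulate_cohort(cfg)
  cohort <- sim$cohort
  cohort$subjects <- lapply(cohort$subjects, normalize_frames)
  fm <- concatenate_subjects(cohort)
  fit <- cap_fit(fm, 6, seed = 1, n_init = 5)
  d <- subject_mean_distances(fit, fm)
  # brute force: per frame, 1 - cor(frame, center) in the fitted space
  x <- capstate:::standardize_rows(fm$x)
  ids <- unique(fm$frame_index$subject_id)
  for (id in ids[1:4]) {
    rows <- which(fm$frame_index$subject_id == id)
    for (c in 1:6) {
      rc <- rows[fit$assignments[rows] == c]
      want <- if (!length(rc)) NA_real_ else
        mean(vapply(rc, function(r) 1 - cor(x[r, ], fit$centers[c, ]), 0))
      expect_equal(d[d$subject_id == id, paste0("dist_", c)], want,
                   tolerance = 1e-10)
    }
  }
  fd <- attr(d, "frame_distances")
  expect_true(all(fd >= 0 & fd <= 2))
})

test_that("a subject never visiting a state gets a missing cell, not zero", {
  centers <- orthogonal_templates(2, 5)
  x <- centers[c(1, 1, 1, 2, 2, 2), ] + 0.01
  fit <- fake_fit(centers, c(1L, 1L, 1L, 2L, 2L, 2L),
                  rep(c("a", "b"), each = 3))
  fm <- frames_of(x, rep(c("a", "b"), each = 3))
  d <- subject_mean_distances(fit, fm)
  expect_true(is.na(d[d$subject_id == "a", "dist_2"]))
  expect_false(is.na(d[d$subject_id == "b", "dist_2"]))
  expect_true(is.na(d[d$subject_id == "b", "dist_1"]))
})

test_that("individual state maps equal the global Z map when frames sit on the center", {
  cfg <- small_config(seed = 22L, n = 2L, n_parcels = 60L)
  sim <- simulate_cohort(cfg)
  cohort <- sim$cohort
  cohort$subjects <- lapply(cohort$subjects, normalize_frames)
  fm <- concatenate_subjects(cohort)
  fit <- cap_fit(fm, 6, seed = 1, n_init = 5)
  zm <- normalize_tns(fit)
  # a synthetic subject whose frames all equal the center of state 3
  one <- individual_tns(fit, fm, fm$frame_index$subject_id[1], 3)
  expect_true(one$defined || one$n_frames == 0L)
  x2 <- fit$centers[c(3, 3, 3), ]
  fit2 <- fit
  fit2$assignments <- rep(3L, 3)
  fit2$frame_index <- data.frame(subject_id = rep("solo", 3), frame = 1:3)
  fm2 <- frames_of(x2, rep("solo", 3))
  fm2$row_standardized <- TRUE   # frames already in the fitted space
  got <- individual_tns(fit2, fm2, "solo", 3)
  expect_equal(unname(got$z_ind), unname(zm$z[3, ]), tolerance = 1e-10)
})

test_that("undefined individual maps are flagged, subject-sd mode is scale invariant", {
  centers <- orthogonal_templates(2, 5) * 3
  x <- centers[c(1, 1, 1, 2, 2, 2), ] +
    matrix(rnorm(30, 0, 0.2), 6, 10)
  sub <- rep(c("a", "b"), each = 3)
  fit <- fake_fit(centers, rep(c(1L, 2L), each = 3), sub)
  fm <- frames_of(x, sub)
  expect_false(individual_tns(fit, fm, "a", 2)$defined)
  z1 <- individual_tns(fit, fm, "a", 1, sd_mode = "subject")$z_ind
  fm2 <- frames_of(2 * x, sub)
  z2 <- individual_tns(fit, fm2, "a", 1, sd_mode = "subject")$z_ind
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("stable regions follow the strict majority rule", {
  # 5 subjects, one frame cluster; within_sd = 1 so z_ind = subject mean
  centers <- rbind(c(0, 0, 0, 0), c(9, 9, 9, 9))
  vals <- c(0.9, 0.8, 0.41, 0.1, -0.2)   # parcel 1: 3/5 above 0.4
  x <- cbind(vals, rep(0.41, 5), rep(-0.9, 5), c(0.9, 0.9, -0.9, -0.9, 0))
  sub <- paste0("s", 1:5)
  fit <- fake_fit(centers, rep(1L, 5), sub)
  fm <- frames_of(x, sub)
  sr <- stable_regions(fit, fm, 1, tau = 0.4)
  expect_true(all(c(1, 2, 3) %in% sr$parcel))
  expect_identical(sr$direction[sr$parcel == 1], 1L)
  expect_identical(sr$direction[sr$parcel == 3], -1L)
  expect_equal(sr$fraction[sr$parcel == 1], 0.6)
  expect_false(4 %in% sr$parcel)   # 2/5 up, 2/5 down: no majority
  # exactly 50% is not a strict majority
  fit4 <- fake_fit(centers, rep(1L, 4), sub[1:4])
  fm4 <- frames_of(x[1:4, , drop = FALSE], sub[1:4])
  sr4 <- stable_regions(fit4, fm4, 1, tau = 0.4)
  expect_false(4 %in% sr4$parcel)  # 2/4 above = exactly half
})

test_that("iSAR is the fraction n/N of suprathreshold member frames", {
  centers <- rbind(c(1, 1), c(-9, 9))
  # subject a: 5 frames in state 1, |intensity| > 0.4 on parcel 1 in 3
  xa <- cbind(c(0.9, 0.5, -0.8, 0.1, 0.2), rep(1, 5))
  fit <- fake_fit(centers, rep(1L, 5), rep("a", 5))
  fm <- frames_of(xa, rep("a", 5))
  r <- isar(fit, fm, "a", 1, parcels = c(1L, 2L), tau = 0.4)
  expect_equal(r$isar, c(3 / 5, 1))
  expect_identical(r$n, c(3L, 5L))
  expect_identical(r$N, c(5L, 5L))
  r0 <- isar(fit, fm, "a", 1, parcels = 1L, tau = 1.0)
  expect_equal(r0$isar, 0)
  tab <- isar_table(fit, fm, 1, c(1L, 2L))
  expect_true(all(tab >= 0 & tab <= 1, na.rm = TRUE))
})

test_that("noiseless cohorts give zero distances and iSAR one on planted regions", {
  cfg <- small_config(seed = 23L, n_parcels = 80L)
  nl <- noiseless_cohort(cfg)
  cohort <- nl$cohort
  cohort$subjects <- lapply(cohort$subjects, normalize_frames)
  fm <- concatenate_subjects(cohort)
  fit <- cap_fit(fm, 6, seed = 2, n_init = 5)
  d <- subject_mean_distances(fit, fm)
  expect_lt(max(abs(as.matrix(d[, -1])), na.rm = TRUE), 1e-12)
  m <- match_states(fit$centers, nl$templates)
  checked <- 0L
  for (c in which(fit$sizes >= 2)) {
    strong <- which(abs(nl$templates[m$mapping[c], ]) > 0.4)
    if (!length(strong)) next
    tab <- isar_table(fit, fm, c, strong)
    ok <- !is.na(tab[, 1])
    expect_true(all(tab[ok, ] == 1))
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("spatial noise strictly degrades the mean distance to center", {
  cfg <- small_config(seed = 24L, n_parcels = 60L)
  tpl <- make_templates(cfg)
  P <- markov_matrix(cfg, "juvenile_CON")
  med_d <- vapply(c(0.2, 0.5, 1.0), function(nsd) {
    ds <- vapply(1:8, function(s) {
      seqs <- simulate_state_sequence(P, 80, seed = 100 * s + nsd * 10)
      x <- simulate_subject(tpl$templates, seqs, nsd,
                            seed = 200 * s + nsd * 10)
      fm <- frames_of(x)
      fit <- cap_fit(fm, 6, seed = 3, n_init = 3)
      mean(attr(subject_mean_distances(fit, fm), "frame_distances"))
    }, 0)
    median(ds)
  }, 0)
  expect_true(all(diff(med_d) > 0))
})

test_that("recovered ECN-pair states are less stable than DMN-pair states", {
  # per-state noise multipliers plant higher spatial variance on the ECN
  cfg <- small_config(seed = 25L, n = 6L, n_parcels = 80L)
  sim <- simulate_cohort(cfg)
  res <- run_cap_pipeline(sim$cohort, reference = sim$ground_truth,
                          select_k = FALSE, k = 6, n_init = 5,
                          cca_state = "none")
  ft <- res$features_raw
  ecn <- rowMeans(ft[, c("dist_ECN_p", "dist_ECN_n")])
  dmn <- rowMeans(ft[, c("dist_DMN_p", "dist_DMN_n")])
  tt <- t.test(ecn, dmn, paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("site-level clusterings reproduce the cohort states", {
  cfg <- small_config(seed = 26L, n = 6L, n_parcels = 80L)
  sim <- simulate_cohort(cfg)
  cohort <- sim$cohort
  cohort$subjects <- lapply(cohort$subjects, normalize_frames)
  fm <- concatenate_subjects(cohort)
  fit <- cap_fit(fm, 6, seed = 1, n_init = 5)
  sr <- site_reproducibility(cohort, fit = fit, fm = fm, k = 6,
                             n_init = 5)
  expect_true(all(abs(sr$site_vs_global) > 0.9))
  # pairwise tensor symmetric in the site pair
  for (c in 1:6)
    expect_lt(max(abs(sr$site_pair[c, , ] - t(sr$site_pair[c, , ]))),
              1e-12)
  # negative control: a site of pure noise reproduces nothing
  noise_subjects <- lapply(1:4, function(i)
    normalize_frames(cap_subject(
      sprintf("noise%02d", i),
      matrix(rnorm(100 * cfg$n_parcels), 100), "NZ", "CON", "juvenile",
      age = 10, full_iq = 100, motion = 0.2, tr = 2)))
  cohort2 <- cap_cohort(c(cohort$subjects, noise_subjects),
                        cohort$atlas)
  sr2 <- site_reproducibility(cohort2, fit = fit, fm = NULL, k = 6,
                              n_init = 5)
  expect_lt(max(abs(sr2$site_vs_global["NZ", ])), 0.5)
  # a site with too few frames is skipped with a warning
  w <- capture_warnings(
    site_reproducibility(cohort, fit = fit, fm = fm, k = 6, n_init = 2,
                         min_frames = 1e6))
  expect_true(any(grepl("skipped", w)))
})
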