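make_ft <- function(n = 60, sites = c("A", "B"), delta = 0,
                    group_effect = 0, seed = 1) {
  set.seed(seed)
  ft <- data.frame(
    site = rep(sites, length.out = n),
    group = rep(c("ASD", "CON"), each = n / 2),
    age_group = rep(c("juvenile", "adult"), length.out = n))
  # the site shift hits every feature, as a scanner effect would
  ft$f1 <- rnorm(n) + delta * (ft$site == sites[1]) +
    group_effect * (ft$group == "ASD")
  ft$f2 <- rnorm(n) + delta * (ft$site == sites[1])
  ft$f3 <- rnorm(n) + delta * (ft$site == sites[1])
  ft$f4 <- rnorm(n) + delta * (ft$site == sites[1])
  ft
}

test_that("harmonization removes a planted site shift", {
  # single harmonized feature: location removal is essentially exact
  ft <- make_ft(n = 80, delta = 2, seed = 2)
  h <- combat_harmonize(ft, "f1", preserve = ~ group)
  dA <- mean(h$f1[h$site == "A"]) - mean(h$f1[h$site == "B"])
  expect_lt(abs(dA), 0.05 * sd(h$f1))
  # many features with heterogeneous site shifts at cohort scale:
  # empirical-Bayes shrinkage leaves residuals of order the sampling
  # noise, so the bound is asserted on the mean over seeds
  resid <- vapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 264
    site <- rep(c("A", "B"), each = n / 2)
    d <- data.frame(site = site, group = rep(c("ASD", "CON"), n / 2))
    shifts <- c(2, runif(11, -2, 2))
    for (j in 1:12)
      d[[paste0("f", j)]] <- rnorm(n) + shifts[j] * (site == "A")
    h <- combat_harmonize(d, paste0("f", 1:12), preserve = ~ group)
    abs(mean(h$f1[site == "A"]) - mean(h$f1[site == "B"])) / sd(h$f1)
  }, 0)
  expect_lt(mean(resid), 0.05)
})

test_that("harmonization preserves a group effect orthogonal to site", {
  ft <- make_ft(n = 200, delta = 1.5, group_effect = 1, seed = 3)
  h <- combat_harmonize(ft, paste0("f", 1:4), preserve = ~ group)
  g_raw <- 1   # planted
  g_harm <- mean(h$f1[h$group == "ASD"]) - mean(h$f1[h$group == "CON"])
  expect_lt(abs(g_harm - g_raw) / g_raw, 0.1)
})

test_that("harmonization edge cases: single batch, tiny batch, constant feature", {
  ft <- make_ft(n = 40, sites = "A")
  expect_identical(combat_harmonize(ft, c("f1", "f2")), ft)
  ft2 <- make_ft(n = 40, sites = c("A", "B"))
  ft2$site[40] <- "C"
  expect_error(combat_harmonize(ft2, "f1"), "single subject")
  ft3 <- make_ft(n = 40, delta = 1)
  ft3$f2 <- 7
  h3 <- combat_harmonize(ft3, c("f1", "f2"), preserve = ~ group)
  expect_identical(attr(h3, "constant_features"), "f2")
  expect_true(all(h3$f2 == 7))
})

test_that("mixed ANOVA with one within level reduces to the squared t test", {
  set.seed(4)
  ft <- data.frame(group = rep(c("ASD", "CON"), each = 15),
                   y = rnorm(30) + rep(c(0.5, 0), each = 15))
  a <- mixed_anova(ft, "y", between = "group", covariates = NULL)
  tt <- t.test(y ~ group, data = ft, var.equal = TRUE)
  expect_equal(a$F[a$effect == "group"], unname(tt$statistic)^2,
               tolerance = 1e-8)
  expect_equal(a$p[a$effect == "group"], tt$p.value, tolerance = 1e-8)
})

test_that("mixed ANOVA returns split-plot strata with the expected dfs", {
  set.seed(5)
  n <- 24; k <- 4
  ft <- data.frame(group = rep(c("ASD", "CON"), each = n / 2),
                   age_group = rep(c("juvenile", "adult"), n / 2),
                   full_iq = rnorm(n), motion = rnorm(n))
  for (c in 1:k) ft[[paste0("dv", c)]] <- rnorm(n)
  a <- mixed_anova(ft, paste0("dv", 1:k))
  expect_setequal(
    a$effect,
    c("group", "age_group", "full_iq", "motion", "group:age_group",
      "tns", "group:tns", "age_group:tns", "full_iq:tns", "motion:tns",
      "group:age_group:tns"))
  expect_equal(unique(a$df2[grepl("tns", a$effect)]), (n - 6) * (k - 1))
  expect_equal(unique(a$df2[!grepl("tns", a$effect)]), n - 6)
  # empty design cell is refused
  ft2 <- ft
  ft2$age_group[ft2$group == "ASD"] <- "juvenile"
  expect_error(mixed_anova(ft2, paste0("dv", 1:k)), "empty design cell")
})

test_that("a planted within-state effect is detected with high power", {
  set.seed(6)
  hits <- vapply(1:100, function(i) {
    n <- 100; k <- 6
    ft <- data.frame(group = rep(c("ASD", "CON"), each = n / 2),
                     age_group = rep(c("juvenile", "adult"), n / 2))
    mu <- scale(seq_len(k))[, 1] * 0.5
    for (c in 1:k) ft[[paste0("dv", c)]] <- rnorm(n, mu[c])
    a <- mixed_anova(ft, paste0("dv", 1:k), covariates = NULL)
    a$p[a$effect == "tns"] < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the GLM t test equals the classical pooled t without covariates", {
  set.seed(7)
  y <- rnorm(40)
  g <- rep(c("CON", "ASD"), each = 20)
  r <- glm_ttest(y, factor(g, levels = c("CON", "ASD")))
  tt <- t.test(y[g == "ASD"], y[g == "CON"], var.equal = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  # a response equal to a covariate is fully absorbed by it: the group
  # coefficient is numerically zero on the scale of the response
  x <- rnorm(40)
  r2 <- glm_ttest(x, g, cbind(x))
  expect_lt(abs(r2$estimate), 1e-8 * sd(x))
  expect_error(glm_ttest(y, g, cbind(x, x)), "collinear")
  expect_error(glm_ttest(y, rep("A", 40)), "2 levels")
})

test_that("a planted group shift is detected in most simulations", {
  set.seed(8)
  hits <- vapply(1:500, function(i) {
    y <- c(rnorm(30, 1), rnorm(30, 0))
    g <- rep(c("ASD", "CON"), each = 30)
    cov <- cbind(age = rnorm(60), iq = rnorm(60))
    glm_ttest(y, g, cov)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("FDR correction matches the brute-force step-up oracle", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    expect_equal(fdr_correct(p), bh_oracle(p), tolerance = 1e-12)
  }
  p <- runif(10)
  expect_true(all(fdr_correct(p) >= p))
  o <- sample(10)
  expect_equal(fdr_correct(p)[o], fdr_correct(p[o]))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("residualization centers, orthogonalizes, and matches partial correlation", {
  set.seed(10)
  n <- 80
  Z <- cbind(rnorm(n), rnorm(n))
  y <- rnorm(n)
  r <- residualize(y, Z)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(max(abs(crossprod(scale(Z, scale = FALSE), r))), 1e-8)
  # exact linear function -> zero residuals
  expect_lt(max(abs(residualize(drop(Z %*% c(2, -1)) + 3, Z))), 1e-10)
  # already-orthogonal input comes back centered but unchanged
  yo <- r
  expect_equal(residualize(yo, Z), yo, tolerance = 1e-10)
  # partial correlation identity
  x <- rnorm(n) + Z[, 1]
  y2 <- rnorm(n) + Z[, 1]
  got <- cor(residualize(x, Z), residualize(y2, Z))
  S <- solve(cor(cbind(x, y2, Z)))
  want <- -S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(residualize(y, cbind(Z, Z[, 1])), "rank")
})

test_that("feature-SRS correlations recover construction and respect symmetry", {
  set.seed(11)
  n <- 60
  ft <- data.frame(age = runif(n, 8, 16), full_iq = runif(n, 85, 130),
                   motion = runif(n, 0.05, 0.6),
                   srs_version = rep(1, n))
  ft$srs_total <- 50 + rnorm(n, 0, 8)
  ft$feat <- ft$srs_total + rnorm(n, 0, 2)
  out <- corr_with_srs(ft, "feat", srs_items = "srs_total")
  expect_gt(out$r, 0.9)
  expect_lt(out$p, 1e-6)
  # symmetric in the roles of the two vectors (same covariates)
  ft$srs_aware <- ft$feat
  ft$feat2 <- ft$srs_total
  a <- corr_with_srs(ft, "feat2", srs_items = "srs_aware",
                     feature_covs = c("age", "full_iq"),
                     srs_covs = c("age", "full_iq"))
  b <- corr_with_srs(ft, "srs_aware", srs_items = "feat2",
                     feature_covs = c("age", "full_iq"),
                     srs_covs = c("age", "full_iq"))
  expect_equal(a$r, b$r, tolerance = 1e-12)
  # tiny n is flagged, not computed
  small <- ft[1:4, ]
  out2 <- corr_with_srs(small, "feat", srs_items = "srs_total")
  expect_true(out2$flagged)
  expect_true(is.na(out2$r))
})

test_that("null residualized correlations are calibrated", {
  set.seed(12)
  hits <- vapply(1:1000, function(i) {
    n <- 150
    Z <- cbind(rnorm(n), rnorm(n), rnorm(n))
    x <- residualize(rnorm(n), Z)
    y <- residualize(rnorm(n), Z)
    cor.test(x, y)$p.value < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.035)
  expect_lt(mean(hits), 0.065)
})
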