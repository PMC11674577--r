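#' Harmonize features across scanning sites (ComBat)
#'
#' Removes additive and multiplicative site (batch) effects from the
#' feature columns by parametric empirical-Bayes location/scale
#' harmonization, while protecting the biological design (by default group,
#' age group and their interaction) from removal. TR and eye status are
#' constant within site in the cohorts this package targets, so a single
#' site batch factor absorbs all three.
#'
#' @param ft data frame, one row per subject, containing `features` columns
#'   plus the batch and design columns.
#' @param features character vector of feature column names to harmonize.
#' @param batch name of the batch column (default `"site"`).
#' @param preserve one-sided formula of design effects to protect (default
#'   `~ group * age_group`).
#' @return `ft` with the feature columns harmonized. Constant features are
#'   passed through untouched and listed in attribute
#'   `"constant_features"`. A single batch level is an identity transform.
#' @export
combat_harmonize <- function(ft, features, batch = "site",
                             preserve = ~ group * age_group) {
  stopifnot(is.data.frame(ft), all(features %in% names(ft)),
            batch %in% names(ft))
  b <- factor(ft[[batch]])
  if (any(table(b) < 2L))
    stop("batch level(s) with a single subject: ",
         paste(names(which(table(b) < 2L)), collapse = ", "))
  if (nlevels(b) < 2L) return(ft)
  x <- as.matrix(ft[, features, drop = FALSE])
  if (!is.numeric(x)) stop("features must be numeric")
  if (anyNA(x))
    stop("missing feature values; drop incomplete subjects before ",
         "harmonization")
  const <- features[apply(x, 2L, function(v) stats::sd(v) < 1e-12)]
  keep <- setdiff(features, const)
  if (length(keep)) {
    mod <- if (is.null(preserve)) NULL else
      stats::model.matrix(preserve, data = ft)
    if (!is.null(mod)) {
      # design columns perfectly confounded with batch (e.g. an age-group
      # factor nested in site) cannot be protected; drop them
      B <- stats::model.matrix(~ b)
      resid <- qr.resid(qr(B), mod)
      confounded <- apply(abs(resid), 2L, max) < 1e-8 &
        colnames(mod) != "(Intercept)"
      if (any(confounded)) {
        message("design column(s) confounded with batch, not preserved: ",
                paste(colnames(mod)[confounded], collapse = ", "))
        mod <- mod[, !confounded, drop = FALSE]
      }
      if (ncol(mod) <= 1L) mod <- NULL
    }
    dat <- t(x[, keep, drop = FALSE])
    if (nrow(dat) == 1L) {
      # shrinkage across features is undefined for one feature; apply the
      # direct location/scale adjustment the EB step degenerates to
      ft[, keep] <- .ls_adjust_one(drop(dat), b, mod)
    } else {
      adj <- t(invisible(suppressMessages(
        sva::ComBat(dat = dat, batch = b, mod = mod,
                    par.prior = TRUE, prior.plots = FALSE))))
      ft[, keep] <- adj
    }
  }
  attr(ft, "constant_features") <- const
  ft
}

# location/scale batch adjustment for a single feature: standardize with
# the preserved design, equalize per-batch mean and variance, restore
.ls_adjust_one <- function(y, b, mod) {
  B <- stats::model.matrix(~ 0 + b)
  design <- if (is.null(mod)) B else
    cbind(B, mod[, colnames(mod) != "(Intercept)", drop = FALSE])
  fit <- stats::lm.fit(design, y)
  beta <- fit$coefficients
  nb <- table(b)
  alpha <- sum(beta[seq_len(nlevels(b))] * nb / length(y))
  stand_mean <- rep(alpha, length(y))
  if (ncol(design) > nlevels(b))
    stand_mean <- stand_mean +
      drop(design[, -seq_len(nlevels(b)), drop = FALSE] %*%
             beta[-seq_len(nlevels(b))])
  var_pooled <- mean((y - drop(design %*% beta))^2)
  s <- (y - stand_mean) / sqrt(var_pooled)
  gamma_hat <- unname(tapply(s, b, mean)[as.character(b)])
  delta_hat <- unname(tapply(s, b, stats::var)[as.character(b)])
  sqrt(var_pooled) * (s - gamma_hat) / sqrt(delta_hat) + stand_mean
}

#' Mixed-design (split-plot) ANOVA with covariates
#'
#' Fits the repeated-measures ANOVA used for state-wise features: the state
#' (TNS) is the within-subject factor, group and age group are
#' between-subject factors, and covariates enter the between-subject
#' stratum. Tests use Type-III sums of squares; between-subject effects are
#' tested against the subject-level error and within-subject effects
#' against the subject-by-state error. No sphericity correction is applied
#' by default (`gg = TRUE` switches to Greenhouse-Geisser corrected
#' p-values for within-subject effects).
#'
#' @param ft data frame, one row per subject.
#' @param dv_cols names of the per-state feature columns (within-subject
#'   levels, in state order).
#' @param between names of between-subject factor columns (default
#'   `c("group", "age_group")`; interaction included).
#' @param covariates names of numeric covariate columns (default
#'   `c("full_iq", "motion")`).
#' @param gg apply the Greenhouse-Geisser correction to within-subject
#'   p-values.
#' @return data frame of class `cap_anova`: `effect`, `df1`, `df2`, `F`,
#'   `p`. Subjects with missing values in any used column are dropped (a
#'   message reports how many).
#' @export
mixed_anova <- function(ft, dv_cols, between = c("group", "age_group"),
                        covariates = c("full_iq", "motion"), gg = FALSE) {
  stopifnot(all(c(dv_cols, between, covariates) %in% names(ft)))
  used <- c(dv_cols, between, covariates)
  ok <- stats::complete.cases(ft[, used, drop = FALSE])
  if (!all(ok)) {
    message(sum(!ok), " subject(s) dropped for missing values")
    ft <- ft[ok, , drop = FALSE]
  }
  for (bcol in between) {
    ft[[bcol]] <- factor(ft[[bcol]])
    if (nlevels(droplevels(ft[[bcol]])) < 2L)
      stop("between factor ", bcol, " has fewer than 2 levels")
  }
  if (length(between) > 1L) {
    cell <- interaction(ft[, between, drop = FALSE], drop = FALSE)
    if (any(table(cell) == 0L))
      stop("empty design cell(s): ",
           paste(names(which(table(cell) == 0L)), collapse = ", "))
  }
  Y <- as.matrix(ft[, dv_cols, drop = FALSE])
  rhs <- paste(c(paste(between, collapse = " * "), covariates),
               collapse = " + ")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  if (length(dv_cols) == 1L) {
    fit <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = ft)
    a <- car::Anova(fit, type = 3)
    a <- a[!rownames(a) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
    out <- data.frame(effect = rownames(a), df1 = a$Df,
                      df2 = stats::df.residual(fit), F = a$`F value`,
                      p = a$`Pr(>F)`, row.names = NULL,
                      stringsAsFactors = FALSE)
  } else {
    fit <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = ft)
    idata <- data.frame(tns = factor(seq_along(dv_cols)))
    a <- car::Anova(fit, idata = idata, idesign = ~ tns, type = 3)
    # car caps the Huynh-Feldt epsilon at 1 with a warning; harmless here
    s <- withCallingHandlers(
      summary(a, multivariate = FALSE),
      warning = function(w) {
        if (grepl("HF eps", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    u <- s$univariate.tests
    out <- data.frame(effect = rownames(u), df1 = u[, "num Df"],
                      df2 = u[, "den Df"], F = u[, "F value"],
                      p = u[, "Pr(>F)"], row.names = NULL,
                      stringsAsFactors = FALSE)
    if (gg) {
      pv <- s$pval.adjustments
      hit <- match(rownames(pv), out$effect)
      out$p[hit] <- pv[, "Pr(>F[GG])"]
    }
    out <- out[out$effect != "(Intercept)", , drop = FALSE]
    row.names(out) <- NULL
  }
  class(out) <- c("cap_anova", "data.frame")
  out
}

#' @export
print.cap_anova <- function(x, ...) {
  y <- as.data.frame(x)
  y$F <- signif(y$F, 5)
  y$p <- format.pval(y$p, digits = 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Covariate-adjusted two-sample t test via the general linear model
#'
#' Fits `y ~ group + covariates` by least squares and reports the t
#' statistic and two-sided p-value of the group effect. Without covariates
#' this equals the classical pooled-variance two-sample t test. The group
#' coefficient is the mean of the second factor level minus the first
#' (e.g. with levels `c("CON", "ASD")` a positive t means ASD > CON).
#'
#' @param y numeric response vector.
#' @param group two-level factor (or coercible); both groups need >= 3
#'   observations.
#' @param covariates optional numeric matrix or data frame of covariates.
#' @return one-row data frame: `t`, `df`, `p`, `estimate`, `direction`.
#' @export
glm_ttest <- function(y, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("group must have 2 levels")
  if (any(table(group) < 3L)) stop("each group needs >= 3 observations")
  X <- cbind(`(Intercept)` = 1, g = as.numeric(group == levels(group)[2L]))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tval <- fit$coefficients["g"] / se
  data.frame(t = unname(tval), df = df,
             p = 2 * stats::pt(-abs(tval), df),
             estimate = unname(fit$coefficients["g"]),
             direction = sign(unname(tval)), row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (step-up, monotone, capped at 1), in the
#'   input order.
#' @export
fdr_correct <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Regress covariates out of a vector
#'
#' Returns least-squares residuals of `values` on the covariates plus an
#' intercept; the result has mean zero and is orthogonal to every centered
#' covariate column.
#'
#' @param values numeric vector.
#' @param covariates numeric matrix or data frame (same number of rows).
#' @return residual vector.
#' @export
residualize <- function(values, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (nrow(X) != length(values)) stop("length mismatch")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  qr.resid(qx, values)
}

#' Residualized correlations between features and SRS T scores
#'
#' For every (feature, SRS item) pair: regresses `feature_covs` out of the
#' feature and `srs_covs` out of the score over the subjects with complete
#' records, then reports the Pearson correlation with a two-sided p-value,
#' FDR-adjusted across the whole family of tested pairs.
#'
#' @param ft data frame with one row per subject.
#' @param features feature column names.
#' @param srs_items SRS column names (default the five item T scores plus
#'   total).
#' @param feature_covs covariates removed from features (default age,
#'   full_iq, motion).
#' @param srs_covs covariates removed from scores (default age, full_iq,
#'   srs_version).
#' @param min_n minimum complete pairs; below it the pair is flagged and
#'   not computed (default 5).
#' @return data frame: `feature`, `item`, `n`, `r`, `p`, `fdrp`, `flagged`.
#' @export
corr_with_srs <- function(ft, features,
                          srs_items = c("srs_aware", "srs_cogn", "srs_comm",
                                        "srs_mot", "srs_manner",
                                        "srs_total"),
                          feature_covs = c("age", "full_iq", "motion"),
                          srs_covs = c("age", "full_iq", "srs_version"),
                          min_n = 5L) {
  stopifnot(all(c(features, srs_items, feature_covs, srs_covs) %in%
                  names(ft)))
  out <- expand.grid(feature = features, item = srs_items,
                     stringsAsFactors = FALSE)
  out$n <- 0L; out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    cols <- c(out$feature[i], out$item[i], feature_covs, srs_covs)
    cc <- stats::complete.cases(ft[, unique(cols), drop = FALSE])
    out$n[i] <- sum(cc)
    if (out$n[i] < min_n) next
    d <- ft[cc, , drop = FALSE]
    # covariates constant over the analyzed subjects (e.g. scale version
    # within one age group) carry no information and are dropped
    usable <- function(covs) {
      m <- as.matrix(d[, covs, drop = FALSE])
      m[, apply(m, 2L, stats::sd) > 1e-12, drop = FALSE]
    }
    rf <- residualize(d[[out$feature[i]]], usable(feature_covs))
    rs <- residualize(d[[out$item[i]]], usable(srs_covs))
    if (stats::sd(rf) < 1e-12 || stats::sd(rs) < 1e-12) next
    ct <- stats::cor.test(rf, rs)
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out$fdrp <- NA_real_
  ok <- !is.na(out$p)
  out$fdrp[ok] <- fdr_correct(out$p[ok])
  out$flagged <- out$n < min_n
  out
}
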