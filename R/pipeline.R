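#' Per-subject feature table
#'
#' Combines the cohort manifest with the per-subject, per-state features:
#' dwell times, mean distances to center, mirror-pair dwell sums and the
#' overall mean distance. State columns use `labels` when given (e.g.
#' planted state names after matching), otherwise `tns1 ... tnsk`.
#'
#' @param fit a `cap_fit`; @param fm the fitted `cap_frames`.
#' @param cohort the [cap_cohort].
#' @param labels optional character vector of k state names.
#' @param pair_of optional pair label per state; enables `dwellpair_*`
#'   columns.
#' @return data frame, one row per subject.
#' @export
build_feature_table <- function(fit, fm, cohort, labels = NULL,
                                pair_of = NULL) {
  man <- cohort_manifest(cohort)
  dw <- dwell_table(fit)
  di <- subject_mean_distances(fit, fm)
  if (is.null(labels)) labels <- paste0("tns", seq_len(fit$k))
  lab <- gsub("-", "_", labels)
  names(dw)[-1L] <- paste0("dwell_", lab)
  names(di)[-1L] <- paste0("dist_", lab)
  ft <- merge(merge(man, dw, by = "subject_id"), di, by = "subject_id")
  if (!is.null(pair_of)) {
    for (pl in unique(pair_of)) {
      cols <- paste0("dwell_", lab[pair_of == pl])
      ft[[paste0("dwellpair_", pl)]] <- rowSums(ft[, cols, drop = FALSE])
    }
  }
  ft$mean_dist <- rowMeans(ft[, paste0("dist_", lab), drop = FALSE])
  ft[match(man$subject_id, ft$subject_id), , drop = FALSE]
}

#' Run the full coactivation-pattern analysis
#'
#' Orchestrates the whole analysis on a cohort: normalize and concatenate
#' frames, optionally choose k by the elbow method, cluster, build Z maps
#' and mirror pairs, optionally check site reproducibility, compute
#' distances, dwell times and transitions, harmonize the features across
#' sites, run the mixed ANOVA and covariate-adjusted group tests with FDR
#' correction, correlate features with SRS scores, and (when a reference
#' state is identifiable) run the iSAR-vs-SRS canonical correlation with a
#' permutation test.
#'
#' @param cohort a [cap_cohort] (raw or normalized).
#' @param reference optional ground truth (`cap_ground_truth`) or a k x
#'   parcels template matrix used to label the recovered states; when
#'   absent states are labeled by mirror pair.
#' @param k number of states (used when `select_k = FALSE` or as fallback).
#' @param k_grid elbow grid; @param select_k run the elbow selection.
#' @param tau activation threshold for Z maps, stable regions and iSAR.
#' @param seed master seed; @param n_init k-means replicates.
#' @param n_perm CCA permutations.
#' @param site_repro run within-site reproducibility.
#' @param cca_state state label whose stable-region iSAR values enter the
#'   CCA (default `"SN-p"`); CCA is run on adults, as the group where
#'   spatial-stability deficits are planted/reported.
#' @param out_dir optional directory; results written as CSV/JSON.
#' @return a results bundle (list) with elements `elbow`, `fit`, `zmaps`,
#'   `mirror`, `similarity`, `state_labels`, `site_repro`, `features`
#'   (harmonized), `features_raw`, `anova_dwell`, `anova_dist`, `posthoc`,
#'   `transitions`, `shares`, `sim_trans`, `srs_corr`, `cca`, `config`.
#' @export
run_cap_pipeline <- function(cohort, reference = NULL, k = 6L,
                             k_grid = c(2L, 4L, 6L, 8L, 10L),
                             select_k = TRUE, tau = 0.4, seed = 1L,
                             n_init = 20L, n_perm = 1000L,
                             site_repro = FALSE, cca_state = "SN-p",
                             out_dir = NULL) {
  config <- list(k = k, k_grid = k_grid, select_k = select_k, tau = tau,
                 seed = seed, n_init = n_init, n_perm = n_perm,
                 cca_state = cca_state)
  if (!all(vapply(cohort$subjects, `[[`, TRUE, "normalized")))
    cohort$subjects <- lapply(cohort$subjects, normalize_frames)
  fm <- concatenate_subjects(cohort)
  # standardize frames across parcels once; every stage reuses this space
  fm$x <- standardize_rows(fm$x)
  fm$row_standardized <- TRUE
  elbow <- NULL
  init <- NULL
  if (select_k) {
    elbow <- select_k_elbow(fm, k_grid, seed = seed)
    k <- elbow$k
    init <- elbow$centers[[as.character(k)]]
  }
  fit <- cap_fit(fm, k, seed = seed, n_init = n_init, init_centers = init)
  zmaps <- normalize_tns(fit, tau = tau)
  mirror <- find_mirror_pairs(zmaps)
  sim <- spatial_similarity_matrix(zmaps)
  # label states: against a reference template set when available,
  # otherwise by mirror pair membership
  pair_lab <- state_lab <- NULL
  ref_match <- NULL
  if (!is.null(reference)) {
    tpl <- if (inherits(reference, "cap_ground_truth"))
      reference$templates else as.matrix(reference)
    if (nrow(tpl) == k) {
      ref_match <- match_states(zmaps, tpl)
      state_lab <- rownames(tpl)[ref_match$mapping]
      if (inherits(reference, "cap_ground_truth"))
        pair_lab <- reference$pair_of[ref_match$mapping]
    }
  }
  if (is.null(state_lab)) {
    state_lab <- paste0("tns", seq_len(k))
    pair_lab <- rep(NA_character_, k)
    for (i in seq_len(nrow(mirror$pairs)))
      pair_lab[mirror$pairs[i, ]] <- paste0("pair", i)
  }
  sr <- if (site_repro)
    site_reproducibility(cohort, fit = fit, fm = fm, k = k, seed = seed)
  else NULL
  ftab <- build_feature_table(fit, fm, cohort, labels = state_lab,
                              pair_of = pair_lab)
  tt <- transition_table(fit)
  shares <- if (!anyNA(pair_lab))
    internetwork_share(tt$mean_P, pair_lab) else NULL
  st_corr <- similarity_transition_correlation(sim, tt)
  # harmonize every derived numeric feature across sites
  featcols <- grep("^(dwell_|dist_|dwellpair_|mean_dist)",
                   names(ftab), value = TRUE)
  ft_raw <- ftab
  cc <- stats::complete.cases(ftab[, featcols, drop = FALSE])
  harm <- ftab[cc, , drop = FALSE]
  if (length(unique(harm$site)) > 1L)
    harm <- combat_harmonize(harm, featcols)
  lab_us <- gsub("-", "_", state_lab)
  anova_dwell <- mixed_anova(harm, paste0("dwell_", lab_us))
  anova_dist <- mixed_anova(harm, paste0("dist_", lab_us))
  posthoc <- posthoc_ttests(harm, featcols)
  srs_corr <- NULL
  if ("srs_total" %in% names(harm) && any(!is.na(harm$srs_total))) {
    dwell_cols <- grep("^dwell", names(harm), value = TRUE)
    srs_corr <- list(
      juvenile = corr_with_srs(harm[harm$age_group == "juvenile", ],
                               dwell_cols),
      adult = corr_with_srs(harm[harm$age_group == "adult", ],
                            c(dwell_cols, grep("^dist", names(harm),
                                               value = TRUE))))
  }
  cca <- NULL
  if (cca_state %in% state_lab && "srs_total" %in% names(ftab)) {
    cca <- tryCatch(
      cca_isar_srs(fit, fm, cohort, tns_id = match(cca_state, state_lab),
                   tau = tau, age_group = "adult", n_perm = n_perm,
                   seed = seed),
      error = function(e) {
        warning("iSAR/SRS CCA skipped: ", conditionMessage(e))
        NULL
      })
  }
  bundle <- list(elbow = elbow, fit = fit, zmaps = zmaps, mirror = mirror,
                 similarity = sim, state_labels = state_lab,
                 pair_labels = pair_lab, reference_match = ref_match,
                 site_repro = sr, features = harm, features_raw = ft_raw,
                 anova_dwell = anova_dwell, anova_dist = anova_dist,
                 posthoc = posthoc, transitions = tt, shares = shares,
                 sim_trans = st_corr, srs_corr = srs_corr, cca = cca,
                 config = config)
  class(bundle) <- "cap_results"
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

# group contrasts with covariates, FDR within feature family
posthoc_ttests <- function(ft, featcols,
                           covariates = c("age", "full_iq", "motion")) {
  strata <- list(all = rep(TRUE, nrow(ft)),
                 juvenile = ft$age_group == "juvenile",
                 adult = ft$age_group == "adult")
  out <- list()
  for (snm in names(strata)) {
    d <- ft[strata[[snm]], , drop = FALSE]
    if (length(unique(d$group)) < 2L) next
    grp <- factor(d$group, levels = c("CON", "ASD"))
    res <- do.call(rbind, lapply(featcols, function(fc) {
      r <- tryCatch(glm_ttest(d[[fc]], grp,
                              as.matrix(d[, covariates, drop = FALSE])),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      cbind(data.frame(feature = fc, stratum = snm,
                       stringsAsFactors = FALSE), r)
    }))
    if (!is.null(res)) {
      res$fdrp <- fdr_correct(res$p)
      out[[snm]] <- res
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' iSAR-vs-SRS canonical correlation for one state
#'
#' Determines the stable regions of the state, collects each subject's
#' iSAR values there and the SRS item T scores, residualizes both blocks
#' (age, full IQ and motion from the iSAR block; age, full IQ and scale
#' version from the SRS block), fits the CCA and runs the max-statistic
#' permutation test.
#'
#' @inheritParams isar
#' @param cohort the [cap_cohort] (for SRS scores and covariates).
#' @param age_group restrict to one age group (default `"adult"`; `NULL`
#'   for all).
#' @param max_regions keep at most this many stable regions, by subject
#'   fraction (keeps n comfortably above the variable count).
#' @param n_perm,seed see [cca_permutation_test].
#' @return a `cap_cca` with `p_perm`, plus `regions` (parcel indices) and
#'   `subjects` used.
#' @export
cca_isar_srs <- function(fit, fm, cohort, tns_id, tau = 0.4,
                         age_group = "adult", max_regions = 12L,
                         n_perm = 1000L, seed = 1L) {
  man <- cohort_manifest(cohort)
  keep_ids <- man$subject_id
  if (!is.null(age_group))
    keep_ids <- man$subject_id[man$age_group == age_group]
  sreg <- stable_regions(fit, fm, tns_id, tau = tau, subjects = keep_ids)
  if (!nrow(sreg)) stop("no stable regions for state ", tns_id)
  sreg <- sreg[order(-sreg$fraction), , drop = FALSE]
  regions <- sort(utils::head(sreg$parcel, max_regions))
  isar_m <- isar_table(fit, fm, tns_id, regions, tau = tau)
  items <- c("srs_aware", "srs_cogn", "srs_comm", "srs_mot", "srs_manner",
             "srs_total")
  stopifnot(all(items %in% names(man)))
  rows <- match(keep_ids, man$subject_id)
  d <- man[rows, , drop = FALSE]
  Xi <- isar_m[keep_ids, , drop = FALSE]
  ok <- stats::complete.cases(cbind(Xi, d[, c(items, "age", "full_iq",
                                              "motion", "srs_version")]))
  d <- d[ok, , drop = FALSE]; Xi <- Xi[ok, , drop = FALSE]
  if (nrow(d) <= ncol(Xi) + 2L)
    stop("too few complete subjects (", nrow(d), ") for ", ncol(Xi),
         " iSAR regions")
  usable <- function(covs) {
    m <- as.matrix(d[, covs, drop = FALSE])
    m[, apply(m, 2L, stats::sd) > 1e-12, drop = FALSE]
  }
  X <- apply(Xi, 2L, residualize,
             covariates = usable(c("age", "full_iq", "motion")))
  Y <- apply(as.matrix(d[, items]), 2L, residualize,
             covariates = usable(c("age", "full_iq", "srs_version")))
  res <- cca_permutation_test(X, Y, n_perm = n_perm, seed = seed)
  res$regions <- regions
  res$subjects <- d$subject_id
  res
}

#' @export
print.cap_results <- function(x, ...) {
  cat("CAP analysis results\n")
  if (!is.null(x$elbow))
    cat(sprintf("  selected k = %d%s\n", x$fit$k,
                if (x$elbow$no_elbow) " (no clear elbow)" else ""))
  cat("  states:", paste(x$state_labels, collapse = ", "), "\n")
  cat("  mirror pair r:", paste(sprintf("%+.2f", x$mirror$r),
                                collapse = ", "), "\n")
  if (!is.null(x$shares))
    cat("  internetwork shares:",
        paste(sprintf("%s=%.3f", names(x$shares$shares), x$shares$shares),
              collapse = " "),
        sprintf(" (within-pair %.3f)", x$shares$within_pair), "\n")
  if (!is.null(x$cca))
    cat(sprintf("  iSAR/SRS CCA: r1 = %.3f, corrected p = %.4g\n",
                x$cca$cor[1L], x$cca$p_perm[1L]))
  invisible(x)
}

# short stable hash of the configuration (FNV-1a over its deparse)
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a results bundle as plain text tables
#'
#' Emits CSVs (Z maps with masks, SSE curve, features, ANOVA tables, post
#' hoc tests, transition matrices, SRS correlations, CCA loadings) and a
#' JSON run manifest carrying the configuration and its hash.
#'
#' @param bundle a `cap_results`; @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  zm <- bundle$zmaps
  k <- nrow(zm$z)
  w(data.frame(tns = rep(bundle$state_labels, each = ncol(zm$z)),
               parcel_id = rep(zm$parcel_ids, k),
               z = as.vector(t(zm$z)), mask = as.vector(t(zm$mask))),
    "zmaps.csv")
  if (!is.null(bundle$elbow))
    w(data.frame(k = bundle$elbow$k_grid, sse = bundle$elbow$sse),
      "sse_curve.csv")
  w(bundle$features, "features_harmonized.csv")
  w(bundle$features_raw, "features_raw.csv")
  # long-format per-subject feature tables
  fr <- bundle$features_raw
  lab <- gsub("-", "_", bundle$state_labels)
  long <- do.call(rbind, lapply(c("dwell", "dist"), function(feat)
    do.call(rbind, lapply(seq_along(lab), function(c)
      data.frame(subject_id = fr$subject_id,
                 tns = bundle$state_labels[c], feature = feat,
                 value = fr[[paste0(feat, "_", lab[c])]])))))
  w(long, "features_long.csv")
  tp <- bundle$transitions$P
  w(data.frame(subject_id = rep(dimnames(tp)[[3]], each = k * k),
               from = rep(bundle$state_labels, times = k),
               to = rep(bundle$state_labels, each = k),
               p = as.vector(tp)), "transitions_subject.csv")
  w(as.data.frame(bundle$anova_dwell), "anova_dwell.csv")
  w(as.data.frame(bundle$anova_dist), "anova_dist.csv")
  if (!is.null(bundle$posthoc)) w(bundle$posthoc, "posthoc_ttests.csv")
  mp <- bundle$transitions$mean_P
  w(data.frame(from = rep(bundle$state_labels, k),
               to = rep(bundle$state_labels, each = k),
               p = as.vector(mp)), "transition_mean.csv")
  if (!is.null(bundle$srs_corr)) {
    w(bundle$srs_corr$juvenile, "srs_corr_juvenile.csv")
    w(bundle$srs_corr$adult, "srs_corr_adult.csv")
  }
  if (!is.null(bundle$cca)) {
    w(data.frame(block = c(rep("isar", length(bundle$cca$loadings_x)),
                           rep("srs", length(bundle$cca$loadings_y))),
                 variable = c(paste0("parcel_", bundle$cca$regions),
                              names(bundle$cca$loadings_y)),
                 loading = c(bundle$cca$loadings_x,
                             bundle$cca$loadings_y)),
      "cca_loadings.csv")
    w(data.frame(cv1_x = bundle$cca$x_scores[, 1L],
                 cv1_y = bundle$cca$y_scores[, 1L],
                 subject_id = bundle$cca$subjects), "cca_scores.csv")
  }
  manifest <- list(config = bundle$config,
                   config_hash = config_hash(bundle$config),
                   k = bundle$fit$k, state_labels = bundle$state_labels,
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
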