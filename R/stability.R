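#' Distance of a frame to a cluster center
#'
#' Defined as one minus the Pearson correlation between the frame and the
#' center across parcels; ranges from 0 (identical pattern) to 2 (opposite
#' pattern).
#'
#' @param frame,centre numeric parcel vectors (non-constant).
#' @return scalar distance in \[0, 2\].
#' @export
frame_distance <- function(frame, centre) {
  if (stats::sd(frame) < 1e-12 || stats::sd(centre) < 1e-12)
    stop("constant vector: correlation distance undefined")
  1 - stats::cor(frame, centre)
}

# distances of all frames to their assigned centers (vectorized per cluster)
.all_frame_distances <- function(fit, x) {
  d <- numeric(nrow(x))
  p <- ncol(x)
  xs <- standardize_rows(x)
  for (c in seq_len(fit$k)) {
    rows <- which(fit$assignments == c)
    if (!length(rows)) next
    mu <- fit$centers[c, ]
    mu <- mu - mean(mu)
    s <- sqrt(sum(mu^2) / (p - 1))
    if (s < 1e-12) stop("constant center in cluster ", c)
    r <- drop(xs[rows, , drop = FALSE] %*% (mu / s)) / (p - 1)
    d[rows] <- 1 - r
  }
  d
}

#' Per-subject mean distance to center for each state
#'
#' Averages the frame-to-center correlation distance over each subject's
#' frames within each state. Cells for states a subject never visits are
#' `NA` (missing, never zero).
#'
#' @param fit a `cap_fit` carrying a frame index.
#' @param fm the `cap_frames` the model was fit on.
#' @return data frame, one row per subject, columns `subject_id` and
#'   `dist_1 ... dist_k`; per-frame distances attached as attribute
#'   `"frame_distances"`.
#' @export
subject_mean_distances <- function(fit, fm) {
  stopifnot(inherits(fit, "cap_fit"), inherits(fm, "cap_frames"))
  x <- .prep_frames(fit, fm)
  d <- .all_frame_distances(fit, x)
  ids <- unique(fm$frame_index$subject_id)
  sub <- factor(fm$frame_index$subject_id, levels = ids)
  a <- factor(fit$assignments, levels = seq_len(fit$k))
  sums <- tapply(d, list(sub, a), sum)
  cnt <- table(sub, a)
  m <- sums / ifelse(cnt > 0, cnt, NA)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (c in seq_len(fit$k)) out[[paste0("dist_", c)]] <- m[, c]
  attr(out, "frame_distances") <- d
  out
}

#' Within-site reproducibility of the states
#'
#' Re-runs the CAP clustering within each site at the same `k`, normalizes
#' the site-level states, and matches them to the cohort-level states by
#' optimal assignment on spatial correlation. Reports matched similarities
#' site-vs-global and between every pair of sites. Sites with fewer than
#' `min_frames` frames are skipped with a warning.
#'
#' @param cohort a normalized [cap_cohort].
#' @param fit the cohort-level `cap_fit`; computed here if `NULL`.
#' @param fm the cohort-level `cap_frames`; built here if `NULL`.
#' @param k number of states for the site-level clusterings.
#' @param seed,n_init,search_n forwarded to the site-level [cap_fit] calls.
#' @param min_frames minimum frames a site needs (default `10 * k`).
#' @return list with `site_vs_global` (sites x k matrix of matched r),
#'   `site_pair` (k x sites x sites array of matched r), `zmaps` (per-site
#'   globally-aligned `cap_zmaps`), `skipped`.
#' @export
site_reproducibility <- function(cohort, fit = NULL, fm = NULL, k = 6L,
                                 seed = 1L, n_init = 10L, search_n = 20000L,
                                 min_frames = 10L * k) {
  stopifnot(inherits(cohort, "cap_cohort"))
  if (is.null(fm)) fm <- concatenate_subjects(cohort)
  if (is.null(fit)) fit <- cap_fit(fm, k, seed = seed, n_init = n_init,
                                   search_n = search_n)
  gz <- normalize_tns(fit)
  site_of <- vapply(cohort$subjects, `[[`, "", "site")
  sites <- unique(site_of)
  frame_site <- site_of[match(fm$frame_index$subject_id,
                              names(cohort$subjects))]
  zmaps <- list(); skipped <- character(0)
  for (s in sites) {
    rows <- which(frame_site == s)
    if (length(rows) < min_frames) {
      warning("site ", s, " has only ", length(rows),
              " frames; skipped (needs ", min_frames, ")")
      skipped <- c(skipped, s)
      next
    }
    sf <- cap_fit(fm$x[rows, , drop = FALSE], k, seed = seed,
                  n_init = n_init, row_standardize = fit$row_standardize,
                  sd_type = fit$sd_type, search_n = search_n)
    sz <- normalize_tns(sf, tau = gz$tau)
    m <- match_states(gz, sz)
    sz$z <- sz$z[m$mapping, , drop = FALSE]      # align to global order
    sz$mask <- sz$mask[m$mapping, , drop = FALSE]
    sz$global_match_r <- m$similarity
    zmaps[[s]] <- sz
  }
  used <- names(zmaps)
  svg <- do.call(rbind, lapply(zmaps, `[[`, "global_match_r"))
  if (!is.null(svg)) dimnames(svg) <- list(used, paste0("tns_", seq_len(k)))
  sp <- array(NA_real_, c(k, length(used), length(used)),
              dimnames = list(paste0("tns_", seq_len(k)), used, used))
  for (i in seq_along(used)) for (j in seq_along(used)) {
    zi <- zmaps[[i]]$z; zj <- zmaps[[j]]$z
    sp[, i, j] <- vapply(seq_len(k), function(c)
      stats::cor(zi[c, ], zj[c, ]), 0)
  }
  list(site_vs_global = svg, site_pair = sp, zmaps = zmaps,
       skipped = skipped)
}

# individual-specific state maps for all subjects in one state:
# subjects x parcels matrix of (mean member frame)/within-sd, plus N
.individual_tns_all <- function(fit, fm, tns_id,
                                sd_mode = c("global", "subject")) {
  sd_mode <- match.arg(sd_mode)
  x <- .prep_frames(fit, fm)
  rows <- which(fit$assignments == tns_id)
  ids <- unique(fm$frame_index$subject_id)
  sub <- factor(fm$frame_index$subject_id[rows], levels = ids)
  n_frames <- as.integer(table(sub))
  names(n_frames) <- ids
  sums <- rowsum(x[rows, , drop = FALSE], sub)   # levels with 0 rows absent
  means <- matrix(NA_real_, length(ids), ncol(x),
                  dimnames = list(ids, fit$parcel_ids))
  present <- ids[n_frames > 0L]
  means[present, ] <- sums[present, , drop = FALSE] / n_frames[present]
  # sd floored at a tiny epsilon: in the noiseless limit a nonzero mean
  # must stay suprathreshold rather than collapse to zero
  if (sd_mode == "global") {
    ws <- pmax(fit$within_sd[tns_id, ], 1e-12)
    z <- sweep(means, 2L, ws, "/")
  } else {
    z <- means
    for (id in present) {
      r <- rows[sub == id]
      if (length(r) < 2L) { z[id, ] <- NA_real_; next }
      m <- means[id, ]
      s <- pmax(sqrt(pmax(colMeans(x[r, , drop = FALSE]^2) - m^2, 0)),
                1e-12)
      z[id, ] <- m / s
    }
  }
  list(z = z, n_frames = n_frames, member_rows = rows, sub = sub)
}

#' Individual-specific state map for one subject
#'
#' The average of the subject's frames assigned to the state, divided by
#' the within-cluster standard deviation (cohort-level sd by default,
#' subject-level with `sd_mode = "subject"`). Undefined (all-`NA`, flagged)
#' when the subject has no frames in the state.
#'
#' @param fit a `cap_fit`; @param fm the fitted `cap_frames`.
#' @param subject_id subject identifier; @param tns_id state index.
#' @param sd_mode `"global"` (default) or `"subject"`.
#' @return list with `z_ind` (parcel vector), `n_frames`, `defined`.
#' @export
individual_tns <- function(fit, fm, subject_id, tns_id,
                           sd_mode = c("global", "subject")) {
  all <- .individual_tns_all(fit, fm, tns_id, sd_mode)
  if (!subject_id %in% rownames(all$z))
    stop("unknown subject: ", subject_id)
  n <- all$n_frames[[subject_id]]
  list(subject_id = subject_id, tns_id = tns_id,
       z_ind = all$z[subject_id, ], n_frames = n, defined = n > 0L)
}

#' Stable regions of a state across subjects
#'
#' A parcel is a stable activated (deactivated) region of a state when
#' strictly more than `majority` of the subjects with a defined individual
#' map have individual intensity above `tau` (below `-tau`) there.
#'
#' @inheritParams individual_tns
#' @param tau activation threshold (default 0.4).
#' @param majority required fraction of subjects (default 0.5; strict).
#' @param subjects optional subset of subject ids to pool (default all).
#' @return data frame with columns `parcel` (index), `parcel_id`,
#'   `direction` (+1/-1), `fraction`.
#' @export
stable_regions <- function(fit, fm, tns_id, tau = 0.4, majority = 0.5,
                           sd_mode = c("global", "subject"),
                           subjects = NULL) {
  all <- .individual_tns_all(fit, fm, tns_id, sd_mode)
  z <- all$z
  if (!is.null(subjects)) z <- z[rownames(z) %in% subjects, , drop = FALSE]
  defined <- !is.na(z[, 1L])
  if (sum(defined) < 2L)
    stop("fewer than 2 subjects with defined individual maps for state ",
         tns_id)
  z <- z[defined, , drop = FALSE]
  fa <- colMeans(z > tau)
  fd <- colMeans(z < -tau)
  act <- which(fa > majority)
  dea <- which(fd > majority)
  out <- data.frame(
    parcel = c(act, dea),
    parcel_id = if (is.null(fit$parcel_ids)) as.character(c(act, dea)) else
      fit$parcel_ids[c(act, dea)],
    direction = rep(c(1L, -1L), c(length(act), length(dea))),
    fraction = c(fa[act], fd[dea]), row.names = NULL,
    stringsAsFactors = FALSE)
  out[order(out$parcel), , drop = FALSE]
}

# iSAR for all subjects on a set of parcels: subjects x parcels matrix
.isar_all <- function(fit, fm, tns_id, parcels, tau = 0.4) {
  x <- .prep_frames(fit, fm)
  rows <- which(fit$assignments == tns_id)
  ids <- unique(fm$frame_index$subject_id)
  sub <- factor(fm$frame_index$subject_id[rows], levels = ids)
  ws <- pmax(fit$within_sd[tns_id, parcels], 1e-12)
  intens <- sweep(x[rows, parcels, drop = FALSE], 2L, ws, "/")
  hit <- abs(intens) > tau
  n_frames <- as.integer(table(sub))
  names(n_frames) <- ids
  cnt <- matrix(NA_real_, length(ids), length(parcels),
                dimnames = list(ids, NULL))
  present <- ids[n_frames > 0L]
  hs <- rowsum(hit + 0, sub)
  cnt[present, ] <- hs[present, , drop = FALSE] / n_frames[present]
  list(isar = cnt, n_frames = n_frames)
}

#' Individual-level stable activation rate (iSAR)
#'
#' For a subject, a state and a stable region: the fraction n/N of the
#' subject's N frames in the state whose normalized intensity (frame value
#' divided by the within-cluster sd) exceeds `tau` in absolute value.
#'
#' @inheritParams individual_tns
#' @param parcels integer parcel indices (typically from [stable_regions]).
#' @param tau activation threshold (default 0.4).
#' @return data frame with one row per parcel: `subject_id`, `tns_id`,
#'   `parcel`, `n`, `N`, `isar` (`NA` and flagged when N = 0).
#' @export
isar <- function(fit, fm, subject_id, tns_id, parcels, tau = 0.4) {
  all <- .isar_all(fit, fm, tns_id, parcels, tau)
  if (!subject_id %in% rownames(all$isar))
    stop("unknown subject: ", subject_id)
  N <- all$n_frames[[subject_id]]
  rate <- all$isar[subject_id, ]
  data.frame(subject_id = subject_id, tns_id = tns_id, parcel = parcels,
             n = if (N > 0L) as.integer(round(rate * N)) else NA_integer_,
             N = N, isar = rate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' iSAR values for all subjects on the stable regions of a state
#'
#' @inheritParams isar
#' @return subjects x parcels matrix of iSAR values (rownames subject ids,
#'   `NA` rows for subjects never visiting the state); `n_frames` attached
#'   as an attribute.
#' @export
isar_table <- function(fit, fm, tns_id, parcels, tau = 0.4) {
  all <- .isar_all(fit, fm, tns_id, parcels, tau)
  out <- all$isar
  colnames(out) <- if (is.null(fit$parcel_ids)) as.character(parcels) else
    fit$parcel_ids[parcels]
  attr(out, "n_frames") <- all$n_frames
  out
}
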