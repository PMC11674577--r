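#' Fit transient network states by frame-wise k-means
#'
#' Clusters the rows of a concatenated frame matrix into `k` coactivation
#' patterns (transient network states, TNSs). By default each frame is first
#' standardized across parcels (mean 0, sd 1 within the row), which makes
#' squared Euclidean distance monotone in one minus the spatial Pearson
#' correlation, so the clustering groups frames by spatial similarity.
#' k-means runs `n_init` greedy k-means++ replicates and keeps the solution
#' with the lowest total within-cluster sum of squared error (SSE); for
#' large matrices the replicate search runs on a fixed random subsample of
#' frames and the best solution is then polished on all frames (see
#' `search_n`).
#'
#' @param fm a `cap_frames` object from [concatenate_subjects], or a plain
#'   numeric matrix of frames.
#' @param k number of states (>= 2).
#' @param seed integer seed; the fit is deterministic given `(seed, n_init)`.
#' @param n_init number of k-means++ replicates.
#' @param row_standardize standardize each frame across parcels before
#'   clustering (default TRUE; set FALSE for raw Euclidean k-means).
#' @param sd_type convention for the within-cluster standard deviation
#'   entering the Z maps: `"population"` (divide by n, default) or
#'   `"sample"`.
#' @param search_n replicate search subsample size (`Inf` to search on all
#'   frames).
#' @param iter_max Lloyd iteration cap for the final polish.
#' @param init_centers optional k x parcels matrix of starting centers (in
#'   the clustering space); when given the replicate search is skipped and
#'   the centers are polished directly on all frames.
#' @return object of class `cap_fit` with elements `k`, `centers` (k x
#'   parcels), `assignments` (one state index per frame), `sizes`,
#'   `within_sd` (k x parcels), `sse`, `frame_index`, `parcel_ids`,
#'   `row_standardize`, `sd_type`, `seed`, `n_init`, `converged`.
#' @seealso [normalize_tns], [select_k_elbow], [subject_mean_distances],
#'   [dwell_table]
#' @export
cap_fit <- function(fm, k, seed = 1L, n_init = 20L, row_standardize = TRUE,
                    sd_type = c("population", "sample"),
                    search_n = 20000L, iter_max = 100L,
                    init_centers = NULL) {
  sd_type <- match.arg(sd_type)
  x <- frames_matrix(fm)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (nrow(x) <= k) stop("k = ", k, " >= number of frames (", nrow(x), ")")
  if (row_standardize && !.prestandardized(fm))
    x <- standardize_rows(x)
  set.seed(seed)
  km <- if (is.null(init_centers))
    .kmeans_fit(x, k, n_init = n_init, iter_max = iter_max,
                search_n = search_n)
  else .lloyd(x, as.matrix(init_centers), rowSums(x^2),
              iter_max = iter_max)
  dimnames(km$centers) <- NULL
  ws <- within_cluster_sd(x, km$assignments, km$centers, sd_type)
  dimnames(ws) <- NULL
  structure(list(
    k = k, centers = km$centers, assignments = km$assignments,
    sizes = tabulate(km$assignments, k), within_sd = ws, sse = km$sse,
    frame_index = if (inherits(fm, "cap_frames")) fm$frame_index else NULL,
    parcel_ids = if (inherits(fm, "cap_frames")) fm$parcel_ids else
      colnames(x),
    row_standardize = row_standardize, sd_type = sd_type,
    seed = as.integer(seed), n_init = as.integer(n_init),
    converged = km$converged, iter = km$iter), class = "cap_fit")
}

frames_matrix <- function(fm) {
  if (inherits(fm, "cap_frames")) fm$x
  else if (is.matrix(fm) && is.numeric(fm)) fm
  else stop("fm must be a cap_frames object or a numeric matrix")
}

# standardize each row to mean 0, sd 1 across columns (sample sd);
# constant rows are left at zero
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  x <- x - mu
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1))
  s[s < 1e-12] <- 1
  x / s
}

.prestandardized <- function(fm) {
  inherits(fm, "cap_frames") && isTRUE(fm$row_standardized)
}

# frames of fm in the space the model was fit in
.prep_frames <- function(fit, fm) {
  x <- frames_matrix(fm)
  if (isTRUE(fit$row_standardize) && !.prestandardized(fm))
    x <- standardize_rows(x)
  x
}

within_cluster_sd <- function(x, a, centers, sd_type) {
  k <- nrow(centers)
  sizes <- tabulate(a, k)
  ssq <- rowsum(x^2, a)
  m2 <- ssq / sizes - centers^2
  m2[m2 < 0] <- 0
  if (sd_type == "sample") {
    if (any(sizes < 2L))
      stop("singleton cluster(s): ", paste(which(sizes < 2L), collapse = ", "),
           " (sample sd undefined)")
    m2 <- m2 * (sizes / (sizes - 1))
  }
  sqrt(m2)
}

#' @export
print.cap_fit <- function(x, ...) {
  cat(sprintf("Frame-wise k-means CAP model: k = %d states, %d frames\n",
              x$k, length(x$assignments)))
  cat("State sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("Total within-cluster SSE: %.4g (%sconverged, %d iterations)\n",
              x$sse, if (x$converged) "" else "not ", x$iter))
  invisible(x)
}

#' @export
summary.cap_fit <- function(object, tau = 0.4, ...) {
  zm <- normalize_tns(object)
  mp <- find_mirror_pairs(zm)
  out <- list(k = object$k, sizes = object$sizes, sse = object$sse,
              occupancy = object$sizes / sum(object$sizes),
              mirror_pairs = mp,
              similarity = spatial_similarity_matrix(zm), tau = tau)
  class(out) <- "summary.cap_fit"
  out
}

#' @export
print.summary.cap_fit <- function(x, ...) {
  cat(sprintf("CAP model with %d transient network states\n", x$k))
  cat("Occupancy (fraction of all frames):",
      paste(sprintf("%.3f", x$occupancy), collapse = ", "), "\n")
  cat("Mirror pairs (state, state, spatial r):\n")
  mp <- x$mirror_pairs
  for (i in seq_len(nrow(mp$pairs)))
    cat(sprintf("  %d <-> %d  r = %+.3f%s\n", mp$pairs[i, 1], mp$pairs[i, 2],
                mp$r[i], if (mp$flagged[i]) "  [not mirror-like]" else ""))
  invisible(x)
}

#' @export
coef.cap_fit <- function(object, type = c("centers", "z"), ...) {
  type <- match.arg(type)
  if (type == "centers") object$centers else normalize_tns(object)$z
}

#' Assign new frames to the fitted states
#'
#' @param object a `cap_fit`.
#' @param newdata `cap_frames` or matrix of frames (same parcel order); the
#'   same row standardization used at fit time is applied.
#' @param ... unused.
#' @return integer vector of state assignments.
#' @export
predict.cap_fit <- function(object, newdata, ...) {
  x <- .prep_frames(object, newdata)
  score <- tcrossprod(x, object$centers)
  score <- sweep(score, 2L, rowSums(object$centers^2) / 2, "-")
  max.col(score, ties.method = "first")
}

#' @export
residuals.cap_fit <- function(object, fm, ...) {
  x <- .prep_frames(object, fm)
  x - object$centers[object$assignments, , drop = FALSE]
}

#' @export
fitted.cap_fit <- function(object, ...) {
  object$centers[object$assignments, , drop = FALSE]
}

#' Choose the number of states with the elbow method
#'
#' Computes the k-means SSE over a grid of candidate `k` and selects the
#' elbow as the interior grid point maximizing the discrete second
#' difference of the SSE curve. When no second difference exceeds 5% of the
#' total SSE range the curve is considered elbow-free: the smallest grid k
#' is returned with a warning and `no_elbow = TRUE`. To keep the curve
#' comparable across k the SSE is evaluated on one fixed random subsample
#' of at most `search_n` frames (all frames when fewer).
#'
#' @inheritParams cap_fit
#' @param k_grid strictly increasing integer grid of length >= 3.
#' @param n_init replicates per grid point.
#' @return object of class `cap_elbow`: `k` (selected), `k_grid`, `sse`
#'   (curve), `second_diff`, `no_elbow`.
#' @export
select_k_elbow <- function(fm, k_grid = c(2L, 4L, 6L, 8L, 10L), seed = 1L,
                           n_init = 5L, row_standardize = TRUE,
                           search_n = 20000L, iter_max = 50L) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) < 3L) stop("k_grid must have at least 3 values")
  if (any(diff(k_grid) <= 0L)) stop("k_grid must be strictly increasing")
  x <- frames_matrix(fm)
  if (row_standardize && !.prestandardized(fm))
    x <- standardize_rows(x)
  set.seed(seed)
  n <- nrow(x)
  if (is.finite(search_n) && search_n < n)
    x <- x[sample.int(n, search_n), , drop = FALSE]
  xsq <- rowSums(x^2)
  centers <- list()
  sse <- vapply(k_grid, function(k) {
    best <- Inf
    for (r in seq_len(n_init)) {
      c0 <- x[.kmeanspp_init(x, k, xsq), , drop = FALSE]
      run <- .lloyd(x, c0, xsq, iter_max = iter_max)
      if (run$sse < best) {
        best <- run$sse
        centers[[as.character(k)]] <<- run$centers
      }
    }
    best
  }, 0)
  names(sse) <- k_grid
  interior <- 2:(length(k_grid) - 1L)
  d2 <- sse[interior - 1L] - 2 * sse[interior] + sse[interior + 1L]
  names(d2) <- k_grid[interior]
  rng <- max(sse) - min(sse)
  # a real elbow needs curvature that stands out against the curve's total
  # drop AND a kink: the slope after the candidate must collapse relative
  # to the slope entering it (a smoothly decaying curve has neither)
  best <- interior[which.max(d2)]
  drop_before <- sse[best - 1L] - sse[best]
  drop_after <- sse[best] - sse[best + 1L]
  no_elbow <- rng <= 0 || max(d2) < 0.05 * rng ||
    (drop_before > 0 && drop_after > 0.5 * drop_before)
  if (no_elbow) {
    warning("no clear elbow in the SSE curve; returning smallest k")
    k_sel <- k_grid[1L]
  } else k_sel <- k_grid[best]
  structure(list(k = k_sel, k_grid = k_grid, sse = sse, second_diff = d2,
                 no_elbow = no_elbow, centers = centers,
                 seed = as.integer(seed)),
            class = "cap_elbow")
}

#' @export
print.cap_elbow <- function(x, ...) {
  cat("SSE curve:\n")
  print(signif(x$sse, 6))
  cat(if (x$no_elbow) "No clear elbow; smallest k returned: "
      else "Elbow at k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' @export
plot.cap_elbow <- function(x, ...) {
  graphics::plot(x$k_grid, x$sse, type = "b", xlab = "k",
                 ylab = "total within-cluster SSE", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Normalized state maps (Z maps)
#'
#' Divides each state's center by its within-cluster standard deviation,
#' parcel by parcel, yielding a dimensionless intensity comparable across
#' states. Parcels with (numerically) zero within-cluster sd get z = 0 and
#' are flagged.
#'
#' @param fit a `cap_fit` (every cluster must have >= 2 member frames).
#' @param tau activation threshold applied by [threshold_map] (stored).
#' @return object of class `cap_zmaps`: `z` (k x parcels), `mask` (k x
#'   parcels, -1/0/+1 for deactivated/neutral/activated), `tau`, `flagged`
#'   (logical k x parcels), `parcel_ids`.
#' @export
normalize_tns <- function(fit, tau = 0.4) {
  stopifnot(inherits(fit, "cap_fit"))
  if (any(fit$sizes < 2L))
    stop("singleton cluster(s): ",
         paste(which(fit$sizes < 2L), collapse = ", "))
  ws <- fit$within_sd
  flagged <- ws < 1e-12
  ws[flagged] <- 1
  z <- fit$centers / ws
  z[flagged] <- 0
  zm <- structure(list(z = z, tau = tau, flagged = flagged,
                       parcel_ids = fit$parcel_ids), class = "cap_zmaps")
  threshold_map(zm, tau)
}

#' Apply an activation threshold to Z maps
#'
#' A parcel is activated when z > tau, deactivated when z < -tau, neutral
#' otherwise (strict inequalities: values exactly at the threshold are
#' neutral).
#'
#' @param zmaps a `cap_zmaps` object (or any list with a `z` matrix).
#' @param tau positive threshold (default 0.4).
#' @return the `cap_zmaps` with updated `mask` and `tau`.
#' @export
threshold_map <- function(zmaps, tau = 0.4) {
  if (tau <= 0) stop("tau must be positive")
  z <- zmaps$z
  mask <- matrix(0L, nrow(z), ncol(z))
  mask[z > tau] <- 1L
  mask[z < -tau] <- -1L
  zmaps$mask <- mask
  zmaps$tau <- tau
  zmaps
}

#' @export
print.cap_zmaps <- function(x, ...) {
  cat(sprintf("<cap_zmaps> %d states x %d parcels, tau = %g\n",
              nrow(x$z), ncol(x$z), x$tau))
  cat("activated / deactivated parcels per state:",
      paste(sprintf("%d/%d", rowSums(x$mask == 1L), rowSums(x$mask == -1L)),
            collapse = ", "), "\n")
  invisible(x)
}

.zmat <- function(z) {
  if (inherits(z, "cap_zmaps")) z$z
  else if (inherits(z, "cap_fit")) normalize_tns(z)$z
  else as.matrix(z)
}

#' Pairwise spatial similarity of state maps
#'
#' @param zmaps `cap_zmaps`, `cap_fit`, or a states x parcels matrix.
#' @return symmetric matrix of Pearson correlations, unit diagonal.
#' @export
spatial_similarity_matrix <- function(zmaps) {
  z <- .zmat(zmaps)
  if (nrow(z) < 2L) stop("need at least 2 maps")
  r <- stats::cor(t(z))
  (r + t(r)) / 2
}

# exact solution of the linear assignment problem by permutation
# enumeration (n <= 8 everywhere in this package); maximizes sum of s
.assign_exact <- function(s) {
  n <- nrow(s)
  perms <- .permutations(n)
  tot <- apply(perms, 1L, function(p) sum(s[cbind(seq_len(n), p)]))
  perms[which.max(tot), ]
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

.assign_greedy <- function(s) {
  n <- nrow(s)
  map <- integer(n)
  free <- rep(TRUE, n)
  for (i in order(apply(s, 1, max), decreasing = TRUE)) {
    j <- which(free)[which.max(s[i, free])]
    map[i] <- j
    free[j] <- FALSE
  }
  map
}

#' Match two sets of state maps by spatial similarity
#'
#' Finds the bijection between the states of `a` and `b` maximizing the
#' total absolute Pearson correlation of matched maps (exact optimal
#' assignment for k <= 8, greedy beyond). Matching on the magnitude keeps
#' sign-flipped versions of the same pattern matched to each other; the
#' reported similarities are signed, so a flip is visible as r near -1.
#'
#' @param a,b `cap_zmaps`, `cap_fit`, or states x parcels matrices with the
#'   same number of states.
#' @return list with `mapping` (index into `b` for each state of `a`),
#'   `similarity` (matched signed Pearson r per state of `a`) and
#'   `cor_matrix`.
#' @export
match_states <- function(a, b) {
  za <- .zmat(a); zb <- .zmat(b)
  if (nrow(za) != nrow(zb)) stop("state-count mismatch: ", nrow(za), " vs ",
                                 nrow(zb))
  s <- stats::cor(t(za), t(zb))
  map <- if (nrow(s) <= 8L) .assign_exact(abs(s)) else
    .assign_greedy(abs(s))
  map <- unname(map)
  list(mapping = map,
       similarity = unname(s[cbind(seq_len(nrow(s)), map)]),
       cor_matrix = s)
}

# all perfect matchings of 1..n (n even); list of 2-column matrices
.pairings <- function(idx) {
  n <- length(idx)
  if (n == 2L) return(list(matrix(idx, 1, 2)))
  first <- idx[1L]
  out <- list()
  for (j in 2:n) {
    rest <- idx[-c(1L, j)]
    for (sub in .pairings(rest))
      out[[length(out) + 1L]] <- rbind(c(first, idx[j]), sub)
  }
  out
}

#' Pair states into mirror pairs
#'
#' Pairs the states so that the summed pairwise spatial correlation is
#' minimized (mirror patterns correlate strongly negatively). For an even
#' number of states up to 12 the optimal perfect matching is found by
#' enumeration; otherwise states are paired greedily by most-negative
#' correlation, leaving one state unpaired when the count is odd. Pairs
#' with r > -0.5 are flagged as not mirror-like.
#'
#' @param zmaps `cap_zmaps`, `cap_fit`, or states x parcels matrix.
#' @return list with `pairs` (m x 2 matrix of state indices), `r` (spatial
#'   correlation per pair), `flagged` (r > -0.5), `unpaired`.
#' @export
find_mirror_pairs <- function(zmaps) {
  z <- .zmat(zmaps)
  k <- nrow(z)
  s <- stats::cor(t(z))
  if (k %% 2L == 0L && k <= 12L) {
    cands <- .pairings(seq_len(k))
    tot <- vapply(cands, function(m) sum(s[m]), 0)
    pairs <- cands[[which.min(tot)]]
    unpaired <- integer(0)
  } else {
    pairs <- matrix(0L, 0, 2)
    left <- seq_len(k)
    while (length(left) >= 2L) {
      sub <- s[left, left, drop = FALSE]
      ij <- arrayInd(which.min(sub), dim(sub))
      pairs <- rbind(pairs, left[ij])
      left <- left[-ij]
    }
    unpaired <- left
  }
  pairs <- t(apply(pairs, 1L, sort))
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  r <- s[pairs]
  list(pairs = pairs, r = r, flagged = r > -0.5, unpaired = unpaired)
}

#' Network-level view of the Z maps
#'
#' @param x a `cap_fit`.
#' @param atlas atlas data frame (parcel order must match the fit).
#' @param ... passed to [graphics::image].
#' @export
plot.cap_fit <- function(x, atlas = NULL, ...) {
  z <- normalize_tns(x)$z
  if (!is.null(atlas)) {
    g <- t(apply(z, 1L, function(v) tapply(v, atlas$network, mean)))
    graphics::image(seq_len(nrow(g)), seq_len(ncol(g)), g, xlab = "state",
                    ylab = "", axes = FALSE,
                    main = "network-mean Z by state", ...)
    graphics::axis(1, at = seq_len(nrow(g)))
    graphics::axis(2, at = seq_len(ncol(g)), labels = colnames(g), las = 2)
  } else {
    graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z),
                    xlab = "parcel", ylab = "state", ...)
  }
  invisible(x)
}
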