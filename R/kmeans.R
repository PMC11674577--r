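# Internal k-means engine used for frame-wise clustering.
#
# Lloyd iterations expressed as BLAS cross-products, greedy k-means++
# seeding, best-of-n_init replicates kept by total within-cluster SSE.
# Written for the scale of concatenated frame matrices (tens of thousands of
# rows by hundreds of parcels): the replicate search optionally runs on a
# row subsample and the best solution is then polished on the full matrix
# until the assignment fixpoint, so returned centers are exact member means.

# squared distances from every row of x to one point (length-n vector)
.d2_to_point <- function(x, centre, xsq) {
  d2 <- xsq - 2 * drop(x %*% centre) + sum(centre^2)
  d2[d2 < 0] <- 0
  d2
}

# greedy k-means++ seeding (several candidates per step, keep the one that
# minimizes the resulting potential); returns k row indices of x
.kmeanspp_init <- function(x, k, xsq, n_candidates = NULL) {
  n <- nrow(x)
  if (is.null(n_candidates)) n_candidates <- 2L + as.integer(floor(log(k)))
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- .d2_to_point(x, x[idx[1L], ], xsq)
  if (k > 1L) {
    for (j in 2:k) {
      tot <- sum(d2)
      cand <- if (tot <= 0) sample.int(n, n_candidates) else
        sample.int(n, n_candidates, replace = TRUE, prob = d2 / tot)
      best_pot <- Inf; best_cand <- cand[1L]; best_d2 <- NULL
      for (ci in cand) {
        d2c <- pmin(d2, .d2_to_point(x, x[ci, ], xsq))
        pot <- sum(d2c)
        if (pot < best_pot) { best_pot <- pot; best_cand <- ci; best_d2 <- d2c }
      }
      idx[j] <- best_cand
      d2 <- best_d2
    }
  }
  idx
}

# Lloyd iterations from given starting centers until the assignment fixpoint
# (or iter_max). Returned centers are exact means of the final assignment.
.lloyd <- function(x, centers, xsq, iter_max = 100L) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_old <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # score[i, c] = x_i . mu_c - ||mu_c||^2 / 2; argmax = nearest center
    score <- tcrossprod(x, centers)
    score <- sweep(score, 2L, rowSums(centers^2) / 2, "-")
    a <- max.col(score, ties.method = "first")
    sizes <- tabulate(a, nbins = k)
    if (any(sizes == 0L)) {
      # re-seed each empty cluster at the point farthest from its center
      d2 <- xsq - 2 * score[cbind(seq_len(n), a)]
      for (c_empty in which(sizes == 0L)) {
        far <- which.max(d2)
        a[far] <- c_empty
        d2[far] <- -Inf
      }
      sizes <- tabulate(a, nbins = k)
    }
    converged <- identical(a, assign_old)
    if (converged || iter >= iter_max) {
      centers <- rowsum(x, a) / sizes
      score <- tcrossprod(x, centers)
      score <- sweep(score, 2L, rowSums(centers^2) / 2, "-")
      sse <- sum(xsq) - 2 * sum(score[cbind(seq_len(n), a)])
      return(list(assignments = max.col(score, ties.method = "first"),
                  centers = centers, sse = sse, iter = iter,
                  converged = converged))
    }
    assign_old <- a
    centers <- rowsum(x, a) / sizes
  }
}

# Best-of-n_init k-means. Deterministic given the RNG state on entry.
# search_n < nrow(x): replicate search runs on a fixed random row subsample,
# then the best centers are polished on the full matrix.
.kmeans_fit <- function(x, k, n_init = 10L, iter_max = 100L,
                        search_n = 20000L, search_iter_max = 50L) {
  stopifnot(is.matrix(x), k >= 2L)
  n <- nrow(x)
  if (n <= k) stop("need more rows than clusters (k = ", k, ")")
  xsq <- rowSums(x^2)
  use_sub <- !is.null(search_n) && is.finite(search_n) && search_n < n
  if (use_sub) {
    sub <- sample.int(n, search_n)
    xs <- x[sub, , drop = FALSE]
    xsq_s <- xsq[sub]
  } else {
    xs <- x
    xsq_s <- xsq
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    c0 <- xs[.kmeanspp_init(xs, k, xsq_s), , drop = FALSE]
    run <- .lloyd(xs, c0, xsq_s, iter_max = search_iter_max)
    if (is.null(best) || run$sse < best$sse) best <- run
  }
  out <- if (use_sub || !best$converged)
    .lloyd(x, best$centers, xsq, iter_max = iter_max) else best
  out$n_init <- as.integer(n_init)
  out
}
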