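#' Canonical correlation analysis between two variable blocks
#'
#' Finds the weighted sums (canonical variates) of the columns of `X` and
#' `Y` with maximal correlation, then successive pairs orthogonal to the
#' previous ones. Solved by QR decomposition of the centered blocks and an
#' SVD of the cross-product of their orthonormal bases, the numerically
#' stable route. Columns are standardized to unit variance internally;
#' weights are reported on the standardized scale (loadings are scale-free
#' either way).
#'
#' @param X,Y numeric matrices, subjects in rows (no missing values).
#' @return object of class `cap_cca`: `cor` (nonincreasing canonical
#'   correlations), `x_weights`, `y_weights`, `x_scores`, `y_scores`,
#'   `loadings_x`, `loadings_y` (per-column Pearson r with the block's
#'   first variate), `n`.
#' @export
cca_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (anyNA(X) || anyNA(Y)) stop("missing values not allowed")
  if (n <= max(p, q)) stop("need more subjects (", n,
                           ") than variables in either block")
  std <- function(M, label) {
    s <- apply(M, 2L, stats::sd)
    if (any(s < 1e-12))
      stop("constant column(s) in ", label, ": ",
           paste(which(s < 1e-12), collapse = ", "))
    scale(M, center = TRUE, scale = s)
  }
  Xs <- std(X, "X"); Ys <- std(Y, "Y")
  qx <- qr(Xs); qy <- qr(Ys)
  if (qx$rank < p)
    stop("rank-deficient X block; redundant column(s): ",
         paste(qx$pivot[(qx$rank + 1L):p], collapse = ", "))
  if (qy$rank < q)
    stop("rank-deficient Y block; redundant column(s): ",
         paste(qy$pivot[(qy$rank + 1L):q], collapse = ", "))
  d <- min(p, q)
  sv <- svd(crossprod(qr.Q(qx), qr.Q(qy)), nu = d, nv = d)
  cors <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  wx <- backsolve(qr.R(qx), sv$u)[order(qx$pivot), , drop = FALSE]
  wy <- backsolve(qr.R(qy), sv$v)[order(qy$pivot), , drop = FALSE]
  sx <- Xs %*% wx; sy <- Ys %*% wy
  # normalize variates to unit variance, fix sign so first pair correlates
  # positively
  nsx <- sqrt(colSums(sx^2) / (n - 1)); nsy <- sqrt(colSums(sy^2) / (n - 1))
  wx <- sweep(wx, 2L, nsx, "/"); sx <- sweep(sx, 2L, nsx, "/")
  wy <- sweep(wy, 2L, nsy, "/"); sy <- sweep(sy, 2L, nsy, "/")
  for (j in seq_len(d)) {
    if (stats::cor(sx[, j], sy[, j]) < 0) {
      wy[, j] <- -wy[, j]; sy[, j] <- -sy[, j]
    }
  }
  structure(list(cor = cors, x_weights = wx, y_weights = wy,
                 x_scores = sx, y_scores = sy,
                 loadings_x = canonical_loadings(X, sx[, 1L]),
                 loadings_y = canonical_loadings(Y, sy[, 1L]),
                 n = n), class = "cap_cca")
}

#' @export
print.cap_cca <- function(x, ...) {
  cat("Canonical correlation analysis, n =", x$n, "\n")
  cat("Canonical correlations:", paste(sprintf("%.3f", x$cor),
                                       collapse = ", "), "\n")
  if (!is.null(x$p_perm))
    cat("Permutation p (max-statistic corrected):",
        paste(sprintf("%.4g", x$p_perm), collapse = ", "), "\n")
  invisible(x)
}


#' Permutation test for the canonical correlations
#'
#' Permutes the rows of `Y` `n_perm` times and compares each observed
#' canonical correlation against the null distribution of the maximum
#' canonical correlation, giving family-wise corrected p-values
#' (max-statistic correction across canonical pairs). The p-value uses the
#' add-one convention, `p = (1 + #{null >= observed}) / (1 + n_perm)`, so
#' it is never exactly zero.
#'
#' @inheritParams cca_fit
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed; the test is deterministic given the seed.
#' @return the fitted `cap_cca` with `p_perm` (per canonical pair) and
#'   `null_max` (the permutation null of the maximum correlation).
#' @export
cca_permutation_test <- function(X, Y, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  fit <- cca_fit(X, Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  # permuting the rows of Y permutes the rows of its orthonormal basis
  # (the triangular factor is unchanged), so each permutation needs only
  # a small cross-product and SVD
  qxQ <- qr.Q(qr(scale(X)))
  qyQ <- qr.Q(qr(scale(Y)))
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    max(svd(crossprod(qxQ, qyQ[sample.int(n), , drop = FALSE]),
            nu = 0, nv = 0)$d)
  }, 0)
  fit$p_perm <- vapply(fit$cor, function(r)
    (1 + sum(null_max >= r)) / (1 + n_perm), 0)
  fit$null_max <- null_max
  fit$n_perm <- as.integer(n_perm)
  fit
}

#' Canonical loadings
#'
#' Pearson correlation of each original variable with a canonical variate,
#' the usual interpretive quantity (how well each variable is represented
#' by the variate).
#'
#' @param M subjects x variables matrix.
#' @param variate numeric vector (one canonical variate).
#' @return numeric vector of per-variable correlations; constant columns
#'   give `NA` with a warning.
#' @export
canonical_loadings <- function(M, variate) {
  M <- as.matrix(M)
  if (nrow(M) != length(variate)) stop("length mismatch")
  s <- apply(M, 2L, stats::sd)
  out <- rep(NA_real_, ncol(M))
  ok <- s >= 1e-12
  if (!all(ok)) warning("constant column(s): loadings undefined for ",
                        paste(which(!ok), collapse = ", "))
  out[ok] <- drop(stats::cor(M[, ok, drop = FALSE], variate))
  names(out) <- colnames(M)
  out
}
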