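#' Dwell time of each state
#'
#' Fraction of frames spent in each state over a subject's assignment
#' sequence; sums to one.
#'
#' @param assignments integer sequence of per-frame state indices.
#' @param k number of states.
#' @return numeric vector of length `k` summing to 1.
#' @export
dwell_time <- function(assignments, k) {
  if (!length(assignments)) stop("empty assignment sequence")
  tabulate(assignments, k) / length(assignments)
}

#' Per-subject dwell times from a fitted model
#'
#' @param fit a `cap_fit` carrying a frame index.
#' @return data frame, one row per subject: `subject_id`, `dwell_1 ...
#'   dwell_k`.
#' @export
dwell_table <- function(fit) {
  stopifnot(inherits(fit, "cap_fit"), !is.null(fit$frame_index))
  ids <- unique(fit$frame_index$subject_id)
  sub <- factor(fit$frame_index$subject_id, levels = ids)
  m <- t(vapply(split(fit$assignments, sub), dwell_time, numeric(fit$k),
                k = fit$k))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (c in seq_len(fit$k)) out[[paste0("dwell_", c)]] <- m[, c]
  out
}

#' Transition probabilities between states
#'
#' Counts ordered between-state changes at consecutive frames and divides
#' by the total number of between-state changes; self-repeats (consecutive
#' frames in the same state) are excluded from both numerator and
#' denominator by default, so the off-diagonal entries sum to one and the
#' diagonal is identically zero. With `include_self = TRUE` self-repeats
#' count as transitions and all entries sum to one.
#'
#' @param assignments integer sequence (length >= 2).
#' @param k number of states.
#' @param include_self count self-repeats as transitions (default FALSE).
#' @return list with `P` (k x k matrix), `counts`, `n_transitions`,
#'   `flagged` (TRUE when no qualifying transition exists; `P` is then all
#'   zero).
#' @export
transition_matrix <- function(assignments, k, include_self = FALSE) {
  if (length(assignments) < 2L) stop("need at least 2 frames")
  from <- assignments[-length(assignments)]
  to <- assignments[-1L]
  if (!include_self) {
    keep <- from != to
    from <- from[keep]; to <- to[keep]
  }
  counts <- matrix(0, k, k)
  if (length(from)) {
    tb <- table(factor(from, levels = seq_len(k)),
                factor(to, levels = seq_len(k)))
    counts <- matrix(as.numeric(tb), k, k)
  }
  n <- sum(counts)
  list(P = if (n > 0) counts / n else counts, counts = counts,
       n_transitions = as.integer(n), flagged = n == 0)
}

#' Per-subject transition matrices from a fitted model
#'
#' Transitions are counted within subject only; the concatenation boundary
#' between subjects is never a transition. Subjects with fewer than 10
#' between-state transitions are flagged low-confidence.
#'
#' @param fit a `cap_fit` carrying a frame index.
#' @param include_self see [transition_matrix].
#' @return list with `P` (k x k x subjects array), `counts` (same shape),
#'   `n_transitions` (per subject), `low_confidence` (logical), `mean_P`
#'   (transition-count-weighted pooled matrix).
#' @export
transition_table <- function(fit, include_self = FALSE) {
  stopifnot(inherits(fit, "cap_fit"), !is.null(fit$frame_index))
  ids <- unique(fit$frame_index$subject_id)
  sub <- factor(fit$frame_index$subject_id, levels = ids)
  seqs <- split(fit$assignments, sub)
  k <- fit$k
  P <- array(0, c(k, k, length(ids)), dimnames = list(NULL, NULL, ids))
  counts <- P
  nt <- integer(length(ids))
  for (i in seq_along(seqs)) {
    tm <- transition_matrix(seqs[[i]], k, include_self)
    P[, , i] <- tm$P
    counts[, , i] <- tm$counts
    nt[i] <- tm$n_transitions
  }
  tot <- apply(counts, c(1, 2), sum)
  list(P = P, counts = counts, n_transitions = nt,
       low_confidence = nt < 10L,
       mean_P = if (sum(tot) > 0) tot / sum(tot) else tot)
}

#' Within-pair and internetwork transition shares
#'
#' Splits the between-state transition mass into transitions within a
#' mirror pair and transitions between states of different pairs
#' (internetwork); the internetwork mass is further partitioned by
#' unordered pair-label combination, renormalized to sum to one.
#'
#' @param P k x k between-state transition probability matrix (or counts).
#' @param pair_of character (or factor) vector of length k giving each
#'   state's pair label (e.g. `"DMN"`, `"ECN"`, `"SN"`).
#' @return list with `within_pair` (fraction of all transitions),
#'   `internetwork` (fraction), `shares` (named vector over pair-label
#'   combinations, summing to 1 within internetwork transitions).
#' @export
internetwork_share <- function(P, pair_of) {
  k <- nrow(P)
  if (length(pair_of) != k) stop("pair_of must label all ", k, " states")
  if (anyNA(pair_of)) stop("unlabeled state(s): ",
                           paste(which(is.na(pair_of)), collapse = ", "))
  pair_of <- as.character(pair_of)
  tot <- sum(P) - sum(diag(P))
  if (tot <= 0) stop("no between-state transition mass in P")
  labs <- sort(unique(pair_of))
  combos <- utils::combn(labs, 2L)
  shares <- stats::setNames(numeric(ncol(combos)),
                            apply(combos, 2L, paste, collapse = "-"))
  within <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (pair_of[i] == pair_of[j]) within <- within + P[i, j]
    else {
      key <- paste(sort(c(pair_of[i], pair_of[j])), collapse = "-")
      shares[key] <- shares[key] + P[i, j]
    }
  }
  inter <- sum(shares)
  list(within_pair = within / tot, internetwork = inter / tot,
       shares = if (inter > 0) shares / inter else shares)
}

#' Correlation between spatial similarity and transition probability
#'
#' Pearson correlation between the off-diagonal spatial similarities of the
#' states and the corresponding symmetrized transition probabilities, at
#' the group level (mean transition matrix) and per subject.
#'
#' @param sim k x k spatial similarity matrix (see
#'   [spatial_similarity_matrix]).
#' @param tt result of [transition_table], or a single k x k matrix.
#' @return list with `r_group`, `p_group`, and (when subject matrices are
#'   supplied) `r_subject`, a per-subject vector.
#' @export
similarity_transition_correlation <- function(sim, tt) {
  k <- nrow(sim)
  if (k < 3L) stop("need k >= 3 (too few off-diagonal pairs)")
  ut <- upper.tri(sim)
  symm <- function(m) (m + t(m)) / 2
  if (is.matrix(tt)) {
    ct <- stats::cor.test(sim[ut], symm(tt)[ut])
    return(list(r_group = unname(ct$estimate), p_group = ct$p.value))
  }
  ct <- stats::cor.test(sim[ut], symm(tt$mean_P)[ut])
  rs <- apply(tt$P, 3L, function(m) {
    m <- symm(m)
    if (stats::sd(m[ut]) < 1e-12) NA_real_ else stats::cor(sim[ut], m[ut])
  })
  list(r_group = unname(ct$estimate), p_group = ct$p.value, r_subject = rs)
}
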