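# shared fixtures and oracles, all generated in code

# compact 4-site cohort layout for fast end-to-end tests
small_sites <- function(n = 8L, frames = c(120L, 150L, 150L, 120L)) {
  data.frame(
    site = c("S1", "S2", "S3", "S4"),
    age_group = c("juvenile", "juvenile", "adult", "adult"),
    n_per_group = rep(as.integer(n), 4),
    frames = as.integer(frames),
    tr = c(2, 2, 1, 3),
    eye_status = c("closed", "closed", "closed", "open"),
    age_min = c(8, 8, 18, 18), age_max = c(16, 16, 40, 60),
    iq_min = rep(85, 4), iq_max = rep(140, 4),
    mot_min = rep(0.06, 4), mot_max = c(0.9, 0.9, 0.5, 0.8),
    noise_mult = c(1, 1.05, 0.97, 1.02),
    stringsAsFactors = FALSE)
}

small_config <- function(seed = 1L, n = 8L, n_parcels = 120L, ...) {
  sim_config(n_parcels = n_parcels, sites = small_sites(n), seed = seed,
             ...)
}

# cap_frames built directly from a matrix (one or more subjects)
frames_of <- function(x, subject_id = "s1") {
  if (length(subject_id) == 1L)
    subject_id <- rep(subject_id, nrow(x))
  structure(list(x = x,
                 frame_index = data.frame(subject_id = subject_id,
                                          frame = stats::ave(
                                            seq_along(subject_id),
                                            subject_id, FUN = seq_along),
                                          stringsAsFactors = FALSE),
                 parcel_ids = sprintf("p%03d", seq_len(ncol(x)))),
            class = "cap_frames")
}

# hand-built cap_fit for rule-level tests (within_sd = 1 by default)
fake_fit <- function(centers, assignments, subject_id,
                     within_sd = NULL) {
  k <- nrow(centers)
  structure(list(
    k = k, centers = centers, assignments = assignments,
    sizes = tabulate(assignments, k),
    within_sd = if (is.null(within_sd))
      matrix(1, k, ncol(centers)) else within_sd,
    sse = NA_real_,
    frame_index = data.frame(subject_id = subject_id,
                             frame = stats::ave(seq_along(subject_id),
                                                subject_id,
                                                FUN = seq_along),
                             stringsAsFactors = FALSE),
    parcel_ids = sprintf("p%03d", seq_len(ncol(centers))),
    row_standardize = FALSE, sd_type = "population", seed = 0L,
    n_init = 1L, converged = TRUE, iter = 0L), class = "cap_fit")
}

# k mutually orthogonal block templates on k*b parcels
orthogonal_templates <- function(k, block = 10L, value = 1) {
  t(vapply(seq_len(k), function(i) {
    v <- numeric(k * block)
    v[((i - 1L) * block + 1L):(i * block)] <- value
    v
  }, numeric(k * block)))
}

# adjusted Rand index between two labelings (Hubert & Arabie)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# noiseless cohort in which every subject shares one state sequence, so
# normalized frames are identical across subjects within a state
noiseless_cohort <- function(cfg, n_subj = 6L, frames = 90L, seed = 5L) {
  tpl <- make_templates(cfg)
  P <- markov_matrix(cfg, "juvenile_CON")
  seqs <- simulate_state_sequence(P, frames, seed = seed)
  while (length(unique(seqs)) < nrow(tpl$templates))
    seqs <- simulate_state_sequence(P, frames)
  subjects <- lapply(seq_len(n_subj), function(i) {
    gain <- 0.5 + 0.25 * i       # gains cancel under normalization
    cap_subject(sprintf("n%02d", i), gain * tpl$templates[seqs, ],
                site = if (i %% 2) "A" else "B", group = "CON",
                age_group = "juvenile", age = 10, full_iq = 100,
                motion = 0.2, tr = 2)
  })
  atlas <- data.frame(parcel_id = sprintf("p%03d",
                                          seq_len(cfg$n_parcels)),
                      network = as.character(tpl$networks),
                      stringsAsFactors = FALSE)
  list(cohort = cap_cohort(subjects, atlas), templates = tpl$templates,
       sequence = seqs, networks = tpl$networks)
}
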