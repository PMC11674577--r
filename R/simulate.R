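#' Configuration for the synthetic multi-site cohort generator
#'
#' Builds the parameter set for [simulate_cohort]. The defaults emulate a
#' 264-subject, 7-site resting-state cohort: four juvenile sites and three
#' adult sites with heterogeneous frame counts and TRs, 400 parcels grouped
#' into the 7 canonical networks, frames generated by a discrete-state
#' Markov process over 6 spatial templates arranged as 3 exact mirror
#' pairs, subject- and site-level gain/noise effects, group-by-age effects
#' on dwell time and on spatial noise, and SRS-like scores coupled to the
#' planted features.
#'
#' Planted effects (relative to the control cells): ASD cells lose dwell
#' mass on the DMN pair; juvenile ASD gains it on the SN pair and adult ASD
#' on the ECN pair; adult ASD has elevated spatial noise (less stable
#' states) while adult controls have the lowest noise.
#'
#' @param n_parcels number of parcels (default 400; network sizes scale
#'   proportionally).
#' @param sites data frame describing the site blocks (columns `site`,
#'   `age_group`, `n_per_group`, `frames`, `tr`, `eye_status`, `age_min`,
#'   `age_max`, `iq_min`, `iq_max`, `mot_min`, `mot_max`, `noise_mult`).
#' @param template_gain activation amplitude of the network signatures.
#' @param texture_sd sd of the fixed parcel-level texture added to each
#'   pair signature.
#' @param stick_prob probability of repeating the current state at the
#'   next frame.
#' @param within_pair_affinity relative affinity of jumps between the two
#'   states of a mirror pair (0 forbids them).
#' @param pair_affinity named 3 x 3 matrix of relative jump affinities
#'   between pairs.
#' @param target_dwell named list of per-cell target pair dwell fractions
#'   (each a named vector over `DMN`, `ECN`, `SN` summing to 1).
#' @param noise_sd named vector of per-cell frame noise sd.
#' @param state_noise_mult named per-pair multiplier on the frame noise sd,
#'   applied by the true state of each frame; the default makes the DMN
#'   pair the most and the ECN pair the least spatially stable.
#' @param subject_gain_sd lognormal sd of the per-subject multiplicative
#'   gain.
#' @param subject_noise_sd lognormal sd of the per-subject noise
#'   multiplier.
#' @param srs list of SRS-coupling parameters (`baseline`, `asd_shift`,
#'   `slope_dwell`, `slope_noise`, `noise_sd`, `range`).
#' @param seed master seed; all generation is deterministic given it
#'   (per-subject seeds are derived by a fixed counter scheme).
#' @return list of class `cap_sim_config`.
#' @export
sim_config <- function(n_parcels = 400L,
                       sites = default_sites(),
                       template_gain = 1,
                       texture_sd = 0.1,
                       stick_prob = 0.55,
                       within_pair_affinity = 0.02,
                       pair_affinity = default_pair_affinity(),
                       target_dwell = default_target_dwell(),
                       noise_sd = c(juvenile_ASD = 1.2, juvenile_CON = 1.2,
                                    adult_ASD = 1.35, adult_CON = 1.1),
                       state_noise_mult = c(DMN = 0.9, ECN = 1.15,
                                            SN = 1.0),
                       subject_gain_sd = 0.1,
                       subject_noise_sd = 0.05,
                       srs = list(baseline = 50, asd_shift = 22,
                                  slope_dwell = 3, slope_noise = 5,
                                  noise_sd = 6, range = c(35, 120)),
                       seed = 1L) {
  sizes <- round(c(ECN = 52, DMN = 91, DAN = 46, Lim = 26, SN = 47,
                   SM = 77, Vis = 61) * n_parcels / 400)
  sizes[1L] <- sizes[1L] + (n_parcels - sum(sizes))
  if (any(sizes < 1L)) stop("n_parcels too small for 7 networks")
  cells <- c("juvenile_ASD", "juvenile_CON", "adult_ASD", "adult_CON")
  stopifnot(all(cells %in% names(target_dwell)),
            all(cells %in% names(noise_sd)),
            all(vapply(target_dwell, function(v)
              abs(sum(v) - 1) < 1e-8, TRUE)))
  if (stick_prob <= 0 || stick_prob >= 1) stop("stick_prob must be in (0,1)")
  structure(list(n_parcels = as.integer(n_parcels), network_sizes = sizes,
                 sites = sites, template_gain = template_gain,
                 texture_sd = texture_sd, stick_prob = stick_prob,
                 within_pair_affinity = within_pair_affinity,
                 pair_affinity = pair_affinity,
                 target_dwell = target_dwell, noise_sd = noise_sd,
                 state_noise_mult = state_noise_mult,
                 subject_gain_sd = subject_gain_sd,
                 subject_noise_sd = subject_noise_sd, srs = srs,
                 seed = as.integer(seed)),
            class = "cap_sim_config")
}

# site blocks: four juvenile sites, three adult sites, 264 subjects total,
# heterogeneous frame counts / TR / eye status, fixed site noise multipliers
default_sites <- function() {
  data.frame(
    site = c("GU", "SDSU", "NYU", "SU", "IU", "ONRC", "BNI"),
    age_group = c("juvenile", "juvenile", "juvenile", "juvenile",
                  "adult", "adult", "adult"),
    n_per_group = c(20L, 21L, 24L, 13L, 13L, 13L, 28L),
    frames = c(147L, 175L, 175L, 175L, 428L, 942L, 115L),
    tr = c(2, 2, 2, 2, 0.813, 0.475, 3),
    eye_status = c("closed", "closed", "closed", "open", "closed",
                   "closed", "open"),
    age_min = c(8.06, 8, 5.89, 8.43, 18, 18, 18),
    age_max = c(13.88, 17.8, 14.98, 12.99, 37, 28, 64),
    iq_min = c(96, 80, 88, 93, 80, 86, 85),
    iq_max = c(149, 130, 138, 137, 135, 138, 141),
    mot_min = c(0.09, 0.06, 0.13, 0.06, 0.09, 0.08, 0.06),
    mot_max = c(0.81, 0.98, 0.89, 0.79, 0.41, 0.80, 0.79),
    noise_mult = c(1.00, 1.05, 0.95, 1.02, 0.97, 1.08, 1.00),
    stringsAsFactors = FALSE)
}

default_pair_affinity <- function() {
  a <- matrix(0, 3, 3, dimnames = list(c("DMN", "ECN", "SN"),
                                       c("DMN", "ECN", "SN")))
  a["DMN", "SN"] <- a["SN", "DMN"] <- 1.20
  a["DMN", "ECN"] <- a["ECN", "DMN"] <- 1.15
  a["SN", "ECN"] <- a["ECN", "SN"] <- 1.13
  a
}

default_target_dwell <- function() {
  list(juvenile_CON = c(DMN = 0.37, ECN = 0.31, SN = 0.32),
       adult_CON = c(DMN = 0.38, ECN = 0.305, SN = 0.315),
       juvenile_ASD = c(DMN = 0.33, ECN = 0.31, SN = 0.36),
       adult_ASD = c(DMN = 0.34, ECN = 0.35, SN = 0.31))
}

# network-level signatures of the three pairs (positive member)
.pair_signatures <- function() {
  list(DMN = c(DMN = 1, Lim = 0.4, SN = -0.8, SM = -1),
       ECN = c(ECN = 1, DAN = 0.8, DMN = -0.8),
       SN = c(SN = 1, Vis = -1, DAN = -0.4))
}

state_names_6 <- c("DMN-p", "DMN-n", "ECN-p", "ECN-n", "SN-p", "SN-n")
pair_of_6 <- c("DMN", "DMN", "ECN", "ECN", "SN", "SN")

#' Planted state templates
#'
#' Builds the 6 spatial templates (3 mirror pairs) from network-level
#' signatures: each pair's positive member is the signature (+gain on its
#' activated networks, -gain on its deactivated networks, 0 elsewhere)
#' plus a small fixed parcel-level texture; the negative member is the
#' exact negation. The texture depends only on the config seed.
#'
#' @param cfg a `cap_sim_config`.
#' @return list with `templates` (6 x parcels matrix, rows named
#'   `DMN-p`, `DMN-n`, `ECN-p`, `ECN-n`, `SN-p`, `SN-n`), `networks`
#'   (parcel-level factor), `pair_of`.
#' @export
make_templates <- function(cfg) {
  stopifnot(inherits(cfg, "cap_sim_config"))
  sizes <- cfg$network_sizes
  networks <- factor(rep(names(sizes), sizes), levels = networks_7)
  p <- length(networks)
  sig <- .pair_signatures()
  set.seed(cfg$seed)
  templates <- matrix(0, 6L, p, dimnames = list(state_names_6, NULL))
  for (i in seq_along(sig)) {
    v <- numeric(p)
    for (nm in names(sig[[i]])) v[networks == nm] <- sig[[i]][[nm]]
    v <- cfg$template_gain * (v + stats::rnorm(p, 0, cfg$texture_sd))
    templates[2L * i - 1L, ] <- v
    templates[2L * i, ] <- -v
  }
  list(templates = templates, networks = networks, pair_of = pair_of_6)
}

#' Markov transition matrix for one group-by-age cell
#'
#' Builds a reversible chain whose stationary distribution equals the
#' cell's target dwell distribution exactly: off-diagonal rates are
#' `P[i, j] = c * A[i, j] * pi[j]` with `A` the symmetric pair-level
#' affinity (within-pair jumps get `within_pair_affinity`) and `c` scaled
#' so the smallest self-transition probability equals `stick_prob`. The
#' stationary distribution is attached as attribute `"stationary"` and is
#' the planted dwell truth.
#'
#' @param cfg a `cap_sim_config`.
#' @param cell one of `"juvenile_ASD"`, `"juvenile_CON"`, `"adult_ASD"`,
#'   `"adult_CON"`.
#' @return 6 x 6 stochastic matrix with attribute `"stationary"`.
#' @export
markov_matrix <- function(cfg, cell) {
  tgt_pair <- cfg$target_dwell[[cell]]
  if (is.null(tgt_pair)) stop("unknown cell: ", cell)
  pi_t <- as.numeric(tgt_pair[pair_of_6] / 2)
  k <- 6L
  A <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    A[i, j] <- if (pair_of_6[i] == pair_of_6[j]) cfg$within_pair_affinity
    else cfg$pair_affinity[pair_of_6[i], pair_of_6[j]]
  }
  out_rate <- drop(A %*% pi_t)
  cc <- (1 - cfg$stick_prob) / max(out_rate)
  P <- cc * A * rep(pi_t, each = k)
  diag(P) <- 1 - rowSums(P)
  dimnames(P) <- list(state_names_6, state_names_6)
  attr(P, "stationary") <- stats::setNames(stationary_distribution(P),
                                           state_names_6)
  P
}

#' Stationary distribution of a stochastic matrix
#'
#' @param P row-stochastic matrix.
#' @return probability vector pi with pi P = pi.
#' @export
stationary_distribution <- function(P) {
  .check_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

.check_stochastic <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < -1e-12) ||
      any(abs(rowSums(P) - 1) > 1e-8))
    stop("P is not a row-stochastic matrix")
}

#' Simulate a Markov state sequence
#'
#' @param P row-stochastic transition matrix.
#' @param T_frames sequence length.
#' @param seed optional seed (the sequence is deterministic given it).
#' @param init initial distribution (defaults to the stationary
#'   distribution).
#' @return integer state sequence of length `T_frames`.
#' @export
simulate_state_sequence <- function(P, T_frames, seed = NULL, init = NULL) {
  .check_stochastic(P)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- stationary_distribution(P)
  k <- nrow(P)
  s <- integer(T_frames)
  s[1L] <- sample.int(k, 1L, prob = init)
  if (T_frames > 1L) {
    u <- stats::runif(T_frames - 1L)
    cp <- t(apply(P, 1L, cumsum))
    for (t in 2:T_frames)
      s[t] <- 1L + sum(u[t - 1L] > cp[s[t - 1L], ])
  }
  s
}

#' Simulate one subject's frame matrix from templates and a state sequence
#'
#' Each frame is `subject_gain * template[state]` plus white Gaussian
#' parcel noise. Temporal autocorrelation beyond state persistence is not
#' modeled (frame-wise analyses operate on band-passed data).
#'
#' @param templates k x parcels template matrix.
#' @param sequence integer state sequence.
#' @param noise_sd Gaussian noise sd per parcel; either a scalar or one
#'   value per frame (e.g. state-dependent noise).
#' @param subject_gain multiplicative subject gain.
#' @param seed optional seed.
#' @return frames x parcels matrix.
#' @export
simulate_subject <- function(templates, sequence, noise_sd,
                             subject_gain = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T_frames <- length(sequence)
  p <- ncol(templates)
  noise <- matrix(stats::rnorm(T_frames * p), T_frames, p) * noise_sd
  subject_gain * templates[sequence, , drop = FALSE] + noise
}

# per-subject seed: fixed counter scheme below 2^31
.subject_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 100003 * counter) %% 2147483647)
}

#' Simulate a full multi-site cohort with ground truth
#'
#' Generates the synthetic cohort described by `cfg`: per-site subject
#' blocks in both groups, frames from the cell-specific Markov chains over
#' the planted templates, subject gains and noise multipliers, covariates
#' drawn within the per-site ranges (motion weakly coupled to the subject
#' noise level so covariate adjustment has something to do), and SRS-like
#' scores coupled to the planted features. Everything is deterministic
#' given `cfg$seed`.
#'
#' @param cfg a `cap_sim_config`.
#' @param dir optional directory: when given, the cohort is also written as
#'   delimited text (see [write_cohort]) plus `ground_truth.json`.
#' @return list with `cohort` (a [cap_cohort]; subjects are raw, not yet
#'   normalized) and `ground_truth` (class `cap_ground_truth`: `templates`,
#'   `networks`, `pair_of`, `state_names`, `markov` and `stationary` per
#'   cell, `true_states`, `noise_sd` and `gain` per subject, `config`).
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "cap_sim_config"))
  tpl <- make_templates(cfg)
  cells <- names(cfg$target_dwell)
  markov <- lapply(stats::setNames(cells, cells),
                   function(cl) markov_matrix(cfg, cl))
  atlas <- data.frame(parcel_id = sprintf("p%03d",
                                          seq_len(cfg$n_parcels)),
                      network = as.character(tpl$networks),
                      stringsAsFactors = FALSE)
  subjects <- list()
  true_states <- list()
  noise_by_subject <- numeric(0)
  gain_by_subject <- numeric(0)
  counter <- 0L
  for (si in seq_len(nrow(cfg$sites))) {
    st <- cfg$sites[si, ]
    for (grp in c("ASD", "CON")) {
      cell <- paste(st$age_group, grp, sep = "_")
      P <- markov[[cell]]
      for (j in seq_len(st$n_per_group)) {
        counter <- counter + 1L
        set.seed(.subject_seed(cfg$seed, counter))
        id <- sprintf("%s_%s_%02d", st$site, grp, j)
        gain <- stats::rlnorm(1, 0, cfg$subject_gain_sd)
        nmult <- stats::rlnorm(1, 0, cfg$subject_noise_sd)
        nsd <- cfg$noise_sd[[cell]] * st$noise_mult * nmult
        seqs <- simulate_state_sequence(P, st$frames)
        frame_sd <- nsd * cfg$state_noise_mult[pair_of_6[seqs]]
        x <- simulate_subject(tpl$templates, seqs, frame_sd, gain)
        age <- stats::runif(1, st$age_min, st$age_max)
        iq <- stats::runif(1, st$iq_min, st$iq_max)
        # motion weakly tracks the subject noise multiplier
        u <- 0.65 * stats::runif(1) +
          0.35 * stats::pnorm(log(nmult), 0, cfg$subject_noise_sd)
        mot <- st$mot_min + u * (st$mot_max - st$mot_min)
        subjects[[id]] <- cap_subject(id, x, st$site, grp, st$age_group,
                                      age = age, full_iq = iq, motion = mot,
                                      eye_status = st$eye_status,
                                      tr = st$tr)
        true_states[[id]] <- seqs
        noise_by_subject[id] <- nsd
        gain_by_subject[id] <- gain
      }
    }
  }
  cohort <- cap_cohort(subjects, atlas)
  gt <- structure(list(
    templates = tpl$templates, networks = tpl$networks,
    pair_of = tpl$pair_of, state_names = state_names_6,
    markov = markov,
    stationary = lapply(markov, attr, "stationary"),
    true_states = true_states, noise_sd = noise_by_subject,
    gain = gain_by_subject, config = cfg), class = "cap_ground_truth")
  srs <- simulate_srs(gt, seed = .subject_seed(cfg$seed, counter + 1L))
  for (i in seq_len(nrow(srs))) {
    v <- unlist(srs[i, -1L])
    cohort$subjects[[srs$subject_id[i]]]$srs <- v
  }
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    write_ground_truth(gt, file.path(dir, "ground_truth.json"))
  }
  list(cohort = cohort, ground_truth = gt)
}

#' @export
print.cap_ground_truth <- function(x, ...) {
  cat(sprintf("<cap_ground_truth> %d subjects, %d states, %d parcels\n",
              length(x$true_states), nrow(x$templates),
              ncol(x$templates)))
  cat("Planted pair dwell (stationary) per cell:\n")
  for (cl in names(x$stationary)) {
    s <- x$stationary[[cl]]
    byp <- tapply(s, x$pair_of, sum)
    cat(sprintf("  %-13s %s\n", cl,
                paste(sprintf("%s=%.3f", names(byp), byp),
                      collapse = " ")))
  }
  invisible(x)
}

#' SRS-like T scores coupled to the planted features
#'
#' Five item T scores plus a total: a group baseline shift (ASD above CON)
#' plus linear couplings to each subject's realized SN-pair dwell time and
#' planted spatial-noise level (both z-scored across the cohort), plus
#' Gaussian item noise; clipped to the plausible T-score range. Scores
#' therefore correlate positively with SN dwell and negatively with
#' spatial stability, the directions the statistical layer is meant to
#' recover. `srs_version` is 1 for juveniles and 2 for adults.
#'
#' @param gt a `cap_ground_truth` from [simulate_cohort].
#' @param seed integer seed.
#' @return data frame: `subject_id`, `srs_aware`, `srs_cogn`, `srs_comm`,
#'   `srs_mot`, `srs_manner`, `srs_total`, `srs_version`.
#' @export
simulate_srs <- function(gt, seed = 1L) {
  stopifnot(inherits(gt, "cap_ground_truth"))
  cfg <- gt$config
  ids <- names(gt$true_states)
  sn_states <- which(gt$pair_of == "SN")
  dw <- vapply(gt$true_states, function(s) mean(s %in% sn_states), 0)
  zdw <- as.numeric(scale(dw))
  zns <- as.numeric(scale(log(gt$noise_sd)))
  grp <- vapply(strsplit(ids, "_"), `[[`, "", 2L)
  adult <- grepl("^(IU|ONRC|BNI)_", ids)
  # recover age group robustly from the stored config site table
  st <- cfg$sites
  site <- vapply(strsplit(ids, "_"), `[[`, "", 1L)
  adult <- st$age_group[match(site, st$site)] == "adult"
  set.seed(seed)
  items <- c("srs_aware", "srs_cogn", "srs_comm", "srs_mot", "srs_manner")
  base <- cfg$srs$baseline + cfg$srs$asd_shift * (grp == "ASD") +
    cfg$srs$slope_dwell * zdw + cfg$srs$slope_noise * zns
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  vals <- matrix(0, length(ids), length(items))
  for (j in seq_along(items)) {
    v <- base + stats::rnorm(length(ids), 0, cfg$srs$noise_sd)
    vals[, j] <- pmin(pmax(round(v), cfg$srs$range[1L]), cfg$srs$range[2L])
    out[[items[j]]] <- vals[, j]
  }
  out$srs_total <- round(rowMeans(vals))
  out$srs_version <- ifelse(adult, 2, 1)
  out
}

#' Write / read ground truth as JSON
#'
#' @param gt a `cap_ground_truth`.
#' @param path JSON file path.
#' @return `read_ground_truth` returns the `cap_ground_truth` (the stored
#'   config is restored as a plain list).
#' @export
write_ground_truth <- function(gt, path) {
  out <- list(templates = gt$templates, networks = as.character(gt$networks),
              pair_of = gt$pair_of, state_names = gt$state_names,
              markov = lapply(gt$markov, function(m) {
                attributes(m)[c("stationary")] <- NULL
                unclass(m)
              }),
              stationary = gt$stationary, true_states = gt$true_states,
              noise_sd = as.list(gt$noise_sd), gain = as.list(gt$gain),
              config = unclass(gt$config))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$templates <- as.matrix(raw$templates)
  raw$networks <- factor(raw$networks, levels = networks_7)
  raw$markov <- lapply(raw$markov, as.matrix)
  raw$true_states <- lapply(raw$true_states, as.integer)
  raw$noise_sd <- unlist(raw$noise_sd)
  raw$gain <- unlist(raw$gain)
  class(raw) <- "cap_ground_truth"
  raw
}
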