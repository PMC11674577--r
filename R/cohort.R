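#' Construct a single-subject parcellated time series
#'
#' Bundles one subject's frames x parcels BOLD matrix with the metadata used
#' throughout the analysis (site, diagnostic group, age group, covariates,
#' scanning parameters, optional SRS T scores).
#'
#' @param subject_id character scalar.
#' @param data numeric matrix, frames in rows, parcels in columns.
#' @param site character scalar, scanning site identifier.
#' @param group `"ASD"` or `"CON"`.
#' @param age_group `"juvenile"` or `"adult"`.
#' @param age age in years.
#' @param full_iq full-scale IQ.
#' @param motion mean absolute head motion in mm.
#' @param eye_status `"open"` or `"closed"`.
#' @param tr repetition time in seconds.
#' @param srs optional named numeric vector of SRS T scores
#'   (`srs_aware`, `srs_cogn`, `srs_comm`, `srs_mot`, `srs_manner`,
#'   `srs_total`, `srs_version`).
#' @return An object of class `cap_subject`.
#' @export
cap_subject <- function(subject_id, data, site, group, age_group,
                        age = NA_real_, full_iq = NA_real_, motion = NA_real_,
                        eye_status = "closed", tr = NA_real_, srs = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("subject ", subject_id, ": non-numeric data")
  if (nrow(data) < 2L) stop("subject ", subject_id, ": fewer than 2 frames")
  if (anyNA(data)) stop("subject ", subject_id, ": missing values in data")
  group <- match.arg(group, c("ASD", "CON"))
  age_group <- match.arg(age_group, c("juvenile", "adult"))
  eye_status <- match.arg(eye_status, c("open", "closed"))
  structure(list(subject_id = as.character(subject_id), data = data,
                 site = as.character(site), group = group,
                 age_group = age_group, age = age, full_iq = full_iq,
                 motion = motion, eye_status = eye_status, tr = tr,
                 srs = srs, normalized = FALSE,
                 flagged_parcels = integer(0)),
            class = "cap_subject")
}

#' @export
print.cap_subject <- function(x, ...) {
  cat(sprintf("<cap_subject %s> %d frames x %d parcels, site %s, %s %s%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$site, x$age_group,
              x$group, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Assemble subjects and an atlas into a cohort
#'
#' @param subjects list of [cap_subject] objects.
#' @param atlas data frame with columns `parcel_id` and `network`
#'   (one of ECN, DMN, DAN, Lim, SN, SM, Vis), optional `name`, `x`, `y`, `z`.
#'   Row order defines the parcel (column) order for every matrix in the
#'   analysis.
#' @return An object of class `cap_cohort`.
#' @export
cap_cohort <- function(subjects, atlas) {
  atlas <- validate_atlas(atlas)
  p <- nrow(atlas)
  bad <- vapply(subjects, function(s) ncol(s$data) != p, logical(1))
  if (any(bad))
    stop("parcel-count mismatch against atlas (", p, " parcels) for: ",
         paste(vapply(subjects[bad], `[[`, "", "subject_id"), collapse = ", "))
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicated subject_id in cohort")
  names(subjects) <- ids
  structure(list(subjects = subjects, atlas = atlas), class = "cap_cohort")
}

networks_7 <- c("ECN", "DMN", "DAN", "Lim", "SN", "SM", "Vis")

validate_atlas <- function(atlas) {
  atlas <- as.data.frame(atlas)
  need <- c("parcel_id", "network")
  if (!all(need %in% names(atlas)))
    stop("atlas must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(atlas$parcel_id)) stop("duplicated parcel_id in atlas")
  bad <- !atlas$network %in% networks_7
  if (any(bad))
    stop("unknown network label(s): ",
         paste(unique(atlas$network[bad]), collapse = ", "))
  atlas$parcel_id <- as.character(atlas$parcel_id)
  atlas$network <- factor(atlas$network, levels = networks_7)
  atlas
}

#' @export
print.cap_cohort <- function(x, ...) {
  ns <- length(x$subjects)
  fr <- vapply(x$subjects, function(s) nrow(s$data), integer(1))
  cat(sprintf("<cap_cohort> %d subjects, %d parcels, %d total frames, %d site(s)\n",
              ns, nrow(x$atlas), sum(fr),
              length(unique(vapply(x$subjects, `[[`, "", "site")))))
  invisible(x)
}

#' @export
`[.cap_cohort` <- function(x, i) {
  cap_cohort(x$subjects[i], x$atlas)
}

#' Per-subject metadata of a cohort as a data frame
#'
#' @param cohort a [cap_cohort].
#' @return data frame with one row per subject (id, site, group, age_group,
#'   age, full_iq, motion, eye_status, tr, n_frames and any SRS columns).
#' @export
cohort_manifest <- function(cohort) {
  subs <- cohort$subjects
  man <- data.frame(
    subject_id = vapply(subs, `[[`, "", "subject_id"),
    site = vapply(subs, `[[`, "", "site"),
    group = vapply(subs, `[[`, "", "group"),
    age_group = vapply(subs, `[[`, "", "age_group"),
    age = vapply(subs, `[[`, 0, "age"),
    full_iq = vapply(subs, `[[`, 0, "full_iq"),
    motion = vapply(subs, `[[`, 0, "motion"),
    eye_status = vapply(subs, `[[`, "", "eye_status"),
    tr = vapply(subs, `[[`, 0, "tr"),
    n_frames = vapply(subs, function(s) nrow(s$data), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  srs <- lapply(subs, `[[`, "srs")
  keys <- unique(unlist(lapply(srs, names)))
  for (k in keys)
    man[[k]] <- vapply(srs, function(v) if (is.null(v)) NA_real_ else
      unname(v[k]), 0)
  man
}

#' Load a cohort from delimited text files
#'
#' Reads a manifest CSV, one time-series file per subject (TSV or CSV,
#' frames as rows, parcels as columns, header row of parcel ids) and a
#' parcel/network atlas CSV. Errors across subjects are aggregated and
#' reported together.
#'
#' @param manifest_path CSV with columns `subject_id`, `site`, `group`,
#'   `age_group`, `age`, `full_iq`, `motion`, `eye_status`, `tr` and optional
#'   SRS columns.
#' @param timeseries_dir directory containing `<subject_id>.tsv` files.
#' @param atlas_path atlas CSV (see [cap_cohort]).
#' @return a [cap_cohort].
#' @export
load_cohort <- function(manifest_path, timeseries_dir, atlas_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  if (!file.exists(atlas_path)) stop("atlas not found: ", atlas_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "site", "group", "age_group", "age", "full_iq",
            "motion", "eye_status", "tr")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  atlas <- validate_atlas(utils::read.csv(atlas_path,
                                          stringsAsFactors = FALSE))
  srs_cols <- grep("^srs_", names(man), value = TRUE)
  errors <- character(0)
  subjects <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    id <- man$subject_id[i]
    f <- file.path(timeseries_dir, paste0(id, ".tsv"))
    if (!file.exists(f)) {
      errors <- c(errors, sprintf("subject %s: time-series file missing (%s)",
                                  id, f))
      next
    }
    x <- tryCatch(as.matrix(utils::read.delim(f, check.names = FALSE)),
                  error = function(e)
                    structure(sprintf("subject %s: parse error in %s: %s",
                                      id, f, conditionMessage(e)),
                              class = "cap_load_error"))
    if (inherits(x, "cap_load_error")) {
      errors <- c(errors, unclass(x)); next
    }
    if (!is.numeric(x)) {
      num <- suppressWarnings(array(as.numeric(x), dim(x)))
      bad <- which(is.na(num) & !is.na(x), arr.ind = TRUE)
      loc <- apply(utils::head(bad, 5L), 1L, function(rc)
        sprintf("row %d/col %d", rc[1], rc[2]))
      errors <- c(errors, sprintf(
        "subject %s: non-numeric cell(s) in %s at %s", id, f,
        paste(loc, collapse = ", ")))
      next
    }
    if (ncol(x) != nrow(atlas)) {
      errors <- c(errors, sprintf(
        "subject %s: %d parcels in file, atlas has %d", id, ncol(x),
        nrow(atlas)))
      next
    }
    srs <- NULL
    if (length(srs_cols)) {
      v <- unlist(man[i, srs_cols])
      if (!all(is.na(v))) srs <- v
    }
    subjects[[i]] <- cap_subject(id, x, man$site[i], man$group[i],
                                 man$age_group[i], man$age[i], man$full_iq[i],
                                 man$motion[i], man$eye_status[i], man$tr[i],
                                 srs = srs)
  }
  if (length(errors)) stop("cohort load failed:\n  ",
                           paste(errors, collapse = "\n  "))
  cap_cohort(subjects, atlas)
}

#' Write a cohort back to delimited text files
#'
#' Inverse of [load_cohort]: writes `manifest.csv`, `atlas.csv` and one
#' `<subject_id>.tsv` per subject under `dir`.
#'
#' @param cohort a [cap_cohort].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort_manifest(cohort),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$atlas, file.path(dir, "atlas.csv"),
                   row.names = FALSE)
  for (s in cohort$subjects) {
    d <- as.data.frame(s$data)
    names(d) <- cohort$atlas$parcel_id
    utils::write.table(d, file.path(dir, paste0(s$subject_id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Z-score each parcel's time course within a subject
#'
#' Standardizes every column (parcel) of the subject's frames x parcels
#' matrix to mean 0 and sample standard deviation 1, the usual preparation
#' before frame-wise clustering. Parcels with (numerically) zero temporal
#' variance are set to all-zero and recorded in `$flagged_parcels` rather
#' than dropped, so parcel indices stay aligned across subjects.
#'
#' @param sts a [cap_subject].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return the subject with normalized `$data` and `normalized = TRUE`.
#' @export
normalize_frames <- function(sts, sd_type = c("sample", "population")) {
  stopifnot(inherits(sts, "cap_subject"))
  sd_type <- match.arg(sd_type)
  x <- sts$data
  n <- nrow(x)
  if (n < 2L) stop("subject ", sts$subject_id, ": fewer than 2 frames")
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu, "-")
  ss <- sqrt(colSums(x^2) / if (sd_type == "sample") (n - 1) else n)
  flat <- which(ss < 1e-12)
  ss[flat] <- 1
  x <- sweep(x, 2L, ss, "/")
  if (length(flat)) x[, flat] <- 0
  sts$data <- x
  sts$normalized <- TRUE
  sts$flagged_parcels <- flat
  sts
}

#' Concatenate normalized subjects into one frame matrix
#'
#' Stacks all subjects' frames (subject order, then time order within
#' subject) into the matrix that frame-wise clustering operates on, with a
#' frame index recording each row's provenance.
#'
#' @param cohort a [cap_cohort] whose subjects are all normalized.
#' @return object of class `cap_frames`: list with `x` (total frames x
#'   parcels), `frame_index` (data frame `subject_id`, `frame`) and
#'   `parcel_ids`.
#' @export
concatenate_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "cap_cohort"))
  subs <- cohort$subjects
  if (!length(subs)) stop("empty cohort")
  if (!all(vapply(subs, `[[`, TRUE, "normalized")))
    stop("all subjects must be normalized first (see normalize_frames)")
  p <- unique(vapply(subs, function(s) ncol(s$data), integer(1)))
  if (length(p) != 1L) stop("heterogeneous parcel counts across subjects")
  nf <- vapply(subs, function(s) nrow(s$data), integer(1))
  x <- do.call(rbind, lapply(subs, `[[`, "data"))
  dimnames(x) <- NULL
  fi <- data.frame(
    subject_id = rep(vapply(subs, `[[`, "", "subject_id"), nf),
    frame = unlist(lapply(nf, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(x = x, frame_index = fi,
                 parcel_ids = cohort$atlas$parcel_id),
            class = "cap_frames")
}

#' @export
print.cap_frames <- function(x, ...) {
  cat(sprintf("<cap_frames> %d frames x %d parcels from %d subjects\n",
              nrow(x$x), ncol(x$x), length(unique(x$frame_index$subject_id))))
  invisible(x)
}

#' Split a frame matrix back into per-subject matrices
#'
#' @param fm a `cap_frames` object.
#' @return named list of frames x parcels matrices, one per subject.
#' @export
split_frames <- function(fm) {
  stopifnot(inherits(fm, "cap_frames"))
  ids <- unique(fm$frame_index$subject_id)
  out <- lapply(ids, function(id)
    fm$x[fm$frame_index$subject_id == id, , drop = FALSE])
  names(out) <- ids
  out
}

# rows of fm belonging to each subject, as an index list (preserves order)
.subject_rows <- function(fm) {
  split(seq_len(nrow(fm$x)),
        factor(fm$frame_index$subject_id,
               levels = unique(fm$frame_index$subject_id)))
}
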