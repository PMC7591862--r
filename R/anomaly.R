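#' Positive-clipped cosine similarity of two connectivity profiles
#'
#' Negative entries of *both* rows are set to zero independently (only
#' positive connectivity enters the comparison) and the cosine of the
#' clipped rows is returned: 1 means an identical positive connectivity
#' pattern, 0 an entirely dissimilar one. If either clipped row is all zero
#' the cosine is undefined and `NA` is returned (a degenerate profile, not a
#' dissimilar one).
#'
#' @param profile_row,reference_row Aligned numeric vectors (self-entry
#'   already removed); `NA` entries are ignored in both rows.
#' @return A similarity in `[0, 1]`, or `NA`.
#' @export
positive_cosine_similarity <- function(profile_row, reference_row) {
  if (length(profile_row) != length(reference_row)) {
    stop("profile and reference rows differ in length", call. = FALSE)
  }
  ok <- !is.na(profile_row) & !is.na(reference_row)
  a <- pmax(profile_row[ok], 0)
  b <- pmax(reference_row[ok], 0)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Voxel-wise similarity of a connectome to the reference
#'
#' Row-wise [positive_cosine_similarity()] between an individual connectome
#' and the group reference, after removing the excluded (tumour) voxels from
#' both. Each retained voxel gets one similarity; excluded voxels are
#' invalid by construction.
#'
#' @param connectome An `fca_connectome`.
#' @param reference An `fca_reference` (or any `fca_connectome`) on the same
#'   mask.
#' @param exclude Optional `fca_mask` of voxels to remove from both matrices
#'   before comparison.
#' @param space `"z"` compares the Fisher-z matrices as stored (default);
#'   `"r"` back-transforms to correlations first.
#' @return An object of class `fca_similarity`: `mask` (retained voxels),
#'   `values` (similarity per retained voxel, `NA` where degenerate) and
#'   `excluded` (sorted indices of the removed voxels).
#' @export
similarity_map <- function(connectome, reference, exclude = NULL,
                           space = c("z", "r")) {
  space <- match.arg(space)
  stopifnot(inherits(connectome, "fca_connectome"),
            inherits(reference, "fca_connectome"))
  if (!identical(connectome$mask$members, reference$mask$members) ||
      !same_grid(connectome$mask$grid, reference$mask$grid)) {
    stop("connectome and reference masks mismatch", call. = FALSE)
  }
  excluded <- integer(0)
  if (!is.null(exclude) && length(exclude$members)) {
    connectome <- drop_voxels(connectome, exclude)
    reference <- drop_voxels(reference, exclude)
    excluded <- sort(as.integer(exclude$members))
  }
  A <- connectome$values
  B <- reference$values
  if (space == "r") { A <- tanh(A); B <- tanh(B) }
  A <- pmax(A, 0); B <- pmax(B, 0)
  A[is.na(A)] <- 0; B[is.na(B)] <- 0   # NA diagonal: self-entry drops out
  dot <- rowSums(A * B)
  na2 <- rowSums(A^2); nb2 <- rowSums(B^2)
  sim <- ifelse(na2 > 0 & nb2 > 0, dot / sqrt(na2 * nb2), NA_real_)
  structure(list(mask = connectome$mask, values = sim, excluded = excluded,
                 space = space),
            class = "fca_similarity")
}

#' Build the control baseline distribution
#'
#' Per-voxel median and median absolute deviation (MAD) of the control
#' similarities. The MAD is used *raw* — no 1.4826 normal-consistency
#' factor — so anomaly scores are in plain MAD units, matching the
#' convention under which a score below -2.3 counts as highly anomalous;
#' `consistency = TRUE` switches the factor on. The exclusion set the
#' similarities were computed under is recorded, making the baseline
#' patient-specific.
#'
#' @param control_similarities List of >= 2 `fca_similarity` objects with
#'   identical masks and exclusion sets.
#' @param mad_floor Voxels with MAD below this floor are marked degenerate
#'   (scores there become invalid rather than infinite).
#' @param consistency Apply the 1.4826 normal-consistency factor to the MAD.
#' @return An object of class `fca_baseline` with per-voxel `median`, `mad`,
#'   the `excluded` set, `n_controls` and the degeneracy flags.
#' @export
build_baseline <- function(control_similarities, mad_floor = 1e-6,
                           consistency = FALSE) {
  sims <- control_similarities
  if (!is.list(sims) || length(sims) < 2L) {
    stop("need at least 2 control similarity maps", call. = FALSE)
  }
  stopifnot(all(vapply(sims, inherits, logical(1), "fca_similarity")))
  first <- sims[[1]]
  for (s in sims[-1]) {
    if (!identical(s$mask$members, first$mask$members) ||
        !identical(s$excluded, first$excluded)) {
      stop("control similarities differ in mask or exclusion set", call. = FALSE)
    }
  }
  S <- do.call(cbind, lapply(sims, `[[`, "values"))
  n_valid <- rowSums(!is.na(S))
  med <- apply(S, 1, stats::median, na.rm = TRUE)
  mad_raw <- apply(abs(S - med), 1, stats::median, na.rm = TRUE)
  if (consistency) mad_raw <- mad_raw * 1.4826
  invalid <- n_valid < 2L
  med[invalid] <- NA_real_
  mad_raw[invalid] <- NA_real_
  structure(list(mask = first$mask, median = med, mad = mad_raw,
                 degenerate = !invalid & mad_raw < mad_floor,
                 excluded = first$excluded, n_controls = length(sims),
                 mad_floor = mad_floor, consistency = consistency),
            class = "fca_baseline")
}

#' Score a similarity map against a baseline
#'
#' The anomaly score is `(similarity - median) / MAD` per voxel: a robust z
#' quantifying how far a voxel's connectivity-profile similarity falls from
#' the control baseline (negative = deteriorated). Voxels with degenerate
#' baselines (MAD below the floor), invalid similarities, or in the
#' exclusion set are invalid (`NA`), never infinite.
#'
#' @param similarity An `fca_similarity`.
#' @param baseline An `fca_baseline` built under the *same* exclusion set
#'   (a mismatch means the baseline is not patient-specific and is an
#'   error).
#' @param subject,session_index,session_label Session metadata carried on
#'   the map.
#' @return An object of class `fca_anomaly` covering the full analysis mask
#'   (retained plus excluded voxels); excluded voxels are always invalid.
#' @export
anomaly_score <- function(similarity, baseline, subject = "subject",
                          session_index = 0L, session_label = "pre") {
  stopifnot(inherits(similarity, "fca_similarity"),
            inherits(baseline, "fca_baseline"))
  if (!identical(similarity$excluded, baseline$excluded) ||
      !identical(similarity$mask$members, baseline$mask$members)) {
    stop("similarity and baseline exclusion sets differ: ",
         "the baseline is not specific to this patient", call. = FALSE)
  }
  score <- (similarity$values - baseline$median) / baseline$mad
  score[baseline$degenerate | is.na(baseline$median)] <- NA_real_
  score[is.na(similarity$values)] <- NA_real_
  grid <- similarity$mask$grid
  full_members <- sort(c(similarity$mask$members, similarity$excluded))
  full_score <- rep(NA_real_, length(full_members))
  full_score[match(similarity$mask$members, full_members)] <- score
  structure(list(grid = grid, mask = voxel_mask(grid, full_members),
                 score = full_score, excluded = similarity$excluded,
                 subject = subject, session_index = as.integer(session_index),
                 session_label = session_label),
            class = "fca_anomaly")
}

#' @export
print.fca_anomaly <- function(x, ...) {
  v <- x$score[!is.na(x$score)]
  cat(sprintf(paste0("<fca_anomaly> %s [%s]: %d voxels (%d valid), ",
                     "median %.2f, %.1f%% below -2.3\n"),
              x$subject, x$session_label, length(x$score), length(v),
              stats::median(v), 100 * mean(v < -2.3)))
  invisible(x)
}

#' @export
as_tibble.fca_anomaly <- function(x, ...) {
  xyz <- voxel_coords(x$grid, x$mask$members)
  tibble::tibble(voxel = x$mask$members,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 score = x$score,
                 excluded = x$mask$members %in% x$excluded,
                 subject = x$subject,
                 session_index = x$session_index,
                 session_label = x$session_label)
}

#' Patient-specific anomaly map with tumour exclusion
#'
#' The full scoring pipeline for one session: remove the (already smoothed,
#' see [smooth_tumour_mask()]) tumour exclusion mask from the patient and
#' every control connectome, recompute the control similarities and the
#' median/MAD baseline on the reduced voxel set, and score the patient.
#' Because the baseline is rebuilt under the patient's own exclusion set, it
#' is patient-specific by construction.
#'
#' @param patient An `fca_ts` or `fca_connectome` for the session.
#' @param controls List of `fca_ts` or `fca_connectome` objects (the control
#'   cohort). Time series are converted one at a time so only one dense
#'   matrix is in memory per control.
#' @param exclude `fca_mask` of voxels to exclude (typically
#'   `smooth_tumour_mask(seg)`); `NULL` or empty excludes nothing.
#' @param reference Optional precomputed `fca_reference` (before exclusion);
#'   computed from `controls` when `NULL`.
#' @param clip,space,consistency,mad_floor Forwarded to the component steps.
#' @return An `fca_anomaly`.
#' @export
patient_anomaly <- function(patient, controls, exclude = NULL,
                            reference = NULL, clip = 1e-6,
                            space = c("z", "r"), consistency = FALSE,
                            mad_floor = 1e-6) {
  space <- match.arg(space)
  as_conn <- function(x) {
    if (inherits(x, "fca_ts")) compute_connectome(x, clip = clip) else x
  }
  if (is.null(reference)) reference <- mean_reference(controls, clip = clip)
  control_sims <- lapply(controls, function(x) {
    similarity_map(as_conn(x), reference, exclude = exclude, space = space)
  })
  baseline <- build_baseline(control_sims, mad_floor = mad_floor,
                             consistency = consistency)
  pat_conn <- as_conn(patient)
  pat_sim <- similarity_map(pat_conn, reference, exclude = exclude, space = space)
  meta <- if (inherits(patient, "fca_ts")) {
    list(patient$subject, patient$session_index, patient$session_label)
  } else list("patient", 0L, "pre")
  anomaly_score(pat_sim, baseline, subject = meta[[1]],
                session_index = meta[[2]], session_label = meta[[3]])
}

#' Look up anomaly scores for a voxel set
#'
#' @param anomaly An `fca_anomaly`.
#' @param voxels An `fca_mask` or integer voxel indices.
#' @param drop_na Drop invalid scores.
#' @return Numeric vector of scores (named by voxel index).
#' @export
anomaly_at <- function(anomaly, voxels, drop_na = TRUE) {
  stopifnot(inherits(anomaly, "fca_anomaly"))
  members <- if (inherits(voxels, "fca_mask")) voxels$members else as.integer(voxels)
  idx <- match(members, anomaly$mask$members)
  out <- anomaly$score[idx]
  names(out) <- members
  if (drop_na) out <- out[!is.na(out)]
  out
}
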