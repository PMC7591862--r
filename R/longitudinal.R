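#' Align anomaly trajectories to the pre-surgical baseline
#'
#' Subtracts each patient's session-0 (pre-surgical) median anomaly from
#' every session, per network x side x compartment cell, so trajectories
#' start at 0 and measure change relative to diagnosis.
#'
#' @param tables Row-bound [network_median_anomaly()] tables across sessions
#'   (`session_index` 0 = pre-surgery must be present per patient).
#' @return A tibble of trajectory points: `patient`, `session_index`,
#'   `network`, `side`, `compartment`, `value` (baseline-subtracted median
#'   anomaly).
#' @export
align_trajectories <- function(tables) {
  need <- c("patient", "session_index", "network", "side", "compartment",
            "median_score")
  if (!all(need %in% names(tables))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  has_pre <- tables |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(pre = any(.data$session_index == 0L))
  if (!all(has_pre$pre)) {
    stop("missing pre-surgical (session 0) table for patient(s): ",
         paste(has_pre$patient[!has_pre$pre], collapse = ", "), call. = FALSE)
  }
  tables |>
    dplyr::group_by(.data$patient, .data$network, .data$side, .data$compartment) |>
    dplyr::mutate(value = .data$median_score -
                    .data$median_score[.data$session_index == 0L][1]) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("patient", "session_index", "network",
                                  "side", "compartment", "value"))) |>
    dplyr::arrange(.data$patient, .data$session_index, .data$network)
}

#' Fit a quadratic trend to pooled trajectory points
#'
#' Ordinary least-squares fit of `value = a + b*session + c*session^2`
#' pooled across patients, with the r-squared and root mean squared error
#' characterising the fit. A positive quadratic coefficient with a negative
#' linear one is the transient-deterioration-then-recovery shape.
#'
#' @param points A data frame with columns `session` (or `session_index`)
#'   and `value`; >= 3 distinct session values required.
#' @return An object of class `fca_trend` with `coefficients` (a, b, c),
#'   `r_squared`, `rmse`, `n` and the underlying `lm` fit.
#' @export
fit_quadratic_trend <- function(points) {
  df <- as.data.frame(points)
  if (!"session" %in% names(df) && "session_index" %in% names(df)) {
    df$session <- df$session_index
  }
  stopifnot(all(c("session", "value") %in% names(df)))
  df <- df[is.finite(df$session) & is.finite(df$value), ]
  if (length(unique(df$session)) < 3L) {
    stop("need >= 3 distinct session values for a quadratic fit", call. = FALSE)
  }
  fit <- stats::lm(value ~ session + I(session^2), data = df)
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((df$value - mean(df$value))^2)
  structure(list(
    coefficients = c(a = unname(stats::coef(fit)[1]),
                     b = unname(stats::coef(fit)[2]),
                     c = unname(stats::coef(fit)[3])),
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(mean(res^2)),
    n = nrow(df),
    fit = fit,
    data = tibble::as_tibble(df[, c("session", "value")])),
    class = "fca_trend")
}

#' @export
print.fca_trend <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<fca_trend> value = %.3g %+.3g s %+.3g s^2 (n = %d, r2 = %s, RMSE = %.3g)\n",
              co["a"], co["b"], co["c"], x$n,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              x$rmse))
  invisible(x)
}

#' @export
tidy.fca_trend <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "session", "session^2"),
                 estimate = unname(x$coefficients))
}

#' @export
glance.fca_trend <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, rmse = x$rmse, nobs = x$n)
}

#' New tumour voxels between two sessions
#'
#' Enhancing or necrotic tumour present at `t1` but absent (as enhancing,
#' necrotic or resection) at `t0`: the prospectively emerging tumour.
#'
#' @param seg_t0,seg_t1 `fca_seg` objects on the same grid.
#' @return An `fca_mask`.
#' @export
new_tumour_voxels <- function(seg_t0, seg_t1) {
  stopifnot(inherits(seg_t0, "fca_seg"), inherits(seg_t1, "fca_seg"))
  assert_same_grid(seg_t1$grid, seg_t0$grid, "segmentation")
  t1 <- seg_mask(seg_t1, c("enhancing", "necrotic"))
  t0 <- seg_mask(seg_t0, c("enhancing", "necrotic", "resection"))
  mask_setdiff(t1, t0)
}

#' Tumour vicinity rim
#'
#' All analysis voxels whose centre lies within `margin_mm` of any voxel of
#' the previous tumour or resection cavity, excluding the prior
#' tumour/resection voxels themselves — a rim around the structurally
#' affected region that serves as the comparison baseline for recurrence
#' prediction.
#'
#' @param seg_t0 The earlier session's `fca_seg`; its lesion (all tumour
#'   classes plus resection) must be nonempty.
#' @param margin_mm Rim width in mm (default 10, i.e. 1 cm).
#' @param analysis_mask Optional `fca_mask` restricting the rim (e.g. the
#'   study's grey-matter mask); defaults to the whole grid.
#' @return An `fca_mask`.
#' @export
tumour_vicinity <- function(seg_t0, margin_mm = 10, analysis_mask = NULL) {
  stopifnot(inherits(seg_t0, "fca_seg"))
  if (margin_mm <= 0) stop("`margin_mm` must be > 0", call. = FALSE)
  lesion <- seg_mask(seg_t0)
  if (!length(lesion$members)) stop("empty tumour/resection at t0", call. = FALSE)
  grid <- seg_t0$grid
  cand <- if (is.null(analysis_mask)) seq_len(n_voxels(grid)) else {
    assert_same_grid(analysis_mask$grid, grid, "analysis mask")
    analysis_mask$members
  }
  cand <- setdiff(cand, lesion$members)
  if (!length(cand)) return(voxel_mask(grid, integer(0)))
  d <- nearest_distance_mm(grid, cand, lesion$members)
  voxel_mask(grid, cand[d <= margin_mm])
}

#' Minimum-volume filter for new tumour
#'
#' Tests whether a voxel set reaches the minimum volume (default 3 cm^3)
#' required for a recurrence analysis; smaller new-tumour labels are treated
#' as potential segmentation error and skipped.
#'
#' @param mask An `fca_mask`.
#' @param min_cm3 Minimum volume in cm^3.
#' @return `TRUE` iff `|mask| * voxel volume >= min_cm3 * 1000` mm^3.
#' @export
volume_filter <- function(mask, min_cm3 = 3) {
  stopifnot(inherits(mask, "fca_mask"))
  voxel_mm3 <- prod(mask$grid$spacing)
  length(mask$members) * voxel_mm3 >= min_cm3 * 1000
}

#' Does anomaly at t0 predict the location of recurrence at t1?
#'
#' Compares the anomaly scores of prospectively emerging tumour voxels
#' (new enhancing/necrotic at `t1`) against the other voxels of the tumour
#' vicinity at `t0`, with (i) a one-sided two-sample permutation test on the
#' difference in means (future voxels more anomalous, i.e. lower scores) and
#' (ii) the AUC of the negated anomaly score as a voxel-wise predictor of
#' future-tumour membership among future-union-vicinity voxels, with its own
#' label-permutation p-value.
#'
#' @param anomaly_t0 The `fca_anomaly` of the earlier session.
#' @param future_mask `fca_mask` of new tumour voxels ([new_tumour_voxels()]).
#' @param vicinity_mask `fca_mask` of the comparison rim
#'   ([tumour_vicinity()]); future voxels are removed from it internally.
#' @param n_perm Permutation budget (default 10000; exhaustive when the
#'   assignment count allows).
#' @param seed Seed for the permutation draws.
#' @return An object of class `fca_recurrence`: a list with `n_future`,
#'   `n_vicinity`, `mean_future`, `mean_vicinity`, `perm` (`fca_perm` for
#'   the mean difference), `auc`, `auc_perm` (`fca_perm` for the AUC).
#' @export
recurrence_test <- function(anomaly_t0, future_mask, vicinity_mask,
                            n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(anomaly_t0, "fca_anomaly"))
  vic_members <- setdiff(vicinity_mask$members, future_mask$members)
  future <- anomaly_at(anomaly_t0, future_mask$members)
  vicinity <- anomaly_at(anomaly_t0, vic_members)
  if (!length(future) || !length(vicinity)) {
    stop("no valid anomaly scores in the future or vicinity set", call. = FALSE)
  }
  perm <- two_sample_permutation(future, vicinity, statistic = "mean_diff",
                                 alternative = "less", n_perm = n_perm,
                                 seed = seed)
  scores <- c(future, vicinity)
  labels <- c(rep(TRUE, length(future)), rep(FALSE, length(vicinity)))
  auc <- auc_mann_whitney(-scores, labels)
  auc_perm <- two_sample_permutation(
    -future, -vicinity,
    statistic = function(a, b) {
      auc_mann_whitney(c(a, b), c(rep(TRUE, length(a)), rep(FALSE, length(b))))
    },
    alternative = "greater", n_perm = n_perm, seed = seed + 1L)
  structure(list(n_future = length(future), n_vicinity = length(vicinity),
                 mean_future = mean(future), mean_vicinity = mean(vicinity),
                 perm = perm, auc = auc, auc_perm = auc_perm),
            class = "fca_recurrence")
}

#' @export
print.fca_recurrence <- function(x, ...) {
  cat(sprintf(paste0("<fca_recurrence> %d future vs %d vicinity voxels: ",
                     "mean %.2f vs %.2f, p = %.4g; AUC = %.3f (p = %.4g)\n"),
              x$n_future, x$n_vicinity, x$mean_future, x$mean_vicinity,
              x$perm$p, x$auc, x$auc_perm$p))
  invisible(x)
}

#' @export
tidy.fca_recurrence <- function(x, ...) {
  tibble::tibble(n_future = x$n_future, n_vicinity = x$n_vicinity,
                 mean_future = x$mean_future, mean_vicinity = x$mean_vicinity,
                 p_mean = x$perm$p, auc = x$auc, p_auc = x$auc_perm$p)
}
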