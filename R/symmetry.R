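#' Median anomaly per network, hemisphere and compartment
#'
#' Summarises an anomaly map into the 7 networks x {ipsi, contra} x
#' {cerebrum, cerebellum} cells, taking the median over valid voxels of
#' each cell. Ipsi/contra is the anatomical hemisphere relative to the
#' declared tumour hemisphere, in the cerebellum as well as the cerebrum.
#'
#' @param anomaly An `fca_anomaly`.
#' @param parcellation An `fca_parcellation`.
#' @param tumour_hemisphere `"L"` or `"R"`.
#' @param patient Patient identifier for the output rows.
#' @return A tibble with columns `patient`, `session_index`, `network`,
#'   `side` (`"ipsi"`/`"contra"`), `compartment`, `median_score`, `n_voxels`
#'   (valid voxels; `median_score` is `NA` when the cell has none).
#' @export
network_median_anomaly <- function(anomaly, parcellation, tumour_hemisphere,
                                   patient = anomaly$subject) {
  stopifnot(inherits(anomaly, "fca_anomaly"),
            tumour_hemisphere %in% c("L", "R"))
  sc <- anomaly_at(anomaly, parcellation$voxel, drop_na = FALSE)
  df <- tibble::tibble(
    network = parcellation$network,
    side = ifelse(parcellation$hemisphere == tumour_hemisphere, "ipsi", "contra"),
    compartment = parcellation$compartment,
    score = unname(sc)
  )
  grid_cells <- tidyr::expand_grid(network = network_names,
                                   side = c("ipsi", "contra"),
                                   compartment = c("cerebrum", "cerebellum"))
  out <- df |>
    dplyr::group_by(.data$network, .data$side, .data$compartment) |>
    dplyr::summarise(
      median_score = if (any(!is.na(.data$score))) {
        stats::median(.data$score, na.rm = TRUE)
      } else NA_real_,
      n_voxels = sum(!is.na(.data$score)), .groups = "drop")
  grid_cells |>
    dplyr::left_join(out, by = c("network", "side", "compartment")) |>
    dplyr::mutate(n_voxels = dplyr::coalesce(.data$n_voxels, 0L),
                  patient = patient,
                  session_index = anomaly$session_index, .before = 1)
}

# Wide ipsi/contra matrices (patients x networks) for one compartment.
symmetry_matrices <- function(table, compartment) {
  tab <- table[table$compartment == compartment, ]
  wide <- function(side) {
    w <- tab[tab$side == side, c("patient", "network", "median_score")] |>
      tidyr::pivot_wider(names_from = "network", values_from = "median_score")
    m <- as.matrix(w[, network_names])
    rownames(m) <- w$patient
    m
  }
  list(ipsi = wide("ipsi"), contra = wide("contra"))
}

#' Bi-hemispheric symmetry correlations
#'
#' For every pair (network_i ipsilateral, network_j contralateral), the
#' Pearson correlation across patients of the median anomaly scores, and its
#' r-squared; computed separately for cerebrum and cerebellum. The diagonal
#' measures within-network bi-hemispheric symmetry; the off-diagonal entries
#' measure cross-network coupling.
#'
#' @param table Row-bound [network_median_anomaly()] tables of >= 3
#'   patients.
#' @return A tibble with columns `compartment`, `network_ipsi`,
#'   `network_contra`, `r`, `r2` (`NA` where a column is constant).
#' @export
symmetry_correlation <- function(table) {
  if (dplyr::n_distinct(table$patient) < 3L) {
    stop("need at least 3 patients", call. = FALSE)
  }
  purrr::map_dfr(c("cerebrum", "cerebellum"), function(cp) {
    m <- symmetry_matrices(table, cp)
    tidyr::expand_grid(network_ipsi = network_names,
                       network_contra = network_names) |>
      dplyr::mutate(
        compartment = cp, .before = 1) |>
      dplyr::rowwise() |>
      dplyr::mutate(r = {
        a <- m$ipsi[, .data$network_ipsi]; b <- m$contra[, .data$network_contra]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
          NA_real_
        } else stats::cor(a[ok], b[ok])
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(r2 = .data$r^2)
  })
}

#' Test within-network excess of bi-hemispheric symmetry
#'
#' Statistic: mean diagonal r-squared minus mean off-diagonal r-squared of
#' the [symmetry_correlation()] matrix for one compartment. The null
#' distribution permutes the network identity of the contralateral columns
#' (a relabelling under which no network is preferentially matched with its
#' own contralateral counterpart).
#'
#' @param table Row-bound [network_median_anomaly()] tables.
#' @param compartment `"cerebrum"` or `"cerebellum"`.
#' @param n_perm Number of sampled relabellings.
#' @param seed Seed for the permutation draw.
#' @return An `fca_perm` (one-sided: diagonal excess).
#' @export
symmetry_diag_test <- function(table, compartment = "cerebrum",
                               n_perm = 999L, seed = 1L) {
  m <- symmetry_matrices(table, compartment)
  diag_stat <- function(contra) {
    r2 <- suppressWarnings(stats::cor(m$ipsi, contra))^2
    mean(diag(r2), na.rm = TRUE) - mean(r2[row(r2) != col(r2)], na.rm = TRUE)
  }
  observed <- diag_stat(m$contra)
  stats_null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      diag_stat(m$contra[, sample.int(7L), drop = FALSE])
    }, numeric(1))
  })
  new_perm_result(observed, stats_null, "greater", exhaustive = FALSE, seed)
}

#' Lesion-network map of a tumour
#'
#' The normative projection of a lesion into network space: voxel `v` is
#' counted once for every tumour voxel `t` whose reference (control-average)
#' connectivity `z(v, t)` exceeds the threshold — i.e. all regions
#' functionally connected to the patient's tumour-bearing voxels in
#' controls.
#'
#' @param tumour_mask Nonempty `fca_mask` of tumour voxels.
#' @param reference The full `fca_reference`.
#' @param threshold Fisher-z connectivity threshold (default
#'   `atanh(0.25)`).
#' @return A tibble of class `fca_lesion_map` with columns `voxel`, `count`,
#'   `connected` (`count > 0`), over the non-tumour reference voxels.
#' @export
lesion_map <- function(tumour_mask, reference, threshold = atanh(0.25)) {
  stopifnot(inherits(tumour_mask, "fca_mask"), inherits(reference, "fca_connectome"))
  tum <- intersect(tumour_mask$members, reference$mask$members)
  if (!length(tum)) stop("empty tumour mask", call. = FALSE)
  rows <- match(tum, reference$mask$members)
  others <- setdiff(reference$mask$members, tum)
  cols <- match(others, reference$mask$members)
  Z <- reference$values[rows, cols, drop = FALSE]
  count <- colSums(Z > threshold, na.rm = TRUE)
  out <- tibble::tibble(voxel = others, count = as.integer(count),
                        connected = count > 0L)
  attr(out, "threshold") <- threshold
  class(out) <- c("fca_lesion_map", class(out))
  out
}

#' Lesion-map / anomaly overlap correlation curves
#'
#' For a group of patients with tumours on the same side, correlates the
#' across-patient overlap of binarised lesion-maps with the across-patient
#' overlap of thresholded anomaly maps, per cerebellar (or cerebral)
#' hemisphere and over a range of anomaly thresholds; then contrasts the
#' contralateral against the ipsilateral correlations with a paired
#' sign-flip permutation test across thresholds. A crossed cerebellar
#' representation shows up as higher overlap correlation in the hemisphere
#' contralateral to the tumours.
#'
#' The overlap of a set of maps is the per-voxel count of patients whose
#' binarised map covers the voxel (voxels excluded for a patient do not
#' count for that patient).
#'
#' @param lesion_maps List of [lesion_map()] results, one per patient.
#' @param anomaly_maps List of `fca_anomaly`, aligned with `lesion_maps`.
#' @param parcellation An `fca_parcellation`.
#' @param tumour_side `"L"` or `"R"`: the (common) tumour hemisphere of the
#'   group.
#' @param anomaly_thresholds Anomaly score magnitudes `t`; a voxel counts as
#'   anomalous when its score is below `-t`.
#' @param compartment Compartment to evaluate (default `"cerebellum"`).
#' @param n_perm,seed Forwarded to [paired_sign_flip_test()] (the contrast
#'   is exhaustive for the default 5-threshold grid).
#' @return A list with `curves` (tibble: `threshold`, `side`, `hemisphere`,
#'   `r`) and `contrast` (an `fca_perm`, one-sided contra > ipsi).
#' @export
lesion_anomaly_overlap <- function(lesion_maps, anomaly_maps, parcellation,
                                   tumour_side,
                                   anomaly_thresholds = c(1.5, 2, 2.3, 2.6, 3),
                                   compartment = "cerebellum",
                                   n_perm = 10000L, seed = 1L) {
  stopifnot(length(lesion_maps) == length(anomaly_maps),
            length(lesion_maps) >= 2L, tumour_side %in% c("L", "R"))
  voxels <- parcellation$voxel[parcellation$compartment == compartment]
  hemi <- parcellation$hemisphere[parcellation$compartment == compartment]
  lesion_overlap <- rowSums(vapply(lesion_maps, function(lm) {
    hit <- lm$connected[match(voxels, lm$voxel)]
    as.numeric(!is.na(hit) & hit)
  }, numeric(length(voxels))))
  anomaly_overlap <- function(thr) {
    rowSums(vapply(anomaly_maps, function(am) {
      sc <- anomaly_at(am, voxels, drop_na = FALSE)
      as.numeric(!is.na(sc) & sc < -thr)
    }, numeric(length(voxels))))
  }
  curves <- purrr::map_dfr(anomaly_thresholds, function(thr) {
    ao <- anomaly_overlap(thr)
    purrr::map_dfr(c("L", "R"), function(h) {
      sel <- hemi == h
      r <- if (stats::sd(lesion_overlap[sel]) == 0 ||
               stats::sd(ao[sel]) == 0) NA_real_
      else stats::cor(lesion_overlap[sel], ao[sel])
      tibble::tibble(threshold = thr,
                     hemisphere = h,
                     side = ifelse(h == tumour_side, "ipsi", "contra"),
                     r = r)
    })
  })
  d <- curves$r[curves$side == "contra"] - curves$r[curves$side == "ipsi"]
  contrast <- if (sum(d != 0, na.rm = TRUE) >= 2) {
    paired_sign_flip_test(d[!is.na(d)], alternative = "greater",
                          n_perm = n_perm, seed = seed)
  } else {
    # degenerate: the two hemispheres are indistinguishable at every
    # threshold, so there is no evidence of a contrast
    fcanomaly_degenerate_perm(mean(d, na.rm = TRUE), seed)
  }
  list(curves = curves, contrast = contrast)
}
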