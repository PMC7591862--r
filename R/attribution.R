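#' Spatial and functional distance fields of one tumour voxel
#'
#' For a single tumour voxel, computes over all non-tumour analysis voxels:
#' the Euclidean distance in mm (*spatial distance*) and the absolute
#' correlation of the control-average connectome (*functional proximity*,
#' back-transformed from Fisher z). Both predictors are oriented as
#' distances — functional distance is `1 - proximity` — so for either kind a
#' *positive* Pearson correlation with the anomaly score means anomaly
#' deepens with closeness.
#'
#' @param tumour_voxel Linear voxel index of the tumour voxel; must be in
#'   the reference mask.
#' @param reference The full (un-excluded) `fca_reference`.
#' @param analysis_voxels Integer vector of non-tumour voxel indices over
#'   which the fields are evaluated.
#' @return A tibble with columns `voxel`, `spatial_mm`, `proximity`,
#'   `functional_distance`.
#' @export
distance_fields <- function(tumour_voxel, reference, analysis_voxels) {
  stopifnot(inherits(reference, "fca_connectome"))
  tumour_voxel <- as.integer(tumour_voxel)
  row <- match(tumour_voxel, reference$mask$members)
  if (is.na(row)) stop("tumour voxel ", tumour_voxel, " not in the reference mask",
                       call. = FALSE)
  cols <- match(analysis_voxels, reference$mask$members)
  if (any(is.na(cols))) stop("analysis voxels outside the reference mask",
                             call. = FALSE)
  grid <- reference$mask$grid
  t_xyz <- voxel_coords(grid, tumour_voxel)
  a_xyz <- voxel_coords(grid, analysis_voxels)
  spatial <- sqrt(rowSums(sweep(a_xyz, 2, as.numeric(t_xyz), `-`)^2))
  z <- reference$values[row, cols]
  proximity <- abs(tanh(z))        # self-entry would be NA; tumour voxels
  proximity[is.na(proximity)] <- 1 # are not analysis voxels anyway
  tibble::tibble(voxel = as.integer(analysis_voxels), spatial_mm = spatial,
                 proximity = proximity, functional_distance = 1 - proximity)
}

#' Attribute one tumour voxel's anomaly relationship
#'
#' Correlates the anomaly scores of highly anomalous non-tumour voxels
#' (score below `anomaly_threshold`) with the tumour voxel's spatial and
#' functional distance fields and labels the voxel by the distance kind with
#' the larger positive correlation. A positive correlation means deeper
#' anomaly at closer voxels. Voxels with no positive relationship are
#' labelled `"none"`, as are exact ties and voxels with fewer than 3 usable
#' anomalous voxels (reason recorded).
#'
#' @param anomaly An `fca_anomaly`.
#' @param fields Output of [distance_fields()] for the tumour voxel.
#' @param anomaly_threshold Scores below this count as highly anomalous
#'   (default -2.3).
#' @param subset `"anomalous"` restricts the correlations to the highly
#'   anomalous voxels (default); `"all"` uses every valid non-tumour voxel.
#' @return A one-row tibble: `r_spatial`, `r_functional`, `label`
#'   (`"functional"`, `"spatial"` or `"none"`), `n_used`, `reason`.
#' @export
attribute_voxel <- function(anomaly, fields, anomaly_threshold = -2.3,
                            subset = c("anomalous", "all")) {
  subset <- match.arg(subset)
  stopifnot(inherits(anomaly, "fca_anomaly"))
  sc <- anomaly_at(anomaly, fields$voxel, drop_na = FALSE)
  use <- !is.na(sc)
  if (subset == "anomalous") use <- use & sc < anomaly_threshold
  n_used <- sum(use)
  if (n_used < 3L) {
    return(tibble::tibble(r_spatial = NA_real_, r_functional = NA_real_,
                          label = "none", n_used = n_used,
                          reason = "fewer than 3 anomalous voxels"))
  }
  safe_cor <- function(d) {
    if (stats::sd(d[use]) == 0 || stats::sd(sc[use]) == 0) return(NA_real_)
    stats::cor(d[use], sc[use])
  }
  r_s <- safe_cor(fields$spatial_mm)
  r_f <- safe_cor(fields$functional_distance)
  pos_s <- !is.na(r_s) && r_s > 0
  pos_f <- !is.na(r_f) && r_f > 0
  label <- if (pos_s && pos_f) {
    if (r_f > r_s) "functional" else if (r_s > r_f) "spatial" else "none"
  } else if (pos_f) "functional" else if (pos_s) "spatial" else "none"
  reason <- if (label == "none") {
    if (!pos_s && !pos_f) "no positive relationship" else "exact tie"
  } else NA_character_
  tibble::tibble(r_spatial = r_s, r_functional = r_f, label = label,
                 n_used = n_used, reason = reason)
}

#' Attribute a patient's tumour voxels
#'
#' Runs [distance_fields()] + [attribute_voxel()] for every tumour voxel of
#' a patient (voxels labelled enhancing or necrotic in the unsmoothed
#' segmentation) and attaches each voxel's network identity.
#'
#' @param anomaly The patient's `fca_anomaly` (tumour-excluded).
#' @param seg The patient's `fca_seg`.
#' @param reference The full `fca_reference` (before exclusion).
#' @param parcellation An `fca_parcellation`.
#' @param anomaly_threshold,subset Forwarded to [attribute_voxel()].
#' @return A tibble with one row per tumour voxel: `voxel`, `network`,
#'   `r_spatial`, `r_functional`, `label`, `n_used`, `reason`.
#' @export
attribute_patient <- function(anomaly, seg, reference, parcellation,
                              anomaly_threshold = -2.3,
                              subset = c("anomalous", "all")) {
  subset <- match.arg(subset)
  tumour <- seg_mask(seg, c("enhancing", "necrotic"))
  tumour_members <- intersect(tumour$members, reference$mask$members)
  if (!length(tumour_members)) stop("no enhancing/necrotic tumour voxels",
                                    call. = FALSE)
  analysis <- setdiff(anomaly$mask$members, seg_mask(seg)$members)
  analysis <- setdiff(analysis, anomaly$excluded)
  net <- parcellation$network[match(tumour_members, parcellation$voxel)]
  purrr::map2_dfr(tumour_members, net, function(tv, nw) {
    fields <- distance_fields(tv, reference, analysis)
    res <- attribute_voxel(anomaly, fields, anomaly_threshold, subset)
    dplyr::bind_cols(tibble::tibble(voxel = tv, network = nw), res)
  })
}

#' Summarise attribution over patients
#'
#' Per patient: the percentage of enhancing/necrotic tumour voxels whose
#' anomaly follows functional proximity, spatial distance, or neither.
#' Percentages sum to 100 within each patient.
#'
#' @param results A tibble of [attribute_patient()] outputs with an added
#'   `patient` column (rows from several patients may be concatenated).
#' @return A tibble with one row per patient x label:
#'   `patient`, `label`, `n_voxels`, `percent`.
#' @export
attribution_summary <- function(results) {
  if (!nrow(results)) stop("no attributed tumour voxels", call. = FALSE)
  if (!"patient" %in% names(results)) results$patient <- "patient"
  results |>
    dplyr::mutate(label = factor(.data$label,
                                 levels = c("functional", "spatial", "none"))) |>
    dplyr::count(.data$patient, .data$label, .drop = FALSE, name = "n_voxels") |>
    dplyr::group_by(.data$patient) |>
    dplyr::mutate(percent = 100 * .data$n_voxels / sum(.data$n_voxels)) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = as.character(.data$label))
}
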