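#' Run the full anomaly-mapping study pipeline
#'
#' Orchestrates the whole analysis from a YAML (or list) configuration:
#' cohort input (simulated phantom cohort, or NIfTI files), connectome and
#' reference construction, patient-specific anomaly maps with tumour
#' exclusion, functional-vs-spatial attribution, network symmetry tables,
#' and — when a longitudinal block is configured — trajectory alignment
#' with a quadratic trend fit and the recurrence-location test. All tabular
#' outputs are TSV and all maps NIfTI; given the same configuration and
#' seeds the outputs are reproduced byte-identically.
#'
#' The configuration must name the control cohort (`controls`), the patient
#' list (`patients`), the output directory (`output_dir`) and the study
#' `seed`; in file mode it must also name the `parcellation`. Validation
#' runs before any computation; any stage failure aborts with the stage name
#' and the offending subject.
#'
#' @param config Path to a YAML file, or an equivalent nested list.
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, a list with the study objects (`phantom`/`parcellation`,
#'   `reference`, `anomalies`, `tables`) and the written file manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_config_yaml(config) else config
  validate_config(cfg)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  an <- cfg$analysis %||% list()
  thr <- an$anomaly_threshold %||% -2.3
  fwhm <- an$exclusion_fwhm %||% 3

  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for %s: %s", name, subject,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## ---- inputs ----
  simulate_mode <- !is.null(cfg$controls$n)
  if (simulate_mode) {
    phantom <- stage("inputs", "phantom", {
      ph_cfg <- cfg$phantom %||% list(size = "compact")
      if (!is.null(ph_cfg$size)) phantom_demo(ph_cfg$size, seed = seed)
      else build_phantom(phantom_spec(nx = ph_cfg$nx, ny = ph_cfg$ny,
                                      nz_cerebrum = ph_cfg$nz_cerebrum,
                                      nz_cerebellum = ph_cfg$nz_cerebellum,
                                      spacing = ph_cfg$spacing %||% 3,
                                      seed = seed))
    })
    parcellation <- phantom$parcellation
    m_cfg <- cfg$model %||% list()
    model <- signal_model(t = m_cfg$t %||% 300, lambda = m_cfg$lambda %||% 1,
                          eta = m_cfg$eta %||% 0.5, sigma = m_cfg$sigma %||% 1)
    controls <- stage("inputs", "controls", {
      simulate_control_cohort(phantom, model, n = cfg$controls$n,
                              seed = seed * 1000L)
    })
    patients <- purrr::imap(cfg$patients, function(p, i) {
      stage("inputs", p$id, {
        centre <- if (!is.null(p$centre)) unlist(p$centre)
          else default_tumour_centre(phantom, p$hemisphere)
        seg <- synthetic_tumour_segmentation(
          phantom, centre, r_necrotic = p$r_necrotic %||% 0,
          r_enhancing = p$r_enhancing %||% 5, r_oedema = p$r_oedema %||% 7)
        lesion <- lesion_spec(seg_mask(seg, c("enhancing", "necrotic")),
                              mode = p$mode %||% "functional",
                              gamma = p$gamma %||% 0.8, tau = p$tau,
                              scope = p$scope %||% "network")
        sim <- simulate_patient(phantom, model, lesion,
                                seed = seed * 1000L + 500L + i,
                                seg = seg, subject = p$id)
        list(id = p$id, hemisphere = p$hemisphere, ts = sim$ts, seg = sim$seg)
      })
    })
    write_parcellation(parcellation, file.path(out_dir, "parcellation.nii.gz"),
                       file.path(out_dir, "parcellation_labels.tsv"))
  } else {
    parcellation <- stage("inputs", "parcellation", {
      read_parcellation(cfg$parcellation$nifti, cfg$parcellation$table)
    })
    grid <- attr(parcellation, "grid")
    mask <- parcellation_mask(parcellation)
    controls <- lapply(seq_along(cfg$controls$files), function(i) {
      stage("inputs", cfg$controls$files[[i]], {
        read_volume(cfg$controls$files[[i]], what = "timeseries",
                    expected_grid = grid, mask = mask,
                    subject = sprintf("control-%03d", i))
      })
    })
    patients <- lapply(cfg$patients, function(p) {
      stage("inputs", p$id, {
        list(id = p$id, hemisphere = p$hemisphere,
             ts = read_volume(p$file, what = "timeseries", expected_grid = grid,
                              mask = mask, subject = p$id,
                              session_label = "pre"),
             seg = read_volume(p$segmentation, what = "segmentation",
                               expected_grid = grid))
      })
    })
  }

  ## ---- connectomes and reference ----
  small <- nrow(controls[[1]]$data) <= 2000L
  control_conns <- if (small) {
    lapply(controls, function(ts) stage("connectome", ts$subject,
                                        compute_connectome(ts)))
  } else controls
  reference <- stage("connectome", "reference", mean_reference(control_conns))

  ## ---- anomaly maps ----
  anomalies <- lapply(patients, function(p) {
    stage("anomaly", p$id, {
      exclude <- smooth_tumour_mask(p$seg, fwhm_mm = fwhm)
      patient_anomaly(p$ts, control_conns, exclude = exclude,
                      reference = reference)
    })
  })
  names(anomalies) <- vapply(patients, `[[`, character(1), "id")
  summary_rows <- purrr::map2_dfr(patients, anomalies, function(p, a) {
    v <- a$score[!is.na(a$score)]
    tibble::tibble(patient = p$id, hemisphere = p$hemisphere,
                   n_valid = length(v), median_score = stats::median(v),
                   pct_below_threshold = 100 * mean(v < thr))
  })
  for (i in seq_along(patients)) {
    write_volume(anomalies[[i]],
                 file.path(out_dir, sprintf("anomaly_%s.nii.gz", patients[[i]]$id)))
  }
  write_tsv_stable(summary_rows, file.path(out_dir, "anomaly_summary.tsv"))

  ## ---- attribution ----
  attribution <- purrr::map2_dfr(patients, anomalies, function(p, a) {
    stage("attribution", p$id, {
      res <- attribute_patient(a, p$seg, reference, parcellation,
                               anomaly_threshold = thr)
      dplyr::bind_cols(tibble::tibble(patient = p$id), res)
    })
  })
  write_tsv_stable(attribution, file.path(out_dir, "attribution.tsv"))
  write_tsv_stable(attribution_summary(attribution),
                   file.path(out_dir, "attribution_summary.tsv"))

  ## ---- symmetry ----
  medians <- purrr::map2_dfr(patients, anomalies, function(p, a) {
    stage("symmetry", p$id,
          network_median_anomaly(a, parcellation, p$hemisphere, patient = p$id))
  })
  write_tsv_stable(medians, file.path(out_dir, "network_medians.tsv"))
  tables <- list(medians = medians, attribution = attribution,
                 summary = summary_rows)
  if (length(patients) >= 3L) {
    sym <- stage("symmetry", "cohort", symmetry_correlation(medians))
    write_tsv_stable(sym, file.path(out_dir, "symmetry_correlation.tsv"))
    tables$symmetry <- sym
  }

  ## ---- longitudinal ----
  if (simulate_mode && isTRUE(cfg$longitudinal$enabled)) {
    lg <- cfg$longitudinal
    tables <- c(tables, stage("longitudinal", "patient-long", {
      schedule <- demo_schedule(phantom, hemisphere = lg$hemisphere %||% "L",
                                silent_gamma = lg$silent_gamma %||% 0.8)
      sessions <- simulate_longitudinal(phantom, model, schedule,
                                        seed = seed * 1000L + 900L)
      session_tables <- purrr::imap_dfr(sessions, function(s, k) {
        exclude <- smooth_tumour_mask(s$seg, fwhm_mm = fwhm)
        a <- patient_anomaly(s$ts, control_conns, exclude = exclude,
                             reference = reference)
        network_median_anomaly(a, parcellation, lg$hemisphere %||% "L",
                               patient = "patient-long")
      })
      traj <- align_trajectories(session_tables)
      write_tsv_stable(traj, file.path(out_dir, "trajectory.tsv"))
      first3 <- traj[traj$session_index <= 2L, ]
      trend <- fit_quadratic_trend(
        data.frame(session = first3$session_index, value = first3$value))
      write_tsv_stable(cbind(tidy(trend), glance(trend)),
                       file.path(out_dir, "trajectory_trend.tsv"))
      k0 <- length(sessions) - 1L
      seg0 <- sessions[[k0]]$seg; seg1 <- sessions[[k0 + 1L]]$seg
      future <- new_tumour_voxels(seg0, seg1)
      vicinity <- tumour_vicinity(seg0, margin_mm = lg$margin_mm %||% 10,
                                  analysis_mask = phantom$mask)
      exclude0 <- smooth_tumour_mask(seg0, fwhm_mm = fwhm)
      a0 <- patient_anomaly(sessions[[k0]]$ts, control_conns,
                            exclude = exclude0, reference = reference)
      rec <- recurrence_test(a0, future, vicinity,
                             n_perm = lg$n_perm %||% 2000L, seed = seed)
      rec_row <- dplyr::bind_cols(
        tibble::tibble(t0 = k0 - 1L, t1 = k0,
                       volume_ok = volume_filter(future,
                                                 min_cm3 = lg$min_cm3 %||% 3)),
        tidy(rec))
      write_tsv_stable(rec_row, file.path(out_dir, "recurrence.tsv"))
      write_volume(future, file.path(out_dir, "recurrence_future_mask.nii.gz"))
      write_volume(vicinity, file.path(out_dir, "recurrence_vicinity_mask.nii.gz"))
      list(trajectory = traj, trend = trend, recurrence = rec)
    }))
  }

  manifest <- tibble::tibble(file = sort(list.files(out_dir)))
  write_tsv_stable(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(parcellation = parcellation, reference = reference,
                 anomalies = anomalies, tables = tables,
                 output_dir = out_dir))
}

# YAML 1.1 treats bare y/n/yes/no as booleans, which would silently turn the
# `n:` key of the controls block into `FALSE`. Keep single-letter scalars as
# strings while preserving genuine true/false values.
read_config_yaml <- function(path) {
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(v) if (tolower(v) %in% c("true", "yes", "on")) TRUE else v,
    "bool#no" = function(v) if (tolower(v) %in% c("false", "no", "off")) FALSE else v))
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list or YAML file", call. = FALSE)
  missing <- setdiff(c("seed", "output_dir", "controls", "patients"), names(cfg))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$controls$n) && is.null(cfg$controls$files)) {
    stop("config `controls` must give either `n` (simulate) or `files`",
         call. = FALSE)
  }
  if (is.null(cfg$controls$n) && is.null(cfg$parcellation)) {
    stop("file-mode config requires a `parcellation` block", call. = FALSE)
  }
  if (!length(cfg$patients)) stop("config `patients` list is empty", call. = FALSE)
  ids <- vapply(cfg$patients, function(p) p$id %||% NA_character_, character(1))
  if (any(is.na(ids))) stop("every patient needs an `id`", call. = FALSE)
  hemi <- vapply(cfg$patients, function(p) p$hemisphere %||% NA_character_,
                 character(1))
  if (any(is.na(hemi) | !hemi %in% c("L", "R"))) {
    stop("every patient needs `hemisphere: L` or `R`", call. = FALSE)
  }
  invisible(TRUE)
}
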