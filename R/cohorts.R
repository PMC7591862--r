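#' Default tumour centre of a phantom hemisphere
#'
#' The voxel at the centre of the given hemisphere's cerebrum block — a
#' reasonable default site for synthetic tumours.
#'
#' @param phantom An `fca_phantom`.
#' @param hemisphere `"L"` or `"R"`.
#' @return 0-based voxel index triple.
#' @export
default_tumour_centre <- function(phantom, hemisphere = "L") {
  sp <- phantom$spec
  half <- sp$nx %/% 2L
  i <- if (hemisphere == "L") half %/% 2L else half + half %/% 2L
  c(i, sp$ny %/% 2L, sp$nz_cerebrum %/% 2L)
}

#' Demo longitudinal schedule with silent recurrence
#'
#' A five-session schedule emulating the clinical course the longitudinal
#' analyses target: a pre-surgical tumour (functional-mode lesion), a
#' post-surgical session with the tumour replaced by a resection cavity and
#' transiently *deeper* network perturbation, recovery at the first
#' follow-up, a second follow-up at which a small site near the cavity is
#' already functionally perturbed but not yet segmented (silent recurrence),
#' and a third follow-up at which that site appears as enhancing tumour.
#'
#' @param phantom An `fca_phantom`.
#' @param hemisphere Tumour hemisphere.
#' @param centre Optional 0-based tumour centre (defaults to
#'   [default_tumour_centre()]).
#' @param gamma_pre,gamma_post,gamma_followup Functional lesion effect sizes
#'   of the pre/post/follow-up sessions (the post > pre > followup ordering
#'   gives the transient-deterioration-then-recovery trajectory).
#' @param silent_gamma Effect size of the silent recurrence perturbation.
#' @param recurrence_offset Voxel offset of the recurrence site from the
#'   tumour centre (default 3 voxels along z: inside the same hemisphere,
#'   adjacent to the 1 cm vicinity rim but mostly outside the smoothed
#'   exclusion mask at 3 mm spacing).
#' @param recurrence_radius_mm Radius of the recurrence site (the default
#'   gives a ~19-voxel site, large enough for a stable AUC).
#' @return An `fca_schedule`.
#' @export
demo_schedule <- function(phantom, hemisphere = "L", centre = NULL,
                          gamma_pre = 0.5, gamma_post = 0.8,
                          gamma_followup = 0.2, silent_gamma = 0.8,
                          recurrence_offset = c(0, 0, 3),
                          recurrence_radius_mm = 5.3) {
  grid <- phantom$grid
  if (is.null(centre)) centre <- default_tumour_centre(phantom, hemisphere)
  seg_pre <- synthetic_tumour_segmentation(phantom, centre, r_necrotic = 0,
                                           r_enhancing = 5, r_oedema = 7)
  tum_mask <- seg_mask(seg_pre, c("enhancing", "necrotic"))
  # post-surgery: the enhancing tumour becomes a resection cavity
  labels_post <- integer(n_voxels(grid))
  labels_post[tum_mask$members] <- seg_classes[["resection"]]
  seg_post <- segmentation_volume(grid, labels_post)
  rec_centre <- centre + recurrence_offset
  rec_mask <- mask_intersect(spherical_mask(grid, rec_centre, recurrence_radius_mm),
                             phantom$mask)
  rec_mask <- mask_setdiff(rec_mask, seg_mask(seg_post))
  labels_rec <- labels_post
  labels_rec[rec_mask$members] <- seg_classes[["enhancing"]]
  seg_rec <- segmentation_volume(grid, labels_rec)
  flesion <- function(g) {
    if (g > 0) list(lesion_spec(tum_mask, mode = "functional", gamma = g))
    else list()
  }
  longitudinal_schedule(list(
    list(label = "pre", seg = seg_pre, lesions = flesion(gamma_pre)),
    list(label = "post", seg = seg_post, lesions = flesion(gamma_post)),
    list(label = "followup-1", seg = seg_post, lesions = flesion(gamma_followup)),
    list(label = "followup-2", seg = seg_post, lesions = flesion(gamma_followup),
         silent_mask = rec_mask, silent_gamma = silent_gamma, silent_tau = 2),
    list(label = "followup-3", seg = seg_rec, lesions = flesion(gamma_followup))
  ))
}

#' Simulate a control cohort
#'
#' @param phantom An `fca_phantom`.
#' @param model An `fca_signal_model`.
#' @param n Number of controls.
#' @param seed Base seed; control `i` uses `seed + i`.
#' @return A list of `fca_ts`.
#' @export
simulate_control_cohort <- function(phantom, model = signal_model(), n = 40,
                                    seed = 1000L) {
  lapply(seq_len(n), function(i) {
    simulate_control(phantom, model, seed = seed + i,
                     subject = sprintf("control-%03d", i))
  })
}
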