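# A hand-built anomaly map over a 1D grid: scores at given voxels.
toy_anomaly <- function(scores, members = seq_along(scores), grid = NULL) {
  if (is.null(grid)) grid <- grid_space(c(max(members), 1, 1), spacing = 1)
  structure(list(grid = grid, mask = voxel_mask(grid, members),
                 score = scores, excluded = integer(0),
                 subject = "toy", session_index = 0L, session_label = "pre"),
            class = "fca_anomaly")
}

test_that("distance fields combine Euclidean mm and 1 - |r|", {
  g <- grid_space(c(5, 5, 1), spacing = 1)
  t_vox <- ijk_to_index_for_test(g, c(0, 0, 0))
  a_vox <- ijk_to_index_for_test(g, c(3, 4, 0))
  b_vox <- ijk_to_index_for_test(g, c(1, 0, 0))
  members <- sort(c(t_vox, a_vox, b_vox))
  Z <- matrix(0, 3, 3)
  ti <- match(t_vox, members); ai <- match(a_vox, members); bi <- match(b_vox, members)
  Z[ti, ai] <- Z[ai, ti] <- 0            # r = 0
  Z[ti, bi] <- Z[bi, ti] <- atanh(0.4)   # r = 0.4
  ref <- toy_connectome(Z, grid = g, members = members)
  fields <- distance_fields(t_vox, ref, c(a_vox, b_vox))
  expect_equal(fields$spatial_mm[fields$voxel == a_vox], 5)   # 3-4-5 triangle
  expect_equal(fields$proximity[fields$voxel == a_vox], 0)
  expect_equal(fields$functional_distance[fields$voxel == a_vox], 1)
  expect_equal(fields$proximity[fields$voxel == b_vox], 0.4, tolerance = 1e-12)
  expect_equal(fields$functional_distance[fields$voxel == b_vox], 0.6,
               tolerance = 1e-12)
  expect_error(distance_fields(999, ref, a_vox), "not in the reference")
})

test_that("voxels are labelled by the larger positive distance correlation", {
  anomaly <- toy_anomaly(c(-3, -2.5, -2.4, -2.35))
  fields <- tibble::tibble(voxel = 1:4, spatial_mm = c(1, 2, 3, 4),
                           proximity = NA_real_,
                           functional_distance = c(4, 3, 2, 1))
  res <- attribute_voxel(anomaly, fields)
  expect_equal(res$r_spatial, o_pearson(c(1, 2, 3, 4), c(-3, -2.5, -2.4, -2.35)),
               tolerance = 1e-12)
  expect_gt(res$r_spatial, 0.85)   # anomaly deepens with spatial closeness
  expect_equal(res$r_functional, -res$r_spatial, tolerance = 1e-12)
  expect_identical(res$label, "spatial")
  # swapping the two distance fields flips the label
  swapped <- fields
  swapped$spatial_mm <- fields$functional_distance
  swapped$functional_distance <- fields$spatial_mm
  expect_identical(attribute_voxel(anomaly, swapped)$label, "functional")
  # anomaly anticorrelated with both (non-collinear) distances: none
  fields2 <- tibble::tibble(voxel = 1:4, spatial_mm = c(1, 2, 3, 4),
                            proximity = NA_real_,
                            functional_distance = c(2, 1, 4, 3))
  both_neg <- toy_anomaly(c(-3, -3, -7, -7))
  res_none <- attribute_voxel(both_neg, fields2)
  expect_lt(res_none$r_spatial, 0)
  expect_lt(res_none$r_functional, 0)
  expect_identical(res_none$label, "none")
  expect_identical(res_none$reason, "no positive relationship")
})

test_that("attribution needs at least 3 highly anomalous voxels", {
  anomaly <- toy_anomaly(c(-3, -1, -1, -1))   # only one below -2.3
  fields <- tibble::tibble(voxel = 1:4, spatial_mm = 1:4, proximity = NA_real_,
                           functional_distance = 4:1)
  res <- attribute_voxel(anomaly, fields)
  expect_identical(res$label, "none")
  expect_match(res$reason, "fewer than 3")
  # with subset = "all" the same map is usable
  expect_false(attribute_voxel(anomaly, fields, subset = "all")$label == "none" &&
                 is.na(attribute_voxel(anomaly, fields, subset = "all")$r_spatial))
})

test_that("labels are invariant to positive affine rescaling of a field", {
  set.seed(40)
  anomaly <- toy_anomaly(runif(30, -5, -2.4))
  fields <- tibble::tibble(voxel = 1:30, spatial_mm = runif(30, 1, 50),
                           proximity = NA_real_,
                           functional_distance = runif(30))
  base <- attribute_voxel(anomaly, fields)
  rescaled <- fields
  rescaled$spatial_mm <- 3.7 * fields$spatial_mm + 11
  rescaled$functional_distance <- 0.2 * fields$functional_distance + 0.05
  res <- attribute_voxel(anomaly, rescaled)
  expect_identical(res$label, base$label)
  expect_equal(res$r_spatial, base$r_spatial, tolerance = 1e-12)
})

test_that("attribution summaries are percentages that sum to 100", {
  results <- tibble::tibble(
    patient = "P01",
    label = c(rep("functional", 6), rep("spatial", 3), "none"))
  sm <- attribution_summary(results)
  expect_equal(sm$percent[sm$label == "functional"], 60)
  expect_equal(sm$percent[sm$label == "spatial"], 30)
  expect_equal(sm$percent[sm$label == "none"], 10)
  all_none <- attribution_summary(tibble::tibble(patient = "P02",
                                                 label = rep("none", 4)))
  expect_equal(all_none$percent, c(0, 0, 100))
  set.seed(41)
  many <- tibble::tibble(patient = rep(c("A", "B", "C"), each = 17),
                         label = sample(c("functional", "spatial", "none"),
                                        51, replace = TRUE))
  sums <- attribution_summary(many) |>
    dplyr::group_by(patient) |>
    dplyr::summarise(total = sum(percent))
  expect_equal(sums$total, rep(100, 3))
})

test_that("a functional-mode phantom patient is attributed to function", {
  study <- compact_study()
  phantom <- study$phantom
  seg <- synthetic_tumour_segmentation(phantom,
                                       default_tumour_centre(phantom, "L"),
                                       0, 4, 6)
  les <- lesion_spec(seg_mask(seg, "enhancing"), "functional", gamma = 0.8)
  pat <- simulate_patient(phantom, study$model, les, seed = 51, seg = seg)
  a <- patient_anomaly(pat$ts, study$connectomes,
                       exclude = smooth_tumour_mask(seg),
                       reference = study$reference)
  att <- attribute_patient(a, seg, study$reference, phantom$parcellation)
  sm <- attribution_summary(att)
  expect_gt(sm$percent[sm$label == "functional"],
            sm$percent[sm$label == "spatial"])
  # every tumour voxel carries its network identity
  expect_true(all(att$network %in% network_names))
})
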