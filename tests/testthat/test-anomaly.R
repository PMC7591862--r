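test_that("positive-clipped cosine matches hand computations", {
  expect_equal(positive_cosine_similarity(c(0.3, 0.5, 0.2), c(0.3, 0.5, 0.2)), 1)
  # negatives clipped independently on both rows; unit norms by construction
  expect_equal(positive_cosine_similarity(c(0.6, 0.8, -0.3), c(0.8, 0.6, -0.5)),
               0.96, tolerance = 1e-12)
  # all-negative profile row: undefined, not zero
  expect_true(is.na(positive_cosine_similarity(c(-1, -2), c(0.5, 0.5))))
  expect_error(positive_cosine_similarity(1:3, 1:4), "length")
})

test_that("similarity_map equals the per-row brute-force cosine", {
  conn <- compute_connectome(random_ts(20, 30, seed = 10))
  ref <- mean_reference(lapply(11:14, function(i) {
    compute_connectome(random_ts(20, 30, seed = i))
  }))
  sim <- similarity_map(conn, ref)
  expect_equal(sim$values, o_similarity(conn$values, ref$values),
               tolerance = 1e-12)
  # a connectome identical to the reference scores 1 everywhere
  self <- similarity_map(ref, ref)
  expect_equal(unname(self$values), rep(1, 20), tolerance = 1e-12)
  # excluding half the voxels leaves one similarity per retained voxel
  excl <- voxel_mask(conn$mask$grid, 1:10)
  half <- similarity_map(conn, ref, exclude = excl)
  expect_length(half$values, 10)
  expect_identical(half$mask$members, 11:20)
  expect_identical(half$excluded, 1:10)
})

test_that("baselines store the raw median and MAD per voxel", {
  sims <- lapply(c(0.8, 0.9, 1.0, 0.7, 0.6), function(v) {
    toy_similarity(c(v, 0.9))
  })
  base <- build_baseline(sims)
  expect_equal(base$median[1], o_median(c(0.8, 0.9, 1.0, 0.7, 0.6)))
  expect_equal(base$median[1], 0.8)
  expect_equal(base$mad[1], o_mad(c(0.8, 0.9, 1.0, 0.7, 0.6)))
  expect_equal(base$mad[1], 0.1)
  # identical control values: zero dispersion flagged degenerate
  expect_equal(base$mad[2], 0)
  expect_true(base$degenerate[2])
  # permutation invariance
  shuffled <- build_baseline(sims[c(3, 1, 5, 2, 4)])
  expect_equal(shuffled$median, base$median)
  expect_equal(shuffled$mad, base$mad)
  expect_error(build_baseline(sims[1]), "at least 2")
})

test_that("anomaly scores are (sim - median) / MAD with safe degeneracy", {
  sims <- lapply(c(0.6, 0.7, 0.7, 0.8, 0.9), function(v) {
    toy_similarity(c(v, v, 0.5))
  })
  base <- build_baseline(sims)     # voxel 1/2: median 0.7, MAD 0.1; voxel 3: MAD 0
  sc <- anomaly_score(toy_similarity(c(0.5, 0.7, 0.9)), base)
  expect_equal(anomaly_at(sc, 1)[[1]], -2)
  expect_equal(anomaly_at(sc, 2)[[1]], 0)
  expect_true(is.na(anomaly_at(sc, 3, drop_na = FALSE)[[1]]))  # MAD 0, not Inf
})

test_that("scoring demands a baseline built under the same exclusion", {
  sims <- lapply(c(0.6, 0.8), function(v) toy_similarity(rep(v, 3),
                                                         excluded = 4L))
  base <- build_baseline(sims)
  other <- toy_similarity(rep(0.7, 3), excluded = 2L)
  expect_error(anomaly_score(other, base), "not specific")
})

test_that("anomaly scores are equivariant to a common similarity shift", {
  vals <- matrix(runif(15, 0.4, 0.9), 5, 3)
  base1 <- build_baseline(apply(vals, 2, function(v) toy_similarity(v),
                                simplify = FALSE))
  base2 <- build_baseline(apply(vals + 0.05, 2, function(v) toy_similarity(v),
                                simplify = FALSE))
  pat <- runif(5, 0.4, 0.9)
  s1 <- anomaly_score(toy_similarity(pat), base1)
  s2 <- anomaly_score(toy_similarity(pat + 0.05), base2)
  expect_equal(s1$score, s2$score)
})

test_that("smoothed tumour masks grow liberally and monotonically", {
  g <- grid_space(c(7, 7, 7), spacing = 3)
  expect_length(smooth_tumour_mask(empty_segmentation(g))$members, 0)
  labels <- integer(343)
  centre <- ijk_to_index_for_test(g, c(3, 3, 3))
  labels[centre] <- seg_classes[["enhancing"]]
  seg <- segmentation_volume(g, labels)
  m3 <- smooth_tumour_mask(seg, fwhm_mm = 3)
  # kernel enumeration at 3 mm spacing: centre voxel plus 6 face neighbours
  face <- vapply(list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                      c(0, 0, -1), c(0, 0, 1)), function(d) {
    ijk_to_index_for_test(g, c(3, 3, 3) + d)
  }, integer(1))
  expect_setequal(m3$members, c(centre, face))
  # wider kernels only add voxels
  m6 <- smooth_tumour_mask(seg, fwhm_mm = 6)
  expect_true(all(m3$members %in% m6$members))
  expect_gt(length(m6$members), length(m3$members))
  expect_error(smooth_tumour_mask(seg, fwhm_mm = 0), "fwhm")
})

test_that("excluded voxels never carry a valid score", {
  study <- compact_study()
  phantom <- study$phantom
  seg <- synthetic_tumour_segmentation(phantom,
                                       default_tumour_centre(phantom, "L"),
                                       0, 4, 6)
  exclude <- smooth_tumour_mask(seg)
  les <- lesion_spec(seg_mask(seg, "enhancing"), "functional", gamma = 0.8)
  pat <- simulate_patient(phantom, study$model, les, seed = 31, seg = seg)
  a <- patient_anomaly(pat$ts, study$connectomes, exclude = exclude,
                       reference = study$reference)
  expect_length(anomaly_at(a, exclude), 0)
  expect_identical(a$mask$members, phantom$mask$members)
})

test_that("lesioned patients score far below unperturbed voxels", {
  study <- compact_study()
  phantom <- study$phantom
  parc <- phantom$parcellation
  seg <- synthetic_tumour_segmentation(phantom,
                                       default_tumour_centre(phantom, "L"),
                                       0, 4, 6)
  tum <- seg_mask(seg, "enhancing")
  exclude <- smooth_tumour_mask(seg)
  les <- lesion_spec(tum, "functional", gamma = 0.8)
  pat <- simulate_patient(phantom, study$model, les, seed = 32, seg = seg)
  a <- patient_anomaly(pat$ts, study$connectomes, exclude = exclude,
                       reference = study$reference)
  tnets <- unique(parc$network[match(intersect(tum$members, parc$voxel),
                                     parc$voxel)])
  perturbed <- anomaly_at(a, setdiff(parc$voxel[parc$network %in% tnets],
                                     exclude$members))
  other <- anomaly_at(a, setdiff(parc$voxel[!parc$network %in% tnets],
                                 exclude$members))
  expect_lt(mean(perturbed), -1)
  expect_lt(mean(perturbed), mean(other))
})

test_that("including tumour voxels barely changes the anomaly map", {
  study <- compact_study()
  phantom <- study$phantom
  seg <- synthetic_tumour_segmentation(phantom,
                                       default_tumour_centre(phantom, "L"),
                                       0, 4, 6)
  exclude <- smooth_tumour_mask(seg)
  les <- lesion_spec(seg_mask(seg, "enhancing"), "functional", gamma = 0.8)
  pat <- simulate_patient(phantom, study$model, les, seed = 33, seg = seg)
  with_excl <- patient_anomaly(pat$ts, study$connectomes, exclude = exclude,
                               reference = study$reference)
  without <- patient_anomaly(pat$ts, study$connectomes,
                             reference = study$reference)
  shared <- intersect(names(anomaly_at(with_excl, phantom$mask)),
                      names(anomaly_at(without, phantom$mask)))
  shared <- as.integer(shared)
  expect_gt(cor(anomaly_at(with_excl, shared), anomaly_at(without, shared)),
            0.9)
})
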