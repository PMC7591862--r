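toy_map <- function(phantom, scores) {
  structure(list(grid = phantom$grid, mask = phantom$mask, score = scores,
                 excluded = integer(0), subject = "toy",
                 session_index = 0L, session_label = "pre"),
            class = "fca_anomaly")
}

test_that("network medians summarise by network, side and compartment", {
  phantom <- phantom_demo("compact")
  V <- length(phantom$mask$members)
  tab <- network_median_anomaly(toy_map(phantom, rep(-1, V)),
                                phantom$parcellation, "L")
  expect_equal(nrow(tab), 7 * 2 * 2)
  expect_true(all(tab$median_score == -1))
  # a cell with values {-3, -1, 0} has median -1
  parc <- phantom$parcellation
  cell <- which(parc$network == "VIS" & parc$hemisphere == "L" &
                  parc$compartment == "cerebrum")[1:3]
  sc <- rep(NA_real_, V)
  sc[match(parc$voxel[cell], phantom$mask$members)] <- c(-3, -1, 0)
  tab2 <- network_median_anomaly(toy_map(phantom, sc), parc, "L")
  got <- tab2[tab2$network == "VIS" & tab2$side == "ipsi" &
                tab2$compartment == "cerebrum", ]
  expect_equal(got$median_score, -1)
  expect_equal(got$n_voxels, 3L)
  # empty cells are invalid, not zero
  expect_true(is.na(tab2$median_score[tab2$network == "DMN"][1]))
})

test_that("mirror-symmetric maps give identical ipsi and contra columns", {
  phantom <- phantom_demo("compact")
  set.seed(60)
  half <- rnorm(length(phantom$mask$members))
  mirrored <- half[match(unname(phantom$mirror[as.character(phantom$mask$members)]),
                         phantom$mask$members)]
  sc <- (half + mirrored) / 2   # score(v) == score(mirror(v))
  tab <- network_median_anomaly(toy_map(phantom, sc), phantom$parcellation, "L")
  wide <- tidyr::pivot_wider(tab, id_cols = c("network", "compartment"),
                             names_from = "side", values_from = "median_score")
  expect_equal(wide$ipsi, wide$contra)
})

test_that("symmetry correlations match brute-force Pearson per pair", {
  set.seed(61)
  tabs <- purrr::map_dfr(1:6, function(p) {
    tidyr::expand_grid(network = network_names, side = c("ipsi", "contra"),
                       compartment = c("cerebrum", "cerebellum")) |>
      dplyr::mutate(patient = sprintf("P%02d", p),
                    median_score = rnorm(dplyr::n()))
  })
  corr <- symmetry_correlation(tabs)
  wide_i <- matrix(tabs$median_score[tabs$side == "ipsi" &
                                       tabs$compartment == "cerebrum"],
                   ncol = 7, byrow = TRUE)
  wide_c <- matrix(tabs$median_score[tabs$side == "contra" &
                                       tabs$compartment == "cerebrum"],
                   ncol = 7, byrow = TRUE)
  for (i in c(1, 4)) for (j in c(2, 7)) {
    got <- corr$r[corr$compartment == "cerebrum" &
                    corr$network_ipsi == network_names[i] &
                    corr$network_contra == network_names[j]]
    expect_equal(got, o_pearson(wide_i[, i], wide_c[, j]), tolerance = 1e-12)
  }
})

test_that("degenerate symmetry cases behave as documented", {
  base <- tidyr::expand_grid(patient = sprintf("P%02d", 1:5),
                             network = network_names,
                             side = c("ipsi", "contra"),
                             compartment = c("cerebrum", "cerebellum"))
  set.seed(62)
  vals <- base |>
    dplyr::filter(side == "ipsi") |>
    dplyr::mutate(median_score = rnorm(dplyr::n()))
  # contra identical to ipsi: diagonal r2 = 1
  mirror <- vals |> dplyr::mutate(side = "contra")
  corr <- symmetry_correlation(dplyr::bind_rows(vals, mirror))
  diag_r2 <- corr$r2[corr$network_ipsi == corr$network_contra]
  expect_equal(diag_r2, rep(1, 14), tolerance = 1e-12)
  # contra = -ipsi: r = -1 but r2 still 1
  flipped <- vals |> dplyr::mutate(side = "contra",
                                   median_score = -median_score)
  corr2 <- symmetry_correlation(dplyr::bind_rows(vals, flipped))
  diag2 <- corr2[corr2$network_ipsi == corr2$network_contra, ]
  expect_equal(diag2$r, rep(-1, 14), tolerance = 1e-12)
  expect_equal(diag2$r2, rep(1, 14), tolerance = 1e-12)
  expect_error(symmetry_correlation(vals[vals$patient %in% c("P01", "P02"), ]),
               "at least 3")
})

test_that("lesion maps count supra-threshold reference connections", {
  g <- grid_space(c(4, 1, 1), spacing = 3)
  Z <- matrix(0, 4, 4)
  Z[1, 2] <- Z[2, 1] <- 0.9
  Z[1, 3] <- Z[3, 1] <- 0.1
  Z[1, 4] <- Z[4, 1] <- 0.5
  ref <- toy_connectome(Z, grid = g, members = 1:4)
  lm1 <- lesion_map(voxel_mask(g, 1), ref, threshold = 0.25)
  expect_identical(lm1$voxel[lm1$connected], c(2L, 4L))
  # threshold above the reference maximum: empty map
  lm_hi <- lesion_map(voxel_mask(g, 1), ref, threshold = 1)
  expect_false(any(lm_hi$connected))
  # two tumour voxels with disjoint supra-threshold sets: counts add
  Z2 <- matrix(0, 4, 4)
  Z2[1, 3] <- Z2[3, 1] <- 0.9
  Z2[2, 4] <- Z2[4, 2] <- 0.9
  ref2 <- toy_connectome(Z2, grid = g, members = 1:4)
  both <- lesion_map(voxel_mask(g, c(1, 2)), ref2, threshold = 0.25)
  expect_equal(both$count[both$voxel %in% c(3, 4)], c(1L, 1L))
  single_sum <- lesion_map(voxel_mask(g, 1), ref2, 0.25)$count[2] +
    lesion_map(voxel_mask(g, 2), ref2, 0.25)$count[2]
  expect_equal(both$count[both$voxel == 4], single_sum)
  expect_error(lesion_map(voxel_mask(g, integer(0)), ref), "empty")
})

test_that("lowering the lesion-map threshold never removes a voxel", {
  study <- compact_study()
  tum <- spherical_mask(study$phantom$grid,
                        default_tumour_centre(study$phantom, "L"), 4)
  prev <- NULL
  for (thr in c(atanh(0.45), atanh(0.35), atanh(0.25), atanh(0.15))) {
    lm <- lesion_map(tum, study$reference, threshold = thr)
    hit <- lm$voxel[lm$connected]
    if (!is.null(prev)) expect_true(all(prev %in% hit))
    prev <- hit
  }
})

test_that("identical lesion and anomaly overlaps correlate perfectly", {
  phantom <- phantom_demo("compact")
  parc <- phantom$parcellation
  cb <- parc$voxel[parc$compartment == "cerebellum"]
  set.seed(63)
  maps <- lapply(1:4, function(i) {
    hot <- sample(cb, 30)
    lm <- tibble::tibble(voxel = parc$voxel,
                         count = as.integer(parc$voxel %in% hot),
                         connected = parc$voxel %in% hot)
    sc <- rep(0, length(phantom$mask$members))
    sc[match(hot, phantom$mask$members)] <- -10   # below every threshold
    list(lm = lm, am = toy_map(phantom, sc))
  })
  ov <- lesion_anomaly_overlap(lapply(maps, `[[`, "lm"),
                               lapply(maps, `[[`, "am"),
                               parc, tumour_side = "L")
  expect_equal(ov$curves$r, rep(1, 10), tolerance = 1e-12)
  # both hemispheres identical: no contrast evidence, p = 1 by convention
  expect_equal(ov$contrast$p, 1)
})
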