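test_that("phantom mirror map is an involution preserving networks", {
  phantom <- phantom_demo("compact")
  parc <- phantom$parcellation
  mirror <- phantom$mirror
  # involution, exhaustively
  expect_identical(unname(mirror[as.character(unname(mirror))]),
                   as.integer(names(mirror)))
  row <- match(parc$voxel, parc$voxel)
  mrow <- match(unname(mirror[as.character(parc$voxel)]), parc$voxel)
  # mirror partner always carries the same network id
  expect_identical(parc$network[row], parc$network[mrow])
  # and the opposite anatomical hemisphere
  expect_true(all(parc$hemisphere[row] != parc$hemisphere[mrow]))
  # equal left/right voxel counts per cerebral network
  counts <- table(parc$network[parc$compartment == "cerebrum"],
                  parc$hemisphere[parc$compartment == "cerebrum"])
  expect_true(all(counts[, "L"] == counts[, "R"]))
})

test_that("cerebellar voxels carry the crossed hemisphere channel", {
  phantom <- phantom_demo("compact")
  parc <- phantom$parcellation
  cb <- parc[parc$compartment == "cerebellum", ]
  expect_true(all(cb$source_hemisphere != cb$hemisphere))
  cr <- parc[parc$compartment == "cerebrum", ]
  expect_true(all(cr$source_hemisphere == cr$hemisphere))
  # a left-cerebellar voxel's network equals its mirrored (right) partner's,
  # i.e. the crossed cerebral source network
  left_cb <- cb[cb$hemisphere == "L", ]
  partner <- unname(phantom$mirror[as.character(left_cb$voxel)])
  expect_identical(left_cb$network,
                   parc$network[match(partner, parc$voxel)])
})

test_that("phantom construction is deterministic and rejects odd nx", {
  a <- build_phantom(phantom_spec(seed = 7))
  b <- build_phantom(phantom_spec(seed = 7))
  expect_identical(a$parcellation$network, b$parcellation$network)
  expect_error(phantom_spec(nx = 9), "even")
})

test_that("control correlations match the closed-form loadings", {
  phantom <- phantom_demo("compact")
  parc <- phantom$parcellation
  # lambda=1, eta=0, sigma=1: expected within-network r = 0.5
  ts <- simulate_control(phantom, signal_model(t = 2000, lambda = 1, eta = 0,
                                               sigma = 1), seed = 21)
  set.seed(1)
  same_net <- which(parc$network == "DAN")
  pairs <- replicate(100, sample(same_net, 2))
  r_within <- vapply(seq_len(100), function(k) {
    cor(ts$data[pairs[1, k], ], ts$data[pairs[2, k], ])
  }, numeric(1))
  expect_equal(mean(r_within), 0.5, tolerance = 0.05)
  # lambda=0, eta=0: null correlations, |r| ~ 1/sqrt(T)
  ts0 <- simulate_control(phantom, signal_model(t = 2000, lambda = 0, eta = 0,
                                                sigma = 1), seed = 22)
  set.seed(2)
  rnd <- replicate(100, sample(nrow(parc), 2))
  r_null <- vapply(seq_len(100), function(k) {
    cor(ts0$data[rnd[1, k], ], ts0$data[rnd[2, k], ])
  }, numeric(1))
  expect_lte(mean(abs(r_null)), 0.06)
  # default model: left-right same-network pairs share only the network
  # signal, r = lambda^2 / total
  ts2 <- simulate_control(phantom, signal_model(t = 2000), seed = 23)
  lef <- which(parc$network == "VIS" & parc$source_hemisphere == "L" &
                 parc$compartment == "cerebrum")
  rig <- which(parc$network == "VIS" & parc$source_hemisphere == "R" &
                 parc$compartment == "cerebrum")
  set.seed(3)
  r_lr <- vapply(seq_len(100), function(k) {
    cor(ts2$data[sample(lef, 1), ], ts2$data[sample(rig, 1), ])
  }, numeric(1))
  expect_equal(mean(r_lr), 1 / 2.25, tolerance = 0.05)
})

test_that("same seed reproduces the series; gamma = 0 is the control", {
  phantom <- phantom_demo("compact")
  model <- signal_model(t = 100)
  expect_identical(simulate_control(phantom, model, seed = 5)$data,
                   simulate_control(phantom, model, seed = 5)$data)
  seg <- synthetic_tumour_segmentation(phantom,
                                       default_tumour_centre(phantom, "L"),
                                       0, 4, 6)
  les0 <- lesion_spec(seg_mask(seg, "enhancing"), "functional", gamma = 0)
  pat <- simulate_patient(phantom, model, les0, seed = 5, seg = seg)
  expect_equal(pat$ts$data, simulate_control(phantom, model, seed = 5)$data)
})

test_that("lesions preserve per-voxel variance", {
  phantom <- phantom_demo("compact")
  model <- signal_model(t = 2000)
  seg <- synthetic_tumour_segmentation(phantom,
                                       default_tumour_centre(phantom, "L"),
                                       0, 4, 6)
  les <- lesion_spec(seg_mask(seg, "enhancing"), "functional", gamma = 0.8)
  pat <- simulate_patient(phantom, model, les, seed = 9, seg = seg)
  ctl <- simulate_control(phantom, model, seed = 9)
  ratio <- apply(pat$ts$data, 1, var) / apply(ctl$data, 1, var)
  p <- fcanomaly:::lesion_proximity(phantom, les)
  perturbed <- p > 0
  expect_equal(mean(ratio[perturbed]), 1, tolerance = 0.02)
  expect_gt(mean(abs(ratio[perturbed] - 1) <= 0.1), 0.95)
})

test_that("lesion specs validate their parameters", {
  g <- toy_grid()
  m <- voxel_mask(g, 1:3)
  expect_error(lesion_spec(voxel_mask(g, integer(0)), "functional"), "empty")
  expect_error(lesion_spec(m, "functional", gamma = 1.2), "gamma")
  expect_error(lesion_spec(m, "spatial", gamma = 0.5), "tau")
  expect_error(lesion_spec(m, "spatial", gamma = 0.5, tau = -1), "tau")
})

test_that("longitudinal schedules enforce ordering and silent-site payoff", {
  phantom <- build_phantom(phantom_spec(nx = 4, ny = 7, nz_cerebrum = 6,
                                        nz_cerebellum = 2))
  sched <- demo_schedule(phantom)
  expect_s3_class(sched, "fca_schedule")
  expect_length(sched$sessions, 5)
  sessions <- simulate_longitudinal(phantom, signal_model(t = 50), sched,
                                    seed = 3)
  expect_length(sessions, 5)
  for (s in sessions) expect_true(same_grid(s$ts$grid, phantom$grid))
  expect_identical(vapply(sessions, `[[`, character(1), "label"),
                   c("pre", "post", "followup-1", "followup-2", "followup-3"))
  # mis-ordered labels are rejected
  bad <- sched$sessions[c(2, 1, 3, 4, 5)]
  expect_error(longitudinal_schedule(bad), "ordered")
  # a silent site that never gets segmented is rejected
  orphan <- sched$sessions
  orphan[[5]] <- orphan[[3]]   # drop the recurrence segmentation
  orphan[[5]]$label <- "followup-3"
  expect_error(longitudinal_schedule(orphan), "silent recurrence")
})

test_that("perturbation depth is monotone in gamma under common random numbers", {
  study <- compact_study()
  phantom <- study$phantom
  seg <- synthetic_tumour_segmentation(phantom,
                                       default_tumour_centre(phantom, "L"),
                                       0, 4, 6)
  tum <- seg_mask(seg, "enhancing")
  exclude <- smooth_tumour_mask(seg)
  parc <- phantom$parcellation
  tnets <- unique(parc$network[match(intersect(tum$members, parc$voxel),
                                     parc$voxel)])
  perturbed <- setdiff(parc$voxel[parc$network %in% tnets], exclude$members)
  means <- vapply(c(0, 0.3, 0.6, 0.9), function(g) {
    les <- lesion_spec(tum, "functional", gamma = g)
    pat <- simulate_patient(phantom, study$model, les, seed = 777, seg = seg)
    a <- patient_anomaly(pat$ts, study$connectomes, exclude = exclude,
                         reference = study$reference)
    mean(anomaly_at(a, perturbed))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
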