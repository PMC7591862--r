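#' Specify the control signal model
#'
#' Generative model for control BOLD series on a phantom: voxel `v` of
#' network `n(v)` and hemisphere channel `c(v)` follows
#' `y_v(t) = lambda * s_n(v)(t) + eta * h_n(v),c(v)(t) + sigma * e_v(t)`
#' with independent standard-normal white processes `s` (one per network),
#' `h` (one per network x hemisphere channel) and `e` (one per voxel).
#' The expected Pearson correlation between two same-network voxels sharing
#' the hemisphere channel is `(lambda^2 + eta^2) / (lambda^2 + eta^2 +
#' sigma^2)`; across hemisphere channels it is `lambda^2 / (lambda^2 + eta^2
#' + sigma^2)`. Cerebellar voxels use the *contralateral* hemisphere channel
#' (crossed cerebro-cerebellar representation).
#'
#' Signals are white: the analyses consume correlations only, so temporal
#' autocorrelation would add nuisance without exercising anything downstream.
#'
#' @param t Number of timepoints (>= 2).
#' @param lambda Network signal loading (>= 0).
#' @param eta Hemisphere-channel loading (>= 0).
#' @param sigma Voxel noise standard deviation (>= 0).
#' @return An object of class `fca_signal_model`.
#' @export
signal_model <- function(t = 300, lambda = 1, eta = 0.5, sigma = 1) {
  t <- as.integer(t)
  if (t < 2L) stop("`t` must be >= 2", call. = FALSE)
  if (lambda < 0 || eta < 0 || sigma < 0) {
    stop("loadings and noise sd must be >= 0", call. = FALSE)
  }
  if (lambda^2 + eta^2 + sigma^2 <= 0) {
    stop("total variance must be positive", call. = FALSE)
  }
  structure(list(t = t, lambda = lambda, eta = eta, sigma = sigma),
            class = "fca_signal_model")
}

#' Specify a connectivity lesion
#'
#' A lesion perturbs the network signal of affected voxels: voxel `v`'s
#' signal loading is scaled by `a_v = 1 - gamma * p_v` and the removed
#' variance is replaced by fresh voxel-specific noise, so the total per-voxel
#' variance is preserved and only the *connectivity* changes.
#'
#' The perturbation field `p_v` is the generative notion of proximity to the
#' tumour:
#' * `mode = "functional"`: `p_v = 1` if voxel `v` shares a network with any
#'   tumour voxel, else 0 (optionally spatially softened via `smooth_fwhm`).
#'   With `scope = "hemisphere"` the perturbation travels only through the
#'   tumour's hemisphere channel, i.e. it reaches same-network voxels whose
#'   hemisphere channel matches a tumour voxel's — in the cerebellum that is
#'   the *contralateral* side (crossed representation).
#' * `mode = "spatial"`: `p_v = exp(-d_v / tau)` with `d_v` the Euclidean
#'   distance (mm) from `v` to the nearest tumour voxel.
#'
#' `gamma = 0` reproduces the control model exactly.
#'
#' @param mask `fca_mask` of tumour voxels (nonempty).
#' @param mode `"functional"` or `"spatial"`.
#' @param gamma Effect size in `[0, 1]`.
#' @param tau Spatial decay length in mm (> 0); spatial mode only.
#' @param scope `"network"` (co-membership, the default) or `"hemisphere"`
#'   (co-membership restricted to the tumour's hemisphere channel);
#'   functional mode only.
#' @param compartments Compartments the perturbation may reach (default
#'   both). Restricting to `"cerebellum"` gives a purely cerebellar
#'   propagation — with `scope = "hemisphere"` that is the crossed
#'   (contralateral) cerebellar representation of the tumour's networks.
#' @param smooth_fwhm Optional FWHM (mm) used to spatially soften the binary
#'   functional-proximity field; 0 disables softening.
#' @return An object of class `fca_lesion_spec`.
#' @export
lesion_spec <- function(mask, mode = c("functional", "spatial"), gamma = 0.8,
                        tau = NULL, scope = c("network", "hemisphere"),
                        compartments = c("cerebrum", "cerebellum"),
                        smooth_fwhm = 0) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  compartments <- match.arg(compartments, several.ok = TRUE)
  stopifnot(inherits(mask, "fca_mask"))
  if (!length(mask$members)) stop("tumour mask is empty", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("`gamma` must be in [0, 1]", call. = FALSE)
  if (mode == "spatial") {
    if (is.null(tau) || tau <= 0) {
      stop("spatial mode needs a decay length `tau` > 0 (mm)", call. = FALSE)
    }
  }
  structure(list(mask = mask, mode = mode, gamma = gamma, tau = tau,
                 scope = scope, compartments = compartments,
                 smooth_fwhm = smooth_fwhm),
            class = "fca_lesion_spec")
}

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Shared draw of the latent signals; the patient generator reuses it so that
# a lesion with gamma = 0 reproduces the control series bit for bit (common
# random numbers across gamma).
draw_signals <- function(phantom, model, seed, with_replacement_noise) {
  parc <- phantom$parcellation
  V <- nrow(parc)
  T <- model$t
  with_local_seed(seed, {
    s <- matrix(stats::rnorm(T * 7L), T, 7L)
    h <- matrix(stats::rnorm(T * 14L), T, 14L)
    e <- matrix(stats::rnorm(T * V), T, V)
    e2 <- if (with_replacement_noise) matrix(stats::rnorm(T * V), T, V) else NULL
    list(s = s, h = h, e = e, e2 = e2)
  })
}

# Column index of a voxel's hemisphere channel in the T x 14 matrix.
channel_index <- function(parcellation) {
  net <- match(parcellation$network, network_names)
  src <- ifelse(parcellation$source_hemisphere == "L", 0L, 1L)
  net + 7L * src
}

compose_series <- function(phantom, model, draws, scale = NULL) {
  parc <- phantom$parcellation
  net <- match(parc$network, network_names)
  ch <- channel_index(parc)
  signal <- model$lambda * draws$s[, net, drop = FALSE] +
    model$eta * draws$h[, ch, drop = FALSE]
  if (is.null(scale)) {
    y <- signal + model$sigma * draws$e
  } else {
    sig2 <- model$lambda^2 + model$eta^2
    topup <- sqrt(pmax(1 - scale^2, 0) * sig2)
    y <- sweep(signal, 2, scale, `*`) + model$sigma * draws$e +
      sweep(draws$e2, 2, topup, `*`)
  }
  t(y)
}

#' Simulate a control subject
#'
#' @param phantom An `fca_phantom`.
#' @param model An `fca_signal_model`.
#' @param seed Integer seed; the series is a deterministic function of
#'   (phantom, model, seed).
#' @param subject Subject identifier.
#' @return An `fca_ts` over the phantom mask.
#' @export
simulate_control <- function(phantom, model = signal_model(), seed = 1L,
                             subject = sprintf("control-%03d", seed)) {
  stopifnot(inherits(phantom, "fca_phantom"), inherits(model, "fca_signal_model"))
  draws <- draw_signals(phantom, model, seed, with_replacement_noise = FALSE)
  data <- compose_series(phantom, model, draws)
  time_series_image(phantom$grid, phantom$mask, data, subject = subject,
                    session_index = 0L, session_label = "control")
}

# Per-voxel perturbation field p_v of one lesion on the phantom mask.
lesion_proximity <- function(phantom, lesion) {
  parc <- phantom$parcellation
  tum <- intersect(lesion$mask$members, parc$voxel)
  if (!length(tum)) stop("tumour mask does not intersect the phantom mask",
                         call. = FALSE)
  if (lesion$mode == "spatial") {
    d <- nearest_distance_mm(phantom$grid, parc$voxel, tum)
    p <- exp(-d / lesion$tau)
    p[!(parc$compartment %in% lesion$compartments)] <- 0
    return(p)
  }
  rows <- match(tum, parc$voxel)
  if (lesion$scope == "network") {
    p <- as.numeric(parc$network %in% unique(parc$network[rows]))
  } else {
    tum_key <- unique(paste(parc$network[rows], parc$source_hemisphere[rows]))
    p <- as.numeric(paste(parc$network, parc$source_hemisphere) %in% tum_key)
  }
  p[!(parc$compartment %in% lesion$compartments)] <- 0
  if (lesion$smooth_fwhm > 0) {
    arr <- array(0, phantom$grid$shape)
    arr[parc$voxel] <- p
    sm <- smooth_field_3d(arr, (lesion$smooth_fwhm / 2.3548) / phantom$grid$spacing)
    p <- pmin(as.vector(sm)[parc$voxel] / max(sm), 1)
  }
  p
}

#' Simulate a lesioned patient session
#'
#' Applies one or more [lesion_spec()]s to the control signal model: each
#' lesion scales voxel `v`'s network signal by `1 - gamma * p_v` (factors
#' multiply when several lesions are given) and replaces the removed
#' variance with fresh noise, preserving the per-voxel total variance.
#' With the same `seed`, `gamma = 0` returns exactly the series of
#' [simulate_control()].
#'
#' @param phantom An `fca_phantom`.
#' @param model An `fca_signal_model`.
#' @param lesions A single `fca_lesion_spec` or a list of them.
#' @param seed Integer seed.
#' @param seg Optional `fca_seg` to attach; defaults to labelling the first
#'   lesion's mask as enhancing tumour.
#' @param subject,session_index,session_label Session metadata.
#' @return A list with elements `ts` (`fca_ts`) and `seg` (`fca_seg`).
#' @export
simulate_patient <- function(phantom, model = signal_model(), lesions,
                             seed = 1L, seg = NULL,
                             subject = sprintf("patient-%03d", seed),
                             session_index = 0L, session_label = "pre") {
  stopifnot(inherits(phantom, "fca_phantom"), inherits(model, "fca_signal_model"))
  if (inherits(lesions, "fca_lesion_spec")) lesions <- list(lesions)
  stopifnot(length(lesions) >= 1,
            all(vapply(lesions, inherits, logical(1), "fca_lesion_spec")))
  scale <- rep(1, nrow(phantom$parcellation))
  for (lesion in lesions) {
    scale <- scale * (1 - lesion$gamma * lesion_proximity(phantom, lesion))
  }
  draws <- draw_signals(phantom, model, seed, with_replacement_noise = TRUE)
  data <- compose_series(phantom, model, draws, scale = scale)
  if (is.null(seg)) {
    labels <- integer(n_voxels(phantom$grid))
    labels[lesions[[1]]$mask$members] <- seg_classes[["enhancing"]]
    seg <- segmentation_volume(phantom$grid, labels)
  }
  assert_same_grid(seg$grid, phantom$grid, "segmentation")
  ts <- time_series_image(phantom$grid, phantom$mask, data, subject = subject,
                          session_index = session_index,
                          session_label = session_label)
  list(ts = ts, seg = seg)
}

#' Specify a longitudinal session schedule
#'
#' An ordered list of sessions: pre-surgery, post-surgery, then follow-ups.
#' Each session carries a segmentation, an optional list of lesions, and
#' optionally a *silent* recurrence site: a voxel set whose connectivity is
#' already perturbed at that session although the segmentation does not show
#' it yet. A silent site must appear as enhancing or necrotic tumour in some
#' later session's segmentation — the generative analogue of network anomaly
#' preceding structural recurrence.
#'
#' @param sessions A list of lists with elements `label` (`"pre"`, `"post"`,
#'   `"followup-1"`, ...), `seg` (`fca_seg`), `lesions` (list of
#'   `fca_lesion_spec`, possibly empty), and optionally `silent_mask`
#'   (`fca_mask`), `silent_gamma` (default 0.8) and `silent_tau` (mm decay
#'   of the silent perturbation, default 2).
#' @return An object of class `fca_schedule`.
#' @export
longitudinal_schedule <- function(sessions) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  labels <- vapply(sessions, function(s) s$label, character(1))
  expected <- c("pre", "post", paste0("followup-", seq_len(max(0, length(sessions) - 2))))
  if (!identical(labels, expected[seq_along(labels)])) {
    stop("sessions must be ordered pre, post, followup-1, followup-2, ...",
         call. = FALSE)
  }
  enh_necr <- lapply(sessions, function(s) {
    stopifnot(inherits(s$seg, "fca_seg"))
    seg_mask(s$seg, c("enhancing", "necrotic"))$members
  })
  for (k in seq_along(sessions)) {
    sm <- sessions[[k]]$silent_mask
    if (is.null(sm)) next
    stopifnot(inherits(sm, "fca_mask"))
    later <- unlist(enh_necr[seq_along(sessions) > k])
    if (!all(sm$members %in% later)) {
      stop(sprintf(paste0("silent recurrence at session %d never appears as ",
                          "enhancing/necrotic tumour in a later segmentation"), k),
           call. = FALSE)
    }
  }
  structure(list(sessions = sessions), class = "fca_schedule")
}

#' Simulate a longitudinal session sequence
#'
#' One [simulate_patient()] call per schedule entry. Session `k` uses seed
#' `seed + k - 1`, so sequences are deterministic under `seed` and sessions
#' are mutually independent. Silent recurrence sites are applied as an
#' additional sharply localised perturbation (spatial mode, decay
#' `silent_tau`); segmentations are returned exactly as scheduled.
#'
#' @param phantom An `fca_phantom`.
#' @param model An `fca_signal_model`.
#' @param schedule An `fca_schedule`.
#' @param seed Integer base seed.
#' @param subject Subject identifier.
#' @return A list of sessions, each a list with `ts`, `seg` and `label`.
#' @export
simulate_longitudinal <- function(phantom, model = signal_model(), schedule,
                                  seed = 1L, subject = "patient-long") {
  stopifnot(inherits(schedule, "fca_schedule"))
  out <- vector("list", length(schedule$sessions))
  for (k in seq_along(schedule$sessions)) {
    s <- schedule$sessions[[k]]
    lesions <- s$lesions %||% list()
    if (!is.null(s$silent_mask)) {
      lesions <- c(lesions, list(lesion_spec(s$silent_mask, mode = "spatial",
                                             gamma = s$silent_gamma %||% 0.8,
                                             tau = s$silent_tau %||% 2)))
    }
    if (!length(lesions)) {
      ts <- simulate_control(phantom, model, seed = seed + k - 1L,
                             subject = subject)
      ts$session_index <- k - 1L
      ts$session_label <- s$label
      out[[k]] <- list(ts = ts, seg = s$seg, label = s$label)
    } else {
      sim <- simulate_patient(phantom, model, lesions, seed = seed + k - 1L,
                              seg = s$seg, subject = subject,
                              session_index = k - 1L, session_label = s$label)
      out[[k]] <- list(ts = sim$ts, seg = sim$seg, label = s$label)
    }
  }
  out
}
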