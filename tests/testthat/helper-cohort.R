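# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Compact phantom with a modest control cohort; the workhorse for the
# integration-level module tests.
compact_study <- function() {
  fixture("compact_study", function() {
    phantom <- phantom_demo("compact")
    model <- signal_model(t = 150)
    controls <- simulate_control_cohort(phantom, model, n = 20, seed = 100)
    connectomes <- lapply(controls, compute_connectome)
    reference <- mean_reference(connectomes)
    list(phantom = phantom, model = model, controls = controls,
         connectomes = connectomes, reference = reference)
  })
}

# Tiny grid for unit-scale toy objects.
toy_grid <- function() grid_space(c(4, 4, 4), spacing = 1)

# Build an fca_connectome directly from a z-matrix (diagonal forced NA).
toy_connectome <- function(values, grid = NULL, members = NULL) {
  V <- nrow(values)
  if (is.null(grid)) grid <- grid_space(c(V, 1, 1), spacing = 1)
  if (is.null(members)) members <- seq_len(V)
  diag(values) <- NA_real_
  fcanomaly:::new_connectome(voxel_mask(grid, members), values)
}

# Build an fca_similarity directly from a vector of similarities.
toy_similarity <- function(values, grid = NULL, members = NULL,
                           excluded = integer(0)) {
  V <- length(values)
  if (is.null(grid)) grid <- grid_space(c(V + length(excluded), 1, 1), spacing = 1)
  if (is.null(members)) members <- setdiff(seq_len(V + length(excluded)), excluded)
  structure(list(mask = voxel_mask(grid, members), values = values,
                 excluded = as.integer(excluded), space = "z"),
            class = "fca_similarity")
}

# Random time-series image on a 1D-ish grid.
random_ts <- function(V, T, seed = 1) {
  grid <- grid_space(c(V, 1, 1), spacing = 1)
  set.seed(seed)
  time_series_image(grid, voxel_mask(grid, seq_len(V)),
                    matrix(rnorm(V * T), V, T))
}

ijk_to_index_for_test <- function(grid, ijk) {
  fcanomaly:::ijk_to_index(grid, matrix(ijk, nrow = 1))
}
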