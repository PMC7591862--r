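#' Define a voxel grid
#'
#' A grid is the common sampling space of one study: every volume (time
#' series, mask, segmentation, parcellation, anomaly map) of a study must
#' live on a bitwise-identical grid. Voxel indices are 0-based along each
#' axis and the centre of voxel `(i, j, k)` sits at
#' `origin + (i, j, k) * spacing` millimetres (diagonal affine).
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing Numeric vector of length 3, voxel size in mm (each > 0).
#'   A single value is recycled to all three axes.
#' @param origin Numeric vector of length 3, mm coordinate of voxel
#'   `(0, 0, 0)`. Defaults to the zero origin.
#' @return An object of class `fca_grid`.
#' @examples
#' grid_space(c(10, 12, 8), spacing = 3)
#' @export
grid_space <- function(shape, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    stop("`shape` must be three integers, each >= 1", call. = FALSE)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "fca_grid")
}

#' @export
print.fca_grid <- function(x, ...) {
  cat(sprintf("<fca_grid> %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x")))
  invisible(x)
}

#' @export
format.fca_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(format(x$spacing, trim = TRUE), collapse = "x"), " mm")
}

n_voxels <- function(grid) prod(grid$shape)

#' Test whether two grids are identical
#'
#' Grids match when shape and spacing are bitwise equal (origin is compared
#' with a strict equality too); this is the gate every reader applies before
#' admitting a volume into a study.
#'
#' @param a,b `fca_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  stopifnot(inherits(a, "fca_grid"), inherits(b, "fca_grid"))
  identical(a$shape, b$shape) && identical(a$spacing, b$spacing) &&
    identical(a$origin, b$origin)
}

assert_same_grid <- function(a, b, what = "volume") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch for %s: expected %s, found %s",
                 what, format(b), format(a)), call. = FALSE)
  }
  invisible(TRUE)
}

# linear index (1-based, column-major) <-> 0-based ijk triples
index_to_ijk <- function(grid, members) {
  idx0 <- as.integer(members) - 1L
  nx <- grid$shape[1]; ny <- grid$shape[2]
  cbind(i = idx0 %% nx,
        j = (idx0 %/% nx) %% ny,
        k = idx0 %/% (nx * ny))
}

ijk_to_index <- function(grid, ijk) {
  as.integer(ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3]) + 1L)
}

#' Millimetre coordinates of voxels
#'
#' @param grid An `fca_grid`.
#' @param members 1-based linear voxel indices (column-major order).
#' @return A numeric matrix with columns `x`, `y`, `z` in mm.
#' @export
voxel_coords <- function(grid, members) {
  ijk <- index_to_ijk(grid, members)
  xyz <- sweep(ijk, 2, grid$spacing, `*`)
  xyz <- sweep(xyz, 2, grid$origin, `+`)
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Construct a voxel mask
#'
#' A set of voxels on a grid, stored as sorted 1-based linear indices
#' (column-major). The sorted order is the stable voxel ordering used by
#' every masked array in the package: row `k` of a connectome always refers
#' to `members[k]`.
#'
#' @param grid An `fca_grid`.
#' @param members Linear voxel indices, or a logical/0-1 array of the grid's
#'   shape.
#' @return An object of class `fca_mask`.
#' @export
voxel_mask <- function(grid, members) {
  stopifnot(inherits(grid, "fca_grid"))
  if (is.array(members)) {
    if (!identical(as.integer(dim(members)), grid$shape)) {
      stop("mask array shape does not match the grid", call. = FALSE)
    }
    members <- which(as.vector(members) != 0)
  } else if (is.logical(members)) {
    if (length(members) != n_voxels(grid)) {
      stop("logical mask length does not match the grid", call. = FALSE)
    }
    members <- which(members)
  }
  members <- sort(unique(as.integer(members)))
  if (length(members) && (members[1] < 1L || members[length(members)] > n_voxels(grid))) {
    stop("mask members outside the grid", call. = FALSE)
  }
  structure(list(grid = grid, members = members), class = "fca_mask")
}

#' @export
print.fca_mask <- function(x, ...) {
  cat(sprintf("<fca_mask> %d voxels on %s\n", length(x$members), format(x$grid)))
  invisible(x)
}

#' @export
length.fca_mask <- function(x) length(x$members)

mask_array <- function(mask) {
  arr <- array(0L, dim = mask$grid$shape)
  arr[mask$members] <- 1L
  arr
}

#' Set operations on voxel masks
#'
#' @param a,b `fca_mask` objects on the same grid.
#' @return An `fca_mask`.
#' @export
mask_union <- function(a, b) {
  assert_same_grid(b$grid, a$grid, "mask")
  voxel_mask(a$grid, union(a$members, b$members))
}

#' @rdname mask_union
#' @export
mask_setdiff <- function(a, b) {
  assert_same_grid(b$grid, a$grid, "mask")
  voxel_mask(a$grid, setdiff(a$members, b$members))
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  assert_same_grid(b$grid, a$grid, "mask")
  voxel_mask(a$grid, intersect(a$members, b$members))
}

#' Construct a masked BOLD time-series image
#'
#' Holds the preprocessed signal of the masked voxels as a `V x T` matrix in
#' the mask's stable voxel ordering, plus session metadata. Values are in
#' arbitrary units; the pipeline only uses correlations, which are invariant
#' to per-voxel affine rescaling.
#'
#' @param grid An `fca_grid`.
#' @param mask An `fca_mask` on `grid` with `V` voxels.
#' @param data Numeric `V x T` matrix, `T >= 2`, all values finite.
#' @param subject Subject identifier.
#' @param session_index Integer session index (0 = pre-surgery by convention).
#' @param session_label One of `"control"`, `"pre"`, `"post"`, or
#'   `"followup-k"`.
#' @return An object of class `fca_ts`.
#' @export
time_series_image <- function(grid, mask, data, subject = "subject",
                              session_index = 0L, session_label = "control") {
  stopifnot(inherits(grid, "fca_grid"), inherits(mask, "fca_mask"))
  assert_same_grid(mask$grid, grid, "mask")
  data <- as.matrix(data)
  if (nrow(data) != length(mask$members)) {
    stop("`data` must have one row per mask voxel", call. = FALSE)
  }
  if (ncol(data) < 2L) stop("time series needs T >= 2 volumes", call. = FALSE)
  if (any(!is.finite(data))) {
    stop("non-finite values in the time series", call. = FALSE)
  }
  structure(list(grid = grid, mask = mask, data = data, subject = subject,
                 session_index = as.integer(session_index),
                 session_label = session_label),
            class = "fca_ts")
}

#' @export
print.fca_ts <- function(x, ...) {
  cat(sprintf("<fca_ts> %s [%s, session %d]: %d voxels x %d timepoints on %s\n",
              x$subject, x$session_label, x$session_index,
              nrow(x$data), ncol(x$data), format(x$grid)))
  invisible(x)
}
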