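#' Compute a voxel-wise Fisher-z connectome
#'
#' Pearson correlation between every pair of masked voxel time series,
#' clipped to `|r| <= 1 - clip` and Fisher z-transformed (`atanh`). The
#' clipping keeps z finite when toy data contain perfect correlations. The
#' diagonal (self-correlation) is marked invalid (`NA`) and excluded from
#' every downstream row-wise computation: profile similarity concerns a
#' voxel's connections, not its self-correlation.
#'
#' With `block_size`, rows are computed in streaming blocks of that many
#' voxels; the result is identical to the all-at-once computation (this is
#' the memory-bounded path for large masks — at the ~60,000-voxel scale of
#' real grey-matter masks the full matrix should only be materialised on
#' purpose).
#'
#' @param ts An `fca_ts` with `T >= 3` timepoints.
#' @param clip Correlation clipping margin; correlations are clipped to
#'   magnitude `1 - clip` before `atanh` (default `1e-6`).
#' @param block_size Optional row-block size for the streaming computation.
#' @return An object of class `fca_connectome`: list with `mask`, `values`
#'   (`V x V` symmetric matrix, `NA` diagonal) and `n_controls = NA`.
#' @export
compute_connectome <- function(ts, clip = 1e-6, block_size = NULL) {
  stopifnot(inherits(ts, "fca_ts"))
  X <- ts$data
  if (ncol(X) < 3L) stop("need T >= 3 timepoints for a connectome", call. = FALSE)
  Xc <- X - rowMeans(X)
  ss <- sqrt(rowSums(Xc^2))
  if (any(ss == 0)) {
    stop("zero-variance voxel series at mask row(s): ",
         paste(utils::head(which(ss == 0), 5), collapse = ", "), call. = FALSE)
  }
  Xs <- Xc / ss
  V <- nrow(Xs)
  bound <- 1 - clip
  if (is.null(block_size) || block_size >= V) {
    C <- tcrossprod(Xs)
  } else {
    C <- matrix(0, V, V)
    for (start in seq(1L, V, by = as.integer(block_size))) {
      idx <- start:min(start + block_size - 1L, V)
      C[idx, ] <- Xs[idx, , drop = FALSE] %*% t(Xs)
    }
  }
  C[C > bound] <- bound
  C[C < -bound] <- -bound
  Z <- atanh(C)
  diag(Z) <- NA_real_
  new_connectome(ts$mask, Z)
}

new_connectome <- function(mask, values, n_controls = NA_integer_,
                           reference = FALSE) {
  structure(list(mask = mask, values = values,
                 n_controls = as.integer(n_controls)),
            class = c(if (reference) "fca_reference", "fca_connectome"))
}

#' @export
print.fca_connectome <- function(x, ...) {
  cat(sprintf("<%s> %d x %d Fisher-z connectome%s\n",
              if (inherits(x, "fca_reference")) "fca_reference" else "fca_connectome",
              nrow(x$values), ncol(x$values),
              if (!is.na(x$n_controls)) sprintf(" (mean of %d controls)", x$n_controls)
              else ""))
  invisible(x)
}

#' Average connectomes into a group reference
#'
#' Element-wise arithmetic mean of the control connectomes, computed on the
#' Fisher-z scale. Accepts ready-made `fca_connectome`s or raw `fca_ts`
#' objects (converted one at a time, so memory stays bounded by a single
#' matrix).
#'
#' @param connectomes Nonempty list of `fca_connectome` or `fca_ts` objects
#'   on identical masks.
#' @param clip Forwarded to [compute_connectome()] for `fca_ts` inputs.
#' @return An `fca_reference` (an `fca_connectome` with `n_controls` set).
#' @export
mean_reference <- function(connectomes, clip = 1e-6) {
  if (!is.list(connectomes) || !length(connectomes)) {
    stop("need at least one connectome", call. = FALSE)
  }
  acc <- NULL
  mask <- NULL
  for (x in connectomes) {
    cx <- if (inherits(x, "fca_ts")) compute_connectome(x, clip = clip) else x
    stopifnot(inherits(cx, "fca_connectome"))
    if (is.null(mask)) {
      mask <- cx$mask
      acc <- cx$values
    } else {
      if (!identical(mask$members, cx$mask$members) ||
          !same_grid(mask$grid, cx$mask$grid)) {
        stop("connectomes have mismatching masks", call. = FALSE)
      }
      acc <- acc + cx$values
    }
  }
  new_connectome(mask, acc / length(connectomes),
                 n_controls = length(connectomes), reference = TRUE)
}

#' Remove voxels from a connectome
#'
#' Deletes the rows and columns of the excluded voxels; the ordering of the
#' remaining voxels is preserved. Used to take patient-specific tumour
#' voxels out of both the patient's and the controls' connectivity profiles.
#'
#' @param connectome An `fca_connectome` (or `fca_reference`).
#' @param exclude An `fca_mask`; members outside the connectome mask are an
#'   error.
#' @return The same type with the excluded voxels removed.
#' @export
drop_voxels <- function(connectome, exclude) {
  stopifnot(inherits(connectome, "fca_connectome"), inherits(exclude, "fca_mask"))
  assert_same_grid(exclude$grid, connectome$mask$grid, "exclusion mask")
  if (!all(exclude$members %in% connectome$mask$members)) {
    stop("exclusion mask is not a subset of the connectome mask", call. = FALSE)
  }
  if (!length(exclude$members)) return(connectome)
  keep <- !(connectome$mask$members %in% exclude$members)
  if (sum(keep) < 2L) stop("exclusion leaves fewer than 2 voxels", call. = FALSE)
  new_connectome(voxel_mask(connectome$mask$grid, connectome$mask$members[keep]),
                 connectome$values[keep, keep, drop = FALSE],
                 n_controls = connectome$n_controls,
                 reference = inherits(connectome, "fca_reference"))
}
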