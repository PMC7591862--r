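# Separable Gaussian smoothing of a scalar field on a grid, with zero
# padding at the edges. sigma is per-axis in voxel units (fwhm_mm / 2.3548 /
# spacing); kernels are truncated at 3 sigma and renormalised.
smooth_field_3d <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, axis)
  }
  arr
}

convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  r <- (length(k) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  n <- nrow(m)
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (o in seq_along(k)) {
    out <- out + k[o] * padded[(o):(o + n - 1L), , drop = FALSE]
  }
  res <- array(out, da)
  aperm(res, order(perm))
}

#' Liberal smoothed tumour mask
#'
#' Takes the union of all tumour tissue classes (necrotic, enhancing,
#' non-enhancing, oedema) plus the resection cavity, smooths the binary
#' volume with a Gaussian kernel of the given FWHM (sigma = FWHM/2.3548),
#' and keeps every voxel above `rel_threshold` of the smoothed peak. The
#' result always contains the input voxels, so the mask can only grow:
#' a liberal exclusion zone around the structural lesion.
#'
#' @param seg An `fca_seg`.
#' @param fwhm_mm Kernel full width at half maximum in mm (> 0).
#' @param rel_threshold Keep voxels whose smoothed value exceeds this
#'   fraction of the smoothed maximum (default 0.05).
#' @return An `fca_mask` (empty if the segmentation has no lesion voxels).
#' @export
smooth_tumour_mask <- function(seg, fwhm_mm = 3, rel_threshold = 0.05) {
  stopifnot(inherits(seg, "fca_seg"))
  if (fwhm_mm <= 0) stop("`fwhm_mm` must be > 0", call. = FALSE)
  lesion <- seg_mask(seg)
  if (!length(lesion$members)) return(voxel_mask(seg$grid, integer(0)))
  arr <- array(0, seg$grid$shape)
  arr[lesion$members] <- 1
  sigma_vox <- (fwhm_mm / 2.3548) / seg$grid$spacing
  sm <- smooth_field_3d(arr, sigma_vox)
  keep <- which(as.vector(sm) > rel_threshold * max(sm))
  voxel_mask(seg$grid, union(keep, lesion$members))
}
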