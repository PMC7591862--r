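#' @importFrom RNifti readNifti writeNifti asNifti pixdim xform
NULL

# Build an fca_grid from a NIfTI image. Real affines are honoured as long as
# they are axis-aligned (diagonal up to sign); rotated acquisitions must be
# resampled upstream.
grid_from_nifti <- function(img) {
  d <- dim(img)[1:3]
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot[col(rot) != row(rot)]) > 1e-6)) {
    stop("non-axis-aligned NIfTI affine; resample the volume first", call. = FALSE)
  }
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  grid_space(d, spacing = spacing, origin = xf[1:3, 4])
}

nifti_from_grid <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::`sform<-`(img, structure(m, code = 2L))
}

#' Read a volume from a NIfTI file
#'
#' Reads a 3D or 4D NIfTI volume into the matching typed object. 4D volumes
#' become [time_series_image()]s; 3D volumes become masks or segmentations.
#' If `expected_grid` is supplied, a volume on any other grid is rejected,
#' which enforces the one-grid-per-study contract.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param what One of `"auto"`, `"timeseries"`, `"mask"`, `"segmentation"`.
#'   With `"auto"`, 4D data is read as a time series and 3D data as a mask
#'   when binary, otherwise as a segmentation.
#' @param expected_grid Optional `fca_grid` the volume must match.
#' @param mask Optional `fca_mask` restricting a 4D read; defaults to all
#'   voxels.
#' @param subject,session_index,session_label Metadata forwarded to
#'   [time_series_image()] for 4D reads.
#' @return An `fca_ts`, `fca_mask` or `fca_seg`.
#' @export
read_volume <- function(path, what = c("auto", "timeseries", "mask", "segmentation"),
                        expected_grid = NULL, mask = NULL, subject = "subject",
                        session_index = 0L, session_label = "control") {
  what <- match.arg(what)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  if (!is.null(expected_grid)) assert_same_grid(grid, expected_grid, path)
  nd <- length(dim(img))
  if (nd == 4L) {
    if (what %in% c("mask", "segmentation")) {
      stop("expected a 3D volume but ", path, " is 4D", call. = FALSE)
    }
    arr <- array(as.numeric(img), dim = dim(img))
    if (is.null(mask)) mask <- voxel_mask(grid, seq_len(n_voxels(grid)))
    assert_same_grid(mask$grid, grid, "mask")
    mat <- matrix(aperm(arr, c(4, 1, 2, 3)), nrow = dim(arr)[4])
    data <- t(mat[, mask$members, drop = FALSE])
    if (any(!is.finite(data))) {
      stop("non-finite voxels in the time series: ", path, call. = FALSE)
    }
    return(time_series_image(grid, mask, data, subject = subject,
                             session_index = session_index,
                             session_label = session_label))
  }
  if (nd != 3L) stop(path, " is neither 3D nor 4D", call. = FALSE)
  vals <- as.vector(img)
  if (what == "timeseries") stop("expected a 4D volume but ", path, " is 3D", call. = FALSE)
  if (what == "auto") {
    what <- if (all(vals %in% c(0, 1))) "mask" else "segmentation"
  }
  if (what == "mask") {
    if (!all(vals %in% c(0, 1))) stop("mask volume is not binary: ", path, call. = FALSE)
    voxel_mask(grid, which(vals != 0))
  } else {
    if (any(abs(vals - round(vals)) > 1e-8)) {
      stop("segmentation volume has non-integer labels: ", path, call. = FALSE)
    }
    segmentation_volume(grid, as.integer(round(vals)))
  }
}

#' Write a typed volume to a NIfTI file
#'
#' Inverse of [read_volume()]: time series are written as 4D volumes (zero
#' outside the mask), masks as binary volumes, segmentations as integer label
#' volumes, and anomaly maps as floating-point volumes with `NaN` at invalid
#' voxels.
#'
#' @param x An `fca_ts`, `fca_mask`, `fca_seg` or `fca_anomaly`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  UseMethod("write_volume")
}

#' @export
write_volume.fca_ts <- function(x, path) {
  T <- ncol(x$data)
  arr <- array(0, dim = c(x$grid$shape, T))
  flat <- matrix(0, nrow = n_voxels(x$grid), ncol = T)
  flat[x$mask$members, ] <- x$data
  arr[] <- flat
  RNifti::writeNifti(nifti_from_grid(arr, x$grid), path)
  invisible(path)
}

#' @export
write_volume.fca_mask <- function(x, path) {
  RNifti::writeNifti(nifti_from_grid(mask_array(x), x$grid), path)
  invisible(path)
}

#' @export
write_volume.fca_seg <- function(x, path) {
  RNifti::writeNifti(nifti_from_grid(array(x$labels, x$grid$shape), x$grid), path)
  invisible(path)
}

#' @export
write_volume.fca_anomaly <- function(x, path) {
  full <- rep(NaN, n_voxels(x$grid))
  full[x$mask$members] <- ifelse(is.na(x$score), NaN, x$score)
  RNifti::writeNifti(nifti_from_grid(array(full, x$grid$shape), x$grid), path)
  invisible(path)
}

#' Write or read a network parcellation
#'
#' The parcellation is stored as a NIfTI label volume plus a TSV label table
#' with columns `code`, `name`, `network`, `hemisphere`, `compartment`; the
#' pair round-trips losslessly.
#'
#' @param parcellation An `fca_parcellation`.
#' @param nifti_path,table_path Output/input paths.
#' @param expected_grid Optional `fca_grid` to enforce on read.
#' @return `write_parcellation` returns the paths invisibly;
#'   `read_parcellation` returns an `fca_parcellation`.
#' @export
write_parcellation <- function(parcellation, nifti_path, table_path) {
  grid <- attr(parcellation, "grid")
  key <- paste(parcellation$network, parcellation$hemisphere,
               parcellation$compartment, sep = "|")
  levels_key <- sort(unique(key))
  code <- match(key, levels_key)
  labels <- integer(n_voxels(grid))
  labels[parcellation$voxel] <- code
  RNifti::writeNifti(nifti_from_grid(array(labels, grid$shape), grid), nifti_path)
  parts <- do.call(rbind, strsplit(levels_key, "|", fixed = TRUE))
  tab <- data.frame(code = seq_along(levels_key),
                    name = gsub("|", "_", levels_key, fixed = TRUE),
                    network = parts[, 1], hemisphere = parts[, 2],
                    compartment = parts[, 3])
  write_tsv_stable(tab, table_path)
  invisible(c(nifti_path, table_path))
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(nifti_path, table_path, expected_grid = NULL) {
  if (!file.exists(nifti_path)) stop("file not found: ", nifti_path, call. = FALSE)
  if (!file.exists(table_path)) stop("file not found: ", table_path, call. = FALSE)
  img <- RNifti::readNifti(nifti_path)
  grid <- grid_from_nifti(img)
  if (!is.null(expected_grid)) assert_same_grid(grid, expected_grid, nifti_path)
  labels <- as.integer(round(as.vector(img)))
  tab <- utils::read.delim(table_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("code", "network", "hemisphere", "compartment")
  if (!all(need %in% names(tab))) {
    stop("label table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  voxels <- which(labels != 0)
  row <- match(labels[voxels], tab$code)
  if (any(is.na(row))) {
    bad <- sort(unique(labels[voxels][is.na(row)]))
    stop("parcellation label code(s) missing from table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  network_parcellation(grid, voxels, tab$network[row], tab$hemisphere[row],
                       tab$compartment[row])
}

# Deterministic TSV writer: fixed separators, no quoting, no row names, and a
# fixed significant-digit format so repeated runs are byte-identical.
write_tsv_stable <- function(df, path, digits = 10) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
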