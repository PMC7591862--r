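#' Specify a phantom brain
#'
#' The phantom is a rectangular two-compartment "brain": a cerebrum block of
#' `nx * ny * nz_cerebrum` voxels and a cerebellum block of
#' `nx * ny * nz_cerebellum` voxels stacked along z. The left hemisphere is
#' `x < nx/2` and the right hemisphere its mirror image, so the mirror map
#' `(i,j,k) -> (nx-1-i, j, k)` is an involution. The seven resting-state
#' networks are assigned in diagonal stripes, `network = (j + k) mod 7`,
#' which makes network membership *spatially distributed* and mirror
#' symmetric: functional proximity and spatial distance are dissociated by
#' construction, which is exactly what the attribution analyses estimate.
#' Cerebellar voxels carry the crossed (contralateral) hemisphere channel of
#' their network.
#'
#' @param nx Voxels along x; must be even so hemispheres mirror.
#' @param ny,nz_cerebrum,nz_cerebellum Voxels along y and z per compartment.
#' @param spacing Voxel size in mm (scalar or length 3).
#' @param seed Integer seed recorded with the phantom (construction itself is
#'   deterministic).
#' @return An object of class `fca_phantom_spec`.
#' @export
phantom_spec <- function(nx = 10, ny = 15, nz_cerebrum = 14, nz_cerebellum = 3,
                         spacing = 3, seed = 1L) {
  nx <- as.integer(nx)
  if (nx %% 2L != 0L) {
    stop("`nx` must be even: hemispheres cannot mirror otherwise", call. = FALSE)
  }
  stopifnot(ny >= 1, nz_cerebrum >= 1, nz_cerebellum >= 1)
  structure(list(nx = nx, ny = as.integer(ny),
                 nz_cerebrum = as.integer(nz_cerebrum),
                 nz_cerebellum = as.integer(nz_cerebellum),
                 spacing = spacing, seed = as.integer(seed)),
            class = "fca_phantom_spec")
}

#' Build a phantom brain
#'
#' Realises a [phantom_spec()] into a grid, analysis mask, seven-network
#' parcellation and mirror map.
#'
#' @param spec An `fca_phantom_spec`.
#' @return An object of class `fca_phantom`: a list with elements `grid`,
#'   `mask`, `parcellation`, `mirror` (integer vector mapping each masked
#'   voxel's linear index to its mirror partner's) and `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "fca_phantom_spec"))
  nz <- spec$nz_cerebrum + spec$nz_cerebellum
  grid <- grid_space(c(spec$nx, spec$ny, nz), spacing = spec$spacing)
  members <- seq_len(n_voxels(grid))
  ijk <- index_to_ijk(grid, members)
  compartment <- ifelse(ijk[, "k"] < spec$nz_cerebrum, "cerebrum", "cerebellum")
  hemisphere <- ifelse(ijk[, "i"] < spec$nx / 2, "L", "R")
  network <- network_names[((ijk[, "j"] + ijk[, "k"]) %% 7L) + 1L]
  parcellation <- network_parcellation(grid, members, network, hemisphere,
                                       compartment)
  mirror_ijk <- cbind(spec$nx - 1L - ijk[, "i"], ijk[, "j"], ijk[, "k"])
  mirror <- ijk_to_index(grid, mirror_ijk)
  names(mirror) <- members
  structure(list(grid = grid,
                 mask = voxel_mask(grid, members),
                 parcellation = parcellation,
                 mirror = mirror,
                 spec = spec),
            class = "fca_phantom")
}

#' @export
print.fca_phantom <- function(x, ...) {
  cat(sprintf("<fca_phantom> %s; %d voxels (%d cerebrum, %d cerebellum)\n",
              format(x$grid), length(x$mask$members),
              sum(x$parcellation$compartment == "cerebrum"),
              sum(x$parcellation$compartment == "cerebellum")))
  invisible(x)
}

#' Ready-made phantoms
#'
#' `"demo"` is the default study phantom (2,550 voxels) used for the null
#' calibration experiments; `"compact"` (728 voxels) keeps the multi-seed
#' recovery simulations fast while preserving the full bilateral and
#' cerebellar structure.
#'
#' @param size `"demo"` or `"compact"`.
#' @param seed Seed recorded with the phantom.
#' @return An `fca_phantom`.
#' @export
phantom_demo <- function(size = c("demo", "compact"), seed = 1L) {
  size <- match.arg(size)
  spec <- switch(size,
    demo = phantom_spec(nx = 10, ny = 15, nz_cerebrum = 14, nz_cerebellum = 3,
                        seed = seed),
    compact = phantom_spec(nx = 8, ny = 7, nz_cerebrum = 11, nz_cerebellum = 2,
                           seed = seed))
  build_phantom(spec)
}

#' Spherical voxel set
#'
#' All voxels whose centre lies within `radius_mm` of the centre voxel's
#' centre; the building block for synthetic tumours and recurrence sites.
#'
#' @param grid An `fca_grid`.
#' @param centre_ijk 0-based voxel index triple.
#' @param radius_mm Radius in mm.
#' @return An `fca_mask`.
#' @export
spherical_mask <- function(grid, centre_ijk, radius_mm) {
  centre_mm <- as.numeric(centre_ijk) * grid$spacing + grid$origin
  xyz <- voxel_coords(grid, seq_len(n_voxels(grid)))
  d2 <- (xyz[, 1] - centre_mm[1])^2 + (xyz[, 2] - centre_mm[2])^2 +
    (xyz[, 3] - centre_mm[3])^2
  voxel_mask(grid, which(d2 <= radius_mm^2))
}

#' Concentric synthetic tumour segmentation
#'
#' Builds a synthetic glioma-like segmentation: a necrotic core inside an
#' enhancing shell inside an oedema rim, centred on a voxel.
#'
#' @param phantom An `fca_phantom`.
#' @param centre_ijk 0-based voxel index triple of the tumour centre.
#' @param r_necrotic,r_enhancing,r_oedema Radii in mm (necrotic <= enhancing
#'   <= oedema); a zero radius omits the class.
#' @return An `fca_seg`.
#' @export
synthetic_tumour_segmentation <- function(phantom, centre_ijk, r_necrotic = 3,
                                          r_enhancing = 6, r_oedema = 9) {
  stopifnot(r_necrotic <= r_enhancing, r_enhancing <= r_oedema)
  grid <- phantom$grid
  labels <- integer(n_voxels(grid))
  assign_shell <- function(radius, code) {
    if (radius > 0) {
      m <- mask_intersect(spherical_mask(grid, centre_ijk, radius), phantom$mask)
      labels[m$members][labels[m$members] == 0L] <<- code
    }
  }
  assign_shell(r_necrotic, seg_classes[["necrotic"]])
  assign_shell(r_enhancing, seg_classes[["enhancing"]])
  assign_shell(r_oedema, seg_classes[["oedema"]])
  segmentation_volume(grid, labels)
}

# Minimum distance (mm) from each `from` voxel centre to the `to` voxel set.
nearest_distance_mm <- function(grid, from_members, to_members, chunk = 4096L) {
  if (!length(to_members)) stop("empty target voxel set", call. = FALSE)
  to_xyz <- voxel_coords(grid, to_members)
  out <- numeric(length(from_members))
  for (start in seq(1L, length(from_members), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(from_members))
    fx <- voxel_coords(grid, from_members[idx])
    d2 <- outer(rowSums(fx^2), rowSums(to_xyz^2), `+`) - 2 * fx %*% t(to_xyz)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
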