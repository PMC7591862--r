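#' Tissue classes of a tumour segmentation
#'
#' Fixed label codes for the segmentation volumes handled by the package:
#' four tumour tissue classes plus the manually delineated resection cavity,
#' with 0 for background.
#'
#' @format Named integer vector.
#' @export
seg_classes <- c(background = 0L, necrotic = 1L, enhancing = 2L,
                 `non-enhancing` = 3L, oedema = 4L, resection = 5L)

#' Construct a tumour segmentation volume
#'
#' One tissue class per voxel over the full grid. Unknown label codes are
#' rejected by name so upstream segmentation mix-ups surface immediately.
#'
#' @param grid An `fca_grid`.
#' @param labels Integer vector or array over the full grid, with values in
#'   [seg_classes].
#' @return An object of class `fca_seg`.
#' @export
segmentation_volume <- function(grid, labels) {
  stopifnot(inherits(grid, "fca_grid"))
  if (is.array(labels)) {
    if (!identical(as.integer(dim(labels)), grid$shape)) {
      stop("segmentation array shape does not match the grid", call. = FALSE)
    }
    labels <- as.vector(labels)
  }
  if (length(labels) != n_voxels(grid)) {
    stop("segmentation must label every voxel of the grid", call. = FALSE)
  }
  labels <- as.integer(labels)
  bad <- setdiff(unique(labels), unname(seg_classes))
  if (length(bad)) {
    stop(sprintf("unknown segmentation label code(s): %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  structure(list(grid = grid, labels = labels), class = "fca_seg")
}

#' @export
print.fca_seg <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seg_classes, labels = names(seg_classes)))
  tab <- tab[tab > 0 & names(tab) != "background"]
  cat(sprintf("<fca_seg> on %s: %s\n", format(x$grid),
              if (length(tab)) paste(names(tab), tab, sep = "=", collapse = ", ")
              else "empty"))
  invisible(x)
}

#' Voxels of a segmentation belonging to given tissue classes
#'
#' @param seg An `fca_seg`.
#' @param classes Character vector of class names (see [seg_classes]);
#'   defaults to every non-background class.
#' @return An `fca_mask`.
#' @export
seg_mask <- function(seg, classes = setdiff(names(seg_classes), "background")) {
  stopifnot(inherits(seg, "fca_seg"))
  codes <- seg_classes[match.arg(classes, names(seg_classes), several.ok = TRUE)]
  voxel_mask(seg$grid, which(seg$labels %in% codes))
}

#' An all-background segmentation
#'
#' @param grid An `fca_grid`.
#' @return An `fca_seg` with every voxel labelled background.
#' @export
empty_segmentation <- function(grid) {
  segmentation_volume(grid, integer(n_voxels(grid)))
}

#' The seven resting-state network names
#'
#' Visual, somatomotor, dorsal attention, ventral attention, limbic,
#' fronto-parietal control and default mode networks.
#'
#' @format Character vector of length 7.
#' @export
network_names <- c("VIS", "SM", "DAN", "VAN", "LIMB", "CON", "DMN")

#' Construct a network parcellation
#'
#' Assigns each masked voxel a resting-state network, an anatomical
#' hemisphere and a compartment (cerebrum or cerebellum). Cerebellar voxels
#' carry the network of the *contralateral* cerebral hemisphere (crossed
#' cerebro-cerebellar representation); the `source_hemisphere` column makes
#' that explicit: it equals `hemisphere` in the cerebrum and the opposite
#' side in the cerebellum.
#'
#' @param grid An `fca_grid`.
#' @param voxel 1-based linear voxel indices of the parcellated voxels.
#' @param network Network id per voxel, one of [network_names] (or `"none"`,
#'   which drops the voxel from the parcellation mask).
#' @param hemisphere `"L"` or `"R"` per voxel.
#' @param compartment `"cerebrum"` or `"cerebellum"` per voxel.
#' @return A tibble of class `fca_parcellation` with columns `voxel`,
#'   `network`, `hemisphere`, `compartment`, `source_hemisphere`, and the
#'   grid stored as an attribute.
#' @export
network_parcellation <- function(grid, voxel, network, hemisphere, compartment) {
  stopifnot(inherits(grid, "fca_grid"))
  voxel <- as.integer(voxel)
  keep <- network != "none"
  voxel <- voxel[keep]; network <- network[keep]
  hemisphere <- hemisphere[keep]; compartment <- compartment[keep]
  if (anyDuplicated(voxel)) stop("duplicate voxels in parcellation", call. = FALSE)
  if (!all(network %in% network_names)) {
    stop("network ids must be one of: ", paste(network_names, collapse = ", "),
         call. = FALSE)
  }
  if (!all(hemisphere %in% c("L", "R"))) stop("hemisphere must be L or R", call. = FALSE)
  if (!all(compartment %in% c("cerebrum", "cerebellum"))) {
    stop("compartment must be cerebrum or cerebellum", call. = FALSE)
  }
  ord <- order(voxel)
  out <- tibble::tibble(
    voxel = voxel[ord],
    network = network[ord],
    hemisphere = hemisphere[ord],
    compartment = compartment[ord]
  )
  out$source_hemisphere <- ifelse(out$compartment == "cerebellum",
                                  ifelse(out$hemisphere == "L", "R", "L"),
                                  out$hemisphere)
  attr(out, "grid") <- grid
  class(out) <- c("fca_parcellation", class(out))
  out
}

#' Mask of all parcellated voxels
#'
#' @param parcellation An `fca_parcellation`.
#' @return An `fca_mask`.
#' @export
parcellation_mask <- function(parcellation) {
  voxel_mask(attr(parcellation, "grid"), parcellation$voxel)
}
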