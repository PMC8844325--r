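#' Euclidean distance transform
#'
#' Exact distance (mm) from every voxel centre to the nearest foreground
#' voxel centre, honouring anisotropic voxel sizes. Foreground voxels map
#' to 0; an empty mask maps everywhere to `Inf`.
#'
#' @param vol a binary `mbf_volume` (or a logical/0-1 array with `spacing`).
#' @param spacing voxel size override when `vol` is a bare array.
#' @return A numeric array of distances, same shape as the input.
#' @export
distance_transform <- function(vol, spacing = NULL) {
  if (is_volume(vol)) {
    arr <- vol$data
    spacing <- vol$voxel_size
  } else {
    arr <- vol
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  }
  d <- dim(arr)
  out <- .cpp_edt(as.logical(arr != 0), as.integer(d), as.numeric(spacing))
  dim(out) <- d
  out
}

#' Dilate / erode a binary mask by a physical radius
#'
#' Spherical structuring element realised through the distance transform:
#' dilation keeps voxels within `radius_mm` of the foreground, erosion keeps
#' foreground voxels farther than `radius_mm` from the background.
#'
#' @param vol binary `mbf_volume`.
#' @param radius_mm radius in mm (>= 0).
#' @return A binary `mbf_volume`.
#' @export
dilate_mask <- function(vol, radius_mm) {
  stopifnot_volume(vol)
  if (radius_mm < 0) stop("`radius_mm` must be >= 0")
  if (radius_mm == 0) return(vol)
  d <- distance_transform(vol)
  volume((d <= radius_mm + 1e-9) + 0, vol$voxel_size, vol$origin, vol$direction)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(vol, radius_mm) {
  stopifnot_volume(vol)
  if (radius_mm < 0) stop("`radius_mm` must be >= 0")
  if (radius_mm == 0) return(vol)
  inv <- volume(1 - vol$data, vol$voxel_size, vol$origin, vol$direction)
  d <- distance_transform(inv)
  volume((vol$data > 0 & d > radius_mm + 1e-9) + 0,
         vol$voxel_size, vol$origin, vol$direction)
}

#' Connected components of a binary mask
#'
#' 6-connected labelling; components are numbered from 1 in order of their
#' lowest linear voxel index, which fixes the tie-break used when selecting
#' "the largest" component deterministically.
#'
#' @param vol binary `mbf_volume`.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(vol) {
  stopifnot_volume(vol)
  lab <- .cpp_label_components(as.logical(vol$data != 0), as.integer(dim(vol$data)))
  dim(lab) <- dim(vol$data)
  lab
}

# largest 6-connected component; ties broken toward the component whose first
# voxel has the lowest linear index (label order is index order)
largest_component <- function(vol) {
  lab <- label_components(vol)
  if (max(lab) == 0L) return(vol)
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # first max = lowest first-voxel index
  volume((lab == keep) + 0, vol$voxel_size, vol$origin, vol$direction)
}

# fill interior holes: background components not touching the grid boundary
fill_holes <- function(vol) {
  inv <- volume(1 - vol$data, vol$voxel_size, vol$origin, vol$direction)
  lab <- label_components(inv)
  d <- dim(vol$data)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  filled <- vol$data > 0 | (lab > 0 & !(lab %in% border_labels))
  volume(filled + 0, vol$voxel_size, vol$origin, vol$direction)
}

# geodesic nearest-seed partition of a domain mask (multi-source Dijkstra,
# 6-neighbour graph, mm edge weights)
geodesic_labels <- function(domain_vol, seed_idx_linear, seed_labels) {
  lab <- .cpp_geodesic_labels(as.logical(domain_vol$data != 0),
                              as.integer(dim(domain_vol$data)),
                              as.numeric(domain_vol$voxel_size),
                              as.integer(seed_idx_linear),
                              as.integer(seed_labels))
  dim(lab) <- dim(domain_vol$data)
  lab
}
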