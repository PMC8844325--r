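#' Discretize the subtended myocardium into 4-mm cubic ROIs
#'
#' Walks the (fused) centerline base to apex in steps of `roi_length_mm` of
#' arc length; at the midpoint of each step the sampling cube is anchored to
#' the nearest myocardial mid-wall voxel (a depth-weighted snap keeps the
#' cube inside tissue even for thin walls), and its member voxels are the
#' myocardial voxels whose centres fall in the half-open axis-aligned cube
#' of edge `roi_length_mm`. ROI longitudinal positions are
#' `(i - 1/2) * roi_length_mm`, spaced exactly one edge length apart, so ROI
#' counts and positions are independent of mask perturbations (the
#' point-by-point comparability the Dice analysis requires).
#'
#' @param cl an `mbf_centerline` in the grid's world frame (already fused).
#' @param masks an `mbf_masks` on the dynamic series' grid.
#' @param roi_length_mm cube edge and longitudinal step, mm.
#' @param clip_to_myocardium restrict member voxels to the myocardium
#'   (default); `FALSE` keeps the pure cube.
#' @param search_radius_mm maximal snap distance from the centerline sample
#'   to the myocardium before the step is declared empty.
#' @param on_empty `"error"` (default) aborts naming the arc-length position
#'   of the offending step — the signature of gross misregistration;
#'   `"truncate"` drops empty trailing steps (and errors only on interior
#'   gaps), accommodating apex-truncated masks.
#' @return An object of class `mbf_roiset`: list with `vessel`,
#'   `roi_length`, and `rois` (each `index`, `position`, `center`,
#'   `voxels` as linear grid indices, `n`).
#' @export
subtended_rois <- function(cl, masks, roi_length_mm = 4,
                           clip_to_myocardium = TRUE,
                           search_radius_mm = 15,
                           on_empty = c("error", "truncate")) {
  if (!is_centerline(cl)) stop("expected `mbf_centerline`")
  if (!is_masks(masks)) stop("expected `mbf_masks`")
  on_empty <- match.arg(on_empty)
  L <- arc_length(cl)
  if (L < roi_length_mm) stop("centerline arc length shorter than one ROI")
  nroi <- floor(L / roi_length_mm + 1e-9)
  positions <- (seq_len(nroi) - 0.5) * roi_length_mm

  myo <- myocardium_mask(masks)
  d <- dim(myo$data)
  myo_lin <- which(myo$data > 0)
  myo_xyz <- voxel_to_world(myo, arrayInd(myo_lin, d))
  # depth inside the myocardium: distance to the nearest non-myocardial voxel
  depth <- distance_transform(volume(1 - myo$data, myo$voxel_size, myo$origin,
                                     myo$direction))[myo_lin]
  grid_lin <- if (clip_to_myocardium) myo_lin else seq_len(prod(d))
  grid_xyz <- if (clip_to_myocardium) myo_xyz else
    voxel_to_world(myo, arrayInd(grid_lin, d))

  rois <- vector("list", nroi)
  empty <- logical(nroi)
  half <- roi_length_mm / 2
  for (i in seq_len(nroi)) {
    p <- drop(centerline_point_at(cl, positions[i]))
    dist <- sqrt((myo_xyz[, 1] - p[1])^2 + (myo_xyz[, 2] - p[2])^2 +
                   (myo_xyz[, 3] - p[3])^2)
    near <- which(dist <= search_radius_mm)
    if (length(near) == 0L) { empty[i] <- TRUE; next }
    # snap toward the mid-wall: trade proximity against depth
    pick <- near[which.min(dist[near] - depth[near])]
    ctr <- myo_xyz[pick, ]
    inx <- grid_xyz[, 1] - ctr[1] >= -half & grid_xyz[, 1] - ctr[1] < half &
      grid_xyz[, 2] - ctr[2] >= -half & grid_xyz[, 2] - ctr[2] < half &
      grid_xyz[, 3] - ctr[3] >= -half & grid_xyz[, 3] - ctr[3] < half
    vox <- grid_lin[inx]
    if (length(vox) == 0L) { empty[i] <- TRUE; next }
    rois[[i]] <- list(index = i, position = positions[i], center = ctr,
                      voxels = vox, n = length(vox))
  }
  if (any(empty)) {
    if (on_empty == "error")
      stop(sprintf("no myocardial voxels for ROI at %.1f mm along %s (misregistration?)",
                   positions[which(empty)[1]], cl$vessel))
    # truncate: only trailing empties are tolerated
    last_ok <- max(c(0L, which(!empty)))
    if (any(empty[seq_len(last_ok)]))
      stop(sprintf("interior ROI gap at %.1f mm along %s (misregistration?)",
                   positions[which(empty[seq_len(last_ok)])[1]], cl$vessel))
    rois <- rois[seq_len(last_ok)]
  }
  if (length(rois) == 0L) stop("no ROIs could be formed along ", cl$vessel)
  structure(list(vessel = cl$vessel, roi_length = roi_length_mm, rois = rois,
                 grid_dim = d),
            class = "mbf_roiset")
}

#' @export
print.mbf_roiset <- function(x, ...) {
  cat(sprintf("<mbf_roiset> %s: %d ROIs of %g mm, %d-%d voxels each\n",
              x$vessel, length(x$rois), x$roi_length,
              min(vapply(x$rois, `[[`, 0L, "n")),
              max(vapply(x$rois, `[[`, 0L, "n"))))
  invisible(x)
}

#' Extract a TAC from a dynamic series
#'
#' Per-frame unweighted mean over the member voxels.
#'
#' @param series an `mbf_series`.
#' @param voxels linear voxel indices into each frame.
#' @param source source tag for the TAC.
#' @return An `mbf_tac`.
#' @export
extract_tac <- function(series, voxels, source = "roi") {
  if (!is_series(series)) stop("expected `mbf_series`")
  voxels <- as.integer(voxels)
  nvox <- prod(dim(series$data)[1:3])
  if (length(voxels) == 0L) stop("empty voxel list")
  if (any(voxels < 1L | voxels > nvox)) stop("voxel index outside the grid")
  nframes <- dim(series$data)[4]
  # index frame-by-frame: avoids reshaping (and copying) the 4D array
  vals <- vapply(seq_len(nframes), function(f)
    mean(series$data[(f - 1) * nvox + voxels]), numeric(1))
  tac_from_schedule(series$schedule, vals, source = source)
}

#' Arterial input TAC from the LV blood pool
#'
#' Samples the LV cavity after eroding the mask by `erosion_mm` to limit
#' myocardial spill-in.
#'
#' @param series an `mbf_series`.
#' @param masks `mbf_masks` in the series' grid/world frame.
#' @param erosion_mm erosion radius, mm (0 = whole LV mask).
#' @return An `mbf_tac` with source `"arterial"`.
#' @export
arterial_input_tac <- function(series, masks, erosion_mm = 4) {
  if (!is_masks(masks)) stop("expected `mbf_masks`")
  lv <- if (erosion_mm > 0) erode_mask(masks$lv, erosion_mm) else masks$lv
  vox <- which(lv$data > 0)
  if (length(vox) == 0L)
    stop("erosion by ", erosion_mm, " mm empties the LV mask; try a smaller erosion")
  extract_tac(series, vox, source = "arterial")
}

#' Export a ROI set as CSV and a labelled volume
#'
#' @param roiset an `mbf_roiset`.
#' @param csv_path CSV output (`index, position_mm, center_x/y/z_mm, n_voxels`).
#' @param ref_volume reference `mbf_volume` for geometry when writing labels.
#' @param label_path optional NIfTI output with per-ROI integer labels.
#' @export
write_roiset <- function(roiset, csv_path, ref_volume = NULL, label_path = NULL) {
  df <- do.call(rbind, lapply(roiset$rois, function(r)
    data.frame(index = r$index, position_mm = r$position,
               center_x_mm = r$center[1], center_y_mm = r$center[2],
               center_z_mm = r$center[3], n_voxels = r$n)))
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(label_path)) {
    if (is.null(ref_volume)) stop("`ref_volume` needed to write the label volume")
    lab <- array(0, dim(ref_volume$data))
    for (r in roiset$rois) lab[r$voxels] <- r$index
    write_volume(volume(lab, ref_volume$voxel_size, ref_volume$origin,
                        ref_volume$direction), label_path)
  }
  invisible(csv_path)
}
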