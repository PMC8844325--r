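# PET/CT fusion: LV-driven rigid initialization (centroid + principal axes,
# refined on mask overlap) followed by mutual-information refinement against
# a labelled rendering of the biventricular anatomy. All optimizers are
# deterministic (Nelder-Mead with fixed starts and iteration caps).

#' Segment the LV blood pool from a summed PET image
#'
#' Thresholds at `threshold_fraction` of the image maximum, keeps the
#' largest 6-connected component (ties broken toward the component with the
#' lowest voxel index) and fills interior holes. On ammonia PET_sum images
#' the hot LV cavity plus myocardium dominates, so the default half-maximum
#' threshold isolates the left heart.
#'
#' @param pet a PET_sum `mbf_volume` with positive maximum.
#' @param threshold_fraction fraction of the maximum in [0, 1].
#' @return A binary `mbf_volume`.
#' @export
segment_lv_from_pet <- function(pet, threshold_fraction = 0.5) {
  stopifnot_volume(pet)
  mx <- max(pet$data)
  if (mx <= 0) stop("PET image has no positive voxels")
  if (threshold_fraction < 0 || threshold_fraction > 1)
    stop("`threshold_fraction` must be in [0, 1]")
  m <- (pet$data > 0 & pet$data >= threshold_fraction * mx) + 0
  if (!any(m > 0))
    stop("empty segmentation at threshold ", threshold_fraction,
         "; try a lower threshold")
  v <- volume(m, pet$voxel_size, pet$origin, pet$direction)
  fill_holes(largest_component(v))
}

# nearest-neighbour rendering of `moving` (CT-space mask) on the grid of
# `fixed`, under ct->pet transform `tf`; fixed_xyz caches the fixed grid's
# world coordinates
render_mask <- function(moving, fixed, tf, fixed_xyz = NULL) {
  if (is.null(fixed_xyz)) fixed_xyz <- all_voxel_world(fixed)
  src <- transform_points(invert_transform(tf), fixed_xyz)
  idx <- round(world_to_voxel(moving, src))
  d <- dim(moving$data)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- numeric(nrow(idx))
  lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
  out[ok] <- moving$data[lin]
  out
}

mask_dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(a & b) / s
}

# optimization parameterization: rotation about a fixed centre `c` plus a
# translation, T(x) = R (x - c) + c + t. Decouples angles from translation
# (about the world origin a degree of rotation also drags the heart by
# ~2 mm per 100 mm of lever arm, which cripples simplex search).
centered_transform <- function(p, centre) {
  tf <- rigid_transform(p[1:3], c(0, 0, 0))
  R <- rotation_matrix(tf)
  rigid_transform(p[1:3], centre - drop(R %*% centre) + p[4:6])
}

# inverse of the above: parameters of an arbitrary transform about `centre`
centered_params <- function(tf, centre) {
  R <- rotation_matrix(tf)
  c(tf$angles_deg,
    tf$translation_mm - centre + drop(R %*% centre))
}

#' Rigid LV-to-LV registration
#'
#' Estimates the CT-to-PET rigid transform from the two LV blood-pool
#' masks: centroid alignment plus principal-axes candidates (the four
#' proper sign combinations) initialize a Nelder-Mead refinement that
#' maximizes mask overlap (Dice) at ~4 mm resolution.
#'
#' @param lv_pet binary `mbf_volume`, LV segmented from PET_sum.
#' @param lv_ct binary `mbf_volume`, LV from the CT anatomy.
#' @param coarse_mm working resolution for the overlap metric, mm.
#' @return An `mbf_rigid_transform` (CT world to PET world).
#' @export
register_rigid_lv <- function(lv_pet, lv_ct, coarse_mm = 4) {
  for (m in list(lv_pet, lv_ct)) {
    stopifnot_volume(m)
    if (sum(m$data) <= 3) stop("degenerate mask (<= 3 voxels)")
  }
  fpet <- pmax(1L, round(coarse_mm / lv_pet$voxel_size))
  fct <- pmax(1L, round(coarse_mm / lv_ct$voxel_size))
  pet_c <- resample(lv_pet, fpet, mask = TRUE)
  ct_c <- resample(lv_ct, fct, mask = TRUE)
  # evaluate the overlap metric only inside the fixed mask's neighbourhood
  d <- dim(pet_c$data)
  pos <- arrayInd(which(pet_c$data > 0), d)
  marg <- ceiling(25 / pet_c$voxel_size)
  sel <- array(FALSE, d)
  sel[max(1, min(pos[, 1]) - marg[1]):min(d[1], max(pos[, 1]) + marg[1]),
      max(1, min(pos[, 2]) - marg[2]):min(d[2], max(pos[, 2]) + marg[2]),
      max(1, min(pos[, 3]) - marg[3]):min(d[3], max(pos[, 3]) + marg[3])] <- TRUE
  sel_lin <- which(sel)
  fixed_xyz <- voxel_to_world(pet_c, arrayInd(sel_lin, d))
  fixed_dat <- pet_c$data[sel_lin] > 0

  stats_of <- function(vol) {
    lin <- which(vol$data > 0)
    xyz <- voxel_to_world(vol, arrayInd(lin, dim(vol$data)))
    ctr <- colMeans(xyz)
    list(ctr = ctr, eig = eigen(stats::cov(xyz), symmetric = TRUE)$vectors)
  }
  sp <- stats_of(pet_c)
  sc <- stats_of(ct_c)

  cands <- list(rigid_transform(c(0, 0, 0), sp$ctr - sc$ctr))
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))      # keeps det(R) = +1
    R <- sp$eig %*% S %*% t(sc$eig)
    if (det(R) < 0) R <- sp$eig %*% (S * -1) %*% t(sc$eig)
    tf <- transform_from_matrix(R, sp$ctr - drop(R %*% sc$ctr))
    cands[[length(cands) + 1L]] <- tf
  }
  score <- function(tf) mask_dice(fixed_dat, render_mask(ct_c, pet_c, tf, fixed_xyz) > 0)
  best <- cands[[which.max(vapply(cands, score, numeric(1)))]]

  par0 <- centered_params(best, sc$ctr)
  obj <- function(p) -score(centered_transform(p, sc$ctr))
  # parscale sets the initial simplex step (~0.4 deg / 0.4 mm): without it
  # Nelder-Mead starting near zero angles cannot traverse 10-15 deg offsets
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-9,
                                     parscale = rep(4, 6)))
  centered_transform(opt$par, sc$ctr)
}

# labelled rendering of the anatomy: 0 background, 1 myocardium, 2 LV, 3 RV
label_volume <- function(masks) {
  lab <- array(0L, dim(masks$epi$data))
  lab[masks$epi$data > 0] <- 1L
  lab[masks$lv$data > 0] <- 2L
  lab[masks$rv$data > 0] <- 3L
  volume(lab, masks$epi$voxel_size, masks$epi$origin, masks$epi$direction)
}

# trilinear sampling of vol at world points (0 outside the grid)
sample_trilinear <- function(vol, pts) {
  idx <- world_to_voxel(vol, pts)
  d <- dim(vol$data)
  out <- numeric(nrow(idx))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  lo <- pmin(pmax(floor(p), 1), matrix(rep(d - 1L, each = nrow(p)), ncol = 3))
  f <- p - lo
  dat <- vol$data
  g <- function(dx, dy, dz)
    dat[cbind(lo[, 1] + dx, lo[, 2] + dy, lo[, 3] + dz)]
  val <-
    g(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    g(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    g(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    g(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    g(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    g(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    g(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    g(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- val
  out
}

# mutual information between binned PET intensities and anatomy labels
mi_metric <- function(pet_samples, labels, nbins = 32L, pet_max = NULL) {
  if (is.null(pet_max)) pet_max <- max(pet_samples)
  bins <- pmin(pmax(as.integer(pet_samples / (pet_max + 1e-12) * nbins), 0L),
               nbins - 1L)
  cnt <- tabulate(bins * 4L + labels + 1L, nbins * 4L)
  p <- matrix(cnt / sum(cnt), nrow = 4L)   # labels x bins
  px <- .rowSums(p, 4L, nbins)
  py <- .colSums(p, 4L, nbins)
  nz <- which(p > 0)
  sum(p[nz] * log(p[nz] / (px[(nz - 1L) %% 4L + 1L] * py[(nz - 1L) %/% 4L + 1L])))
}

#' Mutual-information refinement of a rigid transform
#'
#' Starting from `init`, maximizes the 32-bin joint-histogram mutual
#' information between the PET_sum intensities and a labelled rendering of
#' the biventricular anatomy (distinct labels for LV, RV and myocardium),
#' over a two-level multi-resolution schedule. Never returns a transform
#' whose metric is below the metric at `init`.
#'
#' @param pet PET_sum `mbf_volume`.
#' @param masks CT-space `mbf_masks`.
#' @param init starting `mbf_rigid_transform` (CT to PET).
#' @param levels resampling factors, coarse to fine.
#' @param maxit per-level Nelder-Mead iteration caps.
#' @return An `mbf_rigid_transform`.
#' @export
refine_mutual_information <- function(pet, masks, init, levels = c(2L, 1L),
                                      maxit = c(250L, 80L)) {
  stopifnot_volume(pet)
  if (!is_masks(masks)) stop("expected `mbf_masks`")
  if (!is_rigid_transform(init)) stop("expected `mbf_rigid_transform`")
  labv <- label_volume(masks)
  pet_max <- max(pet$data)
  tf <- init
  metric_at <- NULL
  anat_lin <- which(labv$data > 0)
  centre <- colMeans(voxel_to_world(labv, arrayInd(anat_lin, dim(labv$data))))
  for (li in seq_along(levels)) {
    f <- levels[li]
    first_level <- li == 1L
    # classic multi-resolution: coarsen BOTH images; the block-averaged PET
    # widens the capture range from a few degrees to the grid-search scale
    pet_l <- if (f > 1L) resample(pet, f, mask = FALSE) else pet
    lab_l <- if (f > 1L) resample_labels(labv, f) else labv
    # sample over the anatomy plus a background margin; at full resolution a
    # regular stride-2 lattice keeps the metric smooth at a fraction of the cost
    box <- in_heart_box(lab_l)
    if (f == 1L) {
      dd <- dim(box)
      stride <- array(FALSE, dd)
      stride[seq(1L, dd[1], 2L), seq(1L, dd[2], 2L), seq(1L, dd[3], 2L)] <- TRUE
      box <- box & stride
    }
    sel <- which(box)
    pts <- voxel_to_world(lab_l, arrayInd(sel, dim(lab_l$data)))
    labs <- lab_l$data[sel]
    metric <- function(p) {
      s <- sample_trilinear(pet_l, transform_points(centered_transform(p, centre), pts))
      mi_metric(s, labs, pet_max = pet_max)
    }
    par0 <- centered_params(tf, centre)
    if (first_level) {
      # deterministic basin search: the LV-stage init can be 10-20 deg off
      # (principal axes of the PET blob and the CT envelope differ) and the
      # MI peak is only a few degrees wide, so scan an angle grid first
      offs <- seq(-18, 18, by = 6)
      grid <- as.matrix(expand.grid(offs, offs, offs))
      vals <- apply(grid, 1L, function(o) metric(c(par0[1:3] + o, par0[4:6])))
      par0[1:3] <- par0[1:3] + grid[which.max(vals), ]
    }
    for (cycle in 1:2) {   # restarting refreshes a collapsed simplex
      opt <- stats::optim(par0, function(p) -metric(p), method = "Nelder-Mead",
                          control = list(maxit = maxit[li], reltol = 1e-10,
                                         parscale = rep(if (first_level) 4 else 1.5, 6)))
      par0 <- opt$par
    }
    if (!first_level) {
      # sequential 1D line-search polish: the simplex stalls a degree or two
      # from the peak; coordinate-wise searches close the gap deterministically
      for (sweep in 1:2) {
        for (j in 1:6) {
          f1 <- function(v) { p <- par0; p[j] <- v; -metric(p) }
          par0[j] <- stats::optimize(f1, c(par0[j] - 3, par0[j] + 3),
                                     tol = 0.02)$minimum
        }
      }
    }
    if (metric(par0) >= metric(centered_params(tf, centre)))
      tf <- centered_transform(par0, centre)
    metric_at <- metric
  }
  # contract: metric(final) >= metric(init), evaluated at the finest level
  if (metric_at(centered_params(tf, centre)) <
      metric_at(centered_params(init, centre)))
    return(init)
  tf
}

# majority label per block: resample each label indicator and argmax
resample_labels <- function(labv, f) {
  inds <- lapply(0:3, function(l)
    resample(volume((labv$data == l) + 0, labv$voxel_size, labv$origin,
                    labv$direction), f, mask = FALSE))
  stacked <- vapply(inds, function(v) as.numeric(v$data), numeric(length(inds[[1]]$data)))
  lab <- max.col(stacked, ties.method = "first") - 1L
  out <- inds[[1]]
  out$data <- array(as.integer(lab), dim(inds[[1]]$data))
  out
}

# bounding box of the anatomy plus an 8 mm margin (limits MI sampling)
in_heart_box <- function(lab_l) {
  d <- dim(lab_l$data)
  pos <- which(lab_l$data > 0)
  if (length(pos) == 0L) return(array(TRUE, d))
  ai <- arrayInd(pos, d)
  marg <- ceiling(8 / lab_l$voxel_size)
  lohi <- vapply(1:3, function(a)
    c(max(1L, min(ai[, a]) - marg[a]), min(d[a], max(ai[, a]) + marg[a])),
    numeric(2))
  box <- array(FALSE, d)
  box[lohi[1, 1]:lohi[2, 1], lohi[1, 2]:lohi[2, 2], lohi[1, 3]:lohi[2, 3]] <- TRUE
  box
}

#' One-call fusion: segment, register, refine
#'
#' Convenience wrapper reproducing the fusion chain: PET_sum left-heart
#' segmentation, rigid initialization on the segmented blob, then
#' (optionally) mutual-information refinement against the full
#' biventricular mask. On ammonia PET_sum images the half-maximum "LV"
#' segmentation captures the filled left-heart envelope (cavity plus
#' myocardium), so its CT counterpart for the overlap stage is the filled
#' epicardial envelope rather than the bare blood pool; the blood-pool and
#' RV labels then drive the MI stage.
#'
#' @param series dynamic `mbf_series` (PET side).
#' @param masks CT-side `mbf_masks`.
#' @param mi_refine run the MI refinement stage.
#' @param threshold_fraction PET LV segmentation threshold.
#' @return An `mbf_rigid_transform` (CT to PET).
#' @export
fuse_series <- function(series, masks, mi_refine = TRUE, threshold_fraction = 0.5) {
  psum <- pet_sum(series)
  lv_pet <- segment_lv_from_pet(psum, threshold_fraction)
  ct_blob <- fill_holes(masks$epi)
  tf <- register_rigid_lv(lv_pet, ct_blob)
  if (mi_refine) tf <- refine_mutual_information(psum, masks, tf)
  tf
}
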