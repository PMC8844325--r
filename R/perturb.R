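#' Segmentation-defect perturbation specification
#'
#' Describes the controlled defects applied to truth masks to emulate the
#' output of automated CCTA segmentation (FA masks) or of briefly corrected
#' automated segmentation (C masks): truncated apical coverage, RV
#' over-segmentation toward the liver, smooth boundary jitter, and merged
#' septal borders. An all-zero spec leaves masks bit-identical.
#'
#' @param apex_truncation_slices number of most-apical short-axis slices to
#'   remove from all masks (integer >= 0).
#' @param rv_dilation_mm outward RV dilation, mm >= 0.
#' @param boundary_jitter_mm SD of the smooth random boundary displacement
#'   field, mm >= 0.
#' @param septal_merge logical; morphologically close the epicardium to
#'   emulate merged septal epi/endo borders.
#' @param seed integer seed for the jitter field.
#' @return An object of class `mbf_perturbation_spec`.
#' @export
perturbation_spec <- function(apex_truncation_slices = 0L, rv_dilation_mm = 0,
                              boundary_jitter_mm = 0, septal_merge = FALSE,
                              seed = 1L) {
  if (apex_truncation_slices < 0 || rv_dilation_mm < 0 || boundary_jitter_mm < 0)
    stop("perturbation magnitudes must be >= 0")
  structure(list(apex_truncation_slices = as.integer(apex_truncation_slices),
                 rv_dilation_mm = rv_dilation_mm,
                 boundary_jitter_mm = boundary_jitter_mm,
                 septal_merge = isTRUE(septal_merge), seed = as.integer(seed)),
            class = "mbf_perturbation_spec")
}

is_zero_perturbation <- function(spec) {
  spec$apex_truncation_slices == 0L && spec$rv_dilation_mm == 0 &&
    spec$boundary_jitter_mm == 0 && !spec$septal_merge
}

#' Apply segmentation defects to anatomy masks
#'
#' Deterministic given the spec's seed. Apex truncation removes the stated
#' number of most-apical short-axis slices that contain epicardium; RV
#' dilation grows the RV blood pool outward (the epicardium follows so mask
#' invariants hold); boundary jitter displaces the EPI surface by a smooth
#' seeded random field; septal merge closes the epicardium by 4 mm. The
#' LAD/LCX/rPDA-facing geometry of the jitter field depends only on the
#' seed, not the amplitude, so nested specs produce nested defects.
#'
#' @param masks an `mbf_masks` (typically phantom truth).
#' @param spec an `mbf_perturbation_spec`.
#' @param provenance provenance tag for the perturbed masks (default "FA").
#' @return An `mbf_masks`.
#' @export
perturb_masks <- function(masks, spec, provenance = "FA") {
  if (!is_masks(masks)) stop("expected `mbf_masks`")
  if (!inherits(spec, "mbf_perturbation_spec"))
    stop("expected `mbf_perturbation_spec`")
  if (is_zero_perturbation(spec))
    return(anatomy_masks(masks$lv, masks$rv, masks$epi, provenance = masks$provenance))
  lv <- masks$lv$data
  rv <- masks$rv$data
  epi <- masks$epi$data
  geom <- masks$epi

  if (spec$boundary_jitter_mm > 0) {
    # smooth displacement field (amplitude-independent shape), applied to the
    # signed distance of the EPI surface
    eta <- jitter_field(dim(epi), spec$seed)
    sd_out <- distance_transform(volume(epi, geom$voxel_size, geom$origin, geom$direction))
    sd_in <- distance_transform(volume(1 - epi, geom$voxel_size, geom$origin, geom$direction))
    signed <- sd_in - sd_out            # > 0 inside EPI, < 0 outside
    epi <- (signed + spec$boundary_jitter_mm * eta > 0) + 0
    # blood pools stay where they are; keep them inside the jittered EPI
    epi <- ((epi > 0) | (lv > 0) | (rv > 0)) + 0
  }

  if (spec$rv_dilation_mm > 0) {
    # grow the RV outward only (beyond the original epicardium, toward the
    # liver); the septum and free wall are untouched
    rv_d <- dilate_mask(volume(rv, geom$voxel_size, geom$origin, geom$direction),
                        spec$rv_dilation_mm)$data
    rv <- (rv > 0 | (rv_d > 0 & masks$epi$data == 0)) + 0
    epi <- (epi > 0 | rv > 0) + 0
  }

  if (spec$septal_merge) {
    epi_v <- volume(epi, geom$voxel_size, geom$origin, geom$direction)
    epi <- erode_mask(dilate_mask(epi_v, 4), 4)$data
    epi <- (epi > 0 | lv > 0 | rv > 0) + 0
  }

  if (spec$apex_truncation_slices > 0L) {
    zs <- which(apply(epi, 3, sum) > 0)
    if (spec$apex_truncation_slices >= length(zs))
      stop("apex truncation (", spec$apex_truncation_slices,
           " slices) exceeds the myocardial extent (", length(zs), " slices)")
    drop_z <- zs[seq_len(spec$apex_truncation_slices)]  # apex at low z
    epi[, , drop_z] <- 0
    lv[, , drop_z] <- 0
    rv[, , drop_z] <- 0
  }

  anatomy_masks(volume(lv, geom$voxel_size, geom$origin, geom$direction),
                volume(rv, geom$voxel_size, geom$origin, geom$direction),
                volume(epi, geom$voxel_size, geom$origin, geom$direction),
                provenance = provenance)
}

# smooth unit-scale random field: low-resolution Gaussian noise, trilinearly
# upsampled, normalized to SD 1. Depends only on (dims, seed).
jitter_field <- function(dims, seed, coarse = 8L) {
  nc <- pmax(2L, ceiling(dims / coarse))
  g <- with_seed(seed, array(stats::rnorm(prod(nc)), nc))
  # trilinear upsample by separable linear interpolation along each axis
  up_axis <- function(arr, axis, n_out) {
    n_in <- dim(arr)[axis]
    pos <- seq(1, n_in, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 1L)
    f <- pos - lo
    idx_lo <- switch(axis,
                     arr[lo, , , drop = FALSE], arr[, lo, , drop = FALSE],
                     arr[, , lo, drop = FALSE])
    idx_hi <- switch(axis,
                     arr[lo + 1L, , , drop = FALSE], arr[, lo + 1L, , drop = FALSE],
                     arr[, , lo + 1L, drop = FALSE])
    dd <- dim(idx_lo)
    w <- switch(axis,
                array(rep(f, times = dd[2] * dd[3]), dd),
                array(rep(f, each = dd[1], times = dd[3]), dd),
                array(rep(f, each = dd[1] * dd[2]), dd))
    idx_lo * (1 - w) + idx_hi * w
  }
  out <- g
  for (a in 1:3) out <- up_axis(out, a, dims[a])
  out / stats::sd(out)
}
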