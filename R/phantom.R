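# Digital biventricular phantom. Stands in for patient CCTA anatomy and
# dynamic ammonia PET: a short-axis-aligned half-ellipsoidal LV with a
# crescent RV, a uniform-thickness myocardial shell built from exact
# distance transforms, a geodesic nearest-seed partition of the shell into
# LAD/LCX/rPDA territories, and per-territory rest/stress flow truth maps.

#' Phantom specification
#'
#' Geometry, kinetic truth and noise parameters of the digital heart. The
#' default grid is 96^3 voxels at 2 mm isotropic (the clinical pipeline's
#' 512^3 geometry scaled to desk size with preserved proportions). The long
#' axis runs along +z with the apex at low z; short-axis slices are xy
#' planes.
#'
#' @param grid_shape voxels per axis (length 1 or 3).
#' @param voxel_size mm, isotropic.
#' @param lv_radius LV endocardial short-axis radius, mm.
#' @param rv_radius RV cavity short-axis radius, mm.
#' @param wall_thickness LV myocardial wall thickness, mm.
#' @param apex_extent base-to-apex length of the LV cavity, mm.
#' @param territory_seeds optional 3 x 3 matrix of world-mm seed points for
#'   the LAD/LCX/rPDA territory partition (rows in that order); defaults to
#'   anterior / lateral / inferior epicardial points.
#' @param flow_rest,flow_stress named per-territory truth flow, mL/min/g.
#' @param k2,k3 tissue washout and trapping rate constants, 1/min, shared by
#'   all territories.
#' @param blood_fraction fractional blood volume v_b in myocardium, [0, 1).
#' @param noise_scale unitless >= 0; frame noise SD is
#'   `noise_scale * sqrt(activity / duration_s)`.
#' @param seed integer RNG seed for every stochastic phantom operation.
#' @return An object of class `mbf_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), voxel_size = 2,
                         lv_radius = 16, rv_radius = 14, wall_thickness = 10,
                         apex_extent = 70, territory_seeds = NULL,
                         flow_rest = c(LAD = 0.8, LCX = 0.8, rPDA = 0.8),
                         flow_stress = c(LAD = 2.4, LCX = 2.4, rPDA = 2.4),
                         k2 = 0.4, k3 = 0.1, blood_fraction = 0.3,
                         noise_scale = 1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (any(grid_shape < 8L)) stop("grid too small for a heart phantom")
  if (wall_thickness <= 0) stop("`wall_thickness` must be > 0")
  if (lv_radius <= 0 || rv_radius <= 0) stop("radii must be > 0")
  if (apex_extent <= 0) stop("`apex_extent` must be > 0")
  for (fl in list(flow_rest, flow_stress)) {
    if (!all(c("LAD", "LCX", "rPDA") %in% names(fl)) || any(fl <= 0))
      stop("flows must be positive and named LAD, LCX, rPDA")
  }
  if (blood_fraction < 0 || blood_fraction >= 1)
    stop("`blood_fraction` must be in [0, 1)")
  if (noise_scale < 0) stop("`noise_scale` must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 lv_radius = lv_radius, rv_radius = rv_radius,
                 wall_thickness = wall_thickness, apex_extent = apex_extent,
                 territory_seeds = territory_seeds,
                 flow_rest = flow_rest[c("LAD", "LCX", "rPDA")],
                 flow_stress = flow_stress[c("LAD", "LCX", "rPDA")],
                 k2 = k2, k3 = k3, blood_fraction = blood_fraction,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "mbf_phantom_spec")
}

TERRITORIES <- c("LAD", "LCX", "rPDA")

# run expr with a local, seeded RNG stream; the caller's RNG state survives
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the phantom anatomy and kinetic truth maps
#'
#' Builds LV/RV/EPI masks, the territory label map and per-state truth flow
#' volumes. The LV is a half-ellipsoid (cut at the base plane); the
#' epicardium is the exact `wall_thickness`-mm morphological dilation of the
#' blood pools (thinner over the RV free wall, as in real hearts); the
#' myocardium is partitioned into LAD/LCX/rPDA territories by geodesic
#' nearest-seed labelling within the shell.
#'
#' @param spec an `mbf_phantom_spec`.
#' @return A list of class `mbf_phantom_truth`: `masks` (`mbf_masks`,
#'   provenance `"M"`), `territory` (integer `mbf_volume`, 1 = LAD,
#'   2 = LCX, 3 = rPDA), `flow` (list with `rest`/`stress` flow volumes,
#'   mL/min/g), and the `spec`.
#' @export
generate_anatomy <- function(spec) {
  if (!inherits(spec, "mbf_phantom_spec")) stop("expected `mbf_phantom_spec`")
  d <- spec$grid_shape
  vs <- rep(spec$voxel_size, 3L)
  extent <- d * vs
  w <- spec$wall_thickness
  w_rv <- max(3, 0.4 * w)
  # sizing check: the dilated heart must fit with a one-voxel margin
  need <- c(2 * (spec$lv_radius + w) + 2 * spec$rv_radius + 2 * w_rv + 8,
            2 * (spec$lv_radius + w) + 4,
            spec$apex_extent + w + 4)
  if (any(need > extent - 2 * vs))
    stop("phantom geometry does not fit the grid: need >= ",
         paste(sprintf("%.0f", need), collapse = " x "), " mm, have ",
         paste(sprintf("%.0f", extent), collapse = " x "), " mm")

  ctr <- (d - 1) / 2 * vs                      # world centre of the grid
  # place the LV slightly toward -x so the RV crescent fits on +x
  cx <- ctr[1] - (spec$rv_radius + w_rv) / 2
  cy <- ctr[2]
  z_base <- ctr[3] + spec$apex_extent / 2
  ax <- seq_len(d[1]) - 1
  x <- ax * vs[1]
  y <- (seq_len(d[2]) - 1) * vs[2]
  z <- (seq_len(d[3]) - 1) * vs[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)

  a <- spec$lv_radius
  clen <- spec$apex_extent
  lv_arr <- (((X - cx)^2 + (Y - cy)^2) / a^2 + ((Z - z_base) / clen)^2 <= 1) &
    (Z <= z_base + 1e-9)
  lv <- volume(lv_arr + 0, vs)

  dist_lv <- distance_transform(lv)
  epi_lv <- dist_lv <= w + 1e-9

  rvx <- cx + a + w + spec$rv_radius * 0.4
  rv_a <- spec$rv_radius
  rv_b <- spec$rv_radius * 1.4
  rv_c <- 0.75 * clen
  rv_arr <- (((X - rvx)^2 / rv_a^2 + (Y - cy)^2 / rv_b^2 +
                ((Z - z_base) / rv_c)^2) <= 1) &
    (Z <= z_base + 1e-9) & !epi_lv
  rv <- volume(rv_arr + 0, vs)
  if (!any(rv_arr)) stop("phantom geometry degenerate: empty RV cavity")

  dist_rv <- distance_transform(rv)
  epi_arr <- (epi_lv | dist_rv <= w_rv + 1e-9) & (Z <= z_base + 1e-9)
  epi <- volume(epi_arr + 0, vs)

  masks <- anatomy_masks(lv, rv, epi, provenance = "M")
  myo <- myocardium_mask(masks)

  seeds <- spec$territory_seeds
  if (is.null(seeds)) {
    zm <- z_base - clen / 3                    # mid-ventricular level
    r_epi <- a + w
    seeds <- rbind(
      LAD  = c(cx, cy + r_epi, zm),            # anterior wall
      LCX  = c(cx - r_epi, cy, zm),            # lateral wall (away from RV)
      rPDA = c(cx, cy - r_epi, zm))            # inferior wall
  }
  # snap each seed to the nearest myocardial voxel
  myo_lin <- which(myo$data > 0)
  myo_xyz <- voxel_to_world(myo, arrayInd(myo_lin, d))
  seed_lin <- vapply(1:3, function(i) {
    myo_lin[which.min(colSums((t(myo_xyz) - seeds[i, ])^2))]
  }, integer(1))
  terr <- geodesic_labels(myo, seed_lin, 1:3)
  territory <- volume(terr, vs)

  flow <- lapply(list(rest = spec$flow_rest, stress = spec$flow_stress),
                 function(fl) {
                   fv <- array(0, d)
                   for (i in 1:3) fv[terr == i] <- fl[[TERRITORIES[i]]]
                   volume(fv, vs)
                 })

  structure(list(masks = masks, territory = territory, flow = flow,
                 spec = spec, z_base = z_base),
            class = "mbf_phantom_truth")
}

#' @export
print.mbf_phantom_truth <- function(x, ...) {
  cat("<mbf_phantom_truth>\n")
  print(x$masks)
  invisible(x)
}

#' Generate a vessel centerline on the phantom epicardium
#'
#' Traces an ordered base-to-apex path over the epicardial surface of one
#' vascular territory: at each of `n_points` long-axis levels the outer
#' epicardial voxel of the territory closest to the territory's mean
#' circumferential angle is selected, and the resulting polyline is lightly
#' smoothed.
#'
#' @param truth an `mbf_phantom_truth` from [generate_anatomy()].
#' @param vessel `"LAD"`, `"LCX"` or `"rPDA"`.
#' @param n_points number of sampling levels base to apex.
#' @return An `mbf_centerline`.
#' @export
generate_centerline <- function(truth, vessel = c("LAD", "LCX", "rPDA"),
                                n_points = 40L) {
  vessel <- match.arg(vessel)
  lab <- match(vessel, TERRITORIES)
  terr <- truth$territory$data
  if (!any(terr == lab)) stop("territory label absent from truth map: ", vessel)
  myo <- myocardium_mask(truth$masks)
  epi <- truth$masks$epi
  # outer epicardial surface: EPI voxels adjacent to outside
  out_dist <- distance_transform(volume(1 - epi$data, epi$voxel_size,
                                        epi$origin, epi$direction))
  surf <- terr == lab & out_dist <= max(epi$voxel_size) + 1e-9
  if (!any(surf)) stop("no epicardial surface voxels in territory ", vessel)
  lin <- which(surf)
  xyz <- voxel_to_world(epi, arrayInd(lin, dim(terr)))
  # circumferential angle about the LV long axis
  cxy <- c(mean(xyz[, 1]), mean(xyz[, 2]))
  ang <- atan2(xyz[, 2] - cxy[2], xyz[, 1] - cxy[1])
  mean_ang <- atan2(mean(sin(ang)), mean(cos(ang)))
  dang <- abs(atan2(sin(ang - mean_ang), cos(ang - mean_ang)))
  zs <- xyz[, 3]
  levels <- seq(max(zs), min(zs), length.out = n_points)
  slab <- max(epi$voxel_size)
  pts <- matrix(NA_real_, 0L, 3L)
  for (lv in levels) {
    sel <- which(abs(zs - lv) <= slab)
    if (length(sel) == 0L) next
    pick <- sel[which.min(dang[sel])]
    p <- xyz[pick, ]
    p[3] <- lv
    if (nrow(pts) == 0L || sqrt(sum((p - pts[nrow(pts), ])^2)) > 0.5)
      pts <- rbind(pts, p)
  }
  if (nrow(pts) < 2L) stop("could not trace a centerline for ", vessel)
  if (nrow(pts) >= 3L) {          # light smoothing, endpoints pinned
    sm <- pts
    for (i in 2:(nrow(pts) - 1L))
      sm[i, ] <- (pts[i - 1L, ] + pts[i, ] + pts[i + 1L, ]) / 3
    pts <- sm
  }
  keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-6)
  centerline(pts[keep, , drop = FALSE], vessel)
}

#' Insert a flow-limiting lesion along a vessel
#'
#' Scales the truth flow of the myocardial voxels whose nearest centerline
#' point lies in the arc interval `[from_mm, to_mm]` (restricted to the
#' vessel's territory), emulating a stenosis that reduces hyperemic flow
#' over a stretch of the vessel.
#'
#' @param truth an `mbf_phantom_truth`.
#' @param cl the vessel's `mbf_centerline`.
#' @param from_mm,to_mm arc interval from the base, mm.
#' @param factor multiplicative flow reduction in (0, 1].
#' @param state `"stress"` (default), `"rest"`, or `"both"`.
#' @return The modified `mbf_phantom_truth`.
#' @export
apply_lesion <- function(truth, cl, from_mm, to_mm, factor = 0.5,
                         state = "stress") {
  if (!is_centerline(cl)) stop("expected `mbf_centerline`")
  if (factor <= 0 || factor > 1) stop("`factor` must be in (0, 1]")
  if (to_mm <= from_mm) stop("`to_mm` must exceed `from_mm`")
  lab <- match(cl$vessel, TERRITORIES)
  terr <- truth$territory$data
  lin <- which(terr == lab)
  if (length(lin) == 0L) stop("vessel territory empty: ", cl$vessel)
  xyz <- voxel_to_world(truth$territory, arrayInd(lin, dim(terr)))
  # arc position of the nearest centerline vertex for every territory voxel
  np <- nrow(cl$points)
  nearest_arc <- numeric(length(lin))
  best <- rep(Inf, length(lin))
  for (i in seq_len(np)) {
    d2 <- (xyz[, 1] - cl$points[i, 1])^2 + (xyz[, 2] - cl$points[i, 2])^2 +
      (xyz[, 3] - cl$points[i, 3])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    nearest_arc[upd] <- cl$arc[i]
  }
  hit <- lin[nearest_arc >= from_mm & nearest_arc <= to_mm]
  states <- if (state == "both") c("rest", "stress") else state
  for (st in states) {
    fv <- truth$flow[[st]]$data
    fv[hit] <- fv[hit] * factor
    truth$flow[[st]] <- volume(fv, truth$flow[[st]]$voxel_size,
                               truth$flow[[st]]$origin,
                               truth$flow[[st]]$direction)
  }
  truth
}
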