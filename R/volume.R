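#' 3D image volume
#'
#' A scalar 3D image on a regular grid with world geometry: per-axis voxel
#' size in mm, world coordinates of the first voxel centre, and a direction
#' matrix restricted to right-handed signed axis permutations (oblique grids
#' are out of scope). World coordinates of voxel index `(i, j, k)` (1-based)
#' are `origin + direction %*% (voxel_size * (c(i, j, k) - 1))`.
#'
#' @param data numeric 3D array of voxel values.
#' @param voxel_size numeric length-3, mm per voxel along each array axis.
#' @param origin numeric length-3, world mm of the centre of voxel (1,1,1).
#' @param direction 3x3 signed permutation matrix mapping voxel axes to world
#'   axes; defaults to identity.
#' @return An object of class `mbf_volume`.
#' @export
volume <- function(data, voxel_size, origin = c(0, 0, 0), direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  direction <- check_direction(direction)
  structure(
    list(data = data, voxel_size = voxel_size, origin = origin,
         direction = direction),
    class = "mbf_volume")
}

# signed permutation with det +1 or -1; volume invariant requires right-handed
check_direction <- function(direction, require_right_handed = TRUE) {
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)))
    stop("`direction` must be a 3x3 matrix")
  ok <- all(colSums(abs(direction) > 1e-9) == 1L) &&
    all(rowSums(abs(direction) > 1e-9) == 1L) &&
    all(abs(abs(direction[abs(direction) > 1e-9]) - 1) < 1e-9)
  if (!ok) stop("`direction` must be a signed axis permutation (oblique grids unsupported)")
  direction <- round(direction)
  if (require_right_handed && det(direction) < 0)
    stop("`direction` must be right-handed (det = +1)")
  direction
}

#' @export
print.mbf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mbf_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f; range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "mbf_volume")

stopifnot_volume <- function(x) {
  if (!is_volume(x)) stop("expected an `mbf_volume`")
  invisible(x)
}

#' World coordinates of voxel indices
#'
#' @param vol an `mbf_volume`.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm.
#' @export
voxel_to_world <- function(vol, idx) {
  stopifnot_volume(vol)
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(t(vol$direction %*% (t(idx - 1) * vol$voxel_size)), 2L, vol$origin, "+")
}

#' Voxel indices (1-based, fractional) of world coordinates
#'
#' @param vol an `mbf_volume`.
#' @param xyz n x 3 matrix of world mm.
#' @return n x 3 matrix of fractional 1-based indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  stopifnot_volume(vol)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  rel <- t(t(vol$direction) %*% t(sweep(xyz, 2L, vol$origin, "-")))
  sweep(rel, 2L, vol$voxel_size, "/") + 1
}

# world coordinates of every voxel centre, as an n x 3 matrix in linear
# (column-major) voxel order
all_voxel_world <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2]))
  voxel_to_world(vol, idx)
}

is_binary_data <- function(data) all(data == 0 | data == 1)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    all(a$direction == b$direction)
}

#' Reorient a volume by a signed axis permutation
#'
#' Rearranges the voxel array (e.g. transaxial to short-axis ordering) while
#' updating the geometry tags so that the world coordinates of every voxel
#' are unchanged. `axis_mapping[a] = s * b` means new array axis `a` runs
#' along old axis `b`, reversed when `s` is -1.
#'
#' @param vol an `mbf_volume`.
#' @param axis_mapping signed integer permutation of 1:3, e.g. `c(3, 1, -2)`.
#' @return The reoriented `mbf_volume`.
#' @export
reorient_short_axis <- function(vol, axis_mapping) {
  stopifnot_volume(vol)
  axis_mapping <- as.integer(axis_mapping)
  if (length(axis_mapping) != 3L || !setequal(abs(axis_mapping), 1:3))
    stop("`axis_mapping` must be a signed permutation of 1:3")
  perm <- abs(axis_mapping)
  flip <- axis_mapping < 0L
  dat <- aperm(vol$data, perm)
  for (a in which(flip)) {
    idx <- rev(seq_len(dim(dat)[a]))
    dat <- switch(a, dat[idx, , , drop = FALSE], dat[, idx, , drop = FALSE],
                  dat[, , idx, drop = FALSE])
  }
  # new direction column a = +-(old column perm[a]); origin = world coords of
  # the old voxel that lands at new index (1,1,1)
  newdir <- vol$direction[, perm, drop = FALSE]
  newdir[, flip] <- -newdir[, flip, drop = FALSE]
  d_old <- dim(vol$data)
  corner_old <- ifelse(flip, d_old[perm], 1L)
  old_idx <- integer(3L)
  old_idx[perm] <- corner_old
  origin <- drop(voxel_to_world(vol, matrix(old_idx, 1L)))
  volume(dat, vol$voxel_size[perm], origin, check_direction(newdir))
}

#' Downsample a volume by integer factors
#'
#' Intensity volumes are block-averaged; binary masks are majority-voted
#' (ties counted as foreground). Voxel size scales by the factor and the
#' origin moves to the centre of the first block so world extent is preserved
#' within one coarse voxel.
#'
#' @param vol an `mbf_volume`.
#' @param factor integer factor per axis (scalar recycled).
#' @param mask logical; majority-vote instead of averaging.
#' @return The resampled `mbf_volume`.
#' @export
resample <- function(vol, factor, mask = is_binary_data(vol$data)) {
  stopifnot_volume(vol)
  factor <- as.integer(round(factor))
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (any(factor < 1L)) stop("`factor` must be >= 1")
  d <- dim(vol$data)
  if (any(factor > d)) stop("resampling factor exceeds grid extent")
  if (all(factor == 1L)) return(vol)
  nd <- ceiling(d / factor)
  grp <- lapply(1:3, function(a) (seq_len(d[a]) - 1L) %/% factor[a] + 1L)
  # block mean in one pass: map every voxel to its coarse-block linear index
  gl <- (rep(grp[[1]] - 1L, times = d[2] * d[3]) +
           nd[1] * rep(rep(grp[[2]] - 1L, each = d[1]), times = d[3]) +
           nd[1] * nd[2] * rep(grp[[3]] - 1L, each = d[1] * d[2])) + 1L
  sums <- rowsum(as.vector(vol$data), gl, reorder = TRUE)
  cnts <- tabulate(gl, prod(nd))
  x <- as.vector(sums) / cnts
  if (mask) x <- (x >= 0.5) + 0
  dim(x) <- nd
  origin <- vol$origin + drop(vol$direction %*% (vol$voxel_size * (factor - 1) / 2))
  volume(x, vol$voxel_size * factor, origin, vol$direction)
}
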