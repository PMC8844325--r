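# Shared fixtures, built once per test run and memoised in this environment.
# Everything is generated in code under fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_truth <- function() memo("truth", generate_anatomy(phantom_spec()))

# small, fast phantom for geometry-heavy tests (overridable defaults)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(64, 64, 64), voxel_size = 2.5, lv_radius = 14,
         rv_radius = 12, wall_thickness = 9, apex_extent = 60),
    list(...))
  do.call(phantom_spec, args)
}
small_truth <- function() memo("small_truth", generate_anatomy(small_spec()))

default_series <- function(state = "stress", noise_scale = NULL) {
  memo(paste0("series_", state, "_", noise_scale %||% "spec"),
       simulate_dynamic_pet(default_truth(), state = state,
                            noise_scale = noise_scale))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a fixed seed without clobbering the session RNG
with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# asymmetric test volume with distinct values, handy for orientation checks
asym_volume <- function(d = c(3, 4, 5)) {
  volume(array(seq_len(prod(d)), d), voxel_size = c(1, 2, 3),
         origin = c(10, -5, 2))
}

# brute-force nearest-distance oracle (independent of the C++ EDT)
brute_min_dist <- function(from_xyz, to_xyz) {
  vapply(seq_len(nrow(from_xyz)), function(i) {
    sqrt(min(colSums((t(to_xyz) - from_xyz[i, ])^2)))
  }, numeric(1))
}

rotation_angle_between_t <- function(a, b) mbfvs:::rotation_angle_between(a, b)

# transform with rotation about an explicit centre (mirrors the registration
# parameterization)
make_centered <- function(angles, trans, centre) {
  mbfvs:::centered_transform(c(angles, trans), centre)
}

# resample a volume under a rigid transform: out(x) = vol(Tinv x)
resample_by_transform <- function(vol, tf, mask = TRUE) {
  xyz <- mbfvs:::all_voxel_world(vol)
  src <- transform_points(invert_transform(tf), xyz)
  vals <- mbfvs:::sample_trilinear(vol, src)
  if (mask) vals <- (vals >= 0.5) + 0
  volume(array(vals, dim(vol$data)), vol$voxel_size, vol$origin, vol$direction)
}

# acceptance-shared normal ranges: built once from the stated low-risk world
shared_ranges <- function() {
  memo("ranges", {
    cfg <- experiment_config(n_lowrisk = 15L, seed = 20L)
    build_lowrisk_ranges(cfg)
  })
}
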