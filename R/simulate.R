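#' Simulate a dynamic PET series from phantom truth
#'
#' Voxel kinetics follow the two-tissue irreversible compartment model:
#' myocardial voxels carry `(1 - v_b) (C1 + C2) + v_b Ca` with `K1` equal to
#' the voxel's truth flow, blood-pool voxels carry `Ca`, voxels outside the
#' epicardium are zero. Every frame stores the duration-average of the
#' continuous model curve; optional zero-mean Gaussian noise with
#' `SD = noise_scale * sqrt(activity / duration)` (a scaled-Poisson
#' surrogate) is added per voxel and frame under the given seed.
#'
#' @param truth an `mbf_phantom_truth` from [generate_anatomy()].
#' @param input_fn an `mbf_input_function` (arterial input driving all
#'   voxels).
#' @param schedule an `mbf_schedule`.
#' @param state `"rest"` or `"stress"` — selects the truth flow volume.
#' @param noise_scale overrides the spec's noise scale when given.
#' @param seed overrides the spec's seed when given.
#' @param dt_s fine time step for the model solution, s.
#' @return An `mbf_series`.
#' @export
simulate_dynamic_pet <- function(truth, input_fn = input_function_params(),
                                 schedule = make_schedule("SNUH"),
                                 state = c("rest", "stress"),
                                 noise_scale = NULL, seed = NULL, dt_s = 0.5) {
  if (!inherits(truth, "mbf_phantom_truth")) stop("expected `mbf_phantom_truth`")
  state <- match.arg(state)
  stopifnot_schedule(schedule)
  flow_vol <- truth$flow[[state]]
  if (is.null(flow_vol)) stop("missing truth flow volume for state ", state)
  spec <- truth$spec
  if (is.null(noise_scale)) noise_scale <- spec$noise_scale
  if (is.null(seed)) seed <- spec$seed

  tt <- fine_times(schedule, dt_s)
  ca_fine <- eval_input_function(input_fn, tt)
  ca_frames <- frame_average_fine(ca_fine, dt_s, schedule)

  d <- dim(flow_vol$data)
  myo <- myocardium_mask(truth$masks)$data > 0
  blood <- (truth$masks$lv$data > 0) | (truth$masks$rv$data > 0)
  flows <- flow_vol$data[myo]
  uflow <- sort(unique(flows))
  nframes <- nrow(schedule)

  frames <- array(0, c(d, nframes))
  blood_lin <- which(blood)
  myo_lin <- which(myo)
  flow_grp <- match(flows, uflow)
  # one kinetic solve per distinct flow level, shared across its voxels
  tac_by_flow <- vapply(uflow, function(K1) {
    ct <- two_tissue_fine(K1, spec$k2, spec$k3, spec$blood_fraction,
                          ca_fine, dt_s)
    frame_average_fine(ct, dt_s, schedule)
  }, numeric(nframes))
  base <- prod(d)
  for (f in seq_len(nframes)) {
    off <- (f - 1) * base
    frames[off + blood_lin] <- ca_frames[f]
    frames[off + myo_lin] <- tac_by_flow[f, flow_grp]
  }
  if (noise_scale > 0) {
    durs <- schedule$duration
    with_seed(seed, {
      for (f in seq_len(nframes)) {
        off <- (f - 1) * base
        idx <- c(blood_lin, myo_lin)
        mu <- frames[off + idx]
        sd <- noise_scale * sqrt(pmax(mu, 0) / durs[f])
        frames[off + idx] <- mu + stats::rnorm(length(idx), 0, sd)
      }
    })
  }
  dynamic_series(frames, schedule, flow_vol$voxel_size, flow_vol$origin,
                 flow_vol$direction, state = state)
}

# fine model grid covering the acquisition, starting at 0
fine_times <- function(schedule, dt_s) {
  total <- schedule_total(schedule)
  seq(0, total, by = dt_s)
}

# duration-average of a fine-grid curve over each frame (trapezoid rule;
# frame boundaries snap to the nearest fine-grid sample)
frame_average_fine <- function(values, dt_s, schedule) {
  vapply(seq_len(nrow(schedule)), function(f) {
    i0 <- round(schedule$start[f] / dt_s) + 1L
    i1 <- round((schedule$start[f] + schedule$duration[f]) / dt_s) + 1L
    i1 <- min(i1, length(values))
    v <- values[i0:i1]
    (sum(v) - (v[1] + v[length(v)]) / 2) / (i1 - i0)
  }, numeric(1))
}
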