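#' Dynamic-frame schedules
#'
#' Build a frame schedule either from a named clinical binning preset or from
#' an explicit list of (start, duration) pairs. Presets reproduce the list-mode
#' binning schemes used for 13N-ammonia cardiac studies: `"SNUH"` is
#' 12 x 10 s, 6 x 30 s, 2 x 60 s, 1 x 180 s (21 frames, 600 s total);
#' `"SMC_CNUH"` is 12 x 5 s, 6 x 10 s, 3 x 20 s, 6 x 30 s (27 frames, 360 s).
#' Frames must be contiguous and non-overlapping, starting at 0 s.
#'
#' @param preset `"SNUH"` or `"SMC_CNUH"`, or `NULL` when `frames` is given.
#' @param frames optional 2-column matrix or data.frame (start_s, duration_s).
#' @return A data.frame of class `mbf_schedule` with columns `start`,
#'   `duration`, `mid` (seconds).
#' @export
make_schedule <- function(preset = NULL, frames = NULL) {
  if (!is.null(preset)) {
    preset_tab <- list(
      SNUH = c(rep(10, 12), rep(30, 6), rep(60, 2), rep(180, 1)),
      SMC_CNUH = c(rep(5, 12), rep(10, 6), rep(20, 3), rep(30, 6)))
    durs <- preset_tab[[preset]]
    if (is.null(durs)) stop("unknown schedule preset: ", preset)
    starts <- cumsum(c(0, durs[-length(durs)]))
    frames <- cbind(starts, durs)
  }
  if (is.null(frames)) stop("give either `preset` or `frames`")
  frames <- as.matrix(frames)
  if (ncol(frames) != 2L) stop("`frames` needs columns (start_s, duration_s)")
  start <- as.numeric(frames[, 1])
  duration <- as.numeric(frames[, 2])
  if (any(duration <= 0)) stop("frame durations must be > 0")
  if (abs(start[1]) > 1e-9) stop("schedule must start at 0 s")
  if (length(start) > 1L) {
    gap <- start[-1] - (start[-length(start)] + duration[-length(duration)])
    if (any(abs(gap) > 1e-9))
      stop("frames must be contiguous and non-overlapping")
  }
  structure(
    data.frame(start = start, duration = duration, mid = start + duration / 2),
    class = c("mbf_schedule", "data.frame"))
}

#' Total acquisition time of a schedule
#' @param schedule an `mbf_schedule`.
#' @return End time of the last frame, seconds.
#' @export
schedule_total <- function(schedule) {
  n <- nrow(schedule)
  schedule$start[n] + schedule$duration[n]
}

stopifnot_schedule <- function(x) {
  if (!inherits(x, "mbf_schedule")) stop("expected an `mbf_schedule`")
  invisible(x)
}

#' Dynamic PET series
#'
#' A 4D activity dataset: one 3D frame per schedule entry, all frames sharing
#' one grid geometry.
#'
#' @param data numeric 4D array (x, y, z, frame), kBq/mL.
#' @param schedule an `mbf_schedule`; its length must equal `dim(data)[4]`.
#' @param voxel_size,origin,direction grid geometry, as in [volume()].
#' @param state `"rest"` or `"stress"`.
#' @return An object of class `mbf_series`.
#' @export
dynamic_series <- function(data, schedule, voxel_size, origin = c(0, 0, 0),
                           direction = diag(3), state = c("rest", "stress")) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, frame)")
  stopifnot_schedule(schedule)
  if (dim(data)[4] != nrow(schedule))
    stop("frame count (", dim(data)[4], ") != schedule length (",
         nrow(schedule), ")")
  state <- match.arg(state)
  geom <- volume(array(0, dim(data)[1:3]), voxel_size, origin, direction)
  structure(
    list(data = data, schedule = schedule, voxel_size = geom$voxel_size,
         origin = geom$origin, direction = geom$direction, state = state),
    class = "mbf_series")
}

is_series <- function(x) inherits(x, "mbf_series")

#' @export
print.mbf_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mbf_series> %s: %d frames of %d x %d x %d voxels, %g s total\n",
              x$state, d[4], d[1], d[2], d[3], schedule_total(x$schedule)))
  invisible(x)
}

# extract one frame as a volume
series_frame <- function(series, i) {
  volume(series$data[, , , i, drop = TRUE], series$voxel_size, series$origin,
         series$direction)
}

#' Late summed PET image
#'
#' Builds the static PET_sum image used to drive registration: the
#' duration-weighted sum of all frames whose start time lies at or past the
#' midpoint of the acquisition. A frame straddling the midpoint is included
#' only if its start is past the midpoint (whole-frame selection).
#'
#' @param series an `mbf_series`.
#' @return An `mbf_volume` (kBq s/mL).
#' @export
pet_sum <- function(series) {
  if (!is_series(series)) stop("expected an `mbf_series`")
  total <- schedule_total(series$schedule)
  sel <- which(series$schedule$start >= total / 2 - 1e-9)
  if (length(sel) == 0L) stop("no frame starts in the second half of the acquisition")
  acc <- array(0, dim(series$data)[1:3])
  for (i in sel)
    acc <- acc + series$data[, , , i] * series$schedule$duration[i]
  volume(acc, series$voxel_size, series$origin, series$direction)
}
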