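#' Time-activity curve
#'
#' Per-frame mean tracer concentration for a region (ROI, blood pool, or a
#' model prediction), tied to a frame schedule through mid-times and
#' durations.
#'
#' @param mid_s frame mid-times, seconds, strictly increasing.
#' @param duration_s frame durations, seconds.
#' @param activity mean activity per frame, kBq/mL.
#' @param source tag: ROI index, `"arterial"`, `"model"`, ...
#' @return An object of class `mbf_tac`.
#' @export
tac <- function(mid_s, duration_s, activity, source = "roi") {
  mid_s <- as.numeric(mid_s)
  duration_s <- as.numeric(duration_s)
  activity <- as.numeric(activity)
  if (length(mid_s) != length(duration_s) || length(mid_s) != length(activity))
    stop("mid_s, duration_s and activity must have equal length")
  if (any(diff(mid_s) <= 0)) stop("frame mid-times must be strictly increasing")
  if (any(duration_s <= 0)) stop("durations must be > 0")
  structure(list(mid_s = mid_s, duration_s = duration_s, activity = activity,
                 source = source),
            class = "mbf_tac")
}

is_tac <- function(x) inherits(x, "mbf_tac")

#' @export
print.mbf_tac <- function(x, ...) {
  cat(sprintf("<mbf_tac> [%s] %d frames, %.4g-%.4g kBq/mL\n", x$source,
              length(x$mid_s), min(x$activity), max(x$activity)))
  invisible(x)
}

tac_from_schedule <- function(schedule, activity, source = "roi") {
  tac(schedule$mid, schedule$duration, activity, source)
}

#' Write / read a TAC as CSV
#'
#' Columns `mid_time_s, duration_s, activity`.
#' @param x an `mbf_tac`.
#' @param path CSV path.
#' @export
write_tac <- function(x, path) {
  if (!is_tac(x)) stop("expected `mbf_tac`")
  utils::write.csv(data.frame(mid_time_s = x$mid_s, duration_s = x$duration_s,
                              activity = x$activity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @param source source tag for the loaded TAC.
#' @export
read_tac <- function(path, source = "roi") {
  tab <- utils::read.csv(path)
  if (!all(c("mid_time_s", "duration_s", "activity") %in% names(tab)))
    stop("TAC CSV needs columns mid_time_s,duration_s,activity: ", path)
  tac(tab$mid_time_s, tab$duration_s, tab$activity, source)
}
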