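#' Plot rest/stress flow profiles against a normal range
#'
#' Base-graphics rendering of the per-ROI MBF values (markers), the
#' interpolated continuous curves, and — when ranges are given — the
#' low-risk band as a grey area.
#'
#' @param profiles named list of `mbf_flow_profile`s (e.g. `rest`, `stress`).
#' @param ranges optional named list of `mbf_normal_range` keyed like
#'   `profiles`.
#' @param main title.
#' @export
plot_flow_profiles <- function(profiles, ranges = NULL, main = NULL) {
  if (length(profiles) == 0L) stop("no profiles to plot")
  xs <- range(unlist(lapply(profiles, function(p) p$position)))
  ys <- c(0, max(c(unlist(lapply(profiles, function(p) p$mbf)),
                   unlist(lapply(ranges, function(r) r$upper)))) * 1.1)
  vessel <- attr(profiles[[1]], "vessel")
  graphics::plot(NA, xlim = xs, ylim = ys, xlab = "distance from base (mm)",
                 ylab = "MBF (mL/min/g)",
                 main = main %||% sprintf("%s flow profile", vessel))
  cols <- c(rest = "blue3", stress = "red3")
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    col <- cols[[attr(p, "state")]] %||% "black"
    if (!is.null(ranges) && !is.null(ranges[[nm]])) {
      r <- ranges[[nm]]
      graphics::polygon(c(r$position, rev(r$position)),
                        c(r$lower, rev(r$upper)),
                        col = grDevices::adjustcolor("grey60", 0.4), border = NA)
    }
    if (nrow(p) >= 2L) {
      cur <- interpolate_profile(p, step_mm = 1)
      graphics::lines(cur$position, cur$value, col = col, lwd = 2)
    }
    graphics::points(p$position, p$mbf, pch = 8, col = col)
  }
  graphics::legend("topright", legend = names(profiles), bty = "n",
                   col = vapply(profiles, function(p)
                     cols[[attr(p, "state")]] %||% "black", ""),
                   lwd = 2)
  invisible(NULL)
}
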