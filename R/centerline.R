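#' Coronary centerline
#'
#' An ordered base-to-apex polyline of world coordinates for one vessel
#' (LAD, LCX or rPDA), with cumulative arc length.
#'
#' @param points n x 3 matrix of world mm, ordered base to apex.
#' @param vessel vessel label, one of `"LAD"`, `"LCX"`, `"rPDA"`.
#' @return An object of class `mbf_centerline` with `points`, `arc`
#'   (cumulative arc length starting at 0) and `vessel`.
#' @export
centerline <- function(points, vessel = c("LAD", "LCX", "rPDA")) {
  vessel <- match.arg(vessel)
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0)) stop("centerline arc length must be strictly increasing")
  structure(list(points = points, arc = c(0, cumsum(seg)), vessel = vessel),
            class = "mbf_centerline")
}

is_centerline <- function(x) inherits(x, "mbf_centerline")

#' @export
print.mbf_centerline <- function(x, ...) {
  cat(sprintf("<mbf_centerline> %s: %d points, %.1f mm\n", x$vessel,
              nrow(x$points), max(x$arc)))
  invisible(x)
}

#' Total arc length of a centerline
#' @param cl an `mbf_centerline`.
#' @export
arc_length <- function(cl) {
  if (!is_centerline(cl)) stop("expected `mbf_centerline`")
  max(cl$arc)
}

# world point at arc position s (linear interpolation along the polyline)
centerline_point_at <- function(cl, s) {
  s <- pmin(pmax(s, 0), max(cl$arc))
  vapply(s, function(si) {
    i <- findInterval(si, cl$arc, rightmost.closed = TRUE)
    i <- min(i, nrow(cl$points) - 1L)
    f <- (si - cl$arc[i]) / (cl$arc[i + 1] - cl$arc[i])
    cl$points[i, ] * (1 - f) + cl$points[i + 1, ] * f
  }, numeric(3))
}

#' Write / read a centerline as CSV
#'
#' Columns `x_mm,y_mm,z_mm`, ordered base to apex.
#' @param cl an `mbf_centerline`.
#' @param path CSV path.
#' @export
write_centerline <- function(cl, path) {
  if (!is_centerline(cl)) stop("expected `mbf_centerline`")
  utils::write.csv(data.frame(x_mm = cl$points[, 1], y_mm = cl$points[, 2],
                              z_mm = cl$points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline
#' @param vessel vessel label for the loaded centerline.
#' @export
read_centerline <- function(path, vessel = "LAD") {
  tab <- utils::read.csv(path)
  if (!all(c("x_mm", "y_mm", "z_mm") %in% names(tab)))
    stop("centerline CSV needs columns x_mm,y_mm,z_mm: ", path)
  centerline(cbind(tab$x_mm, tab$y_mm, tab$z_mm), vessel)
}
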