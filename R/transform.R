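#' Rigid transform (CT world to PET world)
#'
#' Proper rigid transform stored as ZYX Euler angles (degrees) plus a
#' translation (mm): `x_pet = R x_ct + t` with
#' `R = Rz(a1) %*% Ry(a2) %*% Rx(a3)`.
#'
#' @param angles_deg length-3 ZYX Euler angles, degrees.
#' @param translation_mm length-3 translation, mm.
#' @return An object of class `mbf_rigid_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0), translation_mm = c(0, 0, 0)) {
  angles_deg <- as.numeric(angles_deg)
  translation_mm <- as.numeric(translation_mm)
  if (length(angles_deg) != 3L || length(translation_mm) != 3L)
    stop("angles and translation must have length 3")
  structure(list(angles_deg = angles_deg, translation_mm = translation_mm,
                 convention = "ct_to_pet"),
            class = "mbf_rigid_transform")
}

is_rigid_transform <- function(x) inherits(x, "mbf_rigid_transform")

#' @export
print.mbf_rigid_transform <- function(x, ...) {
  cat(sprintf("<mbf_rigid_transform> angles (ZYX deg): %.3f %.3f %.3f; t (mm): %.3f %.3f %.3f\n",
              x$angles_deg[1], x$angles_deg[2], x$angles_deg[3],
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3]))
  invisible(x)
}

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

#' Rotation matrix of a rigid transform
#' @param x an `mbf_rigid_transform`.
#' @return 3x3 proper orthonormal matrix.
#' @export
rotation_matrix <- function(x) {
  a <- x$angles_deg * pi / 180
  rot_z(a[1]) %*% rot_y(a[2]) %*% rot_x(a[3])
}

# ZYX Euler angles (degrees) from a rotation matrix
euler_zyx_deg <- function(R) {
  beta <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(beta)) > 1e-9) {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  } else {                              # gimbal lock; split arbitrarily
    alpha <- atan2(-R[2, 3], R[2, 2])
    gamma <- 0
  }
  c(gamma, beta, alpha) * 180 / pi
}

#' Build a transform from a rotation matrix and translation
#' @param R 3x3 proper orthonormal matrix.
#' @param t length-3 translation, mm.
#' @export
transform_from_matrix <- function(R, t) {
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("R must be proper orthonormal")
  rigid_transform(euler_zyx_deg(R), t)
}

#' Apply a rigid transform to points
#' @param x an `mbf_rigid_transform`.
#' @param pts n x 3 matrix of world mm.
#' @return n x 3 matrix.
#' @export
transform_points <- function(x, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts %*% t(rotation_matrix(x)), 2L, x$translation_mm, "+")
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#' @param a,b `mbf_rigid_transform`s.
#' @export
compose_transforms <- function(a, b) {
  Ra <- rotation_matrix(a)
  Rb <- rotation_matrix(b)
  transform_from_matrix(Ra %*% Rb,
                        drop(Ra %*% b$translation_mm) + a$translation_mm)
}

#' @rdname compose_transforms
#' @param x transform to invert.
#' @export
invert_transform <- function(x) {
  R <- rotation_matrix(x)
  transform_from_matrix(t(R), drop(-t(R) %*% x$translation_mm))
}

# geodesic rotation angle (degrees) between two transforms
rotation_angle_between <- function(a, b) {
  R <- rotation_matrix(a) %*% t(rotation_matrix(b))
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

#' Apply a rigid transform to a centerline
#'
#' Pointwise rigid mapping; arc length is preserved exactly up to floating
#' point.
#' @param cl an `mbf_centerline`.
#' @param x an `mbf_rigid_transform` (CT to PET).
#' @export
transform_centerline <- function(cl, x) {
  if (!is_centerline(cl)) stop("expected `mbf_centerline`")
  centerline(transform_points(x, cl$points), cl$vessel)
}

#' Read / write a rigid transform as a JSON sidecar
#'
#' Fields `angles_deg[3]`, `translation_mm[3]`, `convention`.
#' @param x an `mbf_rigid_transform`.
#' @param path JSON path.
#' @export
write_transform <- function(x, path) {
  if (!is_rigid_transform(x)) stop("expected `mbf_rigid_transform`")
  jsonlite::write_json(list(angles_deg = x$angles_deg,
                            translation_mm = x$translation_mm,
                            convention = x$convention),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$convention, "ct_to_pet"))
    stop("unsupported transform convention (field convention): ", j$convention)
  rigid_transform(j$angles_deg, j$translation_mm)
}
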