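#' Rigid (rotation + translation) transform
#'
#' Maps world coordinates of the moving frame (micro-CT) into the fixed
#' frame (CBCT): `x' = R x + t`.
#'
#' @param rotation 3x3 rotation matrix; must be orthonormal with
#'   determinant +1 (checked to 1e-8).
#' @param translation length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- rep_len(as.numeric(translation), 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix must have determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.3f deg, |t| = %.3f mm\n",
              rotation_angle_deg(x), sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n-by-3 matrix of world coordinates (mm).
#' @return Transformed n-by-3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(points, ncol = 3)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @return The composed transform `a %*% b`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation magnitude of a rigid transform in degrees
#' @param transform a [rigid_transform()].
#' @return Geodesic rotation angle in degrees.
#' @export
rotation_angle_deg <- function(transform) {
  ctheta <- (sum(diag(transform$rotation)) - 1) / 2
  acos(pmin(1, pmax(-1, ctheta))) * 180 / pi
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations about the world x, y, then z axes.
#' @param angles_deg length-3 vector of angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(angles_deg) {
  a <- rep_len(angles_deg, 3L) * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}
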