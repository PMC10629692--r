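# Small geometry helpers shared across modules.
#
# Conventions used throughout the package (stated once, here and in the
# vignette):
#  * Lab frame: right-handed, z up (gravity along -z), units meters.
#  * Image frame: x (column) right, y (row) down, pixel centers at integer
#    coordinates, 1-based; pixel (1,1) is the top-left pixel center.
#  * Rotation matrices map body-frame coordinates to lab-frame coordinates;
#    their columns are the body axes expressed in the lab frame.

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps * 100) {
    stop("cannot normalize a (near-)zero vector")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Round half away from zero
#'
#' Continuous pixel coordinates are snapped to integer pixels with
#' round-half-away-from-zero (so 2.5 -> 3, -2.5 -> -3), not banker's
#' rounding. Carving results depend on this choice, which is why it is a
#' named, documented primitive rather than `round()`.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Axis-angle rotation matrix
#'
#' Rodrigues' formula for the proper rotation of angle `angle_deg` (degrees,
#' right-hand rule) about the unit axis `axis`.
#'
#' @param axis 3-vector, need not be normalized.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- unit(axis)
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Elementary rotations about lab axes (degrees).
rot_x <- function(a) rotation_about_axis(c(1, 0, 0), a)
rot_y <- function(a) rotation_about_axis(c(0, 1, 0), a)
rot_z <- function(a) rotation_about_axis(c(0, 0, 1), a)

#' Body orientation from yaw, pitch, roll
#'
#' Z-Y-X (yaw-pitch-roll) Euler sequence for a z-up lab frame: yaw about lab
#' z (counterclockwise from above), then pitch = elevation of the forward
#' axis above horizontal (positive nose-up), then roll about the body
#' forward axis (positive right-wing-down). The returned matrix maps body
#' coordinates (x forward, y left, z up) to lab coordinates.
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return 3x3 rotation matrix with columns x_b, y_b, z_b.
#' @export
body_rotation <- function(yaw, pitch, roll) {
  rot_z(yaw) %*% rot_y(-pitch) %*% rot_x(roll)
}

#' Yaw, pitch, roll from a body orientation matrix
#'
#' Inverse of [body_rotation()]. Pitch is returned in (-90, 90); at gimbal
#' lock (|pitch| = 90) yaw is set to 0 and roll absorbs the remaining
#' rotation.
#'
#' @param R 3x3 rotation matrix (columns x_b, y_b, z_b in lab frame).
#' @return named numeric vector (yaw, pitch, roll) in degrees.
#' @export
body_angles <- function(R) {
  pitch <- asin(max(-1, min(1, R[3, 1])))
  if (abs(cos(pitch)) < 1e-9) {
    yaw <- 0
    roll <- atan2(R[1, 2] * sign(R[3, 1]), R[2, 2])
  } else {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  }
  c(yaw = rad2deg(yaw), pitch = rad2deg(pitch), roll = rad2deg(roll))
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

# Nearest proper rotation (SVD orthogonalization).
orthonormalize <- function(R) {
  s <- svd(R)
  U <- s$u
  V <- s$v
  D <- diag(c(1, 1, sign(det(U %*% t(V)))))
  U %*% D %*% t(V)
}

# Linear interpolation with monotone-cubic option used for y_b resampling.
interp_columns <- function(x, y, xout, method = c("monotone", "linear")) {
  method <- match.arg(method)
  out <- matrix(NA_real_, length(xout), ncol(y))
  for (j in seq_len(ncol(y))) {
    if (length(x) == 1L) {
      out[, j] <- y[1, j]
    } else if (method == "monotone") {
      out[, j] <- stats::splinefun(x, y[, j], method = "monoH.FC")(xout)
    } else {
      out[, j] <- stats::approx(x, y[, j], xout, rule = 2)$y
    }
  }
  out
}
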