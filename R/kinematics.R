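# Body axes, stroke plane, wing Euler angles, body rates and per-wingbeat
# summaries.
#
# Angle conventions (documented once; validation is convention-offset
# invariant):
#  * Stroke plane: normal n_sp obtained by rotating x_b by -45 deg about
#    y_b, i.e. n_sp = (x_b + z_b)/sqrt(2); the plane is tilted 45 deg below
#    the body long axis. The in-plane forward axis is
#    x_sp = (x_b - z_b)/sqrt(2).
#  * Stroke angle phi: azimuth of the span's in-plane projection measured
#    from the body-backward direction (-x_sp), increasing toward the front,
#    so the front stroke is the per-wingbeat maximum of phi (phi = 90 deg is
#    pure lateral).
#  * Elevation theta: angle of the span above the stroke plane.
#  * Wing pitch psi: rotation of the chord about the span, measured from the
#    in-stroke-plane reference chord (psi = 0: wing lying in the stroke
#    plane; psi = 90: wing plane perpendicular to the stroke plane). The
#    chord points from the trailing toward the leading side.
#  * Left/right conventions are mirror images: a mirrored pose yields equal
#    angle triplets for the two wings.

stroke_basis <- function(x_b, y_b) {
  z_b <- cross3(x_b, y_b)
  list(n = (x_b + z_b) / sqrt(2),       # stroke-plane normal
       x_sp = (x_b - z_b) / sqrt(2),    # in-plane forward
       y_sp = y_b, z_b = z_b)
}

#' Stroke plane from body axes
#'
#' The stroke-plane normal is the body forward axis rotated by -45 deg
#' about the body y-axis; the plane passes through the body center of mass.
#'
#' @param x_b,y_b orthonormal body axes (lab frame).
#' @param origin body center of mass (m).
#' @return list with unit `normal` and `origin`.
#' @export
stroke_plane <- function(x_b, y_b, origin = c(0, 0, 0)) {
  b <- stroke_basis(unit(x_b), unit(y_b))
  list(normal = b$n, origin = origin)
}

#' Span and chord unit vectors from wing Euler angles
#'
#' Forward model of the wing-angle conventions: given a wing's stroke,
#' elevation and pitch angles and the body axes, return the lab-frame span
#' and chord unit vectors (and the wing normal span x chord).
#'
#' @param phi,theta,psi wing Euler angles (deg).
#' @param side `"left"` or `"right"`.
#' @param x_b,y_b orthonormal body axes.
#' @return list with unit vectors `s`, `c`, `n_wing`.
#' @export
wing_vectors_from_angles <- function(phi, theta, psi, side, x_b, y_b) {
  side <- match.arg(side, c("left", "right"))
  b <- stroke_basis(x_b, y_b)
  ph <- deg2rad(phi); th <- deg2rad(theta); ps <- deg2rad(psi)
  lat <- if (side == "left") b$y_sp else -b$y_sp
  u <- -cos(ph) * b$x_sp + sin(ph) * lat       # in-plane span direction
  s <- cos(th) * u + sin(th) * b$n
  c0 <- if (side == "left") unit(cross3(b$n, s)) else unit(cross3(s, b$n))
  e2 <- if (side == "left") cross3(s, c0) else cross3(c0, s)
  cc <- cos(ps) * c0 + sin(ps) * e2
  list(s = s, c = cc, n_wing = unit(cross3(s, cc)))
}

#' Wing Euler angles from span and chord vectors
#'
#' Inverse of [wing_vectors_from_angles()]; the round trip is exact to
#' numerical precision away from the gimbal pose (span parallel to the
#' stroke-plane normal), which is flagged.
#'
#' @param s,c unit span and chord vectors (lab frame).
#' @param side `"left"` or `"right"`.
#' @param x_b,y_b orthonormal body axes.
#' @return list with `phi`, `theta`, `psi` (deg) and logical `gimbal`.
#' @export
wing_angles_from_vectors <- function(s, c, side, x_b, y_b) {
  side <- match.arg(side, c("left", "right"))
  b <- stroke_basis(x_b, y_b)
  sn <- sum(s * b$n)
  theta <- asin(max(-1, min(1, sn)))
  sp <- s - sn * b$n
  if (vec_norm(sp) < 1e-8) {
    return(list(phi = NA_real_, theta = rad2deg(theta), psi = NA_real_,
                gimbal = TRUE))
  }
  lat <- if (side == "left") b$y_sp else -b$y_sp
  phi <- atan2(sum(sp * lat), -sum(sp * b$x_sp))
  c0 <- if (side == "left") unit(cross3(b$n, s)) else unit(cross3(s, b$n))
  e2 <- if (side == "left") cross3(s, c0) else cross3(c0, s)
  psi <- atan2(sum(c * e2), sum(c * c0))
  list(phi = rad2deg(phi), theta = rad2deg(theta), psi = rad2deg(psi),
       gimbal = FALSE)
}

#' Estimate the body y-axis from wing span vectors
#'
#' The body hull is nearly cylindrically symmetric, so y_b cannot be read
#' off the hull. Instead, once per back-stroke (span sweeping backward) the
#' frames where each wing's span is most perpendicular to x_b are found;
#' the half-difference of the left and right spans at those frames,
#' projected perpendicular to x_b, is a y_b sample. Samples are interpolated
#' (monotone cubic) to all frames and re-orthogonalized against x_b;
#' z_b = x_b x y_b.
#'
#' @param times frame times (s).
#' @param xb n x 3 matrix of per-frame body forward axes.
#' @param s_left,s_right n x 3 matrices of per-frame span unit vectors.
#' @return list with `yb` (n x 3), `zb` (n x 3), `n_samples`, and logical
#'   `low_confidence` (fewer than 2 samples).
#' @export
estimate_yb <- function(times, xb, s_left, s_right) {
  n <- length(times)
  dot_l <- rowSums(s_left * xb)
  dot_r <- rowSums(s_right * xb)

  # back-stroke sample frames: downward zero-ish crossings of s.x_b
  sample_frames <- function(d) {
    idx <- integer(0)
    for (i in 2:(n - 1)) {
      if (abs(d[i]) <= abs(d[i - 1]) && abs(d[i]) < abs(d[i + 1]) &&
          d[i + 1] < d[i - 1] && abs(d[i]) < 0.5) {
        idx <- c(idx, i)
      }
    }
    idx
  }
  il <- sample_frames(dot_l)
  ir <- sample_frames(dot_r)
  low_conf <- FALSE
  samples <- NULL
  if (length(il) && length(ir)) {
    used <- logical(length(ir))
    for (i in il) {
      j_rel <- which.min(abs(times[ir] - times[i]))
      if (used[j_rel]) next
      used[j_rel] <- TRUE
      j <- ir[j_rel]
      v <- (s_left[i, ] - s_right[j, ]) / 2
      xb_m <- unit(xb[i, ] + xb[j, ])
      v <- v - sum(v * xb_m) * xb_m
      if (vec_norm(v) > 1e-6) {
        samples <- rbind(samples, c((times[i] + times[j]) / 2, unit(v)))
      }
    }
  }
  if (is.null(samples) || nrow(samples) < 1L) {
    # fallback: single best overall sample
    i <- which.min(abs(dot_l)); j <- which.min(abs(dot_r))
    v <- (s_left[i, ] - s_right[j, ]) / 2
    v <- v - sum(v * xb[i, ]) * xb[i, ]
    samples <- matrix(c(times[i], unit(v)), 1)
    low_conf <- TRUE
  }
  if (nrow(samples) < 2L) low_conf <- TRUE
  yb_raw <- interp_columns(samples[, 1], samples[, 2:4, drop = FALSE], times)
  yb <- matrix(0, n, 3)
  zb <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    v <- yb_raw[i, ] - sum(yb_raw[i, ] * xb[i, ]) * xb[i, ]
    yb[i, ] <- unit(v)
    zb[i, ] <- cross3(xb[i, ], yb[i, ])
  }
  list(yb = yb, zb = zb, n_samples = nrow(samples), low_confidence = low_conf)
}

#' Body angles, body-frame angular rates and wingbeat-averaged accelerations
#'
#' Yaw/pitch/roll follow the Z-Y-X sequence of [body_rotation()]. The
#' angular velocity is obtained by central differences of the orientation
#' matrix (axis-angle of R(t+dt) R(t-dt)^T over 2 dt), expressed in the body
#' frame as (p, q, r) about (x_b, y_b, z_b). Angular accelerations are
#' central differences of (p, q, r).
#'
#' @param times frame times (s), uniformly spaced.
#' @param rotations list of 3x3 body orientation matrices (columns x_b, y_b,
#'   z_b), one per frame.
#' @param wingbeat_frames optional list of frame-index vectors, one per
#'   wingbeat, for wingbeat-averaged accelerations.
#' @return data.frame with yaw, pitch, roll (deg), p, q, r (deg/s), and
#'   pdot, qdot, rdot (deg/s^2); wingbeat averages attached as attribute
#'   `wingbeat_accel` when windows are given.
#' @export
body_angles_and_rates <- function(times, rotations, wingbeat_frames = NULL) {
  n <- length(times)
  if (n < 3L) stop("need at least 3 frames for rates")
  rotations <- lapply(rotations, function(R) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
      warning("re-orthogonalizing a non-orthonormal orientation")
      orthonormalize(R)
    } else R
  })
  ang <- t(vapply(rotations, body_angles, numeric(3)))
  omega <- matrix(NA_real_, n, 3)
  for (i in 2:(n - 1)) {
    dR <- rotations[[i + 1]] %*% t(rotations[[i - 1]])
    ca <- (sum(diag(dR)) - 1) / 2
    a <- acos(max(-1, min(1, ca)))
    dt2 <- times[i + 1] - times[i - 1]
    if (a < 1e-12) {
      w_lab <- c(0, 0, 0)
    } else {
      ax <- c(dR[3, 2] - dR[2, 3], dR[1, 3] - dR[3, 1], dR[2, 1] - dR[1, 2]) /
        (2 * sin(a))
      w_lab <- ax * a / dt2
    }
    omega[i, ] <- as.numeric(t(rotations[[i]]) %*% w_lab)
  }
  omega[1, ] <- omega[2, ]
  omega[n, ] <- omega[n - 1, ]
  omega <- rad2deg(omega)
  acc <- matrix(NA_real_, n, 3)
  dt <- diff(times)
  for (i in 2:(n - 1)) {
    acc[i, ] <- (omega[i + 1, ] - omega[i - 1, ]) / (times[i + 1] - times[i - 1])
  }
  acc[1, ] <- acc[2, ]; acc[n, ] <- acc[n - 1, ]
  out <- data.frame(t = times, yaw = ang[, 1], pitch = ang[, 2],
                    roll = ang[, 3], p = omega[, 1], q = omega[, 2],
                    r = omega[, 3], pdot = acc[, 1], qdot = acc[, 2],
                    rdot = acc[, 3])
  if (!is.null(wingbeat_frames)) {
    wb <- t(vapply(wingbeat_frames, function(fr) {
      colMeans(acc[fr, , drop = FALSE])
    }, numeric(3)))
    colnames(wb) <- c("pdot", "qdot", "rdot")
    attr(out, "wingbeat_accel") <- wb
  }
  out
}

#' Segment wingbeats and summarize stroke angles
#'
#' Wingbeats are delimited at the back-stroke extrema (local minima) of the
#' mean of the two stroke angles, subject to a minimum separation of half
#' the nominal period. Per wingbeat, the per-wing front (max phi) and back
#' (min phi) stroke angles, the mean front-stroke angle, the left-right
#' front-stroke difference and the wingbeat-averaged body angular
#' accelerations are reported.
#'
#' @param kin a kinematics table with columns `t`, `phi_left`, `phi_right`
#'   and optionally `pdot`, `qdot`, `rdot`.
#' @param nominal_period nominal wingbeat period (s); estimated from the
#'   dominant oscillation of mean phi when `NULL`.
#' @return data.frame of per-wingbeat summaries (empty when no complete
#'   wingbeat is present).
#' @export
wingbeat_summaries <- function(kin, nominal_period = NULL) {
  phi_m <- (kin$phi_left + kin$phi_right) / 2
  ok <- is.finite(phi_m)
  n <- nrow(kin)
  if (is.null(nominal_period)) {
    dtf <- stats::median(diff(kin$t))
    per <- estimate_dominant_period(phi_m[ok])
    nominal_period <- if (is.na(per)) NA else per * dtf
  }
  min_sep <- if (is.na(nominal_period)) 3L else
    max(3L, floor(nominal_period / 2 / stats::median(diff(kin$t))))
  mins <- find_local_minima(phi_m, min_sep)
  if (length(mins) < 2L) {
    return(data.frame(wingbeat = integer(0)))
  }
  out <- lapply(seq_len(length(mins) - 1L), function(w) {
    fr <- mins[w]:mins[w + 1]
    d <- data.frame(
      wingbeat = w, first_frame = mins[w], last_frame = mins[w + 1],
      phi_front_left = max(kin$phi_left[fr], na.rm = TRUE),
      phi_front_right = max(kin$phi_right[fr], na.rm = TRUE),
      phi_back_left = min(kin$phi_left[fr], na.rm = TRUE),
      phi_back_right = min(kin$phi_right[fr], na.rm = TRUE))
    d$phi_front_mean <- (d$phi_front_left + d$phi_front_right) / 2
    d$dphi_front <- d$phi_front_left - d$phi_front_right
    if (!is.null(kin$pdot)) {
      d$pdot_mean <- mean(kin$pdot[fr], na.rm = TRUE)
      d$qdot_mean <- mean(kin$qdot[fr], na.rm = TRUE)
      d$rdot_mean <- mean(kin$rdot[fr], na.rm = TRUE)
    }
    d
  })
  do.call(rbind, out)
}

# local minima with a minimum index separation, strongest first
find_local_minima <- function(x, min_sep) {
  n <- length(x)
  cand <- which(vapply(seq_len(n), function(i) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    is.finite(x[i]) && x[i] <= min(x[lo:hi], na.rm = TRUE)
  }, logical(1)))
  cand <- cand[order(x[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || min(abs(keep - i)) >= min_sep) keep <- c(keep, i)
  }
  sort(keep)
}

# dominant period (frames) of an oscillatory signal via autocorrelation peak
estimate_dominant_period <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8L) return(NA_real_)
  a <- stats::acf(x, lag.max = min(length(x) - 2L, 400L), plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  # first local max after the initial decay
  for (lag in 3:(length(a) - 1)) {
    if (a[lag] > a[lag - 1] && a[lag] >= a[lag + 1] && a[lag] > 0.2) {
      return(as.numeric(lag - 1))
    }
  }
  NA_real_
}
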