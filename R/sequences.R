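# Prescribed wingbeat kinematics, pose sequences and pose ensembles: the
# ground-truth trajectories behind the synthetic validation experiment.

#' Generate a smooth wingbeat pose sequence
#'
#' Harmonic waveforms over `n_wingbeats` periods sampled at
#' `frames_per_wingbeat` frames per period (default 73, one wingbeat of the
#' reference high-speed recordings):
#' \itemize{
#'   \item stroke:    phi(t) = phi_mean + phi_amp * cos(w t)
#'   \item elevation: theta(t) = theta_mean + theta_amp * sin(2 w t + ph_th)
#'   \item pitch:     psi(t) = psi_mean + psi_amp * sin(w t + ph_ps)
#' }
#' with w = 2 pi frequency. Left and right wings are mirrored unless an
#' `asymmetry` offset list is given. The body follows a constant-velocity,
#' constant-angular-rate trajectory.
#'
#' @param model a `fly_model`.
#' @param n_wingbeats number of wingbeats (>= 1).
#' @param frames_per_wingbeat frames per wingbeat.
#' @param frequency wingbeat frequency (Hz); the frame interval is
#'   `1/(frequency * frames_per_wingbeat)`.
#' @param body list: `position` (m), `velocity` (m/s), `yaw`, `pitch`,
#'   `roll` (deg), `yaw_rate`, `pitch_rate`, `roll_rate` (deg/s).
#' @param wings list: `phi_mean`, `phi_amp`, `theta_mean`, `theta_amp`,
#'   `theta_phase`, `psi_mean`, `psi_amp`, `psi_phase` (deg).
#' @param asymmetry optional list of per-side additive offsets, e.g.
#'   `list(phi_right = -5)`.
#' @param twist_deg spanwise linear wing twist at the tip (deg).
#' @param seed optional integer recorded in the output (the generator
#'   itself is deterministic; the seed is kept for provenance of any
#'   downstream noise).
#' @return an object of class `pose_sequence`.
#' @export
generate_wingbeat_sequence <- function(model, n_wingbeats = 10,
                                       frames_per_wingbeat = 73,
                                       frequency = 250,
                                       body = list(), wings = list(),
                                       asymmetry = NULL, twist_deg = 0,
                                       seed = NULL) {
  if (n_wingbeats < 1) stop("n_wingbeats must be >= 1")
  if (frequency <= 0) stop("frequency must be positive")
  b <- utils::modifyList(list(position = c(0, 0, 0), velocity = c(0.05, 0, 0),
                              yaw = 0, pitch = 45, roll = 0,
                              yaw_rate = 100, pitch_rate = 0, roll_rate = 0),
                         body)
  # psi_phase = 180 puts the wing-pitch flip at stroke reversal with the
  # morphological leading edge leading the motion on both strokes
  w <- utils::modifyList(list(phi_mean = 90, phi_amp = 65,
                              theta_mean = 0, theta_amp = 10, theta_phase = 0,
                              psi_mean = 90, psi_amp = 50, psi_phase = 180),
                         wings)
  n <- as.integer(n_wingbeats * frames_per_wingbeat)
  dt <- 1 / (frequency * frames_per_wingbeat)
  t <- (seq_len(n) - 1) * dt
  om <- 2 * pi * frequency
  ang <- function(side) {
    add <- function(nm) {
      a <- 0
      if (!is.null(asymmetry)) {
        key <- paste0(nm, "_", side)
        if (!is.null(asymmetry[[key]])) a <- asymmetry[[key]]
      }
      a
    }
    list(phi = w$phi_mean + add("phi") + w$phi_amp * cos(om * t),
         theta = w$theta_mean + add("theta") +
           w$theta_amp * sin(2 * om * t + deg2rad(w$theta_phase)),
         psi = w$psi_mean + add("psi") +
           w$psi_amp * sin(om * t + deg2rad(w$psi_phase)))
  }
  structure(list(
    times = t, model = model, frames_per_wingbeat = frames_per_wingbeat,
    frequency = frequency, twist_deg = twist_deg, seed = seed,
    body = list(position = t(vapply(t, function(tt) b$position + b$velocity * tt,
                                    numeric(3))),
                yaw = b$yaw + b$yaw_rate * t,
                pitch = b$pitch + b$pitch_rate * t,
                roll = b$roll + b$roll_rate * t),
    left = ang("left"), right = ang("right")),
    class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose sequence: %d frames (%d per wingbeat), %.0f Hz>\n",
              length(x$times), x$frames_per_wingbeat, x$frequency))
  invisible(x)
}

#' @export
length.pose_sequence <- function(x) length(x$times)

#' Pose the model at one frame of a sequence
#'
#' @param seq a `pose_sequence`.
#' @param i frame index.
#' @return the [pose_model()] output for that frame.
#' @export
sequence_pose <- function(seq, i) {
  bp <- body_pose(seq$body$position[i, ], seq$body$yaw[i],
                  seq$body$pitch[i], seq$body$roll[i])
  pose_model(seq$model, bp,
             wing_pose(seq$left$phi[i], seq$left$theta[i], seq$left$psi[i],
                       "left"),
             wing_pose(seq$right$phi[i], seq$right$theta[i], seq$right$psi[i],
                       "right"),
             twist_deg = seq$twist_deg)
}

#' Ground-truth table of a pose sequence
#'
#' @param seq a `pose_sequence`.
#' @return data.frame with one row per frame: time, body CM, body angles,
#'   and per-wing Euler angles.
#' @export
sequence_truth <- function(seq) {
  data.frame(t = seq$times,
             x = seq$body$position[, 1], y = seq$body$position[, 2],
             z = seq$body$position[, 3],
             yaw = seq$body$yaw, pitch = seq$body$pitch, roll = seq$body$roll,
             phi_left = seq$left$phi, theta_left = seq$left$theta,
             psi_left = seq$left$psi,
             phi_right = seq$right$phi, theta_right = seq$right$theta,
             psi_right = seq$right$psi)
}

#' Render a pose sequence to per-camera silhouette stacks
#'
#' @param seq a `pose_sequence`.
#' @param rig a `camera_rig`.
#' @param frames frame indices to render (default all).
#' @param parts keep the ground-truth per-part visible masks as well
#'   (memory heavy; meant for short test sequences).
#' @return list per camera with `full` (height x width x frames logical
#'   array) and, when `parts = TRUE`, `body`, `wing_left`, `wing_right`.
#' @export
render_sequence <- function(seq, rig, frames = seq_along(seq$times),
                            parts = FALSE) {
  nc <- length(rig$cameras)
  W <- rig$cameras[[1]]$image_size[1]; H <- rig$cameras[[1]]$image_size[2]
  nf <- length(frames)
  alloc <- function() array(FALSE, c(H, W, nf))
  out <- lapply(seq_len(nc), function(j) {
    l <- list(full = alloc())
    if (parts) {
      l$body <- alloc(); l$wing_left <- alloc(); l$wing_right <- alloc()
    }
    l
  })
  for (fi in seq_len(nf)) {
    sil <- render_silhouettes(sequence_pose(seq, frames[fi]), rig)
    for (j in seq_len(nc)) {
      out[[j]]$full[, , fi] <- sil[[j]]$full
      if (parts) {
        out[[j]]$body[, , fi] <- sil[[j]]$body
        out[[j]]$wing_left[, , fi] <- sil[[j]]$wing_left
        out[[j]]$wing_right[, , fi] <- sil[[j]]$wing_right
      }
    }
  }
  names(out) <- names(render_silhouettes(sequence_pose(seq, frames[1]), rig))
  out
}

#' Sample an ensemble of body/wing poses
#'
#' Independent uniform samples from the given ranges, reproducible under a
#' fixed seed. The default ranges emulate experimentally typical fruit-fly
#' postures: full azimuthal freedom, body pitch 30-60 deg, wide stroke
#' range and free wing pitch.
#'
#' @param n ensemble size (0 gives an empty ensemble).
#' @param seed RNG seed.
#' @param ranges named list of `c(min, max)` ranges for `yaw`, `pitch`,
#'   `roll`, `phi`, `theta`, `psi` (wing ranges applied to each wing
#'   independently).
#' @return data.frame with one row per pose.
#' @export
sample_pose_ensemble <- function(n, seed = 1, ranges = list()) {
  rg <- utils::modifyList(list(yaw = c(0, 360), pitch = c(30, 60),
                               roll = c(0, 0), phi = c(-30, 160),
                               theta = c(-30, 30), psi = c(0, 180)),
                          ranges)
  for (nm in names(rg)) {
    if (length(rg[[nm]]) != 2L || rg[[nm]][2] < rg[[nm]][1]) {
      stop("invalid range for ", nm)
    }
  }
  if (n == 0L) {
    return(data.frame(yaw = numeric(0), pitch = numeric(0), roll = numeric(0),
                      phi_left = numeric(0), theta_left = numeric(0),
                      psi_left = numeric(0), phi_right = numeric(0),
                      theta_right = numeric(0), psi_right = numeric(0)))
  }
  set.seed(seed)
  ru <- function(r) stats::runif(n, r[1], r[2])
  data.frame(yaw = ru(rg$yaw), pitch = ru(rg$pitch), roll = ru(rg$roll),
             phi_left = ru(rg$phi), theta_left = ru(rg$theta),
             psi_left = ru(rg$psi), phi_right = ru(rg$phi),
             theta_right = ru(rg$theta), psi_right = ru(rg$psi))
}
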