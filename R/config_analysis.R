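# Camera-configuration analysis: quantify how much of each wing is
# unoccluded across an ensemble of typical flight poses, and compare rigs
# by the fraction of poses whose wing boundaries are sufficiently visible
# in at least three cameras.

#' Wing visibility metrics for one posed fly
#'
#' Two metrics per camera and wing, from per-part z-buffered rasterization:
#' (1) the percentage of the wing's area (pixels of the wing rendered
#' alone) that is not occluded by the body or the other wing; (2) the
#' percentage of `n_boundary` fixed points along the wing outline whose
#' projection is visible (the nearest surface at the projected pixel,
#' within a 1-px tolerance, belongs to that wing).
#'
#' @param posed output of [pose_model()].
#' @param rig a `camera_rig`.
#' @param n_boundary boundary sample count (default 100).
#' @return data.frame: camera, wing, area_visible_pct,
#'   boundary_visible_pct, degenerate.
#' @export
wing_visibility <- function(posed, rig, n_boundary = 100) {
  sil <- render_silhouettes(posed, rig, alone = TRUE)
  bpts <- list(left = wing_boundary_points(posed, "left", n_boundary),
               right = wing_boundary_points(posed, "right", n_boundary))
  out <- list()
  for (j in seq_along(rig$cameras)) {
    cam <- rig$cameras[[j]]
    for (side in c("left", "right")) {
      id <- part_ids[[paste0("wing_", side)]]
      alone <- sil[[j]]$alone[[paste0("wing_", side)]]
      total <- sum(alone)
      visible <- sum(sil[[j]]$labels == id)
      area_pct <- if (total > 0) 100 * min(1, visible / total) else 0
      vis <- boundary_visible(bpts[[side]], sil[[j]]$labels, id, cam)
      out[[length(out) + 1]] <- data.frame(
        camera = cam$id, wing = side,
        area_visible_pct = area_pct,
        boundary_visible_pct = 100 * mean(vis),
        degenerate = total < 3)
    }
  }
  do.call(rbind, out)
}

# visibility of 3D points against a rendered label image: the projected
# pixel (1-px tolerance: its 3x3 neighborhood) must expose the wing's label
boundary_visible <- function(pts, labels, id, cam) {
  px <- project_point(cam, pts)
  xi <- round_half_away(px[, 1]); yi <- round_half_away(px[, 2])
  H <- nrow(labels); W <- ncol(labels)
  vis <- logical(nrow(pts))
  for (dy in -1:1) for (dx in -1:1) {
    x <- xi + dx; y <- yi + dy
    ok <- x >= 1 & x <= W & y >= 1 & y <= H
    hit <- ok
    hit[ok] <- labels[(x[ok] - 1) * H + y[ok]] == id
    vis <- vis | hit
  }
  vis
}

#' Success curve of a rig over a pose ensemble
#'
#' A pose counts as successfully identifiable at a visibility threshold if,
#' for each wing, the fraction of its boundary points visible in at least
#' three cameras exceeds the threshold.
#'
#' @param ensemble data.frame from [sample_pose_ensemble()].
#' @param rig a `camera_rig` with at least three cameras.
#' @param thresholds visibility thresholds in percent (0-100).
#' @param model a `fly_model` (default geometry when `NULL`).
#' @param n_boundary boundary points per wing.
#' @param min_cameras required simultaneous views per boundary point.
#' @return object of class `success_curve`: data.frame with `threshold` and
#'   `success_fraction`; per-pose wing fractions attached as attribute
#'   `pose_fractions`.
#' @export
success_fraction <- function(ensemble, rig, thresholds = seq(0, 100, 5),
                             model = NULL, n_boundary = 100,
                             min_cameras = 3) {
  if (length(rig$cameras) < min_cameras) {
    stop("the visibility criterion needs a rig with >= ", min_cameras,
         " cameras")
  }
  if (!nrow(ensemble)) stop("empty ensemble")
  if (is.null(model)) model <- build_fly_model()
  frac <- matrix(NA_real_, nrow(ensemble), 2,
                 dimnames = list(NULL, c("left", "right")))
  for (i in seq_len(nrow(ensemble))) {
    e <- ensemble[i, ]
    posed <- pose_model(model,
                        body_pose(yaw = e$yaw, pitch = e$pitch, roll = e$roll),
                        wing_pose(e$phi_left, e$theta_left, e$psi_left, "left"),
                        wing_pose(e$phi_right, e$theta_right, e$psi_right,
                                  "right"))
    sil <- render_silhouettes(posed, rig)
    for (side in c("left", "right")) {
      pts <- wing_boundary_points(posed, side, n_boundary)
      id <- part_ids[[paste0("wing_", side)]]
      nvis <- rep(0L, n_boundary)
      for (j in seq_along(rig$cameras)) {
        nvis <- nvis + boundary_visible(pts, sil[[j]]$labels, id,
                                        rig$cameras[[j]])
      }
      frac[i, side] <- mean(nvis >= min_cameras)
    }
  }
  wing_min <- pmin(frac[, 1], frac[, 2])
  curve <- data.frame(threshold = thresholds,
                      success_fraction = vapply(thresholds, function(th) {
                        mean(wing_min * 100 > th)
                      }, numeric(1)))
  attr(curve, "pose_fractions") <- frac
  attr(curve, "rig") <- rig$preset_name
  class(curve) <- c("success_curve", "data.frame")
  curve
}

#' Compare camera rigs on one pose ensemble
#'
#' Tabulates the success curves of several rigs on a common ensemble and
#' summarizes which rig dominates at each threshold.
#'
#' @param ensemble data.frame from [sample_pose_ensemble()].
#' @param rigs named list of `camera_rig` objects (>= 2).
#' @param thresholds visibility thresholds in percent.
#' @param ... passed to [success_fraction()].
#' @return list with `curves` (long data.frame rig x threshold) and
#'   `dominance` (best rig per threshold, ties broken by rig order).
#' @export
compare_rigs <- function(ensemble, rigs, thresholds = seq(0, 100, 5), ...) {
  if (length(rigs) < 2L) stop("need at least two rigs to compare")
  if (is.null(names(rigs))) names(rigs) <- paste0("rig", seq_along(rigs))
  curves <- lapply(names(rigs), function(nm) {
    sc <- success_fraction(ensemble, rigs[[nm]], thresholds, ...)
    data.frame(rig = nm, threshold = sc$threshold,
               success_fraction = sc$success_fraction)
  })
  curves <- do.call(rbind, curves)
  dom <- do.call(rbind, lapply(thresholds, function(th) {
    sub <- curves[curves$threshold == th, ]
    data.frame(threshold = th,
               best_rig = sub$rig[which.max(sub$success_fraction)],
               best_fraction = max(sub$success_fraction))
  }))
  list(curves = curves, dominance = dom)
}

#' Plot success curves
#'
#' @param x output of [compare_rigs()] (or a single `success_curve`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot_success_curves <- function(x, ...) {
  if (inherits(x, "success_curve")) {
    x <- list(curves = data.frame(rig = attr(x, "rig"),
                                  threshold = x$threshold,
                                  success_fraction = x$success_fraction))
  }
  rigs <- unique(x$curves$rig)
  th <- sort(unique(x$curves$threshold))
  m <- sapply(rigs, function(r) {
    sub <- x$curves[x$curves$rig == r, ]
    sub$success_fraction[order(sub$threshold)]
  })
  graphics::matplot(th, m, type = "l", lty = 1, lwd = 2,
                    xlab = "visibility threshold (%)",
                    ylab = "fraction of poses identifiable", ...)
  graphics::legend("bottomleft", legend = rigs, lty = 1, lwd = 2,
                   col = seq_along(rigs))
  invisible(m)
}
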