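# End-to-end orchestration: segmentation -> hull reconstruction ->
# reprojection -> wing geometry -> kinematics, plus the synthetic
# validation harness.

#' Pipeline configuration
#'
#' All tunable parameters of the tracking pipeline with their defaults.
#'
#' @param binarize_threshold intensity threshold for [binarize()].
#' @param fly_dark polarity for [binarize()].
#' @param window wingbeat window (frames) for [segment_body()], or
#'   `"auto"`.
#' @param occupancy_fraction body-occupancy fraction for [segment_body()].
#' @param grid_extent voxel-grid cube side in wing lengths.
#' @param grid_pitch voxel edge (m); `NULL` uses one image-pixel footprint.
#' @param grid_rebuild_voxels rebuild the grid when the triangulated body
#'   CM drifts by more than this many voxels.
#' @param wing_length wing length (m); `NULL` estimates it as the 97.5th
#'   percentile of the farthest-wing-voxel distance over the first two
#'   wingbeats.
#' @param strip_bounds radial strip bounds (fractions of the wing length).
#' @param cone_alpha,cone_beta tip-refinement cone parameters.
#' @param n_sections spanwise bins of the deformation profile.
#' @param min_wing_px minimum pixels for a wing connected component.
#' @param dilate_masks dilate masks by 1 px before carving (for real data
#'   with imperfect calibration; off for synthetic work).
#' @param forward_hint lab-frame flight-direction prior for the first
#'   frame's head/tail disambiguation.
#' @param smooth_rates apply a 5-point moving average to (p, q, r) before
#'   differentiating (off: unsmoothed central differences).
#' @param seed RNG seed recorded with the run.
#' @return a named list of class `flyhull_config`.
#' @export
flyhull_config <- function(binarize_threshold = 0.5, fly_dark = TRUE,
                           window = 73, occupancy_fraction = 0.85,
                           grid_extent = 2.6, grid_pitch = NULL,
                           grid_rebuild_voxels = 5,
                           wing_length = NULL, strip_bounds = c(0.40, 0.65),
                           cone_alpha = 30, cone_beta = 0.8,
                           n_sections = 5, min_wing_px = 6,
                           dilate_masks = FALSE,
                           forward_hint = c(1, 0, 0),
                           smooth_rates = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "flyhull_config"
  cfg
}

default_pixel_pitch <- function(rig) {
  # pixel footprint at the chamber center for the first camera
  cam <- rig$cameras[[1]]
  ctr <- camera_center(cam)
  d <- vec_norm(ctr)
  f <- vec_norm(cam$P[1, 1:3]) / vec_norm(cam$P[3, 1:3])
  d / f
}

#' Run the full hull reconstruction-reprojection pipeline
#'
#' Takes synchronized, binarized per-camera image stacks and produces a
#' per-frame kinematics table: body position and axes, yaw/pitch/roll,
#' body-frame angular rates, per-wing Euler angles and the spanwise local
#' pitch (deformation) profile. Frames that cannot be resolved are flagged
#' and reported, never silently interpolated.
#'
#' @param stacks list (one per camera, rig order) of `height x width x
#'   frames` arrays: logical silhouettes or grayscale to be binarized.
#' @param rig a `camera_rig`.
#' @param times frame times (s), or a single frame rate (Hz).
#' @param config a [flyhull_config()].
#' @return list of class `flyhull_result`: `kinematics` (data.frame),
#'   `wingbeats`, `frames` (per-frame geometry), `seg` (per-camera CMs and
#'   window), `config`, `flags`.
#' @export
run_pipeline <- function(stacks, rig, times, config = flyhull_config()) {
  nc <- length(rig$cameras)
  if (length(stacks) != nc) {
    stop("got ", length(stacks), " stacks for ", nc, " cameras")
  }
  nf <- dim(stacks[[1]])[3]
  if (length(times) == 1L) times <- (seq_len(nf) - 1) / times
  if (length(times) != nf) stop("times must match the frame count")

  # --- binarize + segment each camera ---------------------------------------
  seg <- vector("list", nc)
  for (j in seq_len(nc)) {
    st <- stacks[[j]]
    if (!is.logical(st)) {
      st <- array(binarize(st, config$binarize_threshold, config$fly_dark),
                  dim(st))
    }
    seg[[j]] <- segment_body(st, config$window, config$occupancy_fraction)
    seg[[j]]$wing <- NULL    # recomputed per frame; keeps memory flat
    seg[[j]]$full <- st
  }

  pitch <- if (is.null(config$grid_pitch)) default_pixel_pitch(rig) else
    config$grid_pitch
  Lw0 <- if (is.null(config$wing_length)) 2.5e-3 else config$wing_length

  # --- pass A: per-frame hulls and body axis --------------------------------
  grid <- NULL; ctx <- NULL; epoch <- 0L
  frames <- vector("list", nf)
  prev_xb <- NULL
  prev_cms <- NULL
  tip_dist <- matrix(NA_real_, nf, 2)
  for (f in seq_len(nf)) {
    fr <- list(flags = character(0))
    cms <- t(vapply(seg, function(s) s$cm[f, ], numeric(2)))
    full_m <- lapply(seq_len(nc), function(j) seg[[j]]$full[, , f])
    body_m <- lapply(seq_len(nc), function(j) seg[[j]]$body[, , f])
    wing_m <- lapply(seq_len(nc), function(j) full_m[[j]] & !body_m[[j]])
    if (config$dilate_masks) {
      full_m <- lapply(full_m, close_mask)
      wing_m <- lapply(wing_m, close_mask)
    }
    cm_guess <- tryCatch(triangulate_pixels(rig, cms)$point,
                         error = function(e) NULL)
    if (is.null(cm_guess)) {
      fr$flags <- "no_body_cm"
      frames[[f]] <- fr
      next
    }
    if (is.null(grid) ||
        max(abs(cm_guess - attr(grid, "cm"))) >
          config$grid_rebuild_voxels * pitch) {
      grid <- suppressWarnings(
        build_voxel_grid(cms, rig, Lw0, config$grid_extent, pitch))
      ctx <- carve_context(grid, rig)
      epoch <- epoch + 1L
    }
    h_full <- suppressWarnings(carve(ctx, full_m))
    if (!length(h_full$lin)) {
      fr$flags <- "empty_full_hull"
      frames[[f]] <- fr
      next
    }
    sub <- h_full$lin
    h_body <- suppressWarnings(body_hull(ctx, lapply(body_m, function(m)
      list(body = m)), subset = sub))
    if (length(h_body$lin) < 8L) {
      fr$flags <- "empty_body_hull"
      frames[[f]] <- fr
      next
    }
    # expanded body hulls and their majority hull
    exp_body <- lapply(seq_len(nc), function(j) {
      masks <- full_m
      masks[[j]] <- body_m[[j]]
      suppressWarnings(carve(ctx, masks, subset = sub))
    })
    h_body_exp <- majority_body_hull(exp_body)
    # expanded wing hulls from the wing connected components of each view
    exp_wings <- list()
    for (j in seq_len(nc)) {
      comps <- wing_components(wing_m[[j]], config$min_wing_px)
      if (!length(comps)) next   # wing fully occluded in this view
      for (cmask in comps) {
        exp_wings[[length(exp_wings) + 1]] <-
          expanded_wing_hull(length(exp_wings) + 1, j, cmask, full_m,
                             ctx, subset = sub)
      }
    }
    if (!length(exp_wings)) {
      fr$flags <- "no_wing_pixels"
      frames[[f]] <- fr
      next
    }
    h_two <- combined_wing_hull(exp_wings, h_body_exp)
    if (!length(h_two$lin)) {
      fr$flags <- "wings_unresolvable"
      frames[[f]] <- fr
      next
    }
    ht <- head_tail_refine(h_body, prev_xb, config$forward_hint)
    prev_xb <- ht$xb
    yref <- if (!is.null(prev_cms)) NULL else unit(cross3(c(0, 0, 1), ht$xb))
    sw <- split_wings(h_two, if (is.null(yref))
      unit(cross3(c(0, 0, 1), ht$xb)) else yref, ht$cm, prev_cms)
    fr$flags <- c(fr$flags, ht$flags, sw$flags)
    fr$cm <- ht$cm
    fr$xb <- ht$xb
    fr$grid <- grid
    fr$epoch <- epoch
    fr$h_body <- h_body$lin
    fr$h_left <- sw$left$lin
    fr$h_right <- sw$right$lin
    if (length(sw$left$lin) && length(sw$right$lin)) {
      prev_cms <- list(left = colMeans(hull_coords(sw$left)),
                       right = colMeans(hull_coords(sw$right)))
      tip_dist[f, 1] <- sqrt(max(rowSums(
        sweep(hull_coords(sw$left), 2, ht$cm)^2)))
      tip_dist[f, 2] <- sqrt(max(rowSums(
        sweep(hull_coords(sw$right), 2, ht$cm)^2)))
    }
    frames[[f]] <- fr
  }

  # wing length: 97.5th percentile of tip distance over the first two
  # wingbeats (config override wins)
  if (is.null(config$wing_length)) {
    n0 <- min(nf, 2L * seg[[1]]$window)
    td <- tip_dist[seq_len(n0), ]
    Lw <- stats::quantile(td[is.finite(td)], 0.975, names = FALSE)
    if (!is.finite(Lw)) Lw <- Lw0
  } else {
    Lw <- config$wing_length
  }

  # --- pass B: wing features, body frame, Euler angles ----------------------
  res <- pipeline_wing_pass(frames, rig, times, Lw, config)
  kin <- res$kinematics
  wb <- wingbeat_summaries(kin)
  wingbeat_frames <- if (nrow(wb)) {
    lapply(seq_len(nrow(wb)), function(w) wb$first_frame[w]:wb$last_frame[w])
  } else NULL
  bar <- body_angles_and_rates(times, res$rotations, wingbeat_frames)
  kin <- cbind(kin, bar[, c("yaw", "pitch", "roll", "p", "q", "r",
                            "pdot", "qdot", "rdot")])
  if (nrow(wb) && !is.null(attr(bar, "wingbeat_accel"))) {
    acc <- attr(bar, "wingbeat_accel")
    wb$pdot_mean <- acc[, "pdot"]; wb$qdot_mean <- acc[, "qdot"]
    wb$rdot_mean <- acc[, "rdot"]
  }
  flagged <- sum(vapply(frames, function(fr) length(fr$flags) > 0, logical(1)))
  structure(list(kinematics = kin, wingbeats = wb, frames = frames,
                 seg = lapply(seg, function(s) list(cm = s$cm,
                                                    window = s$window)),
                 wing_length = Lw, config = config,
                 failed = flagged > nf / 2, n_flagged = flagged),
            class = "flyhull_result")
}

#' @export
print.flyhull_result <- function(x, ...) {
  cat(sprintf("<flyhull result: %d frames, %d wingbeats, %d flagged%s>\n",
              nrow(x$kinematics), nrow(x$wingbeats), x$n_flagged,
              if (x$failed) " [RUN FAILED: >50% flagged]" else ""))
  invisible(x)
}

# connected components of a wing mask: up to the two largest, as masks
# (labeling runs on the mask's bounding box)
wing_components <- function(wm, min_px) {
  w <- which(wm)
  if (!length(w)) return(list())
  H <- nrow(wm); W <- ncol(wm)
  ys <- (w - 1) %% H + 1; xs <- (w - 1) %/% H + 1
  y0 <- min(ys); y1 <- max(ys); x0 <- min(xs); x1 <- max(xs)
  lab <- as.matrix(EBImage::bwlabel(wm[y0:y1, x0:x1, drop = FALSE]))
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)
  keep <- keep[sizes[keep] >= min_px]
  keep <- utils::head(keep, 2)
  lapply(keep, function(k) {
    m <- matrix(FALSE, H, W)
    m[y0:y1, x0:x1] <- lab == k
    m
  })
}

# pass B worker: span/chord ladder per wing, y_b estimation, reprojection
# LE/TE stage, Euler angles and deformation profile
pipeline_wing_pass <- function(frames, rig, times, Lw, config) {
  nf <- length(frames)
  nsec <- config$n_sections
  sL <- matrix(NA_real_, nf, 3); sR <- matrix(NA_real_, nf, 3)
  cL <- matrix(NA_real_, nf, 3); cR <- matrix(NA_real_, nf, 3)
  tipL <- matrix(NA_real_, nf, 3); tipR <- matrix(NA_real_, nf, 3)
  cmW <- list(left = matrix(NA_real_, nf, 3), right = matrix(NA_real_, nf, 3))
  xb <- matrix(NA_real_, nf, 3)
  feats <- vector("list", nf)
  prev_c <- list(left = NULL, right = NULL)
  for (f in seq_len(nf)) {
    fr <- frames[[f]]
    if (is.null(fr$cm)) next
    xb[f, ] <- fr$xb
    feats[[f]] <- list()
    for (side in c("left", "right")) {
      lin <- fr[[if (side == "left") "h_left" else "h_right"]]
      if (!length(lin)) next
      hw <- hull(fr$grid, lin)
      wf <- wing_features(hw, fr$cm, Lw, prev_c[[side]],
                          config$cone_alpha, config$cone_beta)
      if (is.null(wf$s) || !all(is.finite(wf$s))) next
      prev_c[[side]] <- wf$c
      feats[[f]][[side]] <- wf
      if (side == "left") {
        sL[f, ] <- wf$s; if (all(is.finite(wf$c))) cL[f, ] <- wf$c
        tipL[f, ] <- wf$tip
      } else {
        sR[f, ] <- wf$s; if (all(is.finite(wf$c))) cR[f, ] <- wf$c
        tipR[f, ] <- wf$tip
      }
      cmW[[side]][f, ] <- wf$cm_w
    }
  }

  # body frame: y_b from the spans, z_b = x_b x y_b
  ok <- which(stats::complete.cases(cbind(xb, sL, sR)))
  if (length(ok) < 3L) stop("too few resolvable frames to estimate y_b")
  ybzb <- estimate_yb(times[ok], xb[ok, , drop = FALSE],
                      sL[ok, , drop = FALSE], sR[ok, , drop = FALSE])
  yb <- matrix(NA_real_, nf, 3); zb <- matrix(NA_real_, nf, 3)
  yb[ok, ] <- ybzb$yb; zb[ok, ] <- ybzb$zb
  # fill unresolved frames by nearest resolved frame (axes only)
  for (f in seq_len(nf)) {
    if (!f %in% ok) {
      nn <- ok[which.min(abs(ok - f))]
      if (!all(is.finite(xb[f, ]))) xb[f, ] <- xb[nn, ]
      yb[f, ] <- yb[nn, ]; zb[f, ] <- zb[nn, ]
      yb[f, ] <- unit(yb[f, ] - sum(yb[f, ] * xb[f, ]) * xb[f, ])
      zb[f, ] <- cross3(xb[f, ], yb[f, ])
    }
  }

  # global chord-sign check: the chord must on average point along the
  # stroke-plane normal (wing pitch in (0, 180) deg in normal flight)
  for (side in c("left", "right")) {
    cm_ <- if (side == "left") cL else cR
    dot <- rep(NA_real_, nf)
    for (f in seq_len(nf)) {
      if (all(is.finite(cm_[f, ])) && all(is.finite(xb[f, ]))) {
        b <- stroke_basis(xb[f, ], yb[f, ])
        dot[f] <- sum(cm_[f, ] * b$n)
      }
    }
    if (is.finite(stats::median(dot, na.rm = TRUE)) &&
        stats::median(dot, na.rm = TRUE) < 0) {
      if (side == "left") cL <- -cL else cR <- -cR
    }
  }

  # tip velocity (central differences), hold direction during reversal
  tip_vel <- function(tips) {
    v <- matrix(NA_real_, nf, 3)
    for (f in 2:(nf - 1)) {
      v[f, ] <- (tips[f + 1, ] - tips[f - 1, ]) / (times[f + 1] - times[f - 1])
    }
    v[1, ] <- v[2, ]; v[nf, ] <- v[nf - 1, ]
    v
  }
  vL <- tip_vel(tipL); vR <- tip_vel(tipR)

  # --- LE/TE reprojection stage + angles ------------------------------------
  # one carve context alive at a time (grid epochs are visited in order)
  cur_epoch <- -1L
  cur_ctx <- NULL
  empty_psi <- as.list(rep(NA_real_, nsec))
  out <- vector("list", nf)
  held_dir <- list(left = NULL, right = NULL)
  vmax <- list(left = sqrt(max(rowSums(vL^2), na.rm = TRUE)),
               right = sqrt(max(rowSums(vR^2), na.rm = TRUE)))
  rotations <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- frames[[f]]
    row <- list(t = times[f], frame = f)
    R <- if (all(is.finite(c(xb[f, ], yb[f, ])))) {
      cbind(xb[f, ], yb[f, ], zb[f, ])
    } else diag(3)
    rotations[[f]] <- orthonormalize(R)
    row$x <- if (!is.null(fr$cm)) fr$cm[1] else NA_real_
    row$y <- if (!is.null(fr$cm)) fr$cm[2] else NA_real_
    row$z <- if (!is.null(fr$cm)) fr$cm[3] else NA_real_
    for (side in c("left", "right")) {
      s <- if (side == "left") sL[f, ] else sR[f, ]
      cc <- if (side == "left") cL[f, ] else cR[f, ]
      vt <- if (side == "left") vL[f, ] else vR[f, ]
      pref <- paste0("_", side)
      ang <- list(phi = NA_real_, theta = NA_real_, psi = NA_real_)
      psis <- empty_psi
      if (all(is.finite(s)) && all(is.finite(c(xb[f, ], yb[f, ])))) {
        wfeat <- feats[[f]][[side]]
        lin <- fr[[if (side == "left") "h_left" else "h_right"]]
        # chord refinement through the LE/TE hulls
        cc2 <- cc
        if (length(lin) && all(is.finite(vt))) {
          sp <- if (vec_norm(vt) >= 0.1 * vmax[[side]]) vt else
            held_dir[[side]]
          if (!is.null(sp)) {
            held_dir[[side]] <- sp
            hw <- hull(fr$grid, lin)
            if (!identical(fr$epoch, cur_epoch)) {
              cur_ctx <- carve_context(fr$grid, rig)
              cur_epoch <- fr$epoch
            }
            et <- edge_stage(hw, rig, wfeat, sp, xb[f, ], yb[f, ], side,
                             fr$cm, nsec, cc, cur_ctx, Lw)
            if (!is.null(et)) {
              if (all(is.finite(et$c))) cc2 <- et$c
              psis <- et$psis
            }
          }
        }
        if (all(is.finite(cc2))) {
          a <- wing_angles_from_vectors(s, cc2, side, xb[f, ], yb[f, ])
          if (!isTRUE(a$gimbal)) ang <- a[c("phi", "theta", "psi")]
        } else {
          a <- wing_angles_from_vectors(s, s, side, xb[f, ], yb[f, ])
          if (!isTRUE(a$gimbal)) {
            ang$phi <- a$phi; ang$theta <- a$theta
          }
        }
      }
      row[paste0(c("phi", "theta", "psi"), pref)] <- ang
      row[paste0("psi", seq_len(nsec), pref)] <- psis
    }
    row$flags <- paste(fr$flags, collapse = ";")
    out[[f]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  kin <- do.call(rbind, out)
  list(kinematics = kin, rotations = rotations,
       spans = list(left = sL, right = sR))
}

# reprojection -> LE/TE split -> edge hulls -> plane/final chord -> local
# pitch profile, for one wing in one frame
edge_stage <- function(hw, rig, wfeat, tipvel, x_b, y_b, side, cm_b, nsec,
                       c_init, ctx = NULL, Lw = 2.5e-3) {
  masks <- reproject_wing(hw, rig)
  edges <- vector("list", length(rig$cameras))
  for (j in seq_along(rig$cameras)) {
    cam <- rig$cameras[[j]]
    cm2 <- project_point(cam, wfeat$cm_w)
    tip2 <- project_point(cam, wfeat$tip)
    v2 <- project_point(cam, wfeat$cm_w + tipvel * 1e-6) - cm2
    edges[[j]] <- extract_le_te(masks[[j]], cm2, tip2 - cm2, v2)
  }
  eh <- edge_hulls(edges, hw, rig, wfeat$cm_w,
                   if (all(is.finite(c_init))) c_init else
                     wing_pitch_basis(wfeat$s, side, x_b, y_b)$e2,
                   ctx = ctx, wing_masks = masks)
  if (!length(eh$h_le$lin) || !length(eh$h_te$lin)) return(NULL)
  pl <- wing_plane_and_final_chord(eh$h_le, eh$h_te, wfeat$s, c_init)
  basis <- wing_pitch_basis(wfeat$s, side, x_b, y_b)
  psis <- as.list(rep(NA_real_, nsec))
  # deformation profile and refined chord by hull tangency on the
  # plane-trimmed wing voxels, anchored at the estimated wing root (one
  # wing length inboard of the refined tip)
  root <- wfeat$tip - Lw * wfeat$s
  hw_trim <- if (!is.null(wfeat$trimmed_lin) && length(wfeat$trimmed_lin) > 8)
    hull(hw$grid, wfeat$trimmed_lin) else hw
  lc <- tryCatch(
    hull_local_chords(hw_trim, root, wfeat$s, basis, nsec,
                      c_ref = if (all(is.finite(c_init))) c_init else NULL,
                      wing_length = Lw),
    error = function(e) NULL)
  cfin <- c_init
  if (!is.null(lc)) {
    psis <- as.list(lc$psi_k)
    # global chord from the outer-span stations: the root stations sit in
    # the wing-body occlusion zone and are the least reliable
    sel <- is.finite(lc$psi_k) & lc$station >= 0.5
    if (sum(sel) >= 2) {
      w <- pmin(lc$n_le[sel], lc$n_te[sel])
      v <- colSums(as.matrix(lc[sel, c("cx", "cy", "cz")]) * w)
      v <- v - sum(v * wfeat$s) * wfeat$s
      if (vec_norm(v) > 1e-12) cfin <- unit(v)
    } else {
      ch <- attr(lc, "chord")
      if (!is.null(ch) && all(is.finite(ch)) &&
          sum(is.finite(lc$psi_k)) >= 2) cfin <- ch
    }
  }
  list(c = cfin, psis = psis, h_le = eh$h_le, h_te = eh$h_te,
       plane = pl)
}

#' Validate the pipeline on a synthetic sequence
#'
#' Renders a ground-truth pose sequence, runs the full pipeline on the
#' silhouettes, removes the per-angle constant convention offset (median
#' error) and reports the standard deviation of the remaining errors —
#' the accuracy statistic of the synthetic validation experiment.
#'
#' @param seq a `pose_sequence`.
#' @param rig a `camera_rig`.
#' @param config a [flyhull_config()].
#' @param stacks optional pre-rendered stacks (to skip re-rendering).
#' @return list of class `flyhull_validation`: `sd` (named vector of error
#'   SDs, deg), `errors` (per-frame error table), `result`, `n_excluded`.
#' @export
validate_on_synthetic <- function(seq, rig, config = flyhull_config(),
                                  stacks = NULL) {
  if (is.null(stacks)) {
    stacks <- lapply(render_sequence(seq, rig), `[[`, "full")
  } else if (is.list(stacks[[1]])) {
    stacks <- lapply(stacks, `[[`, "full")
  }
  fps <- seq$frequency * seq$frames_per_wingbeat
  res <- run_pipeline(stacks, rig, fps, config)
  truth <- sequence_truth(seq)
  kin <- res$kinematics
  wrap <- function(x) ((x + 180) %% 360) - 180
  cols <- c("phi_left", "theta_left", "psi_left",
            "phi_right", "theta_right", "psi_right",
            "yaw", "pitch", "roll")
  errs <- data.frame(frame = kin$frame)
  for (cn in cols) errs[[cn]] <- wrap(kin[[cn]] - truth[[cn]])
  flagged <- nchar(kin$flags) > 0
  sd_off <- function(e, use) {
    e <- e[use & is.finite(e)]
    if (length(e) < 3) return(NA_real_)
    stats::sd(e - stats::median(e))
  }
  use <- !flagged
  sds <- c(
    phi = sd_off(c(errs$phi_left, errs$phi_right), rep(use, 2)),
    theta = sd_off(c(errs$theta_left, errs$theta_right), rep(use, 2)),
    psi = sd_off(c(errs$psi_left, errs$psi_right), rep(use, 2)),
    yaw = sd_off(errs$yaw, use),
    pitch = sd_off(errs$pitch, use),
    roll = sd_off(errs$roll, use))
  structure(list(sd = sds, errors = errs, result = res,
                 n_excluded = sum(flagged), n_frames = nrow(kin)),
            class = "flyhull_validation")
}

#' @export
print.flyhull_validation <- function(x, ...) {
  cat("Synthetic validation: SD of pose errors after offset removal (deg)\n")
  print(round(x$sd, 3))
  cat(sprintf("%d of %d frames flagged and excluded\n", x$n_excluded,
              x$n_frames))
  invisible(x)
}
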