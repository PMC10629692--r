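# Z-buffered silhouette rasterization of the posed fly model. Silhouettes
# are exact binary unions of the projected triangles (no anti-aliasing):
# this is what the real pipeline's thresholding produces. Deterministic for
# fixed inputs.

# Rasterize a list of triangle meshes into a label image and a depth buffer.
# parts: list of list(verts = n x 3 lab coords, tris = m x 3, part = int).
# Returns list(labels = H x W integer matrix [row = y, col = x], depth).
rasterize_parts <- function(parts, camera) {
  W <- camera$image_size[1]; H <- camera$image_size[2]
  labels <- matrix(0L, H, W)
  depth <- matrix(Inf, H, W)
  P <- camera$P
  # normalize so the third homogeneous row yields metric depth
  s3 <- vec_norm(P[3, 1:3]) * sign(det(P[, 1:3]))
  for (part in parts) {
    V <- part$verts
    h <- V %*% t(P[, 1:3]) + matrix(P[, 4], nrow(V), 3, byrow = TRUE)
    z <- h[, 3] / s3
    if (any(z <= 0)) next   # part (partly) behind the camera: skip
    px <- h[, 1] / h[, 3]
    py <- h[, 2] / h[, 3]
    tr <- part$tris
    for (m in seq_len(nrow(tr))) {
      i1 <- tr[m, 1]; i2 <- tr[m, 2]; i3 <- tr[m, 3]
      x1 <- px[i1]; x2 <- px[i2]; x3 <- px[i3]
      y1 <- py[i1]; y2 <- py[i2]; y3 <- py[i3]
      xa <- max(1L, as.integer(ceiling(min(x1, x2, x3) - 1e-9)))
      xb <- min(W, as.integer(floor(max(x1, x2, x3) + 1e-9)))
      ya <- max(1L, as.integer(ceiling(min(y1, y2, y3) - 1e-9)))
      yb <- min(H, as.integer(floor(max(y1, y2, y3) + 1e-9)))
      if (xa > xb || ya > yb) next
      den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
      if (abs(den) < 1e-14) next
      xs <- rep(xa:xb, each = yb - ya + 1L)
      ys <- rep(ya:yb, times = xb - xa + 1L)
      l1 <- ((y2 - y3) * (xs - x3) + (x3 - x2) * (ys - y3)) / den
      l2 <- ((y3 - y1) * (xs - x3) + (x1 - x3) * (ys - y3)) / den
      l3 <- 1 - l1 - l2
      tol <- -1e-9
      ins <- l1 >= tol & l2 >= tol & l3 >= tol
      if (!any(ins)) next
      zz <- l1[ins] * z[i1] + l2[ins] * z[i2] + l3[ins] * z[i3]
      lin <- (xs[ins] - 1L) * H + ys[ins]
      upd <- zz < depth[lin]
      if (any(upd)) {
        lin <- lin[upd]
        depth[lin] <- zz[upd]
        labels[lin] <- part$part
      }
    }
  }
  list(labels = labels, depth = depth)
}

part_ids <- c(body = 1L, wing_left = 2L, wing_right = 3L)

#' Render per-camera binary silhouettes of a posed fly
#'
#' Z-buffered rasterization at each camera's resolution. Besides the full
#' silhouette, per-part visible masks (what each camera actually sees of
#' each part, occlusions applied) and, optionally, each part rendered alone
#' are returned, so tests and the visibility analysis know ground-truth
#' occlusion.
#'
#' @param posed output of [pose_model()].
#' @param rig a `camera_rig`.
#' @param alone also render each part on its own (default `FALSE`).
#' @return list (one element per camera) with `full`, `body`, `wing_left`,
#'   `wing_right` logical masks (`dim = c(height, width)`), `labels`,
#'   `depth`, and `alone` (when requested). A camera seeing nothing gets an
#'   empty image with a warning.
#' @export
render_silhouettes <- function(posed, rig, alone = FALSE) {
  parts <- lapply(names(part_ids), function(nm) {
    p <- posed$parts[[nm]]
    list(verts = p$verts, tris = p$tris, part = part_ids[[nm]])
  })
  out <- lapply(rig$cameras, function(cam) {
    ras <- rasterize_parts(parts, cam)
    full <- ras$labels > 0L
    if (!any(full)) {
      warning("camera ", cam$id, ": model projects entirely outside the image")
    }
    res <- list(full = full,
                body = ras$labels == part_ids[["body"]],
                wing_left = ras$labels == part_ids[["wing_left"]],
                wing_right = ras$labels == part_ids[["wing_right"]],
                labels = ras$labels, depth = ras$depth)
    if (alone) {
      res$alone <- lapply(seq_along(parts), function(k) {
        rasterize_parts(parts[k], cam)$labels > 0L
      })
      names(res$alone) <- names(part_ids)
    }
    res
  })
  names(out) <- paste0("camera", vapply(rig$cameras, `[[`, integer(1), "id"))
  out
}

#' Voxelize a posed fly (inner voxelization)
#'
#' Marks the voxels whose centers lie inside the posed model with a safety
#' margin: body voxels at least `margin` inside the body surface, wing
#' voxels inside the wing slab with in-plane margin `margin` and
#' through-thickness margin 0.75 pitch. The margins make the voxelization a
#' strict subset of what any consistent silhouette rasterization can see,
#' so the visual-hull superset property can be asserted exactly.
#'
#' Only the rigid (untwisted) wing is supported.
#'
#' @param posed output of [pose_model()] with `twist_deg = 0`.
#' @param grid a `voxel_grid`.
#' @param margin in-surface margin (m); default one voxel pitch.
#' @return a `hull` of true-model voxels.
#' @export
voxelize_fly <- function(posed, grid, margin = grid$pitch) {
  if (posed$truth$twist_deg != 0) {
    stop("voxelize_fly supports only the rigid (untwisted) wing")
  }
  model <- posed$model
  d <- grid$dims
  # candidate voxels: model bounding box only
  allv <- rbind(posed$parts$body$verts, posed$parts$wing_left$verts,
                posed$parts$wing_right$verts)
  lo <- pmax(1L, floor((apply(allv, 2, min) - grid$origin) / grid$pitch) + 1L)
  hi <- pmin(d, ceiling((apply(allv, 2, max) - grid$origin) / grid$pitch) + 1L)
  if (any(lo > hi)) return(hull(grid))
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  ctr <- voxel_centers(grid, idx)
  inside <- rep(FALSE, nrow(ctr))

  # body: 6-point offset test against the implicit tapered ellipsoid
  R <- posed$truth$R; pos <- posed$truth$position
  body_in <- function(pts) {
    pb <- sweep(pts, 2, pos) %*% R         # lab -> body frame
    x <- pb[, 1]
    ok <- abs(x) < model$L_b / 2
    u <- acos(pmax(-1, pmin(1, 2 * x / model$L_b)))
    rad <- sqrt(pb[, 2]^2 + pb[, 3]^2)
    ok & rad <= body_radius_profile(u, model$body_width / 2)
  }
  # offsets at sqrt(3) * margin: the convex hull of the 6 axis points of a
  # convex body contains the ball of radius `margin`, which covers the
  # worst-case diagonal pixel-rounding displacement
  off <- rbind(diag(3), -diag(3)) * sqrt(3) * margin
  bin <- body_in(ctr)
  for (o in seq_len(6)) {
    keep <- which(bin)
    if (!length(keep)) break
    bin[keep] <- body_in(sweep(ctr[keep, , drop = FALSE], 2, off[o, ], "+"))
  }
  inside <- inside | bin

  # wings: analytic slab test with explicit margins
  o <- model$outline
  for (side in c("left", "right")) {
    w <- posed$parts[[paste0("wing_", side)]]
    rel <- sweep(ctr, 2, w$hinge)
    r <- rel %*% w$s
    q <- rel %*% w$c
    h <- rel %*% w$n_wing
    t_span <- as.numeric(r) / model$L_w
    ok <- t_span > margin / model$L_w & t_span < 1 - margin / model$L_w &
      abs(h) <= model$wing_thickness / 2 - 0.75 * grid$pitch
    if (any(ok)) {
      g <- wing_chord_profile(t_span[ok])
      le <- model$le_frac * model$max_chord * g
      te <- -(1 - model$le_frac) * model$max_chord * g
      ok[ok] <- q[ok] <= le - margin & q[ok] >= te + margin
    }
    inside <- inside | ok
  }
  hull(grid, idx[inside, , drop = FALSE])
}
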