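# Per-wing geometric features, extracted in the refinement ladder: mid-span
# voxel strip -> CM -> provisional tip -> cone-refined tip -> span ->
# 2-means chord -> strip re-cut -> reprojection to the image planes (which
# reveals wing pixels occluded in the raw views) -> LE/TE boundary hulls ->
# wing plane, final chord and local chord (deformation) profile.

#' Refine body axis and center of mass from the body hull
#'
#' The initial axis is the first principal component of the body-hull voxel
#' coordinates; the hull is then split into head and tail blobs (front/back
#' quartiles along that axis), the axis refined as the tail-to-head
#' unit vector, and the center of mass as the blob midpoint. Head/tail
#' disambiguation uses temporal continuity (`prev_xb`) or, on the first
#' frame, a flight-direction prior.
#'
#' @param h_body body `hull`.
#' @param prev_xb previous-frame body axis (preferred disambiguator).
#' @param forward_hint lab-frame prior for the flight direction (first
#'   frame only).
#' @return list with `cm`, `xb` (unit), `head_cm`, `tail_cm`, `flags`.
#' @export
head_tail_refine <- function(h_body, prev_xb = NULL,
                             forward_hint = c(1, 0, 0)) {
  xyz <- hull_coords(h_body)
  if (nrow(xyz) < 4L) stop("body hull too small")
  flags <- character(0)
  cm0 <- colMeans(xyz)
  cc <- sweep(xyz, 2, cm0)
  sv <- svd(cc, nu = 0, nv = 3)
  ax <- sv$v[, 1]
  if (sv$d[1] < 1.5 * sv$d[2]) {
    flags <- c(flags, "degenerate_body_hull")
    ref <- if (!is.null(prev_xb)) prev_xb else forward_hint
    if (sum(ax * ref) < 0) ax <- -ax
    return(list(cm = cm0, xb = ax, head_cm = cm0, tail_cm = cm0,
                flags = flags))
  }
  t <- as.numeric(cc %*% ax)
  qs <- stats::quantile(t, c(0.25, 0.75))
  blob_lo <- colMeans(xyz[t <= qs[1], , drop = FALSE])
  blob_hi <- colMeans(xyz[t >= qs[2], , drop = FALSE])
  xb <- unit(blob_hi - blob_lo)
  ref <- if (!is.null(prev_xb)) prev_xb else forward_hint
  if (sum(xb * ref) < 0) {
    xb <- -xb
    tmp <- blob_lo; blob_lo <- blob_hi; blob_hi <- tmp
  }
  list(cm = (blob_lo + blob_hi) / 2, xb = xb, head_cm = blob_hi,
       tail_cm = blob_lo, flags = flags)
}

#' Mid-span voxel strip of a wing hull
#'
#' Voxels whose distance from the body center of mass lies between
#' `bounds[1]` and `bounds[2]` of the wing length (defaults 0.40 and 0.65).
#' If the strip is empty, one widened attempt (0.35-0.70) is made and
#' flagged; a still-empty strip marks the wing unresolvable for the frame.
#'
#' @param h_wing wing `hull`.
#' @param r_cm_b body center of mass (m).
#' @param wing_length wing length (m).
#' @param bounds radial bounds as fractions of `wing_length`.
#' @return list with `lin` (linear voxel indices), `coords`, `flags`.
#' @export
wing_strip <- function(h_wing, r_cm_b, wing_length, bounds = c(0.40, 0.65)) {
  if (wing_length <= 0) stop("wing_length must be positive")
  xyz <- hull_coords(h_wing)
  d <- sqrt(rowSums(sweep(xyz, 2, r_cm_b)^2))
  sel <- d >= bounds[1] * wing_length & d <= bounds[2] * wing_length
  flags <- character(0)
  if (!any(sel)) {
    flags <- "strip_widened"
    sel <- d >= 0.35 * wing_length & d <= 0.70 * wing_length
    if (!any(sel)) {
      return(list(lin = numeric(0), coords = xyz[0, , drop = FALSE],
                  flags = c(flags, "wing_unresolvable")))
    }
  }
  list(lin = h_wing$lin[sel], coords = xyz[sel, , drop = FALSE],
       flags = flags)
}

#' Wing center of mass, tip and span vector with cone refinement
#'
#' The wing CM is the strip CM; the tip starts as the farthest wing voxel
#' from the body CM; the span as CM-to-tip. The tip is then refined as the
#' CM of the cone base: hull voxels within half-angle `alpha` of the span
#' axis (apex at the wing CM) beyond radial fraction `beta` of the wing
#' extent; the span is updated from the refined tip.
#'
#' @param h_wing wing `hull`.
#' @param strip output of [wing_strip()].
#' @param r_cm_b body center of mass.
#' @param alpha cone half-angle (deg).
#' @param beta base region start, fraction of the maximum radial extent.
#' @return list with `cm_w`, `tip`, `s` (unit span), `flags`.
#' @export
estimate_span_tip <- function(h_wing, strip, r_cm_b, alpha = 30, beta = 0.8) {
  flags <- strip$flags
  if (!length(strip$lin)) stop("empty strip")
  cm_w <- colMeans(strip$coords)
  xyz <- hull_coords(h_wing)
  d_body <- sqrt(rowSums(sweep(xyz, 2, r_cm_b)^2))
  tip0 <- xyz[which.max(d_body), ]
  if (vec_norm(tip0 - cm_w) < 1e-12) {
    return(list(cm_w = cm_w, tip = tip0, s = c(NA, NA, NA),
                flags = c(flags, "degenerate_single_voxel")))
  }
  s0 <- unit(tip0 - cm_w)
  rel <- sweep(xyz, 2, cm_w)
  r <- sqrt(rowSums(rel^2))
  proj <- as.numeric(rel %*% s0)
  with_r <- r > 1e-12
  cosang <- rep(-1, length(r))
  cosang[with_r] <- proj[with_r] / r[with_r]
  in_cone <- cosang >= cos(deg2rad(alpha)) & r >= beta * max(r)
  if (any(in_cone)) {
    tip <- colMeans(xyz[in_cone, , drop = FALSE])
  } else {
    tip <- tip0
    flags <- c(flags, "empty_cone_base")
  }
  list(cm_w = cm_w, tip = tip, s = unit(tip - cm_w), flags = flags)
}

#' Initial chord direction by 2-means on the strip
#'
#' k-means with k = 2 on the strip voxel coordinates separates the
#' leading-side and trailing-side halves of the wing plate; the chord is
#' the unit vector between the cluster CMs, orthogonalized against the
#' span. The sign is aligned with `ref_dir` (trailing-to-leading
#' disambiguator, e.g. the previous chord or the stroke-plane normal);
#' without a reference the sign is arbitrary and flagged.
#'
#' @param strip_coords n x 3 strip voxel coordinates.
#' @param s unit span vector.
#' @param ref_dir optional sign reference.
#' @param pitch voxel pitch (m), for the separability check.
#' @return list with `c` (unit chord, `NA` when deferred), `flags`.
#' @export
estimate_chord_initial <- function(strip_coords, s, ref_dir = NULL,
                                   pitch = 0) {
  if (nrow(strip_coords) < 2L) {
    return(list(c = c(NA, NA, NA), flags = "chord_deferred"))
  }
  # initialize at the two voxels extreme along the first transverse PC
  cc <- sweep(strip_coords, 2, colMeans(strip_coords))
  cc <- cc - (cc %*% s) %*% t(s)
  v1 <- svd(cc, nu = 0, nv = 1)$v[, 1]
  tproj <- as.numeric(cc %*% v1)
  init <- strip_coords[c(which.max(tproj), which.min(tproj)), , drop = FALSE]
  if (vec_norm(init[1, ] - init[2, ]) < 1e-12) {
    return(list(c = c(NA, NA, NA), flags = "chord_deferred"))
  }
  km <- suppressWarnings(stats::kmeans(strip_coords, centers = init,
                                       iter.max = 50))
  dcm <- km$centers[1, ] - km$centers[2, ]
  if (vec_norm(dcm) < 2 * pitch) {
    return(list(c = c(NA, NA, NA), flags = "chord_deferred"))
  }
  cv <- dcm - sum(dcm * s) * s
  if (vec_norm(cv) < 1e-12) {
    return(list(c = c(NA, NA, NA), flags = "chord_deferred"))
  }
  cv <- unit(cv)
  flags <- character(0)
  if (!is.null(ref_dir)) {
    if (sum(cv * ref_dir) < 0) cv <- -cv
  } else {
    flags <- "chord_sign_arbitrary"
  }
  list(c = cv, flags = flags)
}

#' Full refinement ladder for one wing hull
#'
#' Runs strip -> CM/tip/span -> initial chord, then one refinement pass:
#' the span direction is re-estimated as the first principal (inertia) axis
#' of the wing-hull voxels, which — unlike the CM-to-tip line — is not
#' biased by the chordwise asymmetry of the wing outline (the area centroid
#' of a wing section sits toward the trailing edge, tilting the CM-to-tip
#' line by several degrees; the inertia axis is insensitive to that
#' first-moment offset). The tip is then cone-refined along the new axis,
#' the strip is re-cut as a slab perpendicular to it, and the chord is
#' recomputed. If the inertia axis disagrees with the CM-to-tip line by
#' more than 25 deg (occlusion artifacts), the ladder keeps the CM-to-tip
#' estimate and flags the frame.
#'
#' @param h_wing wing `hull`.
#' @param r_cm_b body center of mass.
#' @param wing_length wing length (m).
#' @param ref_dir chord-sign reference (see [estimate_chord_initial()]).
#' @param alpha,beta cone parameters of [estimate_span_tip()].
#' @return list with `cm_w`, `tip`, `s`, `c`, `strip_lin`, `flags`.
#' @export
wing_features <- function(h_wing, r_cm_b, wing_length, ref_dir = NULL,
                          alpha = 30, beta = 0.8) {
  strip <- wing_strip(h_wing, r_cm_b, wing_length)
  if (!length(strip$lin)) {
    return(list(cm_w = NULL, tip = NULL, s = NULL, c = NULL,
                strip_lin = numeric(0), flags = strip$flags))
  }
  st <- estimate_span_tip(h_wing, strip, r_cm_b, alpha, beta)
  ch <- estimate_chord_initial(strip$coords, st$s, ref_dir, h_wing$grid$pitch)
  flags <- unique(c(st$flags, ch$flags))
  if (!all(is.finite(st$s))) {
    return(list(cm_w = st$cm_w, tip = st$tip, s = st$s, c = ch$c,
                strip_lin = strip$lin, flags = flags))
  }
  # refinement pass: trimmed inertia-axis span, cone tip along it, slab
  # re-cut. The trim iterates a total-least-squares plane fit and drops
  # voxels farther than 3 pitches from the plane: occlusion ghosts and
  # voxels mis-assigned from the other wing (the failure mode when the
  # wings meet at the end of the back-stroke) are off-plane and get
  # rejected, while the thin wing slab survives.
  xyz <- hull_coords(h_wing)
  sel <- rep(TRUE, nrow(xyz))
  for (it in 1:3) {
    xs <- xyz[sel, , drop = FALSE]
    if (nrow(xs) < 8L) { sel <- rep(TRUE, nrow(xyz)); break }
    cmp <- colMeans(xs)
    nrm <- svd(sweep(xs, 2, cmp), nu = 0, nv = 3)$v[, 3]
    dn <- abs(as.numeric(sweep(xyz, 2, cmp) %*% nrm))
    sel <- dn < 3 * h_wing$grid$pitch
  }
  xs <- xyz[sel, , drop = FALSE]
  v1 <- svd(sweep(xs, 2, colMeans(xs)), nu = 0, nv = 1)$v[, 1]
  if (sum(v1 * st$s) < 0) v1 <- -v1
  if (sum(v1 * st$s) < cos(deg2rad(25))) {
    flags <- c(flags, "span_axis_disagreement")
  } else {
    rr_all <- as.numeric(sweep(xyz, 2, r_cm_b) %*% v1)
    sel2 <- sel & rr_all >= 0.40 * wing_length & rr_all <= 0.65 * wing_length
    if (sum(sel2) >= 2L) {
      strip2 <- list(lin = h_wing$lin[sel2],
                     coords = xyz[sel2, , drop = FALSE],
                     flags = character(0))
      cm_w2 <- colMeans(strip2$coords)
      # cone-refined tip along the trimmed inertia axis
      rel <- sweep(xs, 2, cm_w2)
      r <- sqrt(rowSums(rel^2))
      proj <- as.numeric(rel %*% v1)
      cosang <- ifelse(r > 1e-12, proj / r, -1)
      in_cone <- cosang >= cos(deg2rad(alpha)) & r >= beta * max(r)
      tip2 <- if (any(in_cone)) colMeans(xs[in_cone, , drop = FALSE]) else
        st$tip
      ref2 <- if (!is.null(ch$c) && all(is.finite(ch$c))) ch$c else ref_dir
      ch2 <- estimate_chord_initial(strip2$coords, v1, ref2,
                                    h_wing$grid$pitch)
      st <- list(cm_w = cm_w2, tip = tip2, s = v1, flags = character(0))
      strip <- strip2
      if (all(is.finite(ch2$c))) ch <- ch2
      flags <- unique(c(flags, ch2$flags))
    }
  }
  list(cm_w = st$cm_w, tip = st$tip, s = st$s, c = ch$c,
       strip_lin = strip$lin, trimmed_lin = h_wing$lin[sel], flags = flags)
}

#' Reproject a wing hull to the image planes
#'
#' Rounded pixels of all wing-hull voxels per camera, morphologically
#' closed (one 3x3 iteration) to seal rounding gaps. Because the hull
#' combines information from every view, the reprojected masks contain
#' wing pixels that are occluded by the body or the other wing in that
#' camera's raw image.
#'
#' @param h_wing wing `hull`.
#' @param rig a `camera_rig`.
#' @return list of logical masks (`dim = c(height, width)`), one per camera.
#' @export
reproject_wing <- function(h_wing, rig) {
  idx <- hull_indices(h_wing)
  lapply(rig$cameras, function(cam) {
    H <- cam$image_size[2]; W <- cam$image_size[1]
    m <- matrix(FALSE, H, W)
    pv <- project_voxels(cam, h_wing$grid, idx)
    ok <- pv$in_image
    if (any(ok)) {
      m[(pv$px[ok] - 1L) * H + pv$py[ok]] <- TRUE
      m <- close_mask(m)
    }
    m
  })
}

# one iteration of 3x3 morphological closing, cropped for speed
close_mask <- function(m) {
  w <- which(m)
  if (!length(w)) return(m)
  H <- nrow(m)
  ys <- (w - 1) %% H + 1; xs <- (w - 1) %/% H + 1
  y0 <- max(1, min(ys) - 2); y1 <- min(H, max(ys) + 2)
  x0 <- max(1, min(xs) - 2); x1 <- min(ncol(m), max(xs) + 2)
  sub <- m[y0:y1, x0:x1, drop = FALSE]
  k <- EBImage::makeBrush(3, "box")
  sub2 <- EBImage::closing(EBImage::Image(sub * 1), k) > 0.5
  m[y0:y1, x0:x1] <- as.matrix(sub2)
  m
}

# one-pixel 3x3 dilation via shifted logical OR (restricted to the content
# bounding box for speed)
dilate_mask <- function(m) {
  w <- which(m)
  if (!length(w)) return(m)
  H <- nrow(m); W <- ncol(m)
  ys <- (w - 1) %% H + 1; xs <- (w - 1) %/% H + 1
  y0 <- max(1, min(ys) - 1); y1 <- min(H, max(ys) + 1)
  x0 <- max(1, min(xs) - 1); x1 <- min(W, max(xs) + 1)
  sub <- m[y0:y1, x0:x1, drop = FALSE]
  h <- nrow(sub); wd <- ncol(sub)
  pad <- matrix(FALSE, h + 2, wd + 2)
  pad[2:(h + 1), 2:(wd + 1)] <- sub
  out <- sub
  for (dy in -1:1) for (dx in -1:1) {
    out <- out | pad[(2 + dy):(h + 1 + dy), (2 + dx):(wd + 1 + dx)]
  }
  m[y0:y1, x0:x1] <- out
  m
}

# boundary pixels: mask pixels with at least one background 4-neighbor
mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  m & !inner
}

#' Split a reprojected wing mask boundary into leading and trailing edges
#'
#' The boundary pixels are split by the image-plane line through the
#' projected wing CM along the projected span; the side containing the
#' projected tip-velocity direction is the leading edge. Cameras in which
#' the wing is edge-on (projected span shorter than `min_span_px`) are
#' excluded.
#'
#' @param mask reprojected wing mask (logical, `dim = c(height, width)`).
#' @param cm2d projected wing CM (pixel x, y).
#' @param span2d projected span direction (pixel frame, need not be unit).
#' @param tipvel2d projected tip-velocity direction (pixel frame).
#' @param min_span_px minimum usable projected span length (px).
#' @param min_width_px minimum mean projected chord width (mask area over
#'   projected span length, px); cameras seeing the wing nearly edge-on
#'   chordwise carry no usable LE/TE separation and are excluded.
#' @return list with `le`, `te` (n x 2 matrices of pixel x, y), `usable`.
#' @export
extract_le_te <- function(mask, cm2d, span2d, tipvel2d, min_span_px = 3,
                          min_width_px = 2.5) {
  if (vec_norm(span2d) < min_span_px || !any(mask)) {
    return(list(le = NULL, te = NULL, usable = FALSE))
  }
  if (sum(mask) / vec_norm(span2d) < min_width_px) {
    return(list(le = NULL, te = NULL, usable = FALSE))
  }
  b <- mask_boundary(mask)
  w <- which(b)
  H <- nrow(mask)
  py <- (w - 1) %% H + 1
  px <- (w - 1) %/% H + 1
  sp <- unit(span2d)
  side <- (px - cm2d[1]) * sp[2] - (py - cm2d[2]) * sp[1]  # 2D cross product
  vel_side <- tipvel2d[1] * sp[2] - tipvel2d[2] * sp[1]
  if (abs(vel_side) < 1e-12) {
    return(list(le = NULL, te = NULL, usable = FALSE))
  }
  le_sel <- side * sign(vel_side) > 0
  list(le = cbind(x = px[le_sel], y = py[le_sel]),
       te = cbind(x = px[!le_sel], y = py[!le_sel]), usable = TRUE)
}

#' Carve leading- and trailing-edge hulls
#'
#' Boundary pixels seen in different cameras correspond to different 3D
#' wing points (an obliquely viewed camera's silhouette boundary is not
#' the planform outline), so the edge hulls are built the same way as the
#' occlusion-resolving expanded hulls: for each usable camera, its LE
#' (resp. TE) pixel set is carved together with the reprojected wing masks
#' of the other cameras, and the per-camera hulls are united. Everything
#' is restricted to a one-voxel-dilated shell of the wing hull. The
#' one-pixel-wide boundary masks are dilated by one pixel to tolerate
#' rounding. Voxels claimed by both edges are resolved by the sign of
#' their chordwise coordinate (distance along the trailing-to-leading
#' chord direction from the wing CM).
#'
#' @param edges per-camera output of [extract_le_te()].
#' @param h_wing wing `hull`.
#' @param rig a `camera_rig`.
#' @param cm_w wing CM; `c_ref` trailing-to-leading chord direction.
#' @param ctx optional `carve_context` for the wing hull's grid (built on
#'   the fly when absent).
#' @param wing_masks per-camera reprojected wing masks from
#'   [reproject_wing()] (recomputed when absent).
#' @return list with `h_le`, `h_te` (hulls), `n_usable`, `flags`.
#' @export
edge_hulls <- function(edges, h_wing, rig, cm_w, c_ref, ctx = NULL,
                       wing_masks = NULL) {
  usable <- which(vapply(edges, function(e) isTRUE(e$usable), logical(1)))
  g <- h_wing$grid
  if (length(usable) < 2L) {
    return(list(h_le = hull(g), h_te = hull(g), n_usable = length(usable),
                flags = "edges_too_few_cameras"))
  }
  if (is.null(ctx)) ctx <- carve_context(g, rig)
  if (is.null(wing_masks)) wing_masks <- reproject_wing(h_wing, rig)
  shell <- hull_dilate(h_wing)
  px_mask <- function(pts, cam) {
    H <- cam$image_size[2]
    m <- matrix(FALSE, H, cam$image_size[1])
    m[(pts[, 1] - 1L) * H + pts[, 2]] <- TRUE
    dilate_mask(m)
  }
  wing_dil <- lapply(wing_masks, dilate_mask)
  mk <- function(field) {
    lin <- numeric(0)
    for (j in usable) {
      masks <- wing_dil
      masks[[j]] <- px_mask(edges[[j]][[field]], rig$cameras[[j]])
      h <- suppressWarnings(carve(ctx, masks, subset = shell$lin))
      lin <- c(lin, h$lin)
    }
    hull(g, lin)
  }
  h_le <- mk("le")
  h_te <- mk("te")
  both <- intersect(h_le$lin, h_te$lin)
  if (length(both)) {
    q <- as.numeric(sweep(voxel_centers(g, both), 2, cm_w) %*% c_ref)
    to_le <- both[q > 0]
    h_le <- hull(g, setdiff(h_le$lin, both[q <= 0]))
    h_te <- hull(g, setdiff(h_te$lin, to_le))
  }
  list(h_le = h_le, h_te = h_te, n_usable = length(usable),
       flags = character(0))
}

#' Local chord vectors and local pitch profile along the span
#'
#' The span axis is divided into `n_sections` equal radial bins between the
#' innermost and outermost edge voxels. Per bin, the local chord runs from
#' the trailing-edge to the leading-edge tangency points: the visual hull
#' is exact at silhouette-generating contours, so within each bin the edge
#' voxels extreme along the current chord direction (within one voxel
#' pitch of the extreme) are averaged into the LE and TE points. Plain
#' bin means would inherit the tilt of the asymmetric hull wedge around
#' the thin wing; the extremes do not. The local pitch `psi_k` is the
#' signed rotation of the local chord about the span axis, measured
#' against the stroke-plane reference chord (the wing-pitch convention of
#' [wing_angles_from_vectors()]).
#'
#' @param h_le,h_te edge hulls.
#' @param origin root reference point (body CM or hinge).
#' @param s unit span vector.
#' @param basis list with unit vectors `c0` (reference chord) and `e2`
#'   (quarter-turn direction) for the wing side, from
#'   [wing_pitch_basis()].
#' @param n_sections number of spanwise bins (default 5).
#' @param c_ref current chord direction used to pick the tangency
#'   extremes; defaults to the dominant transverse direction of the edge
#'   voxels.
#' @param iterations extreme-selection refinement iterations (the chord
#'   direction from one pass picks the extremes of the next).
#' @return data.frame: station (bin center, fraction of the span range),
#'   chord vector components, `psi_k` (deg, `NA` where a bin lacks an
#'   edge), `n_le`, `n_te`.
#' @export
local_chords <- function(h_le, h_te, origin, s, basis, n_sections = 5,
                         c_ref = NULL, iterations = 2) {
  if (!length(h_le$lin) || !length(h_te$lin)) {
    stop("both edge hulls must be non-empty")
  }
  pitch <- h_le$grid$pitch
  le <- hull_coords(h_le)
  te <- hull_coords(h_te)
  r_le <- as.numeric(sweep(le, 2, origin) %*% s)
  r_te <- as.numeric(sweep(te, 2, origin) %*% s)
  # quantile-trimmed span range: stray voxels at the wing root (wing-body
  # occlusion zone) and the tip cap would otherwise stretch the bins
  rng <- stats::quantile(c(r_le, r_te), c(0.05, 0.99), names = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_sections + 1)
  if (is.null(c_ref)) {
    # dominant transverse direction, oriented TE -> LE
    all_pts <- rbind(le, te)
    cc <- sweep(all_pts, 2, colMeans(all_pts))
    cc <- cc - (cc %*% s) %*% t(s)
    c_ref <- svd(cc, nu = 0, nv = 1)$v[, 1]
    if (sum(c_ref * (colMeans(le) - colMeans(te))) < 0) c_ref <- -c_ref
  }
  c_est <- unit(c_ref - sum(c_ref * s) * s)
  res <- NULL
  for (it in seq_len(max(1, iterations))) {
    q_le <- as.numeric(le %*% c_est)
    q_te <- as.numeric(te %*% c_est)
    out <- lapply(seq_len(n_sections), function(k) {
      in_le <- r_le >= br[k] & r_le <= br[k + 1]
      in_te <- r_te >= br[k] & r_te <= br[k + 1]
      st <- (k - 0.5) / n_sections
      if (!any(in_le) || !any(in_te)) {
        return(data.frame(station = st, cx = NA, cy = NA, cz = NA,
                          psi_k = NA, n_le = sum(in_le), n_te = sum(in_te)))
      }
      ql <- q_le[in_le]; qt <- q_te[in_te]
      le_pt <- colMeans(le[in_le, , drop = FALSE][ql >= max(ql) - pitch, ,
                                                  drop = FALSE])
      te_pt <- colMeans(te[in_te, , drop = FALSE][qt <= min(qt) + pitch, ,
                                                  drop = FALSE])
      v <- le_pt - te_pt
      v <- v - sum(v * s) * s
      if (vec_norm(v) < 1e-12) {
        return(data.frame(station = st, cx = NA, cy = NA, cz = NA,
                          psi_k = NA, n_le = sum(in_le), n_te = sum(in_te)))
      }
      v <- unit(v)
      psi <- rad2deg(atan2(sum(v * basis$e2), sum(v * basis$c0)))
      data.frame(station = st, cx = v[1], cy = v[2], cz = v[3], psi_k = psi,
                 n_le = sum(in_le), n_te = sum(in_te))
    })
    res <- do.call(rbind, out)
    good <- is.finite(res$psi_k)
    if (!any(good)) break
    cm <- colMeans(res[good, c("cx", "cy", "cz"), drop = FALSE])
    if (vec_norm(cm) < 1e-12) break
    c_est <- unit(cm - sum(cm * s) * s)
  }
  if (all(!is.finite(res$psi_k))) {
    attr(res, "deformation_unavailable") <- TRUE
  }
  attr(res, "chord") <- c_est
  res
}

# Local chords by hull tangency: per spanwise bin, the chord connects the
# wing-hull voxels extreme along the current chord direction (the visual
# hull is exact where silhouette contours graze the wing, so these extremes
# are true leading/trailing-edge boundary points; the carved LE/TE label
# sets are shell-dilated and lose that sharpness). Bins cover
# span_range * wing_length measured along s from the estimated wing root.
hull_local_chords <- function(h_wing, root, s, basis, n_sections = 5,
                              c_ref = NULL, wing_length = NULL,
                              span_range = c(0.08, 0.95), iterations = 2) {
  xyz <- hull_coords(h_wing)
  pitch <- h_wing$grid$pitch
  rr <- as.numeric(sweep(xyz, 2, root) %*% s)
  if (is.null(wing_length)) wing_length <- diff(range(rr))
  # anchor the span stations at the outboard hull extent: the hull is
  # tangency-tight at the tip, whereas the inboard end blurs into the
  # wing-body occlusion zone
  r0 <- stats::quantile(rr, 0.995, names = FALSE) - wing_length
  rr <- rr - r0
  br <- seq(span_range[1], span_range[2],
            length.out = n_sections + 1) * wing_length
  if (is.null(c_ref)) c_ref <- basis$e2
  c_est <- unit(c_ref - sum(c_ref * s) * s)
  res <- NULL
  for (it in seq_len(max(1, iterations))) {
    q <- as.numeric(xyz %*% c_est)
    out <- lapply(seq_len(n_sections), function(k) {
      inb <- rr >= br[k] & rr <= br[k + 1]
      st <- (br[k] + br[k + 1]) / 2 / wing_length
      if (sum(inb) < 4) {
        return(data.frame(station = st, cx = NA, cy = NA, cz = NA,
                          psi_k = NA, n_le = 0L, n_te = 0L))
      }
      qq <- q[inb]
      xs <- xyz[inb, , drop = FALSE]
      sel_le <- qq >= max(qq) - pitch
      sel_te <- qq <= min(qq) + pitch
      # effective station: the extremes cluster where the chord is widest
      # within the bin, not at the bin center
      st <- mean(rr[inb][sel_le | sel_te]) / wing_length
      v <- colMeans(xs[sel_le, , drop = FALSE]) -
        colMeans(xs[sel_te, , drop = FALSE])
      v <- v - sum(v * s) * s
      if (vec_norm(v) < 1e-12) {
        return(data.frame(station = st, cx = NA, cy = NA, cz = NA,
                          psi_k = NA, n_le = sum(sel_le), n_te = sum(sel_te)))
      }
      v <- unit(v)
      psi <- rad2deg(atan2(sum(v * basis$e2), sum(v * basis$c0)))
      data.frame(station = st, cx = v[1], cy = v[2], cz = v[3], psi_k = psi,
                 n_le = sum(sel_le), n_te = sum(sel_te))
    })
    res <- do.call(rbind, out)
    good <- is.finite(res$psi_k)
    if (!any(good)) break
    cm <- colMeans(res[good, c("cx", "cy", "cz"), drop = FALSE])
    if (vec_norm(cm) < 1e-12) break
    c_est <- unit(cm - sum(cm * s) * s)
  }
  attr(res, "chord") <- c_est
  res
}

#' Stroke-plane pitch basis for one wing
#'
#' Reference chord direction (psi = 0) and its quarter-turn companion for
#' the given span vector and side, matching the wing-pitch convention.
#'
#' @param s unit span vector.
#' @param side `"left"` or `"right"`.
#' @param x_b,y_b body axes.
#' @return list with unit vectors `c0` and `e2`.
#' @export
wing_pitch_basis <- function(s, side, x_b, y_b) {
  b <- stroke_basis(x_b, y_b)
  c0 <- if (side == "left") unit(cross3(b$n, s)) else unit(cross3(s, b$n))
  e2 <- if (side == "left") cross3(s, c0) else cross3(c0, s)
  list(c0 = c0, e2 = e2)
}

#' Least-squares wing plane and final chord
#'
#' Fits a plane through the LE and TE voxels (total least squares); the
#' final chord is the mean-LE-minus-mean-TE vector projected into the
#' plane and orthogonalized against the span.
#'
#' @param h_le,h_te edge hulls.
#' @param s unit span vector.
#' @param c_init fallback chord when the fit is rank-deficient.
#' @return list with `normal` (unit), `c` (unit final chord), `rms`
#'   (residual, m), `flags`.
#' @export
wing_plane_and_final_chord <- function(h_le, h_te, s, c_init = NULL) {
  pts <- rbind(hull_coords(h_le), hull_coords(h_te))
  flags <- character(0)
  if (nrow(pts) < 3L) {
    return(list(normal = c(NA, NA, NA), c = c_init, rms = NA_real_,
                flags = "plane_rank_deficient"))
  }
  cc <- sweep(pts, 2, colMeans(pts))
  sv <- svd(cc, nu = 0, nv = 3)
  if (sv$d[2] < 1e-12) {
    return(list(normal = c(NA, NA, NA), c = c_init, rms = NA_real_,
                flags = "plane_rank_deficient"))
  }
  nrm <- sv$v[, 3]
  rms <- sqrt(mean(as.numeric(cc %*% nrm)^2))
  v <- colMeans(hull_coords(h_le)) - colMeans(hull_coords(h_te))
  v <- v - sum(v * nrm) * nrm      # into the plane
  v <- v - sum(v * s) * s          # orthogonal to the span
  if (vec_norm(v) < 1e-12) {
    return(list(normal = nrm, c = c_init, rms = rms,
                flags = "plane_rank_deficient"))
  }
  list(normal = nrm, c = unit(v), rms = rms, flags = flags)
}
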