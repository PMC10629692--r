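# Articulated synthetic fly: a tapered-ellipsoid body plus two thin planar
# wings attached at hinges, posed by body pose and per-wing Euler angles.
# Serves as ground truth for every stage of the tracking pipeline and for
# the camera-configuration visibility analysis.

# half-chord shape profile along the normalized span t in [0, 1]
wing_chord_profile <- function(t) sin(pi * t)

# body radius profile: tapered ellipsoid of revolution, slightly fuller
# toward the abdomen; u in [0, pi] runs head -> tail
body_radius_profile <- function(u, half_width) {
  half_width * sin(u) * (1 - 0.25 * cos(u))
}

#' Build the articulated fly model
#'
#' Default geometry is a fruit-fly-scale stand-in: body = tapered ellipsoid
#' of length 2.5 mm and max width 1.2 mm; each wing a thin planar outline of
#' span 2.5 mm and max chord 1.0 mm (leading edge carries 35% of the chord,
#' trailing edge 65%), attached at hinges 0.55 body lengths from the tail,
#' offset laterally and slightly dorsally. Wings get a small physical
#' thickness so that edge-on silhouettes rasterize robustly.
#'
#' @param L_b body length (m).
#' @param L_w wing span length, hinge to tip (m).
#' @param body_width maximum body width (m).
#' @param max_chord maximum wing chord (m).
#' @param wing_thickness wing slab thickness (m).
#' @param hinge_frac hinge station from the tail, fraction of `L_b`.
#' @param le_frac fraction of the local chord ahead of the span line.
#' @param n_body_lon,n_body_circ body mesh resolution (rings, sectors).
#' @param n_wing_stations spanwise stations of the wing mesh.
#' @return an object of class `fly_model`.
#' @export
build_fly_model <- function(L_b = 2.5e-3, L_w = 2.5e-3,
                            body_width = 1.2e-3, max_chord = 1.0e-3,
                            wing_thickness = 80e-6, hinge_frac = 0.55,
                            le_frac = 0.35,
                            n_body_lon = 17, n_body_circ = 16,
                            n_wing_stations = 16) {
  if (L_b <= 0 || L_w <= 0 || body_width <= 0 || max_chord <= 0) {
    stop("all fly dimensions must be positive")
  }
  body <- make_body_mesh(L_b, body_width, n_body_lon, n_body_circ)
  hinge_x <- -L_b / 2 + hinge_frac * L_b
  hinge_y <- 0.45 * body_width
  hinge_z <- 0.15 * body_width
  hinges <- list(left = c(hinge_x, hinge_y, hinge_z),
                 right = c(hinge_x, -hinge_y, hinge_z))
  ts <- seq(0, 1, length.out = n_wing_stations)
  le <- le_frac * max_chord * wing_chord_profile(ts)
  te <- -(1 - le_frac) * max_chord * wing_chord_profile(ts)
  outline <- list(t = ts, le = le, te = te)
  structure(list(L_b = L_b, L_w = L_w, body_width = body_width,
                 max_chord = max_chord, wing_thickness = wing_thickness,
                 hinge_frac = hinge_frac, le_frac = le_frac,
                 body = body, hinges = hinges, outline = outline),
            class = "fly_model")
}

#' @export
print.fly_model <- function(x, ...) {
  cat(sprintf("<fly model: body %.2f mm, wing span %.2f mm, area %.3f mm^2>\n",
              x$L_b * 1e3, x$L_w * 1e3, wing_area(x) * 1e6))
  invisible(x)
}

#' Planar wing area from the outline (shoelace on the mid-plane polygon)
#' @param model a `fly_model`.
#' @return area in m^2.
#' @export
wing_area <- function(model) {
  p <- wing_outline_polygon(model)
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# mid-plane outline polygon in wing coordinates (span, chord):
# LE root->tip then TE tip->root; simple and closed
wing_outline_polygon <- function(model) {
  o <- model$outline
  r <- o$t * model$L_w
  rbind(cbind(r, o$le), cbind(rev(r)[-1], rev(o$te)[-1]))
}

# watertight tapered-ellipsoid body mesh (uv sphere topology with poles)
make_body_mesh <- function(L_b, body_width, n_lon, n_circ) {
  us <- seq(0, pi, length.out = n_lon)
  verts <- matrix(0, 0, 3)
  head_v <- c(L_b / 2, 0, 0)
  tail_v <- c(-L_b / 2, 0, 0)
  ring_id <- list()
  for (i in 2:(n_lon - 1)) {
    u <- us[i]
    r <- body_radius_profile(u, body_width / 2)
    x <- (L_b / 2) * cos(u)
    th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
    ring <- cbind(x, r * cos(th), r * sin(th))
    ring_id[[i - 1]] <- nrow(verts) + seq_len(n_circ)
    verts <- rbind(verts, ring)
  }
  i_head <- nrow(verts) + 1L
  i_tail <- nrow(verts) + 2L
  verts <- rbind(verts, head_v, tail_v)
  tris <- matrix(0L, 0, 3)
  nr <- length(ring_id)
  for (k in seq_len(nr - 1)) {
    a <- ring_id[[k]]; b <- ring_id[[k + 1]]
    for (j in seq_len(length(a))) {
      j2 <- if (j == length(a)) 1L else j + 1L
      tris <- rbind(tris, c(a[j], a[j2], b[j]), c(a[j2], b[j2], b[j]))
    }
  }
  a <- ring_id[[1]]
  for (j in seq_along(a)) {
    j2 <- if (j == length(a)) 1L else j + 1L
    tris <- rbind(tris, c(i_head, a[j], a[j2]))
  }
  a <- ring_id[[nr]]
  for (j in seq_along(a)) {
    j2 <- if (j == length(a)) 1L else j + 1L
    tris <- rbind(tris, c(i_tail, a[j2], a[j]))
  }
  list(verts = verts, tris = tris)
}

# wing slab mesh in local wing coordinates (q = chord toward LE, r = span,
# h = thickness), with optional linear spanwise twist about the span axis
make_wing_mesh <- function(model, twist_deg = 0) {
  o <- model$outline
  n <- length(o$t)
  t2 <- model$wing_thickness / 2
  top <- matrix(0, 0, 3); bot <- matrix(0, 0, 3)
  le_pts <- matrix(0, n, 3); te_pts <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    r <- o$t[i] * model$L_w
    tw <- deg2rad(twist_deg) * o$t[i]
    # rotate (q, h) about the span axis by the local twist
    rot <- function(q, h) c(q * cos(tw) - h * sin(tw), r,
                            q * sin(tw) + h * cos(tw))
    le_pts[i, ] <- rot(o$le[i], 0)
    te_pts[i, ] <- rot(o$te[i], 0)
    top <- rbind(top, rot(o$le[i], t2), rot(o$te[i], t2))
    bot <- rbind(bot, rot(o$le[i], -t2), rot(o$te[i], -t2))
  }
  verts <- rbind(top, bot)       # top: rows 1..2n (LE,TE per station)
  idx_top <- function(i, which) (i - 1L) * 2L + which   # which: 1 LE, 2 TE
  idx_bot <- function(i, which) 2L * n + (i - 1L) * 2L + which
  tris <- matrix(0L, 0, 3)
  for (i in seq_len(n - 1)) {
    # top and bottom faces
    tris <- rbind(tris,
      c(idx_top(i, 1), idx_top(i, 2), idx_top(i + 1, 1)),
      c(idx_top(i, 2), idx_top(i + 1, 2), idx_top(i + 1, 1)),
      c(idx_bot(i, 1), idx_bot(i + 1, 1), idx_bot(i, 2)),
      c(idx_bot(i, 2), idx_bot(i + 1, 1), idx_bot(i + 1, 2)),
      # LE and TE rims
      c(idx_top(i, 1), idx_top(i + 1, 1), idx_bot(i, 1)),
      c(idx_bot(i, 1), idx_top(i + 1, 1), idx_bot(i + 1, 1)),
      c(idx_top(i, 2), idx_bot(i, 2), idx_top(i + 1, 2)),
      c(idx_bot(i, 2), idx_bot(i + 1, 2), idx_top(i + 1, 2)))
  }
  # root and tip caps
  tris <- rbind(tris,
    c(idx_top(1, 1), idx_bot(1, 1), idx_top(1, 2)),
    c(idx_top(1, 2), idx_bot(1, 1), idx_bot(1, 2)),
    c(idx_top(n, 1), idx_top(n, 2), idx_bot(n, 1)),
    c(idx_top(n, 2), idx_bot(n, 2), idx_bot(n, 1)))
  list(verts = verts, tris = tris, le = le_pts, te = te_pts)
}

#' Construct a body pose
#'
#' @param position body CM position, lab frame (m).
#' @param yaw,pitch,roll body Euler angles (deg), used when `R` is `NULL`.
#' @param R optional 3x3 orientation matrix (columns x_b, y_b, z_b).
#' @return an object of class `body_pose`.
#' @export
body_pose <- function(position = c(0, 0, 0), yaw = 0, pitch = 0, roll = 0,
                      R = NULL) {
  if (is.null(R)) R <- body_rotation(yaw, pitch, roll)
  if (!is_rotation(R)) stop("orientation must be a proper rotation matrix")
  structure(list(position = as.numeric(position), R = R), class = "body_pose")
}

#' Construct a wing pose
#'
#' @param phi,theta,psi wing Euler angles (deg); see the package conventions.
#' @param side `"left"` or `"right"`.
#' @return an object of class `wing_pose`.
#' @export
wing_pose <- function(phi, theta, psi, side) {
  if (!all(is.finite(c(phi, theta, psi)))) stop("wing angles must be finite")
  structure(list(phi = phi, theta = theta, psi = psi,
                 side = match.arg(side, c("left", "right"))),
            class = "wing_pose")
}

#' Pose the fly model in the lab frame
#'
#' Rigidly transforms the body and attaches each wing at its hinge with the
#' span/chord orientation given by the wing Euler angles. Ground-truth
#' span and chord unit vectors, hinge and tip positions are returned
#' alongside the posed surfaces.
#'
#' @param model a `fly_model`.
#' @param body a `body_pose`.
#' @param wing_left,wing_right `wing_pose` objects.
#' @param twist_deg linear spanwise twist (deg at the tip, 0 at the root)
#'   applied to both wings, for deformation-recovery experiments.
#' @return list with `parts` (named list body/wing_left/wing_right of
#'   verts+tris in lab frame) and `truth` (axes, hinges, span/chord/tip per
#'   wing).
#' @export
pose_model <- function(model, body, wing_left, wing_right, twist_deg = 0) {
  if (!inherits(body, "body_pose")) stop("body must be a body_pose")
  R <- body$R
  pos <- body$position
  x_b <- R[, 1]; y_b <- R[, 2]; z_b <- R[, 3]
  to_lab <- function(v) sweep(v %*% t(R), 2, pos, "+")
  body_lab <- list(verts = to_lab(model$body$verts), tris = model$body$tris)
  place_wing <- function(wp) {
    vec <- wing_vectors_from_angles(wp$phi, wp$theta, wp$psi, wp$side, x_b, y_b)
    hinge <- pos + as.numeric(R %*% model$hinges[[wp$side]])
    mesh <- make_wing_mesh(model, twist_deg)
    # local (q, r, h) -> lab: q along chord, r along span, h along normal
    B <- cbind(vec$c, vec$s, vec$n_wing)
    verts <- sweep(mesh$verts %*% t(B), 2, hinge, "+")
    tip <- hinge + model$L_w * vec$s
    list(verts = verts, tris = mesh$tris, side = wp$side, s = vec$s,
         c = vec$c, n_wing = vec$n_wing, hinge = hinge, tip = tip,
         angles = c(phi = wp$phi, theta = wp$theta, psi = wp$psi))
  }
  wl <- place_wing(wing_left)
  wr <- place_wing(wing_right)
  list(parts = list(body = body_lab, wing_left = wl, wing_right = wr),
       truth = list(position = pos, R = R, x_b = x_b, y_b = y_b, z_b = z_b,
                    hinges = list(left = wl$hinge, right = wr$hinge),
                    s = list(left = wl$s, right = wr$s),
                    c = list(left = wl$c, right = wr$c),
                    tip = list(left = wl$tip, right = wr$tip),
                    twist_deg = twist_deg),
       model = model)
}

#' Fixed 3D boundary points along a posed wing outline
#'
#' Equally spaced (by arclength) points along the mid-plane wing outline,
#' the fixed point set used by the visibility metrics.
#'
#' @param posed output of [pose_model()].
#' @param side `"left"` or `"right"`.
#' @param n number of points.
#' @return n x 3 matrix of lab-frame coordinates.
#' @export
wing_boundary_points <- function(posed, side, n = 100) {
  model <- posed$model
  w <- posed$parts[[paste0("wing_", side)]]
  poly <- wing_outline_polygon(model)       # (span r, chord q)
  seg <- rbind(poly, poly[1, ])
  d <- sqrt(rowSums(diff(seg)^2))
  cum <- c(0, cumsum(d))
  tt <- seq(0, cum[length(cum)], length.out = n + 1)[-(n + 1)]
  pts2 <- t(vapply(tt, function(a) {
    k <- findInterval(a, cum, rightmost.closed = TRUE)
    k <- min(k, nrow(seg) - 1)
    f <- (a - cum[k]) / max(d[k], 1e-300)
    (1 - f) * seg[k, ] + f * seg[k + 1, ]
  }, numeric(2)))
  # (r, q) -> lab
  sweep(pts2[, 1, drop = FALSE] %*% t(w$s) +
          pts2[, 2, drop = FALSE] %*% t(w$c), 2, w$hinge, "+")
}
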