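# Voxel grids, visual-hull carving, and the expanded-hull algebra that
# resolves wing-body occlusions.
#
# A hull is kept in two equivalent views: a set of integer voxel indices and
# a membership function on the grid. Internally the set is a sorted vector
# of linear indices, which makes the union / intersection / majority algebra
# exact integer set arithmetic.

#' Construct a voxel grid
#'
#' @param origin lab-frame coordinate (m) of the center of voxel (1,1,1).
#' @param pitch voxel edge length (m).
#' @param dims integer `c(nx, ny, nz)`.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, pitch, dims) {
  if (pitch <= 0) stop("pitch must be positive")
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L)) stop("dims must be positive length-3")
  structure(list(origin = as.numeric(origin), pitch = as.numeric(pitch),
                 dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel grid %d x %d x %d, pitch %.3g m>\n",
              x$dims[1], x$dims[2], x$dims[3], x$pitch))
  invisible(x)
}

n_voxels <- function(grid) prod(as.numeric(grid$dims))

#' Lab-frame centers of voxels
#'
#' @param grid a `voxel_grid`.
#' @param indices n x 3 integer matrix of 1-based voxel indices, or a vector
#'   of linear indices.
#' @return n x 3 matrix of coordinates (m).
#' @export
voxel_centers <- function(grid, indices) {
  if (is.null(dim(indices))) indices <- lin_to_ijk(grid, indices)
  sweep((as.matrix(indices) - 1) * grid$pitch, 2, grid$origin, "+")
}

ijk_to_lin <- function(grid, ijk) {
  d <- grid$dims
  (as.numeric(ijk[, 3]) - 1) * d[1] * d[2] + (ijk[, 2] - 1) * d[1] + ijk[, 1]
}

lin_to_ijk <- function(grid, lin) {
  d <- grid$dims
  lin0 <- as.numeric(lin) - 1
  k <- lin0 %/% (d[1] * d[2])
  r <- lin0 - k * d[1] * d[2]
  j <- r %/% d[1]
  i <- r - j * d[1]
  cbind(i + 1, j + 1, k + 1)
}

#' Construct a hull from voxel indices
#'
#' @param grid a `voxel_grid`.
#' @param lin vector of linear voxel indices (or n x 3 index matrix).
#' @return an object of class `hull`.
#' @export
hull <- function(grid, lin = numeric(0)) {
  if (!is.null(dim(lin))) lin <- ijk_to_lin(grid, lin)
  lin <- sort(unique(as.numeric(lin)))
  if (length(lin) && (lin[1] < 1 || lin[length(lin)] > n_voxels(grid))) {
    stop("voxel indices outside the grid")
  }
  structure(list(grid = grid, lin = lin), class = "hull")
}

#' @export
print.hull <- function(x, ...) {
  cat(sprintf("<hull: %d voxels on %d x %d x %d grid>\n", length(x$lin),
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' @export
length.hull <- function(x) length(x$lin)

#' Voxel indices of a hull (set view)
#' @param h a `hull`.
#' @return n x 3 integer matrix.
#' @export
hull_indices <- function(h) lin_to_ijk(h$grid, h$lin)

#' Voxel centers of a hull (m)
#' @param h a `hull`.
#' @return n x 3 numeric matrix.
#' @export
hull_coords <- function(h) voxel_centers(h$grid, h$lin)

#' Membership function of a hull (functional view)
#'
#' @param h a `hull`.
#' @return logical array of the grid dimensions; `TRUE` where the hull's set
#'   view contains the voxel. The two views are equivalent by construction.
#' @export
hull_membership <- function(h) {
  m <- array(FALSE, h$grid$dims)
  m[h$lin] <- TRUE
  m
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$grid$origin, b$grid$origin)) &&
    a$grid$pitch == b$grid$pitch && all(a$grid$dims == b$grid$dims)
}

#' Set algebra on hulls
#'
#' Exact integer set operations on hulls sharing one grid.
#' @param a,b hulls on the same grid.
#' @return a `hull`.
#' @export
hull_union <- function(a, b) {
  stopifnot(same_grid(a, b))
  hull(a$grid, c(a$lin, b$lin))
}

#' @rdname hull_union
#' @export
hull_intersect <- function(a, b) {
  stopifnot(same_grid(a, b))
  hull(a$grid, intersect(a$lin, b$lin))
}

#' @rdname hull_union
#' @export
hull_setdiff <- function(a, b) {
  stopifnot(same_grid(a, b))
  hull(a$grid, setdiff(a$lin, b$lin))
}

#' Dilate a hull by one voxel (26-neighborhood)
#'
#' @param h a `hull`.
#' @return a `hull` grown by one voxel in every direction, clipped to the
#'   grid.
#' @export
hull_dilate <- function(h) {
  if (!length(h$lin)) return(h)
  ijk <- hull_indices(h)
  d <- h$grid$dims
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ni <- outer(ijk[, 1], off[, 1], "+")
  nj <- outer(ijk[, 2], off[, 2], "+")
  nk <- outer(ijk[, 3], off[, 3], "+")
  ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
  lin <- (as.numeric(nk[ok]) - 1) * d[1] * d[2] + (nj[ok] - 1) * d[1] + ni[ok]
  hull(h$grid, lin)
}

#' Build a voxel grid around the triangulated body center of mass
#'
#' The per-camera 2D body centers of mass are triangulated by linear least
#' squares, and the grid is a cube of side `extent * wing_length` centered
#' on the triangulated point, aligned with the lab axes.
#'
#' @param body_cm_2d n_cameras x 2 matrix of 2D body CMs (pixels), `NA` rows
#'   for cameras where the CM was not found.
#' @param rig a `camera_rig`.
#' @param wing_length nominal wing length (m).
#' @param extent cube side in wing lengths (default 2.6; large enough to
#'   hold the body and both fully extended wings).
#' @param pitch voxel edge (m); the natural default is one image-pixel
#'   footprint at the chamber center.
#' @param residual_warn warn if the triangulation RMS residual (px) exceeds
#'   this.
#' @return a `voxel_grid`; the triangulated CM and residual are attached as
#'   attributes `cm` and `residual`.
#' @export
build_voxel_grid <- function(body_cm_2d, rig, wing_length, extent = 2.6,
                             pitch = 40e-6, residual_warn = 2) {
  tri <- triangulate_pixels(rig, body_cm_2d)
  if (tri$residual > residual_warn) {
    warning(sprintf("body CM triangulation residual %.2f px", tri$residual))
  }
  side <- extent * wing_length
  n <- max(2L, as.integer(round(side / pitch)))
  origin <- tri$point - (n - 1) / 2 * pitch
  g <- voxel_grid(origin, pitch, c(n, n, n))
  attr(g, "cm") <- tri$point
  attr(g, "residual") <- tri$residual
  g
}

# ---- carving ---------------------------------------------------------------

# Precompute, per camera, the linear pixel index of every grid voxel's
# rounded projection (0 where the projection falls outside the image).
# Reused across all hull reconstructions on one grid.

#' Precompute voxel-to-pixel projections for carving
#'
#' @param grid a `voxel_grid`.
#' @param rig a `camera_rig`.
#' @return an opaque carve context, reusable for any carve on this
#'   grid/rig pair.
#' @export
carve_context <- function(grid, rig) {
  d <- grid$dims
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$pitch
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$pitch
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$pitch
  n <- prod(d)
  pix <- vector("list", length(rig$cameras))
  for (j in seq_along(rig$cameras)) {
    cam <- rig$cameras[[j]]
    P <- cam$P
    # separable accumulation of P * [x y z 1]' over the lattice
    hx1 <- P[1, 1] * xs; hx2 <- P[2, 1] * xs; hx3 <- P[3, 1] * xs
    hy1 <- P[1, 2] * ys; hy2 <- P[2, 2] * ys; hy3 <- P[3, 2] * ys
    hz1 <- P[1, 3] * zs + P[1, 4]
    hz2 <- P[2, 3] * zs + P[2, 4]
    hz3 <- P[3, 3] * zs + P[3, 4]
    W <- cam$image_size[1]; H <- cam$image_size[2]
    idx <- integer(n)
    nxy <- d[1] * d[2]
    a1 <- outer(hx1, hy1, "+"); a2 <- outer(hx2, hy2, "+")
    a3 <- outer(hx3, hy3, "+")
    for (k in seq_len(d[3])) {
      h3 <- a3 + hz3[k]
      px <- round_half_away((a1 + hz1[k]) / h3)
      py <- round_half_away((a2 + hz2[k]) / h3)
      ok <- px >= 1 & px <= W & py >= 1 & py <= H & h3 > 0
      v <- integer(nxy)
      v[ok] <- (as.integer(px[ok]) - 1L) * H + as.integer(py[ok])
      idx[(k - 1L) * nxy + seq_len(nxy)] <- v
    }
    pix[[j]] <- idx
  }
  ctx <- new.env(parent = emptyenv())
  ctx$grid <- grid
  ctx$n_cameras <- length(rig$cameras)
  ctx$pix <- pix
  ctx$inverse <- vector("list", length(rig$cameras))
  ctx$npx <- vapply(rig$cameras, function(cm) prod(cm$image_size), numeric(1))
  class(ctx) <- "carve_context"
  ctx
}

# Inverse map for one camera: voxels grouped by their projected pixel, so a
# full-grid carve can gather candidates from the mask's on-pixels instead
# of scanning every voxel. Built lazily, cached in the context.
carve_inverse <- function(ctx, j) {
  if (is.null(ctx$inverse[[j]])) {
    idx <- ctx$pix[[j]]
    ord <- order(idx)
    counts <- tabulate(idx + 1L, nbins = ctx$npx[j] + 1L)
    starts <- cumsum(c(1, counts))   # starts[p + 1] .. gives range of pixel p
    ctx$inverse[[j]] <- list(ord = ord, starts = starts)
  }
  ctx$inverse[[j]]
}

# Masks are matrices indexed [row = image y, col = image x], i.e.
# dim = c(height, width); the linear pixel index above matches this layout.

#' Carve a visual hull from per-camera binary masks
#'
#' A voxel is kept if and only if its rounded projected pixel is foreground
#' in every camera's mask. Voxels projecting outside an image count as not
#' seen by that camera and are rejected (conservative: the hull stays inside
#' the covisible volume). A camera whose mask entry is `NULL` is skipped
#' (used by the expanded-hull constructions).
#'
#' @param grid a `voxel_grid`, or a `carve_context` from [carve_context()].
#' @param masks list of logical matrices (`dim = c(height, width)`), one per
#'   camera, `NULL` to skip a camera.
#' @param rig a `camera_rig` (ignored when `grid` is a carve context).
#' @param subset optional vector of linear voxel indices to restrict the
#'   carve to (used to carve sub-hulls inside an already-carved hull).
#' @return a `hull`.
#' @export
carve <- function(grid, masks, rig = NULL, subset = NULL) {
  ctx <- if (inherits(grid, "carve_context")) grid else carve_context(grid, rig)
  cams <- which(!vapply(masks, is.null, logical(1)))
  if (!length(cams)) stop("carve needs at least one mask")
  cand <- subset
  for (j in cams) {
    mv <- as.logical(masks[[j]])
    if (is.null(cand)) {
      # full-grid pass: gather candidate voxels from the mask's on-pixels
      # through the cached pixel -> voxel inverse map
      inv <- carve_inverse(ctx, j)
      on <- which(mv)
      st <- inv$starts[on + 1L]
      en <- inv$starts[on + 2L] - 1L
      len <- en - st + 1L
      pos <- len > 0L
      cand <- inv$ord[sequence(len[pos], from = st[pos])]
    } else {
      idx <- ctx$pix[[j]][cand]
      keep <- idx > 0L
      keep[keep] <- mv[idx[keep]]
      cand <- cand[keep]
    }
    if (!length(cand)) break
  }
  h <- hull(ctx$grid, cand)
  if (!length(h$lin)) warning("carve produced an empty hull")
  h
}

#' Body hull from body-only masks
#'
#' @param grid `voxel_grid` or carve context.
#' @param seg list of per-camera segmented frames, each with a `body` mask.
#' @param rig a `camera_rig`.
#' @param subset optional linear-index restriction.
#' @return a `hull`.
#' @export
body_hull <- function(grid, seg, rig = NULL, subset = NULL) {
  carve(grid, lapply(seg, `[[`, "body"), rig, subset)
}

#' Expanded wing hull for wing i in camera j
#'
#' Carves the wing-component-`i` mask in camera `j` together with the
#' full-fly masks of every other camera. When the wings appear as a single
#' merged component in view `j`, the caller passes the merged component for
#' both wings, so the two expanded hulls for that view coincide.
#'
#' @param i wing index (1 or 2); used only for labeling.
#' @param j camera index whose wing-only image is used.
#' @param wing_mask_ij the wing-component mask of wing `i` in camera `j`.
#' @param full_masks list of full-fly masks for all cameras.
#' @param grid `voxel_grid` or carve context.
#' @param rig a `camera_rig`.
#' @param subset optional linear-index restriction.
#' @return a `hull`; empty (with attribute `occluded = TRUE`) when the wing
#'   has no pixels in view `j`.
#' @export
expanded_wing_hull <- function(i, j, wing_mask_ij, full_masks, grid,
                               rig = NULL, subset = NULL) {
  if (is.null(wing_mask_ij) || !any(wing_mask_ij)) {
    g <- if (inherits(grid, "carve_context")) grid$grid else grid
    h <- hull(g)
    attr(h, "occluded") <- TRUE
    return(h)
  }
  masks <- full_masks
  masks[[j]] <- wing_mask_ij
  suppressWarnings(carve(grid, masks, rig, subset))
}

#' Majority expanded body hull
#'
#' Keeps the voxels present in at least two of the four per-camera expanded
#' body hulls.
#'
#' @param hulls list of expanded body hulls on one grid.
#' @param min_count minimum membership count (default 2).
#' @return a `hull`.
#' @export
majority_body_hull <- function(hulls, min_count = 2L) {
  g <- hulls[[1]]$grid
  lin <- sort(unlist(lapply(hulls, `[[`, "lin")))
  if (!length(lin)) return(hull(g))
  r <- rle(lin)
  hull(g, r$values[r$lengths >= min_count])
}

#' Combined two-wing hull
#'
#' Union of the eight expanded wing hulls minus the majority expanded body
#' hull; removes body voxels and most wing-body occlusion artifacts.
#'
#' @param wing_hulls list of expanded wing hulls (all wings x cameras).
#' @param body_expanded the majority expanded body hull.
#' @return a `hull`; empty result flags the frame unresolvable.
#' @export
combined_wing_hull <- function(wing_hulls, body_expanded) {
  g <- body_expanded$grid
  u <- hull(g, unlist(lapply(wing_hulls, `[[`, "lin")))
  out <- hull_setdiff(u, body_expanded)
  if (!length(out$lin)) attr(out, "unresolvable") <- TRUE
  out
}

#' Split the combined wing hull into two wings
#'
#' k-means (k = 2) on the voxel coordinates, initialized at the two extreme
#' voxels along the body y-axis (deterministic). Cluster-to-wing identity is
#' taken from the nearest previous-frame wing CM when available, otherwise
#' from the sign of the projection on the body y-axis (left wing positive).
#'
#' @param h_two_wings combined wing hull.
#' @param body_y body y-axis (unit, lab frame).
#' @param body_cm body center of mass (m).
#' @param prev_cms optional list(left =, right =) of previous-frame wing CMs.
#' @return list(left =, right = `hull`, flags = character()); flag
#'   `"wings_merged_3d"` when the clusters cannot be separated.
#' @export
split_wings <- function(h_two_wings, body_y, body_cm, prev_cms = NULL) {
  g <- h_two_wings$grid
  flags <- character(0)
  xyz <- hull_coords(h_two_wings)
  if (nrow(xyz) < 2L) {
    return(list(left = hull(g), right = hull(g), flags = "wings_merged_3d"))
  }
  proj <- as.numeric((xyz - matrix(body_cm, nrow(xyz), 3, TRUE)) %*% body_y)
  init <- xyz[c(which.max(proj), which.min(proj)), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(xyz, centers = init, iter.max = 50))
  cl <- km$cluster
  cm1 <- km$centers[1, ]; cm2 <- km$centers[2, ]
  if (min(km$size) == 0L || vec_norm(cm1 - cm2) < 2 * g$pitch) {
    return(list(left = hull(g), right = hull(g), flags = "wings_merged_3d"))
  }
  # identity assignment
  if (!is.null(prev_cms) && !is.null(prev_cms$left) && !is.null(prev_cms$right)) {
    d_l <- c(vec_norm(cm1 - prev_cms$left), vec_norm(cm2 - prev_cms$left))
    d_r <- c(vec_norm(cm1 - prev_cms$right), vec_norm(cm2 - prev_cms$right))
    left_is_1 <- (d_l[1] + d_r[2]) <= (d_l[2] + d_r[1])
  } else {
    p1 <- sum((cm1 - body_cm) * body_y)
    p2 <- sum((cm2 - body_cm) * body_y)
    left_is_1 <- p1 >= p2
  }
  lin1 <- h_two_wings$lin[cl == 1]
  lin2 <- h_two_wings$lin[cl == 2]
  if (left_is_1) {
    list(left = hull(g, lin1), right = hull(g, lin2), flags = flags)
  } else {
    list(left = hull(g, lin2), right = hull(g, lin1), flags = flags)
  }
}
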