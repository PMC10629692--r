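# Camera projection model, rig presets and calibration I/O.
#
# A camera is a single 3x4 DLT-style projection matrix P mapping a
# homogeneous lab-frame point to a homogeneous pixel; no lens distortion is
# modeled (synthetic validation needs none; real footage can be
# pre-undistorted). Pixel coordinates are 1-based with integer pixel
# centers, x right / y down.

#' Construct a camera model
#'
#' @param id small integer camera identifier.
#' @param P 3x4 projection matrix (rank 3).
#' @param image_size integer vector `c(width, height)` in pixels.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(id, P, image_size) {
  P <- matrix(as.numeric(P), 3, 4)
  if (!all(is.finite(P))) stop("camera ", id, ": non-finite projection matrix")
  if (qr(P)$rank < 3) stop("camera ", id, ": projection matrix is rank-deficient")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size <= 0L)) {
    stop("image_size must be positive c(width, height)")
  }
  structure(list(id = as.integer(id), P = P, image_size = image_size),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera %d: %d x %d px>\n", x$id, x$image_size[1], x$image_size[2]))
  invisible(x)
}

# Camera center: right null vector of P (dehomogenized).
camera_center <- function(camera) {
  ns <- svd(camera$P, nu = 0, nv = 4)$v[, 4]
  ns[1:3] / ns[4]
}

# Unit optical axis (direction of increasing depth), lab frame.
camera_axis <- function(camera) {
  m3 <- camera$P[3, 1:3]
  unit(m3) * sign(det(camera$P[, 1:3]))
}

#' Project a lab-frame point to continuous pixel coordinates
#'
#' Homogeneous-normalized image coordinate of a 3D point; the pixel may fall
#' outside the image bounds (clipping is the caller's decision).
#'
#' @param camera a `camera_model`.
#' @param point 3-vector (meters) or n x 3 matrix of points.
#' @return a length-2 pixel `c(x, y)`, or an n x 2 matrix.
#' @export
project_point <- function(camera, point) {
  single <- is.null(dim(point))
  X <- if (single) matrix(point, 1, 3) else as.matrix(point)
  h <- X %*% t(camera$P[, 1:3]) +
    matrix(camera$P[, 4], nrow(X), 3, byrow = TRUE)
  if (any(abs(h[, 3]) < 1e-12)) {
    stop("degenerate projection: point at zero homogeneous depth ",
         "(camera ", camera$id, ")")
  }
  px <- h[, 1:2, drop = FALSE] / h[, 3]
  if (single) as.numeric(px) else px
}

#' Project voxel centers to rounded integer pixels
#'
#' One rounded pixel per voxel center (round-half-away-from-zero). Voxels
#' whose projection falls outside the image are flagged with `in_image =
#' FALSE`; their rounded coordinates are still returned.
#'
#' @param camera a `camera_model`.
#' @param grid a `voxel_grid`.
#' @param indices n x 3 integer matrix of voxel indices (1-based); may have
#'   zero rows.
#' @return list with `px`, `py` (integer vectors) and logical `in_image`.
#' @export
project_voxels <- function(camera, grid, indices) {
  indices <- as.matrix(indices)
  if (nrow(indices) == 0L) {
    return(list(px = integer(0), py = integer(0), in_image = logical(0)))
  }
  centers <- voxel_centers(grid, indices)
  px <- project_point(camera, centers)
  xi <- round_half_away(px[, 1])
  yi <- round_half_away(px[, 2])
  inside <- xi >= 1 & xi <= camera$image_size[1] &
    yi >= 1 & yi <= camera$image_size[2]
  list(px = as.integer(xi), py = as.integer(yi), in_image = inside)
}

# Look-at camera: positioned at `distance` along unit direction `dir` from
# the target, optical axis toward the target, focal length set so one pixel
# subtends `pixel_pitch` meters at the target.
make_lookat_camera <- function(id, dir, distance, image_size, pixel_pitch,
                               target = c(0, 0, 0), up_hint = c(0, 0, 1)) {
  dir <- unit(dir)
  pos <- target + distance * dir
  z_c <- -dir                              # optical axis, camera z forward
  if (abs(sum(up_hint * z_c)) > 1 - 1e-8) up_hint <- c(1, 0, 0)
  y0 <- -unit(up_hint)                     # image y points down
  x_c <- unit(cross3(y0, z_c))
  y_c <- cross3(z_c, x_c)
  Rwc <- rbind(x_c, y_c, z_c)
  f <- distance / pixel_pitch
  K <- matrix(c(f, 0, 0,
                0, f, 0,
                (image_size[1] + 1) / 2, (image_size[2] + 1) / 2, 1), 3, 3)
  P <- K %*% cbind(Rwc, -Rwc %*% pos)
  camera_model(id, P, image_size)
}

rig_presets <- c("cartesian3", "pyramidal3", "pyramidal4", "hybrid4")

#' Build a preset multi-camera rig
#'
#' Presets (all cameras aimed at the origin, the chamber center):
#' \describe{
#'   \item{cartesian3}{three cameras along +x, +y and +z — two horizontal
#'     and one vertical, mutually orthogonal optical axes.}
#'   \item{pyramidal3}{a mutually orthogonal triplet tilted symmetrically
#'     above the chamber: azimuths 0/120/240 deg, elevation atan(1/sqrt(2))
#'     ~ 35.26 deg (the unique equal-elevation orthogonal triplet).}
#'   \item{pyramidal4}{four cameras at four-fold azimuthal symmetry
#'     (0/90/180/270 deg) at the same elevation.}
#'   \item{hybrid4}{pyramidal3 plus one vertical (top-down) camera.}
#' }
#'
#' @param preset_name one of `"cartesian3"`, `"pyramidal3"`, `"pyramidal4"`,
#'   `"hybrid4"`.
#' @param distance camera-to-chamber-center distance (m).
#' @param image_size `c(width, height)` pixels.
#' @param pixel_pitch meters per pixel at the chamber center.
#' @return an object of class `camera_rig`.
#' @export
make_rig <- function(preset_name, distance = 0.15,
                     image_size = c(256, 256), pixel_pitch = 40e-6) {
  if (!preset_name %in% rig_presets) {
    stop("unknown preset '", preset_name, "'; available: ",
         paste(rig_presets, collapse = ", "))
  }
  elev <- atan(1 / sqrt(2))      # radians; equal-elevation orthogonal triplet
  az3 <- deg2rad(c(0, 120, 240))
  az4 <- deg2rad(c(0, 90, 180, 270))
  dir_at <- function(az, el) c(cos(az) * cos(el), sin(az) * cos(el), sin(el))
  dirs <- switch(preset_name,
    cartesian3 = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    pyramidal3 = lapply(az3, dir_at, el = elev),
    pyramidal4 = lapply(az4, dir_at, el = elev),
    hybrid4 = c(lapply(az3, dir_at, el = elev), list(c(0, 0, 1)))
  )
  cams <- lapply(seq_along(dirs), function(j) {
    make_lookat_camera(j, dirs[[j]], distance, image_size, pixel_pitch)
  })
  camera_rig(cams, preset_name)
}

#' Construct a camera rig from a list of cameras
#'
#' @param cameras list of `camera_model` objects with unique ids.
#' @param preset_name text label (preset name or `"custom"`).
#' @return an object of class `camera_rig`.
#' @export
camera_rig <- function(cameras, preset_name = "custom") {
  ids <- vapply(cameras, function(cm) cm$id, integer(1))
  if (anyDuplicated(ids)) stop("camera ids must be unique")
  structure(list(cameras = cameras, preset_name = preset_name),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("<camera rig '%s': %d cameras>\n",
              x$preset_name, length(x$cameras)))
  invisible(x)
}

#' @export
length.camera_rig <- function(x) length(x$cameras)

#' Write rig calibration to JSON
#'
#' Schema: `{"cameras":[{"id":1,"P":[12 floats row-major],"width":W,
#' "height":H}, ...], "preset": "..."}`. The round trip write-then-read
#' reproduces the matrices bit-exactly.
#'
#' @param rig a `camera_rig`.
#' @param path output file path.
#' @export
write_calibration <- function(rig, path) {
  cams <- lapply(rig$cameras, function(cm) {
    list(id = cm$id, P = as.numeric(t(cm$P)),
         width = cm$image_size[1], height = cm$image_size[2])
  })
  jsonlite::write_json(list(preset = rig$preset_name, cameras = cams),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read rig calibration from JSON
#'
#' @param path calibration file written by [write_calibration()] or by hand
#'   following the documented schema.
#' @return a `camera_rig`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$cameras)) stop("calibration file has no 'cameras' entry")
  cams_raw <- obj$cameras
  if (is.data.frame(cams_raw)) {
    cams_raw <- lapply(seq_len(nrow(cams_raw)), function(i) {
      as.list(cams_raw[i, , drop = FALSE])
    })
    cams_raw <- lapply(cams_raw, function(cm) {
      cm$P <- unlist(cm$P)
      cm
    })
  }
  cams <- lapply(cams_raw, function(cm) {
    Pv <- as.numeric(unlist(cm$P))
    if (length(Pv) != 12L || !all(is.finite(Pv))) {
      stop("calibration schema error for camera ", cm$id,
           ": P must contain 12 finite entries (got ", length(Pv), ")")
    }
    camera_model(cm$id, matrix(Pv, 3, 4, byrow = TRUE),
                 c(cm$width, cm$height))
  })
  preset <- if (!is.null(obj$preset)) obj$preset else "custom"
  camera_rig(cams, preset)
}

#' Triangulate a 3D point from per-camera pixel observations
#'
#' Linear least-squares (DLT) triangulation from two or more cameras.
#'
#' @param rig a `camera_rig`.
#' @param pixels n x 2 matrix of pixel coordinates, one row per camera, `NA`
#'   rows for cameras without an observation.
#' @return list with `point` (3-vector, m) and `residual` (RMS reprojection
#'   error in pixels over the used cameras).
#' @export
triangulate_pixels <- function(rig, pixels) {
  pixels <- as.matrix(pixels)
  use <- which(stats::complete.cases(pixels))
  if (length(use) < 2L) stop("triangulation needs >= 2 cameras with observations")
  A <- do.call(rbind, lapply(use, function(j) {
    P <- rig$cameras[[j]]$P
    rbind(pixels[j, 1] * P[3, ] - P[1, ],
          pixels[j, 2] * P[3, ] - P[2, ])
  }))
  v <- svd(A)$v[, 4]
  pt <- v[1:3] / v[4]
  err <- vapply(use, function(j) {
    sqrt(sum((project_point(rig$cameras[[j]], pt) - pixels[j, ])^2))
  }, numeric(1))
  list(point = pt, residual = sqrt(mean(err^2)))
}
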