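# Motion-based body/wing segmentation. The wings sweep past any pixel only
# briefly during a wingbeat while the body occupies its pixels continuously,
# so summing binary frames over one wingbeat window makes the body stand
# out. A second pass compensates for body motion by aligning the window
# frames on the provisional 2D CM before re-summing.

#' Threshold a grayscale frame to a binary fly mask
#'
#' Back-illuminated recordings show the fly dark on a bright background, so
#' the default keeps pixels below the threshold; set `fly_dark = FALSE` for
#' the opposite polarity. Logical input is passed through.
#'
#' @param frame numeric matrix (any range) or logical matrix.
#' @param threshold intensity threshold.
#' @param fly_dark logical; is the fly darker than the background?
#' @return logical matrix; an all-empty result triggers a warning.
#' @export
binarize <- function(frame, threshold = 0.5, fly_dark = TRUE) {
  m <- if (is.logical(frame)) frame
       else if (fly_dark) frame < threshold else frame > threshold
  if (!any(m)) warning("binarize: empty mask")
  m
}

#' Binarize a whole grayscale stack
#'
#' @param stack numeric array `height x width x frames`.
#' @inheritParams binarize
#' @return logical array of the same dimensions.
#' @export
binarize_stack <- function(stack, threshold = 0.5, fly_dark = TRUE) {
  if (is.logical(stack)) return(stack)
  m <- if (fly_dark) stack < threshold else stack > threshold
  array(m, dim(stack))
}

# integer-pixel 2D shift of a matrix, zero fill; d = c(dx, dy) in pixels
shift_mask <- function(m, d) {
  dx <- d[1]; dy <- d[2]
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  sx <- max(1, 1 + dx):min(W, W + dx)
  sy <- max(1, 1 + dy):min(H, H + dy)
  if (!length(sx) || !length(sy) || sx[1] > sx[length(sx)] ||
      sy[1] > sy[length(sy)]) return(out)
  out[sy, sx] <- m[sy - dy, sx - dx]
  out
}

mask_cm <- function(m) {
  if (!any(m)) return(c(NA_real_, NA_real_))
  w <- which(m)
  H <- nrow(m)
  y <- (w - 1) %% H + 1
  x <- (w - 1) %/% H + 1
  c(mean(x), mean(y))
}

# Sliding-window occupancy via a running sum (truncated, re-normalized
# windows at the stack ends). M: n_pixels x n_frames logical matrix. Calls
# `fun(f, occupancy_vector)` for each frame in order.
window_occupancy_apply <- function(M, window, fun) {
  nf <- ncol(M)
  half <- window %/% 2
  lo <- pmax(0L, seq_len(nf) - half - 1L)   # window is (lo, hi]
  hi <- pmin(nf, seq_len(nf) + half)
  acc <- rowSums(M[, 1:hi[1], drop = FALSE])
  fun(1L, acc / (hi[1] - lo[1]))
  for (f in 2:nf) {
    if (hi[f] > hi[f - 1]) acc <- acc + M[, hi[f]]
    if (lo[f] > lo[f - 1]) acc <- acc - M[, lo[f]]
    fun(f, acc / (hi[f] - lo[f]))
  }
  invisible(NULL)
}

#' Motion-based body segmentation of one camera's binary stack
#'
#' Two passes. Pass 1: for each frame, pixels occupied in at least
#' `occupancy_fraction` of a `window`-frame sliding window are the
#' provisional body, giving a provisional 2D CM per frame. Pass 2: frames
#' are translated by their integer-pixel CM displacement (motion
#' compensation), the occupancy is recomputed on the aligned stack, and the
#' resulting mask is shifted back per frame. The wing mask is the full mask
#' minus the body mask.
#'
#' @param stack logical array `height x width x frames` of binarized
#'   full-fly masks.
#' @param window wingbeat window length in frames; `"auto"` estimates it
#'   from the dominant period of the total-fly-pixel-count signal.
#' @param occupancy_fraction fraction of the window a body pixel must be
#'   occupied (default 0.85; wings sweep past any pixel only briefly).
#' @return list with `body` and `wing` logical arrays, `cm` (frames x 2
#'   matrix of continuous 2D body CMs, pixel coordinates x, y), `window`,
#'   and a character vector `flags`.
#' @export
segment_body <- function(stack, window = 73, occupancy_fraction = 0.85) {
  dm <- dim(stack)
  H <- dm[1]; W <- dm[2]; nf <- dm[3]
  counts <- colSums(matrix(stack, H * W, nf))
  if (identical(window, "auto")) {
    per <- estimate_dominant_period(counts)
    if (is.na(per)) stop("could not auto-estimate the wingbeat window")
    window <- as.integer(round(per))
  }
  if (window > nf) stop("window (", window, ") longer than stack (", nf, ")")
  flags <- character(0)
  M <- matrix(as.logical(stack), H * W, nf)

  # pass 1: raw occupancy -> provisional per-frame body CM
  cm1 <- matrix(NA_real_, nf, 2)
  window_occupancy_apply(M, window, function(f, occ) {
    bm <- occ >= occupancy_fraction & M[, f]
    cm1[f, ] <<- if (any(bm)) mask_cm(matrix(bm, H, W)) else
      mask_cm(matrix(M[, f], H, W))
  })
  ref <- cm1[max(1L, nf %/% 2L), ]
  shifts <- round(sweep(cm1, 2, ref))     # integer displacement per frame
  shifts[!is.finite(shifts)] <- 0

  # pass 2: align frames on the CM, re-sum, threshold, shift back
  A <- matrix(FALSE, H * W, nf)
  for (f in seq_len(nf)) {
    A[, f] <- shift_mask(matrix(M[, f], H, W), -shifts[f, ])
  }
  body <- array(FALSE, dm)
  wing <- array(FALSE, dm)
  cm <- matrix(NA_real_, nf, 2)
  window_occupancy_apply(A, window, function(f, occ) {
    bm_al <- matrix(occ >= occupancy_fraction & A[, f], H, W)
    bm <- shift_mask(bm_al, shifts[f, ])
    full <- matrix(M[, f], H, W)
    bm <- bm & full
    if (!any(bm)) {
      flags <<- c(flags, sprintf("frame %d: empty body mask", f))
    }
    body[, , f] <<- bm
    wing[, , f] <<- full & !bm
    cm[f, ] <<- if (any(bm)) mask_cm(bm) else mask_cm(full)
  })
  list(body = body, wing = wing, cm = cm, window = as.integer(window),
       flags = flags)
}
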