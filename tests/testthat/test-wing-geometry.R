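# voxelized prolate ellipsoid along a given axis, for body-axis tests
ellipsoid_hull <- function(g, axis, a = 1.2e-3, b = 0.5e-3,
                           center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  d <- g$dims
  idx <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  ctr <- voxel_centers(g, idx)
  rel <- sweep(ctr, 2, center)
  t <- as.numeric(rel %*% axis)
  r2 <- rowSums(rel^2) - t^2
  hull(g, idx[t^2 / a^2 + r2 / b^2 <= 1, , drop = FALSE])
}

test_that("head/tail refinement recovers the body axis", {
  g <- voxel_grid(rep(-2e-3, 3), 50e-6, rep(81, 3))
  h <- ellipsoid_hull(g, c(1, 0, 0))
  ht <- head_tail_refine(h, forward_hint = c(1, 0, 0))
  expect_gt(sum(ht$xb * c(1, 0, 0)), cos(2 * pi / 180))
  expect_lt(max(abs(ht$cm)), 60e-6)
  # known yaw: axis at 30 deg recovered within 2 deg
  ax30 <- c(cos(pi / 6), sin(pi / 6), 0)
  h30 <- ellipsoid_hull(g, ax30)
  ht30 <- head_tail_refine(h30, forward_hint = ax30)
  expect_gt(sum(ht30$xb * ax30), cos(2 * pi / 180))
  # continuity rule beats a flipped PCA sign
  ht_flip <- head_tail_refine(h30, prev_xb = -ax30)
  expect_gt(sum(ht_flip$xb * (-ax30)), 0)
})

test_that("the strip matches a brute-force distance oracle", {
  g <- voxel_grid(rep(-2e-3, 3), 50e-6, rep(81, 3))
  h <- ellipsoid_hull(g, c(0, 1, 0), a = 1.5e-3, b = 0.3e-3,
                      center = c(0, 1.2e-3, 0))
  Lw <- 2.5e-3
  st <- wing_strip(h, c(0, 0, 0), Lw)
  d <- sqrt(rowSums(hull_coords(h)^2))
  expect_identical(sort(st$lin),
                   sort(h$lin[d >= 0.40 * Lw & d <= 0.65 * Lw]))
  expect_length(st$flags, 0)
  # all voxels at 0.5 L_w are included
  near <- hull(g, flyhull:::ijk_to_lin(g, cbind(41 + 25, 41, 41)))  # 1.25 mm
  st2 <- wing_strip(near, c(0, 0, 0), Lw)
  expect_length(st2$lin, 1)
  # all voxels at 0.9 L_w trigger the widen-once fallback, then fail
  far <- hull(g, flyhull:::ijk_to_lin(g, cbind(41 + 45, 41, 41)))   # 2.25 mm
  st3 <- wing_strip(far, c(0, 0, 0), Lw)
  expect_true("strip_widened" %in% st3$flags)
  expect_true("wing_unresolvable" %in% st3$flags)
})

test_that("degenerate single-voxel wings are flagged", {
  g <- voxel_grid(rep(-2e-3, 3), 50e-6, rep(81, 3))
  one <- hull(g, flyhull:::ijk_to_lin(g, cbind(41 + 25, 41, 41)))
  st <- wing_strip(one, c(0, 0, 0), 2.5e-3)
  est <- estimate_span_tip(one, st, c(0, 0, 0))
  expect_true("degenerate_single_voxel" %in% est$flags)
  expect_true(all(is.na(est$s)))
})

test_that("two parallel voxel planes give a chord perpendicular to them", {
  g <- voxel_grid(rep(0, 3), 1e-4, c(30, 30, 30))
  idx <- rbind(as.matrix(expand.grid(5:25, 13:17, 4)),
               as.matrix(expand.grid(5:25, 13:17, 26)))
  coords <- voxel_centers(g, idx)
  s <- c(1, 0, 0)
  ch <- estimate_chord_initial(coords, s, ref_dir = c(0, 0, 1), pitch = 1e-4)
  expect_equal(unname(abs(ch$c)), c(0, 0, 1), tolerance = 1e-9)
  expect_lt(abs(sum(ch$c * s)), 1e-9)
  # inseparable clusters defer the chord
  flat <- voxel_centers(g, as.matrix(expand.grid(5:25, 10:20, 5)))
  ch2 <- estimate_chord_initial(flat[, , drop = FALSE], s, pitch = 1e-2)
  expect_true("chord_deferred" %in% ch2$flags)
})

test_that("boundary extraction matches a brute-force neighbor test", {
  set.seed(5)
  m <- matrix(FALSE, 40, 40)
  m[10:30, 8:28] <- TRUE
  m[15:20, 15:18] <- FALSE
  b <- flyhull:::mask_boundary(m)
  for (y in 1:40) for (x in 1:40) {
    if (!m[y, x]) {
      expect_false(b[y, x])
    } else {
      nb <- c(if (y > 1) m[y - 1, x] else FALSE,
              if (y < 40) m[y + 1, x] else FALSE,
              if (x > 1) m[y, x - 1] else FALSE,
              if (x < 40) m[y, x + 1] else FALSE)
      expect_identical(b[y, x], any(!nb))
    }
  }
})

test_that("LE/TE split follows the tip-velocity side", {
  # rectangle with span along image x, motion toward +y (down the image):
  # the leading edge is the larger-y side of the split line
  m <- matrix(FALSE, 40, 40)
  m[18:22, 5:35] <- TRUE
  out <- extract_le_te(m, cm2d = c(20, 20), span2d = c(30, 0),
                       tipvel2d = c(0, 1))
  expect_true(out$usable)
  expect_true(all(out$le[, "y"] >= 21))
  expect_true(all(out$te[, "y"] <= 20))
  # opposite motion flips the labels
  out2 <- extract_le_te(m, c(20, 20), c(30, 0), c(0, -1))
  expect_true(all(out2$le[, "y"] <= 20))
  # degenerate projected span excludes the camera
  expect_false(extract_le_te(m, c(20, 20), c(1, 0), c(0, 1))$usable)
  # near-edge-on chord width excludes the camera
  thin <- matrix(FALSE, 40, 40)
  thin[20, 5:35] <- TRUE
  expect_false(extract_le_te(thin, c(20, 20), c(30, 0), c(0, 1))$usable)
})

test_that("reprojection reveals wing pixels and respects containment", {
  rig <- fix_rig()
  sil <- fix_sil()
  full_m <- lapply(sil, `[[`, "full")
  g <- fix_grid()
  ctx <- fix_ctx()
  h_full <- carve(ctx, full_m)
  ew <- lapply(1:4, function(j) {
    mm <- full_m; mm[[j]] <- sil[[j]]$wing_left
    suppressWarnings(carve(ctx, mm, subset = h_full$lin))
  })
  body_m <- lapply(sil, `[[`, "body")
  eb <- lapply(1:4, function(j) {
    mm <- full_m; mm[[j]] <- body_m[[j]]
    suppressWarnings(carve(ctx, mm, subset = h_full$lin))
  })
  hw <- combined_wing_hull(ew, majority_body_hull(eb))
  masks <- reproject_wing(hw, rig)
  for (j in 1:4) {
    raw <- sil[[j]]$wing_left            # visible wing pixels
    # reprojected mask covers nearly all truly visible wing pixels
    expect_gt(sum(masks[[j]] & raw) / sum(raw), 0.9)
  }
  # single voxel reprojects to a closed pixel neighborhood
  single <- hull(g, hw$lin[1])
  m1 <- reproject_wing(single, rig)
  expect_gte(sum(m1[[1]]), 1)
})

test_that("a rigid flat wing yields a tight plane and uniform pitch", {
  # isolated planar wing at a known pitch, voxelized directly at a fine
  # pitch (short root chords need it: the quantization error scales as
  # pitch over local chord)
  g <- voxel_grid(c(-0.8e-3, -0.1e-3, -0.8e-3), 20e-6, c(81, 141, 81))
  s <- c(0, 1, 0)
  psi_true <- 50
  model <- fix_model()
  basis <- wing_pitch_basis(s, "left", c(1, 0, 0), c(0, 1, 0))
  cc <- cos(psi_true * pi / 180) * basis$c0 +
    sin(psi_true * pi / 180) * basis$e2
  d <- g$dims
  idx <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  ctr <- voxel_centers(g, idx)
  r <- as.numeric(ctr %*% s)
  q <- as.numeric(ctr %*% cc)
  h <- as.numeric(ctr %*% flyhull:::cross3(s, cc))
  t <- r / model$L_w
  gpro <- flyhull:::wing_chord_profile(pmax(0, pmin(1, t)))
  inside <- t >= 0 & t <= 1 & abs(h) <= 25e-6 &
    q <= 0.35e-3 * gpro & q >= -0.65e-3 * gpro
  rm(ctr, r, q, h, t, gpro)
  hw <- hull(g, idx[inside, , drop = FALSE])
  # split the wing voxels into LE/TE halves by the true chord side
  qh <- as.numeric(hull_coords(hw) %*% cc)
  h_le <- hull(g, hw$lin[qh > 0])
  h_te <- hull(g, hw$lin[qh <= 0])
  lc <- local_chords(h_le, h_te, c(0, 0, 0), s, basis, n_sections = 5,
                     c_ref = cc)
  expect_true(all(abs(lc$psi_k - psi_true) < 3, na.rm = TRUE))
  pl <- wing_plane_and_final_chord(h_le, h_te, s)
  n_true <- flyhull:::cross3(s, cc)
  expect_gt(abs(sum(pl$normal * n_true)), cos(3 * pi / 180))
  expect_lt(pl$rms, 2 * g$pitch)
  expect_lt(abs(sum(pl$c * s)), 1e-9)
})
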