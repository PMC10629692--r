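test_that("stroke plane is the -45 deg rotation of the body axis", {
  sp <- stroke_plane(c(1, 0, 0), c(0, 1, 0))
  # hand evaluation of R(y, -45) x = cos45 x + sin45 z
  expect_equal(sp$normal, c(cos(pi / 4), 0, sin(pi / 4)), tolerance = 1e-12)
  # properties for arbitrary orientations
  set.seed(21)
  for (i in 1:20) {
    R <- body_rotation(runif(1, 0, 360), runif(1, -80, 80), runif(1, -90, 90))
    sp <- stroke_plane(R[, 1], R[, 2])
    expect_lt(abs(sum(sp$normal * R[, 2])), 1e-9)             # n . y_b = 0
    expect_equal(sum(sp$normal * R[, 1]), cos(pi / 4),
                 tolerance = 1e-9)                            # 45 deg to x_b
  }
})

test_that("wing angle conventions are exactly invertible", {
  set.seed(8)
  for (i in 1:40) {
    R <- body_rotation(runif(1, 0, 360), runif(1, -60, 60), runif(1, -45, 45))
    phi <- runif(1, -20, 175); theta <- runif(1, -60, 60)
    psi <- runif(1, 1, 179)
    side <- sample(c("left", "right"), 1)
    v <- wing_vectors_from_angles(phi, theta, psi, side, R[, 1], R[, 2])
    a <- wing_angles_from_vectors(v$s, v$c, side, R[, 1], R[, 2])
    expect_false(a$gimbal)
    expect_equal(c(a$phi, a$theta, a$psi), c(phi, theta, psi),
                 tolerance = 1e-9)
  }
  # definition anchor: span lateral in the stroke plane, chord in-plane
  v <- wing_vectors_from_angles(90, 0, 0, "left", c(1, 0, 0), c(0, 1, 0))
  expect_equal(v$s, c(0, 1, 0), tolerance = 1e-12)
  a <- wing_angles_from_vectors(v$s, v$c, "left", c(1, 0, 0), c(0, 1, 0))
  expect_equal(a$theta, 0, tolerance = 1e-9)
  expect_equal(a$psi, 0, tolerance = 1e-9)
  # gimbal pose is flagged, not silently wrong
  b <- flyhull:::stroke_basis(c(1, 0, 0), c(0, 1, 0))
  g <- wing_angles_from_vectors(b$n, b$x_sp, "left", c(1, 0, 0), c(0, 1, 0))
  expect_true(g$gimbal)
  # mirrored poses give equal triplets on both sides
  for (i in 1:10) {
    phi <- runif(1, 0, 160); theta <- runif(1, -30, 30); psi <- runif(1, 10, 170)
    vl <- wing_vectors_from_angles(phi, theta, psi, "left",
                                   c(1, 0, 0), c(0, 1, 0))
    vr <- wing_vectors_from_angles(phi, theta, psi, "right",
                                   c(1, 0, 0), c(0, 1, 0))
    expect_equal(vl$s * c(1, -1, 1), vr$s, tolerance = 1e-9)
  }
})

test_that("y_b estimation recovers the body frame from wing spans", {
  m <- fix_model()
  seqq <- generate_wingbeat_sequence(m, n_wingbeats = 3,
                                     body = list(yaw_rate = 0, roll = 0))
  n <- length(seqq$times)
  xb <- matrix(NA_real_, n, 3); sl <- xb; sr <- xb
  yb_true <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    R <- body_rotation(seqq$body$yaw[f], seqq$body$pitch[f],
                       seqq$body$roll[f])
    xb[f, ] <- R[, 1]; yb_true[f, ] <- R[, 2]
    vl <- wing_vectors_from_angles(seqq$left$phi[f], seqq$left$theta[f],
                                   seqq$left$psi[f], "left", R[, 1], R[, 2])
    vr <- wing_vectors_from_angles(seqq$right$phi[f], seqq$right$theta[f],
                                   seqq$right$psi[f], "right", R[, 1], R[, 2])
    sl[f, ] <- vl$s; sr[f, ] <- vr$s
  }
  est <- estimate_yb(seqq$times, xb, sl, sr)
  ang <- acos(pmin(1, rowSums(est$yb * yb_true))) * 180 / pi
  expect_lt(max(ang), 2)
  # orthogonality contracts per frame
  expect_lt(max(abs(rowSums(est$yb * xb))), 1e-9)
  expect_equal(rowSums(est$zb^2), rep(1, n), tolerance = 1e-9)
  # mirror-symmetric perpendicular spans give y_b exactly
  e2 <- estimate_yb(c(0, 1, 2),
                    matrix(c(1, 0, 0), 3, 3, byrow = TRUE),
                    matrix(c(0, 1, 0), 3, 3, byrow = TRUE),
                    matrix(c(0, -1, 0), 3, 3, byrow = TRUE))
  expect_equal(e2$yb[2, ], c(0, 1, 0), tolerance = 1e-9)
})

test_that("body rates recover prescribed angular velocities", {
  dt <- 1e-4
  t <- seq(0, 0.05, dt)
  # constant 100 deg/s about the body x axis
  rots <- lapply(t, function(tt) {
    body_rotation(10, 20, 0) %*% rotation_about_axis(c(1, 0, 0), 100 * tt)
  })
  bar <- body_angles_and_rates(t, rots)
  mid <- 10:40
  expect_lt(max(abs(bar$p[mid] - 100)), 1)
  expect_lt(max(abs(bar$q[mid])), 1)
  expect_lt(max(abs(bar$r[mid])), 1)
  # static body: all rates zero
  bar0 <- body_angles_and_rates(t[1:10], rep(list(body_rotation(5, 5, 5)), 10))
  expect_equal(max(abs(c(bar0$p, bar0$q, bar0$r))), 0, tolerance = 1e-9)
  # convergence: halving dt shrinks the worst-case rate error quadratically
  err_at <- function(dt) {
    t <- seq(0, 0.02, dt)
    rots <- lapply(t, function(tt) {
      rotation_about_axis(c(0, 0, 1), 300 * tt) %*%
        rotation_about_axis(c(1, 0, 0), 200 * tt)
    })
    b <- body_angles_and_rates(t, rots)
    max(abs(b$p[5:(length(t) - 5)] - 200))
  }
  e1 <- err_at(2e-4); e2 <- err_at(1e-4)
  expect_lt(e2, e1 / 2.5)
})

test_that("yaw/pitch/roll round-trip through the rotation matrix", {
  set.seed(12)
  for (i in 1:30) {
    ang <- c(runif(1, -179, 179), runif(1, -89, 89), runif(1, -179, 179))
    R <- body_rotation(ang[1], ang[2], ang[3])
    expect_equal(as.numeric(body_angles(R)), ang, tolerance = 1e-9)
  }
})

test_that("wingbeat summaries extract analytic stroke extrema", {
  m <- fix_model()
  seqq <- generate_wingbeat_sequence(m, n_wingbeats = 5,
                                     wings = list(phi_mean = 90,
                                                  phi_amp = 70))
  kin <- data.frame(t = seqq$times, phi_left = seqq$left$phi,
                    phi_right = seqq$right$phi)
  wb <- wingbeat_summaries(kin)
  expect_gte(nrow(wb), 3)                 # interior beats are segmented
  expect_lt(max(abs(wb$phi_front_left - 160)), 1)
  expect_lt(max(abs(wb$phi_back_left - 20)), 1)
  expect_equal(wb$dphi_front, rep(0, nrow(wb)), tolerance = 1e-9)
  expect_true(all(wb$phi_front_left >= wb$phi_back_left))
  # fewer than one complete wingbeat -> empty summary
  short <- kin[1:20, ]
  expect_equal(nrow(wingbeat_summaries(short)), 0)
})
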