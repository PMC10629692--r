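test_that("fly model constructor contracts hold", {
  m <- fix_model()
  # watertight body: every edge shared by exactly two triangles
  tr <- m$body$tris
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # planar, simple wing outline with positive area
  expect_gt(wing_area(m), 0)
  expect_error(build_fly_model(L_b = -1), "positive")
  expect_error(build_fly_model(L_w = 0), "positive")
})

test_that("wing area equals an independent chord-profile integral", {
  m <- fix_model()
  # area = integral of (le - te) over the span, fine trapezoid rule
  ts <- seq(0, 1, length.out = 20001)
  width <- m$max_chord * flyhull:::wing_chord_profile(ts)  # le - te
  a_int <- sum((width[-1] + width[-length(width)]) / 2 * diff(ts)) * m$L_w
  expect_equal(wing_area(m), a_int, tolerance = 5e-3)
})

test_that("doubling the span scales the outline about the hinge", {
  m1 <- build_fly_model(L_w = 2.5e-3)
  m2 <- build_fly_model(L_w = 5.0e-3)
  p1 <- flyhull:::wing_outline_polygon(m1)
  p2 <- flyhull:::wing_outline_polygon(m2)
  expect_equal(p2[, 1], 2 * p1[, 1], tolerance = 1e-12)  # span coordinate
  expect_equal(p2[, 2], p1[, 2], tolerance = 1e-12)      # chord unchanged
})

test_that("pose_model places the body and wings as prescribed", {
  m <- fix_model()
  p <- pose_model(m, body_pose(), wing_pose(90, 0, 0, "left"),
                  wing_pose(90, 0, 0, "right"))
  expect_equal(p$truth$position, c(0, 0, 0))
  expect_equal(p$truth$x_b, c(1, 0, 0))
  # ground-truth span/chord are unit and orthogonal
  for (side in c("left", "right")) {
    expect_equal(sum(p$truth$s[[side]]^2), 1, tolerance = 1e-9)
    expect_equal(sum(p$truth$c[[side]]^2), 1, tolerance = 1e-9)
    expect_lt(abs(sum(p$truth$s[[side]] * p$truth$c[[side]])), 1e-9)
  }
  expect_error(pose_model(m, list(position = 0, R = diag(2)),
                          wing_pose(0, 0, 0, "left"),
                          wing_pose(0, 0, 0, "right")))
})

test_that("returned span matches an independent rotation-composition oracle", {
  # left wing, arbitrary pose: compose the construction by explicit
  # Rodrigues rotations instead of the package's algebra
  yaw <- 25; pitch <- 40; roll <- -10
  phi <- 115; theta <- 12
  R <- rotation_about_axis(c(0, 0, 1), yaw) %*%
    rotation_about_axis(c(0, 1, 0), -pitch) %*%
    rotation_about_axis(c(1, 0, 0), roll)
  x_b <- R[, 1]; y_b <- R[, 2]; z_b <- R[, 3]
  n <- (x_b + z_b) / sqrt(2)
  x_sp <- (x_b - z_b) / sqrt(2)
  u <- -cos(phi * pi / 180) * x_sp + sin(phi * pi / 180) * y_b
  s_expected <- cos(theta * pi / 180) * u + sin(theta * pi / 180) * n
  p <- pose_model(fix_model(), body_pose(yaw = yaw, pitch = pitch,
                                         roll = roll),
                  wing_pose(phi, theta, 70, "left"),
                  wing_pose(phi, theta, 70, "right"))
  expect_equal(p$truth$s$left, s_expected, tolerance = 1e-9)
  # mesh tip sits at hinge + L_w * s
  expect_equal(p$parts$wing_left$tip,
               p$parts$wing_left$hinge + fix_model()$L_w * p$truth$s$left,
               tolerance = 1e-12)
})

test_that("mirrored wing poses give mirror-symmetric geometry", {
  p <- pose_model(fix_model(), body_pose(),
                  wing_pose(70, 15, 50, "left"),
                  wing_pose(70, 15, 50, "right"))
  sl <- p$truth$s$left; sr <- p$truth$s$right
  # mirror across the body xz-plane: y components flip
  expect_equal(sl * c(1, -1, 1), sr, tolerance = 1e-9)
  expect_equal(p$truth$c$left * c(1, -1, 1), p$truth$c$right,
               tolerance = 1e-9)
})
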