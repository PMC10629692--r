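test_that("projection reproduces hand-computed pinhole results", {
  # canonical camera P = [I | 0]
  cam <- camera_model(1, cbind(diag(3), 0), c(128, 128))
  expect_equal(project_point(cam, c(0, 0, 1)), c(0, 0))
  # focal 100 px, principal point (64, 64): x = 100*0.01/1 + 64 = 65
  K <- matrix(c(100, 0, 0, 0, 100, 0, 64, 64, 1), 3, 3)
  cam2 <- camera_model(2, K %*% cbind(diag(3), 0), c(128, 128))
  expect_equal(project_point(cam2, c(0.01, 0, 1)), c(65, 64))
  # zero homogeneous depth is a degenerate projection
  expect_error(project_point(cam, c(0.1, 0.1, 0)), "degenerate")
})

test_that("rig presets satisfy their defining geometry", {
  for (preset in c("cartesian3", "pyramidal3")) {
    rig <- make_rig(preset)
    ax <- vapply(rig$cameras, flyhull:::camera_axis, numeric(3))
    G <- crossprod(ax)
    expect_lt(max(abs(G - diag(3))), 1e-9)   # mutually orthogonal axes
  }
  # pyramidal3: equal elevations atan(1/sqrt(2))
  rig <- make_rig("pyramidal3")
  elev <- vapply(rig$cameras, function(cm) {
    asin(-flyhull:::camera_axis(cm)[3])
  }, numeric(1))
  expect_equal(elev, rep(atan(1 / sqrt(2)), 3), tolerance = 1e-9)
  # hybrid4: one optical axis antiparallel to lab vertical
  rig <- make_rig("hybrid4")
  ax <- vapply(rig$cameras, flyhull:::camera_axis, numeric(3))
  expect_true(any(colSums(ax * c(0, 0, -1)) > 1 - 1e-9))
  expect_length(rig$cameras, 4)
  # every preset camera is aimed at the chamber center
  for (preset in c("cartesian3", "pyramidal3", "pyramidal4", "hybrid4")) {
    r <- make_rig(preset)
    for (cm in r$cameras) {
      pp <- c((cm$image_size[1] + 1) / 2, (cm$image_size[2] + 1) / 2)
      expect_lt(max(abs(project_point(cm, c(0, 0, 0)) - pp)), 1)
    }
  }
  expect_error(make_rig("nonsense"), "cartesian3")
})

test_that("project_voxels equals the per-point projection oracle", {
  grid <- fix_grid(n = 25)
  set.seed(11)
  idx <- cbind(sample(25, 1000, TRUE), sample(25, 1000, TRUE),
               sample(25, 1000, TRUE))
  for (cam in fix_rig()$cameras) {
    pv <- project_voxels(cam, grid, idx)
    for (r in sample(1000, 50)) {
      px <- project_point(cam, voxel_centers(grid, idx[r, , drop = FALSE]))
      expect_identical(pv$px[r], as.integer(round_half_away(px[1])))
      expect_identical(pv$py[r], as.integer(round_half_away(px[2])))
    }
  }
  # empty index set is allowed
  e <- project_voxels(fix_rig()$cameras[[1]], grid, idx[0, , drop = FALSE])
  expect_length(e$px, 0)
})

test_that("rounding is half-away-from-zero", {
  expect_equal(round_half_away(c(2.5, -2.5, 1.49, -1.5)), c(3, -3, 1, -2))
})

test_that("projection scale: doubling pixel pitch halves displacement", {
  r1 <- make_rig("hybrid4", pixel_pitch = 40e-6)
  r2 <- make_rig("hybrid4", pixel_pitch = 80e-6)
  p0 <- c(0, 0, 0); p1 <- c(1e-3, 0, 0)
  d1 <- project_point(r1$cameras[[1]], p1) - project_point(r1$cameras[[1]], p0)
  d2 <- project_point(r2$cameras[[1]], p1) - project_point(r2$cameras[[1]], p0)
  expect_equal(d1, 2 * d2, tolerance = 1e-9)
})

test_that("calibration JSON round-trips bit-exactly and validates schema", {
  rig <- make_rig("hybrid4")
  path <- tempfile(fileext = ".json")
  write_calibration(rig, path)
  rig2 <- read_calibration(path)
  for (j in 1:4) {
    expect_identical(rig2$cameras[[j]]$P, rig$cameras[[j]]$P)
    expect_identical(rig2$cameras[[j]]$image_size,
                     rig$cameras[[j]]$image_size)
  }
  # 11 entries -> schema error naming the camera
  bad <- list(cameras = list(list(id = 3, P = as.list(1:11),
                                  width = 64, height = 64)))
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_calibration(path), "camera 3")

  # hand-written canonical camera file agrees with manual matrix product
  hand <- list(cameras = list(list(
    id = 1, P = as.list(c(100, 0, 0, 0, 0, 100, 0, 0, 0, 0, 1, 0)),
    width = 128, height = 128)))
  jsonlite::write_json(hand, path, auto_unbox = TRUE)
  cam <- read_calibration(path)$cameras[[1]]
  expect_equal(project_point(cam, c(0.02, -0.01, 2)), c(1, -0.5))
})

test_that("triangulation recovers a point from exact projections", {
  rig <- fix_rig()
  pt <- c(3e-4, -2e-4, 5e-4)
  px <- t(vapply(rig$cameras, function(cm) project_point(cm, pt), numeric(2)))
  tri <- triangulate_pixels(rig, px)
  expect_lt(max(abs(tri$point - pt)), 1e-9)
  expect_lt(tri$residual, 1e-6)
  expect_error(triangulate_pixels(rig, matrix(NA_real_, 4, 2)), ">= 2")
})
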