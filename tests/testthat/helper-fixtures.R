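# Shared fixtures, built once per test run. Everything is generated in
# code; no stored data.

.fix <- new.env()

fix_rig <- function(preset = "hybrid4", image_size = c(256, 256),
                    pixel_pitch = 40e-6) {
  key <- paste(preset, image_size[1], pixel_pitch, sep = "_")
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- make_rig(preset, image_size = image_size,
                            pixel_pitch = pixel_pitch)
  }
  .fix[[key]]
}

fix_model <- function() {
  if (is.null(.fix$model)) .fix$model <- build_fly_model()
  .fix$model
}

# centered grid matching the default rig scale
fix_grid <- function(pitch = 40e-6, n = 163) {
  voxel_grid(origin = rep(-(n - 1) / 2 * pitch, 3), pitch = pitch,
             dims = rep(n, 3))
}

fix_ctx <- function() {
  if (is.null(.fix$ctx)) .fix$ctx <- carve_context(fix_grid(), fix_rig())
  .fix$ctx
}

# one posed fly + silhouettes, reused across tests
fix_posed <- function() {
  if (is.null(.fix$posed)) {
    .fix$posed <- pose_model(fix_model(), body_pose(pitch = 45),
                             wing_pose(60, 5, 45, "left"),
                             wing_pose(100, -10, 120, "right"))
  }
  .fix$posed
}

fix_sil <- function() {
  if (is.null(.fix$sil)) {
    .fix$sil <- render_silhouettes(fix_posed(), fix_rig(), alone = TRUE)
  }
  .fix$sil
}

# brute-force carve oracle: per-voxel, per-camera loop over the whole grid
oracle_carve <- function(grid, masks, rig) {
  d <- grid$dims
  keep <- numeric(0)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    ctr <- grid$origin + (c(i, j, k) - 1) * grid$pitch
    ok <- TRUE
    for (cj in seq_along(rig$cameras)) {
      if (is.null(masks[[cj]])) next
      cam <- rig$cameras[[cj]]
      px <- project_point(cam, ctr)
      xi <- round_half_away(px[1]); yi <- round_half_away(px[2])
      if (xi < 1 || xi > cam$image_size[1] || yi < 1 ||
          yi > cam$image_size[2] || !masks[[cj]][yi, xi]) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i)
  }
  sort(keep)
}
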