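tpl <- make_skeleton_template()

test_that("depth fusion replaces only the depth of the camera translation", {
  joints <- matrix(rnorm(135), 45, 3)
  # identical depths: fusion is a no-op relative to plain translation
  plain <- sweep(joints, 2, c(1, 2, 3), `+`)
  expect_equal(fuse_depth(joints, c(1, 2, 3), depth_b = 3), plain)
  # zero local joints land exactly at the fused translation
  z45 <- matrix(0, 45, 3)
  fused <- fuse_depth(z45, c(0, 0, 5), depth_b = 2)
  expect_true(all(fused[, 1] == 0 & fused[, 2] == 0 & fused[, 3] == 2))
  # algebraic identity: z-mean shifts by depth_b - translation z; x,y exact
  f <- fuse_depth(joints, c(0.3, -0.2, 5), depth_b = 2)
  u <- fuse_depth(joints, c(0.3, -0.2, 5), depth_b = 5)
  expect_equal(mean(f[, 3]) - mean(u[, 3]), 2 - 5)
  expect_identical(f[, 1:2], u[, 1:2])
  expect_error(fuse_depth(joints, c(0, 0, 1), depth_b = -1), "positive")
  expect_error(fuse_depth(joints, c(0, 0, NA), depth_b = 1), "finite")
})

test_that("completeness filter keeps exactly the all-valid videos", {
  ds <- make_test_dataset(40, seed = 20, dropout_rate = 0.01)
  flt <- filter_complete_videos(ds$tracks)
  truth <- vapply(ds$tracks, function(p) {
    all(p[[1]]$frame_valid) && all(p[[2]]$frame_valid)
  }, logical(1))
  expect_identical(flt$kept, names(ds$tracks)[truth])
  expect_identical(flt$excluded, names(ds$tracks)[!truth])
  # one manually injected failure excludes that video
  tr2 <- make_test_dataset(5, seed = 21)$tracks
  tr2[[3]][[2]]$frame_valid[47] <- FALSE
  flt2 <- filter_complete_videos(tr2)
  expect_identical(flt2$excluded, names(tr2)[3])
  expect_length(flt2$kept, 4)
  # wrong agent count is an error
  bad <- tr2
  bad[[1]] <- bad[[1]][1]
  expect_error(filter_complete_videos(bad), "two agents")
})

test_that("frame averaging equals the per-coordinate brute-force mean", {
  set.seed(22)
  coords <- array(rnorm(90 * 45 * 3), dim = c(90, 45, 3))
  trk <- structure(list(video_id = "v", agent = 0, coords = coords,
                        frame_valid = rep(TRUE, 90)),
                   class = "joint_track")
  avg <- average_frames(trk)
  oracle <- matrix(0, 45, 3)
  for (j in 1:45) for (k in 1:3) oracle[j, k] <- sum(coords[, j, k]) / 90
  expect_equal(avg, oracle, tolerance = 1e-12)
  # idempotent on constant tracks
  const <- array(rep(coords[1, , ], each = 4), dim = c(4, 45, 3))
  expect_equal(average_frames(const), coords[1, , ], tolerance = 1e-12)
  trk$frame_valid[10] <- FALSE
  expect_error(average_frames(trk), "invalid frames")
})

test_that("face position is the eye midpoint and translation-equivariant", {
  pose <- tpl$rest_pose
  li <- tpl$landmark_index
  pose[li[["left_eye"]], ] <- c(1, 0, 0)
  pose[li[["right_eye"]], ] <- c(-1, 0, 0)
  expect_equal(face_position(pose, tpl), c(0, 0, 0), ignore_attr = TRUE)
  pose[li[["right_eye"]], ] <- c(1, 0, 0)
  expect_equal(face_position(pose, tpl), c(1, 0, 0), ignore_attr = TRUE)
  v <- c(0.3, -1.2, 2.5)
  shifted <- sweep(tpl$rest_pose, 2, v, `+`)
  expect_equal(face_position(shifted, tpl) - face_position(tpl$rest_pose, tpl),
               v, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("facing direction matches the average-then-normalize definition", {
  li <- tpl$landmark_index
  pose <- tpl$rest_pose
  # both component vectors identical
  pose[li[["head_center"]], ] <- c(0, 0, 0)
  pose[li[["neck"]], ] <- c(0, 0, 0)
  pose[li[["nose"]], ] <- c(0, 0, 1)
  expect_equal(facing_direction(pose, tpl), c(0, 0, 1), ignore_attr = TRUE)
  # hand-computed asymmetric case: normalize((0, 0.5, 1))
  pose[li[["neck"]], ] <- c(0, -1, 0)
  expect_equal(facing_direction(pose, tpl),
               c(0, 0.5, 1) / sqrt(1.25), tolerance = 1e-6,
               ignore_attr = TRUE)
  # degenerate geometry errors out
  pose[li[["neck"]], ] <- c(0, 0, 2)
  pose[li[["head_center"]], ] <- c(0, 0, 2)
  pose[li[["nose"]], ] <- c(0, 0, 1.5)  # averaged vector = (0,0,-0.5): fine
  expect_equal(facing_direction(pose, tpl), c(0, 0, -1), ignore_attr = TRUE)
  pose[li[["nose"]], ] <- c(0, 0, 2)
  expect_error(facing_direction(pose, tpl), "degenerate")
})

test_that("facing direction is unit-norm, translation-invariant and rotation-equivariant", {
  set.seed(23)
  for (i in 1:20) {
    pose <- tpl$rest_pose + matrix(rnorm(135, sd = 0.05), 45, 3)
    d <- facing_direction(pose, tpl)
    expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-12)
    v <- rnorm(3)
    expect_equal(facing_direction(sweep(pose, 2, v, `+`), tpl), d,
                 tolerance = 1e-12)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    expect_equal(facing_direction(pose %*% t(R), tpl), drop(R %*% d),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("social pose vectors have the documented layout and lengths", {
  ds <- make_test_dataset(4, seed = 24)
  pair <- order_agents(ds$tracks[[1]])
  v3 <- assemble_social_vector(pair[[1]], pair[[2]], tpl, mode = "3D")
  v2 <- assemble_social_vector(pair[[1]], pair[[2]], tpl, mode = "2D")
  expect_length(v3, 12)
  expect_length(v2, 8)
  # 2D is the 3D vector with the z and dz components dropped, per agent
  expect_equal(unname(v2), unname(v3[c(1, 2, 4, 5, 7, 8, 10, 11)]),
               tolerance = 1e-12)
  # constant-over-time track: per-frame-then-average == average-pose route
  lat <- ds$latents[[1]]
  tr0 <- render_joint_tracks(lat, noise_sd = 0, frames = 10, seed = 1)
  a <- assemble_social_vector(tr0[[1]], tr0[[2]], tpl, mode = "3D",
                              frames_mode = "per_frame_then_average")
  b <- assemble_social_vector(tr0[[1]], tr0[[2]], tpl, mode = "3D",
                              frames_mode = "average_pose")
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("joint flattening is the documented bijection", {
  set.seed(25)
  p1 <- matrix(rnorm(135), 45, 3)
  p2 <- matrix(rnorm(135), 45, 3)
  v <- flatten_joints(p1, p2)
  expect_length(v, 270)
  expect_equal(unname(v[1:3]), p1[1, ], ignore_attr = TRUE)
  expect_equal(unname(v[4:6]), p1[2, ], ignore_attr = TRUE)
  expect_equal(unname(v[136:138]), p2[1, ], ignore_attr = TRUE)
  back <- socialpose3d:::unflatten_joints(v)
  expect_equal(back[[1]], p1, ignore_attr = TRUE)
  expect_equal(back[[2]], p2, ignore_attr = TRUE)
  expect_error(flatten_joints(p1, p2[1:10, ]), "mismatch")
})

test_that("agent ordering is canonical and input-order invariant", {
  ds <- make_test_dataset(1, seed = 26)
  pair <- ds$tracks[[1]]
  # left agent first
  shift <- function(tr, dx, dz = 0) {
    tr$coords[, , 1] <- tr$coords[, , 1] + dx
    tr$coords[, , 3] <- tr$coords[, , 3] + dz
    tr
  }
  a <- shift(pair[[1]], -5)
  b <- shift(pair[[2]], +5)
  expect_identical(order_agents(list(a, b))[[1]]$agent, a$agent)
  expect_identical(order_agents(list(b, a))[[1]]$agent, a$agent)
  # tie in x broken by depth: nearer agent first
  base <- pair[[1]]
  near <- shift(base, -mean(base$coords[, , 1]), 2 - mean(base$coords[, , 3]))
  far <- shift(base, -mean(base$coords[, , 1]), 3 - mean(base$coords[, , 3]))
  ord <- order_agents(list(far, near))
  expect_equal(mean(ord[[1]]$coords[, , 3]), 2, tolerance = 1e-9)
})

test_that("noiseless scenes recover the latent positions and directions", {
  lat <- sample_scene_latents(25, scene_config(), seed = 27)
  for (l in lat[1:10]) {
    tr <- render_joint_tracks(l, noise_sd = 0, frames = 5, seed = 1)
    v3 <- assemble_social_vector(tr[[1]], tr[[2]], tpl, mode = "3D")
    expect_equal(unname(v3[1:3]), l$p1, tolerance = 1e-9,
                 ignore_attr = TRUE)
    ang <- acos(min(1, sum(v3[4:6] * l$d1)))
    expect_lt(ang, 1e-6)
    expect_equal(unname(v3[7:9]), l$p2, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("feature tables have exact dimensionality on every construction", {
  ds <- make_test_dataset(12, seed = 28, dropout_rate = 0.005)
  ft <- ds$feats
  expect_identical(ncol(ft$social3d) - 1L, 12L)
  expect_identical(ncol(ft$social2d) - 1L, 8L)
  expect_identical(ncol(ft$joints) - 1L, 270L)
  expect_identical(nrow(ft$social3d), length(ft$kept))
  expect_identical(sort(c(ft$kept, ft$excluded)), sort(names(ds$tracks)))
})
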