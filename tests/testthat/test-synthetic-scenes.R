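test_that("skeleton template satisfies its geometric invariants", {
  tpl <- make_skeleton_template()
  expect_identical(tpl$joint_count, 45L)
  expect_identical(nrow(tpl$rest_pose), 45L)
  li <- tpl$landmark_index
  expect_setequal(names(li), c("left_eye", "right_eye", "nose",
                               "head_center", "neck"))
  expect_identical(anyDuplicated(li), 0L)
  expect_true(all(li >= 1 & li <= 45))
  # eyes mirror across the sagittal plane
  le <- tpl$rest_pose[li[["left_eye"]], ]
  re <- tpl$rest_pose[li[["right_eye"]], ]
  expect_equal(le[["x"]], -re[["x"]])
  expect_equal(le[c("y", "z")], re[c("y", "z")])
  # nose strictly forward of head center along the canonical facing axis
  expect_gt(tpl$rest_pose[li[["nose"]], "z"],
            tpl$rest_pose[li[["head_center"]], "z"])
  # construction is deterministic
  expect_identical(tpl, make_skeleton_template())
})

test_that("scene latent sampling is seeded and respects configured ranges", {
  cfg <- scene_config()
  a <- sample_scene_latents(4, cfg, seed = 1)
  b <- sample_scene_latents(4, cfg, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, sample_scene_latents(4, cfg, seed = 2)))

  lat <- sample_scene_latents(1000, cfg, seed = 7)
  d <- vapply(lat, function(l) sqrt(sum((l$p1 - l$p2)^2)), numeric(1))
  lim <- cfg$distance_range * cfg$scene_scale_range[c(1, 2)]
  expect_true(all(d >= lim[1] - 1e-9 & d <= lim[2] + 1e-9))
  s <- vapply(lat, `[[`, numeric(1), "scene_scale")
  expect_true(all(s >= cfg$scene_scale_range[1] &
                  s <= cfg$scene_scale_range[2]))
  # unit facing, positive depth
  for (l in lat[1:50]) {
    expect_equal(sqrt(sum(l$d1^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(l$d2^2)), 1, tolerance = 1e-12)
    expect_gt(l$p1[3], 0)
    expect_gt(l$p2[3], 0)
  }
})

test_that("mutual facing mode points each agent exactly at the other", {
  lat <- sample_scene_latents(20, scene_config(facing_mode = "mutual"),
                              seed = 3)
  for (l in lat) {
    u12 <- (l$p2 - l$p1) / sqrt(sum((l$p2 - l$p1)^2))
    expect_equal(l$d1, u12, tolerance = 1e-12)
    expect_equal(l$d2, -u12, tolerance = 1e-12)
  }
})

test_that("zero-noise rendering repeats the posed rest pose on every frame", {
  lat <- sample_scene_latents(1, scene_config(), seed = 4)[[1]]
  tr <- render_joint_tracks(lat, noise_sd = 0, frames = 90, seed = 1)
  for (agent in tr) {
    expect_true(all(agent$frame_valid))
    first <- agent$coords[1, , ]
    for (f in c(2, 45, 90)) {
      expect_equal(agent$coords[f, , ], first)
    }
  }
  # face anchored at the latent position, direction recovered exactly
  tpl <- make_skeleton_template()
  avg <- average_frames(tr[[1]])
  expect_equal(face_position(avg, tpl), lat$p1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(facing_direction(avg, tpl), lat$d1, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rendering is a rigid motion that realizes the latent pose", {
  tpl <- make_skeleton_template()
  lat <- sample_scene_latents(5, scene_config(), seed = 5)
  rest_d <- as.matrix(dist(tpl$rest_pose))
  for (l in lat) {
    tr <- render_joint_tracks(l, tpl, noise_sd = 0, frames = 1, seed = 1)
    for (a in 1:2) {
      posed <- tr[[a]]$coords[1, , ]
      # rigid: all pairwise joint distances preserved
      expect_equal(as.matrix(dist(posed)), rest_d, tolerance = 1e-9,
                   ignore_attr = TRUE)
      # the canonical facing axis lands on the latent direction and the
      # anchor (eye midpoint) on the latent position
      d_lat <- if (a == 1) l$d1 else l$d2
      p_lat <- if (a == 1) l$p1 else l$p2
      expect_equal(unname(facing_direction(posed, tpl)), d_lat,
                   tolerance = 1e-9)
      expect_equal(unname(face_position(posed, tpl)), p_lat,
                   tolerance = 1e-9)
    }
    # translating the latent position translates every joint rigidly
    l2 <- l; v <- c(0.4, -0.2, 1.1); l2$p1 <- l$p1 + v
    tr2 <- render_joint_tracks(l2, tpl, noise_sd = 0, frames = 1, seed = 1)
    expect_equal(tr2[[1]]$coords[1, , ],
                 sweep(tr[[1]]$coords[1, , ], 2, v, `+`), tolerance = 1e-9)
  }
})

test_that("frame dropout fails videos at the closed-form rate", {
  rate <- 0.1
  n <- 200
  frames <- 90
  lat <- sample_scene_latents(n, scene_config(), seed = 6)
  tracks <- render_scene_batch(lat, noise_sd = 0, dropout_rate = rate,
                               frames = frames, seed = 8)
  failed <- sum(!vapply(tracks, function(pair) {
    all(pair[[1]]$frame_valid) && all(pair[[2]]$frame_valid)
  }, logical(1)))
  p_fail <- 1 - (1 - rate)^frames
  # 3-sigma binomial band around the expectation
  expect_lt(abs(failed / n - p_fail), 3 * sqrt(p_fail * (1 - p_fail) / n))
  # invalid frames are shared between the two agents and have NA coords
  pair <- tracks[[which(!vapply(tracks, function(p) all(p[[1]]$frame_valid),
                                logical(1)))[1]]]
  expect_identical(pair[[1]]$frame_valid, pair[[2]]$frame_valid)
  bad <- which(!pair[[1]]$frame_valid)[1]
  expect_true(all(is.na(pair[[1]]$coords[bad, , ])))
})

test_that("ratings match the generative law in the noiseless limit", {
  lat <- sample_scene_latents(100, scene_config(), seed = 9)
  rt0 <- generate_ratings(lat, rater_sd = 0, seed = 10)
  expect_true(all(vapply(rating_names(), function(d) {
    all(rt0[[d]] >= 1 & rt0[[d]] <= 5)
  }, logical(1))))
  # noiseless ratings are the affinely rescaled raw scores: the distance
  # rating is a perfect monotone transform of the true distance
  d_true <- vapply(lat, function(l) sqrt(sum((l$p1 - l$p2)^2)), numeric(1))
  expect_equal(cor(rt0$interagent_distance, d_true, method = "spearman"), 1)
  expect_equal(range(rt0$interagent_distance), c(1, 5))
  # exact mutual facing pins the facing score at the top of the batch scale
  lat_mut <- sample_scene_latents(50, scene_config(facing_mode = "mutual"),
                                  seed = 11)
  lat_mix <- c(lat_mut, sample_scene_latents(50, scene_config(), seed = 12))
  # keep ids unique after concatenation
  for (i in seq_along(lat_mix)) lat_mix[[i]]$video_id <- sprintf("v%03d", i)
  rt_mix <- generate_ratings(lat_mix, rater_sd = 0, seed = 13)
  expect_equal(max(rt_mix$agents_facing[1:50]), 5)
})

test_that("rater panel noise averages down at the 1/sqrt(n) rate", {
  lat <- sample_scene_latents(500, scene_config(), seed = 14)
  rt0 <- generate_ratings(lat, rater_sd = 0, seed = 15)
  rt <- generate_ratings(lat, rater_sd = 0.5, n_raters = 10, seed = 15)
  resid <- unlist(lapply(rating_names(), function(d) rt[[d]] - rt0[[d]]))
  # clipping at the scale ends shrinks the SD slightly below 0.5/sqrt(10)
  expect_lt(abs(sd(resid) - 0.5 / sqrt(10)), 0.04)
  expect_true(all(rt[rating_names()] >= 1 & rt[rating_names()] <= 5))
})

test_that("facing score is bounded and symmetric under agent swap", {
  lat <- sample_scene_latents(200, scene_config(), seed = 16)
  raw <- socialpose3d:::raw_rating_scores(lat)
  expect_true(all(raw[, "agents_facing"] >= -1 - 1e-12 &
                  raw[, "agents_facing"] <= 1 + 1e-12))
  swapped <- lapply(lat, function(l) {
    s <- l; s$p1 <- l$p2; s$p2 <- l$p1; s$d1 <- l$d2; s$d2 <- l$d1; s
  })
  raw_sw <- socialpose3d:::raw_rating_scores(swapped)
  expect_equal(raw_sw[, "agents_facing"], raw[, "agents_facing"],
               tolerance = 1e-12)
})

test_that("embedding sets carry controlled, monotone pose information", {
  ds <- make_test_dataset(120, seed = 17)
  # determinism
  e1 <- generate_embeddings(ds$feats$social3d, 0.5, dim = 32, seed = 1)
  e2 <- generate_embeddings(ds$feats$social3d, 0.5, dim = 32, seed = 1)
  expect_identical(e1, e2)
  X3 <- fmat(ds$feats$social3d)
  dec <- vapply(c(0, 0.6, 1), function(il) {
    E <- generate_embeddings(ds$feats$social3d, il, dim = 24, seed = 3)
    decode_features(E$matrix, X3, ds$split, seed = 4)$mean_r
  }, numeric(1))
  expect_lt(abs(dec[1]), 0.15)          # info 0: chance-level decoding
  expect_gt(dec[3], 0.99)               # info 1, dim >= k: fully decodable
  expect_true(all(diff(dec) > 0))       # monotone in between
  expect_error(generate_embeddings(ds$feats$social3d, 1.2, dim = 8, seed = 1),
               "info_level")
})

test_that("generator input validation rejects bad arguments", {
  expect_error(sample_scene_latents(0, scene_config(), seed = 1), "positive")
  expect_error(scene_config(distance_range = c(-1, 2)))
  expect_error(generate_ratings(sample_scene_latents(3, seed = 1),
                                n_raters = 0), "n_raters")
  expect_error(generate_ratings(sample_scene_latents(3, seed = 1),
                                rater_sd = -0.1), "rater_sd")
})

test_that("file round-trips reproduce tracks, ratings and embeddings", {
  ds <- make_test_dataset(6, seed = 18, dropout_rate = 0.01, frames = 30)
  td <- withr::local_tempdir()
  # joint tracks
  p <- file.path(td, "tracks.csv")
  write_joint_tracks(ds$tracks, p)
  back <- read_joint_tracks(p)
  expect_identical(names(back), names(ds$tracks))
  for (id in names(back)) {
    for (a in 1:2) {
      expect_equal(back[[id]][[a]]$coords, ds$tracks[[id]][[a]]$coords,
                   tolerance = 1e-12)
      expect_identical(back[[id]][[a]]$frame_valid,
                       ds$tracks[[id]][[a]]$frame_valid)
    }
  }
  # ratings
  rp <- file.path(td, "ratings.csv")
  write_rating_table(ds$ratings, rp)
  rt_back <- read_rating_table(rp)
  expect_equal(rt_back, ds$ratings[, names(rt_back)], tolerance = 1e-12,
               ignore_attr = TRUE)
  # embeddings
  emb <- generate_embeddings(ds$feats$social3d, 0.7, dim = 16, seed = 2,
                             model_name = "m1", layer_name = "l2")
  ep <- write_embedding_set(emb, td)
  emb_back <- read_embedding_set(file.path(td, "m1__l2.csv"))
  expect_identical(emb_back$model_name, "m1")
  expect_identical(emb_back$layer_name, "l2")
  expect_equal(emb_back$matrix, emb$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  # feature table
  fp <- file.path(td, "social3d.csv")
  write_feature_table(ds$feats$social3d, fp)
  expect_equal(read_feature_table(fp), ds$feats$social3d,
               tolerance = 1e-12, ignore_attr = TRUE)
})
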