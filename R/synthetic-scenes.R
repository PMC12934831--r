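#' Scene generator settings
#'
#' Defaults describe naturalistic two-person scenes filmed by a fixed camera
#' (x lateral, y vertical, z depth away from the camera, meters): agents a
#' few meters away, separated mostly along depth, loosely oriented toward
#' each other.  The depth-heavy separation reflects that in real footage the
#' camera-to-subject axis carries most of the spatial layout variance.
#'
#' @param distance_range Base inter-agent distance range (m), sampled
#'   uniformly and multiplied by the scene scale (people stand farther
#'   apart in bigger scenes).
#' @param midpoint_x_range,midpoint_y_range,midpoint_z_range Ranges for the
#'   dyad midpoint before scene scaling.
#' @param separation_sd Axis standard deviations (x, y, z) used to draw the
#'   direction of the inter-agent separation; the default puts most
#'   separation variance into depth (z).  The x and z components are drawn
#'   with a consistent sign (a staging convention: the nearer agent appears
#'   on the left), so depth separation is linearly decodable from 3D
#'   positions instead of being an even-symmetric, linearly invisible
#'   quantity.
#' @param scene_scale_range Scene scale `s` is log-uniform over this range;
#'   it multiplies the dyad midpoint and the inter-agent distance (bigger
#'   scenes place people farther away and more spread out).
#' @param facing_mode One of `"noisy_mutual"` (each agent faces the other
#'   plus angular noise), `"mutual"` (exactly toward the other), or
#'   `"uniform"` (uniform random directions).
#' @param facing_jitter_sd SD of the isotropic Gaussian perturbation added
#'   to the unit toward-other vector in `"noisy_mutual"` mode (unitless;
#'   larger values spread facing angles over the sphere).
#' @return A list of settings for [sample_scene_latents()].
#' @export
scene_config <- function(distance_range = c(0.6, 2.5),
                         midpoint_x_range = c(-1.5, 1.5),
                         midpoint_y_range = c(-0.3, 0.3),
                         midpoint_z_range = c(3.0, 7.0),
                         separation_sd = c(1.0, 0.25, 1.6),
                         scene_scale_range = c(0.6, 1.8),
                         facing_mode = c("noisy_mutual", "mutual", "uniform"),
                         facing_jitter_sd = 0.8) {
  facing_mode <- match.arg(facing_mode)
  stopifnot(length(distance_range) == 2L, distance_range[1] > 0,
            diff(distance_range) >= 0,
            length(scene_scale_range) == 2L, scene_scale_range[1] > 0,
            diff(scene_scale_range) >= 0,
            length(separation_sd) == 3L, all(separation_sd >= 0),
            sum(separation_sd) > 0,
            facing_jitter_sd >= 0)
  list(distance_range = distance_range,
       midpoint_x_range = midpoint_x_range,
       midpoint_y_range = midpoint_y_range,
       midpoint_z_range = midpoint_z_range,
       separation_sd = separation_sd,
       scene_scale_range = scene_scale_range,
       facing_mode = facing_mode,
       facing_jitter_sd = facing_jitter_sd)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Sample latent scene descriptions for two-agent videos
#'
#' Draws, per video, the ground-truth quantities the synthetic pipeline is
#' built on: each agent's 3D position (the eventual face position), unit
#' facing direction, and a positive scene scale.  Identical seed and config
#' give bit-identical output.
#'
#' @param n_videos Number of videos (>= 1).
#' @param config Settings from [scene_config()].
#' @param seed Integer seed.
#' @return A list of `scene_latents` objects, each with `video_id`, `p1`,
#'   `p2` (3-vectors, meters, camera frame, positive depth), `d1`, `d2`
#'   (unit 3-vectors), `scene_scale`, and `seed`.
#' @examples
#' lat <- sample_scene_latents(3, scene_config(), seed = 1)
#' lat[[1]]$p1
#' @export
sample_scene_latents <- function(n_videos, config = scene_config(), seed = 1) {
  if (!is.numeric(n_videos) || n_videos < 1) {
    stop("`n_videos` must be a positive integer", call. = FALSE)
  }
  n_videos <- as.integer(n_videos)
  with_seed(seed, {
    s <- exp(runif_range(n_videos, log(config$scene_scale_range)))
    mid <- cbind(runif_range(n_videos, config$midpoint_x_range),
                 runif_range(n_videos, config$midpoint_y_range),
                 runif_range(n_videos, config$midpoint_z_range))
    dist <- s * runif_range(n_videos, config$distance_range)
    sep_dir <- matrix(stats::rnorm(3L * n_videos), n_videos, 3L,
                      byrow = TRUE) *
      matrix(config$separation_sd, n_videos, 3L, byrow = TRUE)
    # staging convention: separation points rightward and away from the
    # camera, so the left agent is also the nearer one
    sep_dir[, 1L] <- abs(sep_dir[, 1L])
    sep_dir[, 3L] <- abs(sep_dir[, 3L])
    sep_dir <- sep_dir / sqrt(rowSums(sep_dir^2))
    lapply(seq_len(n_videos), function(i) {
      m <- s[i] * mid[i, ]
      half <- 0.5 * dist[i] * sep_dir[i, ]
      p1 <- m - half
      p2 <- m + half
      # keep both agents in front of the camera
      min_z <- min(p1[3], p2[3])
      if (min_z < 0.5) {
        shift <- 0.5 - min_z
        p1[3] <- p1[3] + shift
        p2[3] <- p2[3] + shift
      }
      toward <- function(from, to) unitize(to - from)
      d <- switch(config$facing_mode,
        mutual = list(toward(p1, p2), toward(p2, p1)),
        noisy_mutual = list(
          unitize(toward(p1, p2) + config$facing_jitter_sd * stats::rnorm(3)),
          unitize(toward(p2, p1) + config$facing_jitter_sd * stats::rnorm(3))
        ),
        uniform = list(unitize(stats::rnorm(3)), unitize(stats::rnorm(3)))
      )
      structure(
        list(video_id = sprintf("vid%04d", i),
             p1 = p1, p2 = p2,
             d1 = d[[1]], d2 = d[[2]],
             scene_scale = s[i],
             seed = as.integer(seed)),
        class = "scene_latents"
      )
    })
  })
}

#' Render noisy joint tracks for one synthetic scene
#'
#' Emulates a pose estimator's per-frame output: the skeleton rest pose is
#' rotated so the template's canonical facing axis maps onto the agent's
#' latent direction, pivoted about the eye midpoint, translated to the
#' agent's latent position, and perturbed by per-frame isotropic Gaussian
#' jitter.  Optional frame dropout emulates detector failures: a dropped
#' frame invalidates both agents' detections on that frame (its coordinates
#' are set to `NA`).
#'
#' @param latents A `scene_latents` object.
#' @param template Skeleton from [make_skeleton_template()].
#' @param noise_sd Per-coordinate jitter SD in meters (default 0.02, the
#'   order of modern per-joint estimator error).
#' @param dropout_rate Per-frame probability of a detection failure.
#' @param frames Number of frames (default 90, i.e. 3 s at 30 fps).
#' @param seed Integer seed.
#' @return List of two `joint_track` objects (`video_id`, `agent` in 0:1,
#'   `coords` frames x 45 x 3 array, `frame_valid` logical vector).
#' @export
render_joint_tracks <- function(latents, template = make_skeleton_template(),
                                noise_sd = 0.02, dropout_rate = 0,
                                frames = 90L, seed = 1) {
  stopifnot(inherits(latents, "scene_latents"), frames >= 1,
            noise_sd >= 0, dropout_rate >= 0, dropout_rate <= 1)
  frames <- as.integer(frames)
  rest <- template$rest_pose
  eye_mid <- (landmark_coords(rest, template, "left_eye") +
              landmark_coords(rest, template, "right_eye")) / 2
  centered <- sweep(rest, 2L, eye_mid)
  with_seed(seed, {
    valid <- if (dropout_rate > 0) {
      stats::runif(frames) >= dropout_rate
    } else {
      rep(TRUE, frames)
    }
    tracks <- lapply(0:1, function(a) {
      d <- if (a == 0L) latents$d1 else latents$d2
      p <- if (a == 0L) latents$p1 else latents$p2
      if (vnorm(d) < 1e-12) {
        stop("degenerate facing direction (zero vector)", call. = FALSE)
      }
      posed <- centered %*% t(rotation_from_z(d))
      posed <- sweep(posed, 2L, p, `+`)
      coords <- array(rep(posed, each = frames),
                      dim = c(frames, nrow(rest), 3L))
      if (noise_sd > 0) {
        coords <- coords + array(stats::rnorm(length(coords), sd = noise_sd),
                                 dim = dim(coords))
      }
      coords[!valid, , ] <- NA_real_
      structure(
        list(video_id = latents$video_id, agent = a,
             coords = coords, frame_valid = valid),
        class = "joint_track"
      )
    })
    tracks
  })
}

#' Simulate a full batch of joint tracks
#'
#' Convenience wrapper: renders both agents of every scene with per-video
#' seeds derived from `seed`.
#'
#' @inheritParams render_joint_tracks
#' @param latents_list List from [sample_scene_latents()].
#' @return Named list (by video id) of two-track lists.
#' @export
render_scene_batch <- function(latents_list,
                               template = make_skeleton_template(),
                               noise_sd = 0.02, dropout_rate = 0,
                               frames = 90L, seed = 1) {
  out <- lapply(seq_along(latents_list), function(i) {
    render_joint_tracks(latents_list[[i]], template,
                        noise_sd = noise_sd, dropout_rate = dropout_rate,
                        frames = frames, seed = derive_seed(seed, i))
  })
  names(out) <- vapply(latents_list, `[[`, character(1), "video_id")
  out
}

#' Default generative rating weights
#'
#' Coefficients of the latent-to-rating model: the communicative score is
#' `w_facing * facing - w_distance * distance`, and the physical score is
#' `w_physical * max(0, 1 - distance / contact_range)`.
#'
#' @param w_facing,w_distance,w_physical Positive coefficients.
#' @param contact_range Distance (m) beyond which physical interaction is
#'   scored zero.
#' @return Named list of weights.
#' @export
rating_weights <- function(w_facing = 1, w_distance = 0.3, w_physical = 1,
                           contact_range = 2.0) {
  list(w_facing = w_facing, w_distance = w_distance,
       w_physical = w_physical, contact_range = contact_range)
}

# raw (pre-rescaling) scores computed from the latents
raw_rating_scores <- function(latents_list, weights = rating_weights()) {
  vals <- t(vapply(latents_list, function(l) {
    dvec <- l$p2 - l$p1
    dist <- vnorm(dvec)
    u12 <- dvec / dist
    facing <- 0.5 * (sum(l$d1 * u12) + sum(l$d2 * (-u12)))
    c(spatial_expanse = log(l$scene_scale),
      interagent_distance = dist,
      agents_facing = facing,
      communicative = weights$w_facing * facing -
        weights$w_distance * dist,
      physical = weights$w_physical *
        max(0, 1 - dist / weights$contact_range))
  }, numeric(5)))
  rownames(vals) <- vapply(latents_list, `[[`, character(1), "video_id")
  vals
}

# affine rescale of a column to [1, 5]; a constant column maps to 3
rescale_1_5 <- function(x) {
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) return(rep(3, length(x)))
  1 + 4 * (x - rng[1]) / diff(rng)
}

#' Generate averaged behavioral ratings from scene latents
#'
#' Each of the five dimensions is derived from the latent scene variables
#' (scene scale, inter-agent distance, mutual facing), affinely rescaled to
#' the 1-5 rating scale over the batch, perturbed independently per
#' simulated rater with Gaussian noise, clipped to the scale, and averaged
#' over the rater panel.
#'
#' @param latents_list List from [sample_scene_latents()].
#' @param weights Generative coefficients from [rating_weights()].
#' @param n_raters Panel size (>= 1; default 10).
#' @param rater_sd Per-rater noise SD on the 1-5 scale (default 0.5).
#' @param train_fraction Fraction of videos assigned to the training split.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `video_id`, `split` ("train" or
#'   "test"), and the five rating dimensions, each in \[1, 5\].
#' @export
generate_ratings <- function(latents_list, weights = rating_weights(),
                             n_raters = 10L, rater_sd = 0.5,
                             train_fraction = 0.8, seed = 1) {
  if (n_raters < 1) stop("`n_raters` must be >= 1", call. = FALSE)
  if (rater_sd < 0) stop("`rater_sd` must be non-negative", call. = FALSE)
  raw <- raw_rating_scores(latents_list, weights)
  scaled <- apply(raw, 2L, rescale_1_5)
  if (is.null(dim(scaled))) scaled <- matrix(scaled, nrow = 1L,
                                             dimnames = list(rownames(raw),
                                                             colnames(raw)))
  n <- nrow(scaled)
  with_seed(seed, {
    rated <- scaled
    if (rater_sd > 0) {
      for (k in seq_len(ncol(scaled))) {
        noise <- matrix(stats::rnorm(n * n_raters, sd = rater_sd),
                        n, n_raters)
        panel <- pmin(pmax(scaled[, k] + noise, 1), 5)
        rated[, k] <- rowMeans(panel)
      }
    }
    n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
    split <- rep("test", n)
    split[sample.int(n, n_train)] <- "train"
    if (n == 1L) split <- "train"
    data.frame(video_id = rownames(raw), split = split,
               rated, row.names = NULL, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic model embedding set with controlled pose information
#'
#' Stands in for a pretrained network's video embeddings.  The feature table
#' is column-standardized and passed through a seeded random linear map; the
#' resulting signal columns are mixed with Gaussian noise as
#' `info_level * signal + (1 - info_level) * noise`, and any remaining
#' columns are pure noise.  `info_level = 0` gives embeddings independent of
#' the pose features; `info_level = 1` makes them fully linearly decodable.
#'
#' @param features Numeric matrix or data.frame (with `video_id` column) of
#'   per-video pose features.
#' @param info_level Pose information level in \[0, 1\].
#' @param dim Embedding width (>= 1).
#' @param seed Integer seed.
#' @param model_name,layer_name Labels stored with the set.
#' @return An `embedding_set`: list with `model_name`, `layer_name`,
#'   `matrix` (n_videos x dim), `video_index`, `info_level`.
#' @export
generate_embeddings <- function(features, info_level, dim = 64L, seed = 1,
                                model_name = "synth", layer_name = "layer0") {
  if (info_level < 0 || info_level > 1) {
    stop("`info_level` must lie in [0, 1]", call. = FALSE)
  }
  if (dim < 1) stop("`dim` must be >= 1", call. = FALSE)
  dim <- as.integer(dim)
  if (is.data.frame(features)) {
    video_index <- as.character(features$video_id)
    F <- as.matrix(features[, setdiff(names(features), "video_id"),
                            drop = FALSE])
  } else {
    F <- as.matrix(features)
    video_index <- rownames(F)
    if (is.null(video_index)) video_index <- sprintf("vid%04d", seq_len(nrow(F)))
  }
  n <- nrow(F)
  k <- ncol(F)
  Fs <- scale(F)
  Fs[, attr(Fs, "scaled:scale") == 0] <- 0
  n_sig <- min(dim, k)
  with_seed(seed, {
    W <- matrix(stats::rnorm(k * n_sig), k, n_sig)
    S <- Fs %*% W
    ssd <- apply(S, 2L, stats::sd)
    ssd[ssd == 0] <- 1
    S <- sweep(S, 2L, ssd, `/`)
    E <- info_level * S +
      (1 - info_level) * matrix(stats::rnorm(n * n_sig), n, n_sig)
    if (dim > n_sig) {
      E <- cbind(E, matrix(stats::rnorm(n * (dim - n_sig)), n, dim - n_sig))
    }
    rownames(E) <- video_index
    colnames(E) <- sprintf("e%04d", seq_len(dim))
    structure(
      list(model_name = model_name, layer_name = layer_name,
           matrix = E, video_index = video_index,
           info_level = info_level),
      class = "embedding_set"
    )
  })
}
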