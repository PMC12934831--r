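#' Fuse an auxiliary metric depth into a camera translation
#'
#' Places a body's local joints in the camera frame using a hybrid
#' translation: the x and y components of the primary estimator's camera
#' translation are kept, while its depth (z) component is replaced by the
#' auxiliary estimator's metric depth.  This preserves high-fidelity local
#' pose while adopting the more reliable depth ordering.
#'
#' @param local_joints 45 x 3 matrix of joints in the body-local frame.
#' @param translation_a Length-3 camera translation (x, y, z-depth).
#' @param depth_b Positive replacement depth (m).
#' @return 45 x 3 matrix of global joint coordinates.
#' @examples
#' tpl <- make_skeleton_template()
#' g <- fuse_depth(tpl$rest_pose, c(0.5, 0, 5), depth_b = 3.2)
#' mean(g[, 3]) - mean(tpl$rest_pose[, 3])  # equals 3.2
#' @export
fuse_depth <- function(local_joints, translation_a, depth_b) {
  local_joints <- as.matrix(local_joints)
  if (!all(is.finite(local_joints)) || !all(is.finite(translation_a)) ||
      !is.finite(depth_b)) {
    stop("non-finite inputs to fuse_depth()", call. = FALSE)
  }
  if (depth_b <= 0) stop("`depth_b` must be positive", call. = FALSE)
  t_star <- c(translation_a[1], translation_a[2], depth_b)
  sweep(local_joints, 2L, t_star, `+`)
}

#' Keep only videos with complete two-agent tracks
#'
#' A video survives only if both agents' detections are valid on every
#' frame; clips with any pose-estimation failure are excluded so that all
#' downstream features are computed from complete 90-frame tracks.
#'
#' @param tracks Named list (by video id) of two-`joint_track` lists.
#' @return List with character vectors `kept` and `excluded`, in input
#'   order.
#' @export
filter_complete_videos <- function(tracks) {
  ids <- names(tracks)
  if (is.null(ids)) {
    ids <- vapply(tracks, function(tr) tr[[1]]$video_id, character(1))
  }
  ok <- vapply(tracks, function(pair) {
    if (length(pair) != 2L) {
      stop("each video must have exactly two agents", call. = FALSE)
    }
    all(pair[[1]]$frame_valid) && all(pair[[2]]$frame_valid)
  }, logical(1))
  list(kept = ids[ok], excluded = ids[!ok])
}

#' Average a joint track over frames
#'
#' Unweighted mean of the 45 x 3 joint coordinates over the frame axis.
#' All frames must be valid; run [filter_complete_videos()] first.
#'
#' @param track A `joint_track` (or a frames x 45 x 3 array).
#' @return 45 x 3 matrix (an agent pose).
#' @export
average_frames <- function(track) {
  coords <- if (inherits(track, "joint_track")) {
    if (!all(track$frame_valid)) {
      stop("track has invalid frames; filter before averaging", call. = FALSE)
    }
    track$coords
  } else {
    track
  }
  out <- apply(coords, c(2L, 3L), mean)
  if (!all(is.finite(out))) {
    stop("non-finite coordinates in track", call. = FALSE)
  }
  out
}

#' Face position of an agent pose
#'
#' Midpoint of the two eye joints.
#'
#' @param pose 45 x 3 matrix.
#' @param template Skeleton template providing landmark indices.
#' @return Length-3 numeric vector.
#' @export
face_position <- function(pose, template = make_skeleton_template()) {
  (landmark_coords(pose, template, "left_eye") +
   landmark_coords(pose, template, "right_eye")) / 2
}

#' Facing direction of an agent pose
#'
#' Unit vector obtained by averaging the head-center-to-nose and
#' neck-to-nose vectors and normalizing once, giving a direction consistent
#' with both the face plane and the head-torso hinge.
#'
#' @inheritParams face_position
#' @return Unit length-3 numeric vector.
#' @export
facing_direction <- function(pose, template = make_skeleton_template()) {
  nose <- landmark_coords(pose, template, "nose")
  head <- landmark_coords(pose, template, "head_center")
  neck <- landmark_coords(pose, template, "neck")
  avg <- ((nose - head) + (nose - neck)) / 2
  if (vnorm(avg) < 1e-12) {
    stop("degenerate head geometry: averaged facing vector is zero",
         call. = FALSE)
  }
  unitize(avg)
}

# per-frame (frames x 6) position+direction features for one agent track
agent_frame_features <- function(coords, template) {
  li <- template$landmark_index
  eyes <- 0.5 * (coords[, li[["left_eye"]], , drop = FALSE] +
                 coords[, li[["right_eye"]], , drop = FALSE])
  nose <- coords[, li[["nose"]], , drop = FALSE]
  head <- coords[, li[["head_center"]], , drop = FALSE]
  neck <- coords[, li[["neck"]], , drop = FALSE]
  avg <- ((nose - head) + (nose - neck)) / 2
  avg <- matrix(avg, nrow = dim(coords)[1], ncol = 3L)
  nrm <- sqrt(rowSums(avg^2))
  if (any(!is.finite(nrm)) || any(nrm < 1e-12)) {
    stop("degenerate head geometry on at least one frame", call. = FALSE)
  }
  dir <- avg / nrm
  pos <- matrix(eyes, nrow = dim(coords)[1], ncol = 3L)
  cbind(pos, dir)
}

#' Assemble the compact social pose vector for a video
#'
#' Concatenates per-agent face position and facing direction for the two
#' agents: `(x, y, z, dx, dy, dz)` per agent in 3D mode (12 values) or the
#' depth-dropped projection `(x, y, dx, dy)` per agent in 2D mode (8
#' values), ordered agent 1 then agent 2.  In `per_frame_then_average` mode
#' (the default, matching how these features are computed from video) the
#' position and direction are computed on every frame and then averaged
#' over time, without renormalizing the averaged direction; in
#' `average_pose` mode they are computed once from a time-averaged pose.
#'
#' @param pose1,pose2 Either 45 x 3 averaged poses or frames x 45 x 3
#'   arrays / `joint_track` objects for the two agents.
#' @param template Skeleton template.
#' @param mode `"3D"` or `"2D"`.
#' @param frames_mode `"per_frame_then_average"` or `"average_pose"`.
#' @return Named numeric vector of length 12 (3D) or 8 (2D).
#' @export
assemble_social_vector <- function(pose1, pose2,
                                   template = make_skeleton_template(),
                                   mode = c("3D", "2D"),
                                   frames_mode = c("per_frame_then_average",
                                                   "average_pose")) {
  mode <- match.arg(mode)
  frames_mode <- match.arg(frames_mode)
  as_input <- function(p) {
    if (inherits(p, "joint_track")) p$coords else p
  }
  one_agent <- function(p) {
    p <- as_input(p)
    if (length(dim(p)) == 3L) {
      if (frames_mode == "per_frame_then_average") {
        colMeans(agent_frame_features(p, template))
      } else {
        avg <- average_frames(p)
        c(face_position(avg, template), facing_direction(avg, template))
      }
    } else {
      c(face_position(p, template), facing_direction(p, template))
    }
  }
  f1 <- one_agent(pose1)
  f2 <- one_agent(pose2)
  keep <- if (mode == "3D") 1:6 else c(1L, 2L, 4L, 5L)
  suffix <- if (mode == "3D") c("x", "y", "z", "dx", "dy", "dz") else
    c("x", "y", "dx", "dy")
  out <- c(f1[keep], f2[keep])
  names(out) <- c(paste0("a1_", suffix), paste0("a2_", suffix))
  stopifnot(length(out) == if (mode == "3D") 12L else 8L)
  out
}

#' Flatten two averaged agent poses into a 270-vector
#'
#' Agent-major, joint-major, coordinate-minor layout: elements 1-3 are
#' agent 1's joint 1 (x, y, z), elements 4-6 its joint 2, and so on; agent
#' 2 occupies elements 136-270.
#'
#' @param pose1,pose2 45 x 3 averaged poses.
#' @return Named numeric vector of length 270.
#' @export
flatten_joints <- function(pose1, pose2) {
  pose1 <- as.matrix(pose1); pose2 <- as.matrix(pose2)
  if (!identical(dim(pose1), dim(pose2))) {
    stop("agent poses have mismatched shapes", call. = FALSE)
  }
  out <- c(as.vector(t(pose1)), as.vector(t(pose2)))
  stopifnot(length(out) == 2L * prod(dim(pose1)))
  names(out) <- paste0(
    rep(c("a1", "a2"), each = length(out) / 2L), "_j",
    rep(rep(seq_len(nrow(pose1)), each = 3L), times = 2L), "_",
    rep(c("x", "y", "z"), times = length(out) / 3L)
  )
  out
}

# inverse of flatten_joints; used for checking the bijection
unflatten_joints <- function(v, joints = 45L) {
  half <- length(v) / 2L
  list(matrix(v[seq_len(half)], joints, 3L, byrow = TRUE),
       matrix(v[half + seq_len(half)], joints, 3L, byrow = TRUE))
}

#' Canonically order the two agents of a video
#'
#' Agents are sorted by ascending mean horizontal (x) position over valid
#' frames, ties broken by ascending mean depth (z), so the left-most (then
#' nearest) person is always agent 1 regardless of detection order.
#'
#' @param track_pair List of two `joint_track` objects.
#' @return The pair, reordered.
#' @export
order_agents <- function(track_pair) {
  stopifnot(length(track_pair) == 2L)
  key <- vapply(track_pair, function(tr) {
    v <- tr$frame_valid
    c(mean(tr$coords[v, , 1L]), mean(tr$coords[v, , 3L]))
  }, numeric(2))
  if (key[1, 1] > key[1, 2] ||
      (key[1, 1] == key[1, 2] && key[2, 1] > key[2, 2])) {
    track_pair <- track_pair[c(2L, 1L)]
  }
  track_pair
}

#' Build all three feature tables from a batch of joint tracks
#'
#' Applies the completeness filter, canonical agent ordering, and all three
#' feature constructions: time-averaged flattened joints (270 columns),
#' 3D social pose vectors (12 columns, per-frame features averaged over
#' time), and their 2D projections (8 columns).
#'
#' @param tracks Named list (by video id) of two-track lists.
#' @param template Skeleton template.
#' @return List with data.frames `joints`, `social3d`, `social2d` (each
#'   `video_id` + feature columns) and character vectors `kept`,
#'   `excluded`.
#' @export
build_feature_tables <- function(tracks, template = make_skeleton_template()) {
  flt <- filter_complete_videos(tracks)
  rows_j <- list(); rows_3 <- list(); rows_2 <- list()
  for (id in flt$kept) {
    pair <- order_agents(tracks[[id]])
    avg1 <- average_frames(pair[[1]])
    avg2 <- average_frames(pair[[2]])
    rows_j[[id]] <- flatten_joints(avg1, avg2)
    rows_3[[id]] <- assemble_social_vector(pair[[1]], pair[[2]], template,
                                           mode = "3D")
    rows_2[[id]] <- assemble_social_vector(pair[[1]], pair[[2]], template,
                                           mode = "2D")
  }
  to_df <- function(rows) {
    m <- do.call(rbind, rows)
    data.frame(video_id = flt$kept, m, row.names = NULL,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  list(joints = to_df(rows_j), social3d = to_df(rows_3),
       social2d = to_df(rows_2), kept = flt$kept, excluded = flt$excluded)
}
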