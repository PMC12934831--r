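#' Canonical 45-joint skeleton template
#'
#' Builds the fixed skeleton used by the synthetic renderer and the social
#' pose feature extractor: the 24 canonical SMPL body joints plus 21 face,
#' hand, and foot landmarks (45 joints total), with a rest pose expressed in
#' a canonical body frame (x lateral, y vertical, z forward along the facing
#' axis, meters, standing adult).
#'
#' The rest pose is constructed so that the head geometry is exactly
#' consistent with the facing-direction definition used downstream: the nose
#' sits vertically midway between the head center and the neck and forward of
#' both, so the average of the head-center-to-nose and neck-to-nose vectors
#' points along +z.  The two eyes mirror each other across the sagittal
#' (x = 0) plane.
#'
#' @return An object of class `skeleton_template`: a list with
#'   `joint_count` (45), `landmark_index` (named integer vector mapping
#'   `left_eye`, `right_eye`, `nose`, `head_center`, `neck` to joint rows),
#'   `rest_pose` (45 x 3 matrix, named rows), and `facing_axis`
#'   (`c(0, 0, 1)`).
#' @examples
#' tpl <- make_skeleton_template()
#' tpl$joint_count
#' tpl$rest_pose[tpl$landmark_index[["nose"]], ]
#' @export
make_skeleton_template <- function() {
  j <- function(name, x, y, z) c(name = name, x = x, y = y, z = z)
  # 24 SMPL body joints
  body <- list(
    j("pelvis",         0.00, 0.95, 0.00),
    j("left_hip",       0.12, 0.92, 0.00),
    j("right_hip",     -0.12, 0.92, 0.00),
    j("spine1",         0.00, 1.05, 0.00),
    j("left_knee",      0.12, 0.50, 0.00),
    j("right_knee",    -0.12, 0.50, 0.00),
    j("spine2",         0.00, 1.15, 0.00),
    j("left_ankle",     0.12, 0.08, 0.00),
    j("right_ankle",   -0.12, 0.08, 0.00),
    j("spine3",         0.00, 1.28, 0.00),
    j("left_foot",      0.12, 0.02, 0.10),
    j("right_foot",    -0.12, 0.02, 0.10),
    j("neck",           0.00, 1.45, 0.00),
    j("left_collar",    0.08, 1.38, 0.00),
    j("right_collar",  -0.08, 1.38, 0.00),
    j("head",           0.00, 1.60, 0.00),
    j("left_shoulder",  0.20, 1.40, 0.00),
    j("right_shoulder",-0.20, 1.40, 0.00),
    j("left_elbow",     0.45, 1.40, 0.00),
    j("right_elbow",   -0.45, 1.40, 0.00),
    j("left_wrist",     0.70, 1.40, 0.00),
    j("right_wrist",   -0.70, 1.40, 0.00),
    j("left_hand",      0.78, 1.40, 0.00),
    j("right_hand",    -0.78, 1.40, 0.00)
  )
  # 21 extra face, hand, and foot landmarks
  extra <- list(
    j("nose",           0.000, 1.525, 0.110),
    j("left_eye",       0.035, 1.630, 0.090),
    j("right_eye",     -0.035, 1.630, 0.090),
    j("left_ear",       0.080, 1.600, 0.020),
    j("right_ear",     -0.080, 1.600, 0.020),
    j("jaw",            0.000, 1.500, 0.080),
    j("head_top",       0.000, 1.750, 0.000),
    j("left_thumb",     0.80, 1.43, 0.03),
    j("right_thumb",   -0.80, 1.43, 0.03),
    j("left_index",     0.84, 1.40, 0.02),
    j("right_index",   -0.84, 1.40, 0.02),
    j("left_middle",    0.85, 1.39, 0.00),
    j("right_middle",  -0.85, 1.39, 0.00),
    j("left_pinky",     0.83, 1.37, -0.02),
    j("right_pinky",   -0.83, 1.37, -0.02),
    j("left_big_toe",   0.10, 0.02, 0.18),
    j("right_big_toe", -0.10, 0.02, 0.18),
    j("left_small_toe", 0.16, 0.02, 0.16),
    j("right_small_toe",-0.16, 0.02, 0.16),
    j("left_heel",      0.12, 0.02, -0.06),
    j("right_heel",    -0.12, 0.02, -0.06)
  )
  rows <- c(body, extra)
  rest <- t(vapply(rows, function(r) as.numeric(r[c("x", "y", "z")]),
                   numeric(3)))
  rownames(rest) <- vapply(rows, function(r) r[["name"]], character(1))
  colnames(rest) <- c("x", "y", "z")
  stopifnot(nrow(rest) == 45L)
  landmarks <- c(
    left_eye    = match("left_eye", rownames(rest)),
    right_eye   = match("right_eye", rownames(rest)),
    nose        = match("nose", rownames(rest)),
    head_center = match("head", rownames(rest)),
    neck        = match("neck", rownames(rest))
  )
  structure(
    list(joint_count = 45L,
         landmark_index = landmarks,
         rest_pose = rest,
         facing_axis = c(0, 0, 1)),
    class = "skeleton_template"
  )
}

# fetch one landmark's coordinates from a 45 x 3 pose
landmark_coords <- function(pose, template, name) {
  idx <- template$landmark_index[[name]]
  if (is.null(idx) || is.na(idx)) {
    stop(sprintf("template has no landmark '%s'", name), call. = FALSE)
  }
  pose[idx, ]
}
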