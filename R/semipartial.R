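# CV over the alpha grid for a multi-output ridge (shared alpha across
# outputs).  Returns the smallest alpha whose mean validation r is within
# `tol` of the best: when several penalties are statistically
# indistinguishable, the smallest one removes the predictable component
# most completely, which is what residualization needs.
cv_alpha_multi <- function(X, Y, alphas = alpha_grid(), folds = 5L,
                           repeats = 2L, seed = 1, tol = 1e-3) {
  n <- nrow(as.matrix(X))
  assignments <- make_folds(n, folds, repeats, seed)
  acc <- matrix(0, length(alphas), 0L)
  for (fa in assignments) {
    for (f in seq_len(folds)) {
      tr <- fa != f
      acc <- cbind(acc, ridge_val_r_path(
        as.matrix(X)[tr, , drop = FALSE], as.matrix(Y)[tr, , drop = FALSE],
        as.matrix(X)[!tr, , drop = FALSE], as.matrix(Y)[!tr, , drop = FALSE],
        alphas))
    }
  }
  mean_r <- rowMeans(acc)
  ord <- order(alphas)
  cand <- ord[mean_r[ord] >= max(mean_r) - tol]
  alphas[cand[1L]]
}

#' Residualize joint features on a predictor feature set
#'
#' Isolates the part of the dense joint representation not linearly
#' predictable from a compact feature set: a multi-output ridge (one
#' cross-validated penalty shared across all joint outputs) is fit on the
#' training rows to predict every standardized joint coordinate from the
#' predictors, and its predictions are subtracted from the standardized
#' joints for both splits using the train-fitted map.
#'
#' @param joints n x 270 matrix of flattened joint features (rownames =
#'   video ids) or a data.frame with a `video_id` column.
#' @param predictors Feature matrix/data.frame over the same videos (e.g.
#'   positions only, directions only, or the full social pose vector).
#' @param split List with `train_ids`, `test_ids`.
#' @param alphas Penalty grid for the shared-alpha cross-validation.
#' @param folds,repeats Cross-validation layout.
#' @param seed Integer seed.
#' @return A `residual_joint_features`: list with `residuals` (n x 270
#'   matrix, standardized joint units, rownames = video ids), `alpha`, and
#'   `predictor_cols`.
#' @export
semipartial_residualize <- function(joints, predictors, split,
                                    alphas = alpha_grid(), folds = 5L,
                                    repeats = 2L, seed = 1) {
  to_mat <- function(x) {
    if (is.data.frame(x)) {
      m <- as.matrix(x[, setdiff(names(x), "video_id"), drop = FALSE])
      rownames(m) <- as.character(x$video_id)
      m
    } else {
      as.matrix(x)
    }
  }
  J <- to_mat(joints)
  P <- to_mat(predictors)
  ids <- c(split$train_ids, split$test_ids)
  if (!all(ids %in% rownames(J)) || !all(ids %in% rownames(P))) {
    stop("joints and predictors must cover all split videos", call. = FALSE)
  }
  tr <- split$train_ids
  alpha <- cv_alpha_multi(P[tr, , drop = FALSE], J[tr, , drop = FALSE],
                          alphas = alphas, folds = folds, repeats = repeats,
                          seed = seed)
  mp <- zscore_fit(P[tr, , drop = FALSE])
  mj <- zscore_fit(J[tr, , drop = FALSE])
  Ps <- zscore_apply(mp, P[ids, , drop = FALSE])
  Js <- zscore_apply(mj, J[ids, , drop = FALSE])
  Xtr <- Ps[tr, , drop = FALSE]
  sv <- svd(Xtr)
  keep <- sv$d > max(dim(Xtr)) * .Machine$double.eps * max(sv$d, 1)
  shrink <- numeric(length(sv$d))
  shrink[keep] <- sv$d[keep] / (sv$d[keep]^2 + alpha)
  # B = V diag(shrink) U' J_train
  B <- sv$v %*% (shrink * crossprod(sv$u, Js[tr, , drop = FALSE]))
  res <- Js - Ps %*% B
  structure(
    list(residuals = res, alpha = alpha, predictor_cols = colnames(P)),
    class = "residual_joint_features"
  )
}

#' Encode ratings from residualized joint features
#'
#' Standard cross-validated ridge encoding run on residualized joints; a
#' high score means the joints carry rating-relevant information beyond
#' the predictor set they were residualized on.
#'
#' @param residuals A `residual_joint_features` object (or plain matrix
#'   with video-id rownames).
#' @param y Named ratings vector.
#' @param split List with `train_ids`, `test_ids`.
#' @inheritParams ridge_encode
#' @return An `encoding_result`.
#' @export
semipartial_encode <- function(residuals, y, split, folds = 5L,
                               repeats = 2L, alphas = alpha_grid(),
                               seed = 1) {
  R <- if (inherits(residuals, "residual_joint_features")) {
    residuals$residuals
  } else {
    as.matrix(residuals)
  }
  ridge_encode(R, y, split, feature_source = "residual_joints",
               folds = folds, repeats = repeats, alphas = alphas,
               seed = seed)
}
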