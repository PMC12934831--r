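#' Fit a z-scoring map on training data
#'
#' Per-column centering and scaling with the population (1/n) standard
#' deviation, computed from the training rows only.  Zero-variance columns
#' are mapped to zeros rather than dividing by zero.
#'
#' @param train Numeric matrix (>= 2 rows) or vector.
#' @return A `zscore_map`: list with `center`, `scale` (zeros kept as
#'   zeros), usable with [zscore_apply()].
#' @export
zscore_fit <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("need at least 2 training rows", call. = FALSE)
  ctr <- colMeans(train)
  centered <- sweep(train, 2L, ctr)
  scl <- sqrt(colMeans(centered^2))
  structure(list(center = ctr, scale = scl), class = "zscore_map")
}

#' Apply a fitted z-scoring map
#'
#' @param map A `zscore_map` from [zscore_fit()].
#' @param x Matrix or vector with the same columns as the training data.
#' @return Standardized matrix; zero-variance columns become all zeros.
#' @export
zscore_apply <- function(map, x) {
  x <- as.matrix(x)
  out <- sweep(x, 2L, map$center)
  s <- map$scale
  pos <- s > 0
  if (any(pos)) out[, pos] <- sweep(out[, pos, drop = FALSE], 2L, s[pos], `/`)
  if (any(!pos)) out[, !pos] <- 0
  out
}

#' Logarithmic regularization grid
#'
#' Log10-equispaced ridge penalties from 1e-10 to 1e10 inclusive.
#'
#' @param n_points Number of grid points (>= 2; default 21, one per
#'   decade).
#' @return Numeric vector of penalties.
#' @export
alpha_grid <- function(n_points = 21L) {
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  10^seq(-10, 10, length.out = n_points)
}

#' Johnson-Lindenstrauss minimum embedding dimension
#'
#' Smallest dimension guaranteeing pairwise distance preservation within
#' relative distortion `eps` for `n_samples` points:
#' `floor(4 log(n) / (eps^2 / 2 - eps^3 / 3))`.
#'
#' @param n_samples Number of points (>= 2).
#' @param eps Distortion in (0, 1).
#' @return Integer dimension.
#' @examples
#' jl_min_dim(250, 0.1)  # 4732
#' @export
jl_min_dim <- function(n_samples, eps) {
  if (n_samples < 2) stop("`n_samples` must be >= 2", call. = FALSE)
  if (eps <= 0 || eps >= 1) stop("`eps` must lie in (0, 1)", call. = FALSE)
  as.integer(floor(4 * log(n_samples) / (eps^2 / 2 - eps^3 / 3)))
}

#' Sparse random projection
#'
#' Achlioptas-style sparse projection: entries are
#' `+/- sqrt(1 / (density * n_components))` with probability `density / 2`
#' each and zero otherwise, with `density = 1 / sqrt(d)`.  Applied only
#' when the input is wider than `n_components`; narrower inputs pass
#' through unchanged.
#'
#' @param X n x d numeric matrix.
#' @param n_components Target width (>= 1).
#' @param seed Integer seed (the projection matrix is fully determined by
#'   the seed and the input width).
#' @return n x n_components matrix (or `X` itself when d <= n_components).
#' @export
sparse_random_projection <- function(X, n_components, seed = 1) {
  if (n_components < 1) stop("`n_components` must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  d <- ncol(X)
  if (d <= n_components) return(X)
  density <- 1 / sqrt(d)
  scale <- sqrt(1 / (density * n_components))
  with_seed(seed, {
    total <- as.numeric(d) * n_components
    nnz <- stats::rbinom(1L, size = total, prob = density)
    pos <- sort(sample(total, nnz))
    i <- ((pos - 1) %% d) + 1
    j <- ((pos - 1) %/% d) + 1
    x <- sample(c(-scale, scale), nnz, replace = TRUE)
    P <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(d, n_components))
    out <- as.matrix(X %*% P)
    rownames(out) <- rownames(X)
    out
  })
}

#' Sample Pearson correlation with a zero-variance guard
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return The correlation; if either input has zero variance, returns 0
#'   with attribute `zero_variance = TRUE` and a warning.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("inputs must be equal-length vectors of length >= 2", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance input to pearson_r(); returning 0")
    return(structure(0, zero_variance = TRUE))
  }
  stats::cor(a, b)
}

#' Closed-form ridge regression weights
#'
#' Unique minimizer of `||y - X w||^2 + alpha ||w||^2`, computed through
#' the singular value decomposition for stability across the full 1e-10 to
#' 1e10 penalty range.  No intercept: inputs are expected standardized.
#'
#' @param X n x d numeric matrix.
#' @param y Length-n numeric vector.
#' @param alpha Non-negative penalty.
#' @return Length-d weight vector.
#' @export
ridge_solve <- function(X, y, alpha) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)) || !is.finite(alpha) ||
      alpha < 0) {
    stop("non-finite inputs (or negative alpha) in ridge_solve()",
         call. = FALSE)
  }
  sv <- svd(X)
  dsq <- sv$d^2
  uty <- crossprod(sv$u, y)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 1)
  shrink <- numeric(length(sv$d))
  shrink[keep] <- sv$d[keep] / (dsq[keep] + alpha)
  drop(sv$v %*% (shrink * uty))
}

# SVD-path ridge: validation/test predictions for every alpha at once.
# Returns a matrix n_new x n_alphas of predictions from standardized data.
ridge_predict_path <- function(sv, y, X_new, alphas) {
  uty <- drop(crossprod(sv$u, y))
  M <- X_new %*% sv$v                      # n_new x r
  keep <- sv$d > max(length(y), nrow(sv$v)) * .Machine$double.eps *
    max(sv$d, 1)
  sapply(alphas, function(a) {
    shrink <- numeric(length(sv$d))
    shrink[keep] <- sv$d[keep] / (sv$d[keep]^2 + a)
    drop(M %*% (shrink * uty))
  })
}

# vector of validation r per alpha for one candidate and one fold;
# Y may be a matrix (multi-output: returns mean r across outputs)
ridge_val_r_path <- function(X_tr, Y_tr, X_val, Y_val, alphas) {
  mx <- zscore_fit(X_tr)
  Xs <- zscore_apply(mx, X_tr)
  Xv <- zscore_apply(mx, X_val)
  Y_tr <- as.matrix(Y_tr); Y_val <- as.matrix(Y_val)
  my <- zscore_fit(Y_tr)
  Ys <- zscore_apply(my, Y_tr)
  sv <- svd(Xs)
  r_by_alpha <- matrix(NA_real_, length(alphas), ncol(Y_tr))
  for (k in seq_len(ncol(Y_tr))) {
    preds <- ridge_predict_path(sv, Ys[, k], Xv, alphas)
    yv <- Y_val[, k]
    if (stats::sd(yv) == 0) {
      r_by_alpha[, k] <- 0
    } else {
      sds <- apply(preds, 2L, stats::sd)
      r <- rep(0, length(alphas))
      ok <- sds > 0
      if (any(ok)) r[ok] <- drop(stats::cor(preds[, ok, drop = FALSE], yv))
      r_by_alpha[, k] <- r
    }
  }
  rowMeans(r_by_alpha)
}

# seeded fold assignments: list of `repeats` integer vectors in 1..folds
make_folds <- function(n, folds, repeats, seed) {
  if (folds > n) stop("fold count exceeds number of training rows",
                      call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      rep(seq_len(folds), length.out = n)[order(sample.int(n))]
    })
  })
}

#' Cross-validated candidate (layer) and penalty selection
#'
#' For every candidate feature matrix and every penalty on the grid,
#' computes the mean validation Pearson r over `folds x repeats` fold fits
#' with within-fold standardization (statistics from the fold-training rows
#' only), and returns the argmax.  Ties are broken toward the smaller
#' penalty, then the lexicographically first candidate name.
#'
#' @param candidates Named list of n x d feature matrices over the same
#'   training rows.
#' @param y Length-n training target.
#' @param folds,repeats Cross-validation layout (defaults 5 and 2).
#' @param alphas Penalty grid (default [alpha_grid()]).
#' @param seed Integer seed for the fold shuffles.
#' @return List with `name`, `alpha`, and `cv_table` (data.frame
#'   `candidate`, `alpha`, `mean_val_r`).
#' @export
cv_select <- function(candidates, y, folds = 5L, repeats = 2L,
                      alphas = alpha_grid(), seed = 1) {
  stopifnot(is.list(candidates), length(candidates) >= 1L,
            !is.null(names(candidates)))
  n <- length(y)
  assignments <- make_folds(n, folds, repeats, seed)
  nm <- sort(names(candidates))
  tab <- list()
  for (cand in nm) {
    X <- as.matrix(candidates[[cand]])
    acc <- matrix(0, length(alphas), 0L)
    for (fa in assignments) {
      for (f in seq_len(folds)) {
        tr <- fa != f
        acc <- cbind(acc, ridge_val_r_path(X[tr, , drop = FALSE], y[tr],
                                           X[!tr, , drop = FALSE], y[!tr],
                                           alphas))
      }
    }
    tab[[cand]] <- data.frame(candidate = cand, alpha = alphas,
                              mean_val_r = rowMeans(acc))
  }
  cv_table <- do.call(rbind, tab)
  rownames(cv_table) <- NULL
  # ties break toward smaller alpha, then lexicographic candidate name
  ord <- order(cv_table$alpha, cv_table$candidate)
  cv_table_o <- cv_table[ord, ]
  best <- which.max(cv_table_o$mean_val_r)
  list(name = cv_table_o$candidate[best],
       alpha = cv_table_o$alpha[best],
       cv_table = cv_table)
}

#' Fit on the full training split and score on the held-out test split
#'
#' Standardization statistics are recomputed on the full training rows,
#' the ridge model is fit at the given penalty, and performance is the
#' Pearson correlation between predicted and observed test targets.
#'
#' @param X_train,y_train Training features and target.
#' @param X_test,y_test Held-out features and target.
#' @param alpha Ridge penalty.
#' @return Test-set Pearson r (0 with attribute `zero_variance` if the
#'   predictions or targets are constant).
#' @export
fit_evaluate <- function(X_train, y_train, X_test, y_test, alpha) {
  mx <- zscore_fit(X_train)
  Xs <- zscore_apply(mx, X_train)
  Xt <- zscore_apply(mx, X_test)
  my <- zscore_fit(matrix(y_train, ncol = 1L))
  ys <- drop(zscore_apply(my, matrix(y_train, ncol = 1L)))
  w <- ridge_solve(Xs, ys, alpha)
  pred <- drop(Xt %*% w)
  pearson_r(pred, y_test)
}

#' End-to-end encoding fit for one target
#'
#' Runs the full encoding recipe: cross-validated selection of the best
#' candidate (layer) and penalty on the training split only, refit on the
#' full training split, and evaluation on the held-out test split.  With a
#' single candidate only the penalty is selected.
#'
#' @param candidates Named list of feature matrices covering all analysis
#'   videos (rownames = video ids), or a single matrix.
#' @param y Named numeric vector of ratings (names = video ids).
#' @param split List with `train_ids` and `test_ids`.
#' @param feature_source Label stored in the result.
#' @inheritParams cv_select
#' @return An `encoding_result`: list with `feature_source`,
#'   `chosen_layer` (NULL for a single unnamed candidate), `chosen_alpha`,
#'   `test_r`, `cv_table`.
#' @export
ridge_encode <- function(candidates, y, split, feature_source = "features",
                         folds = 5L, repeats = 2L, alphas = alpha_grid(),
                         seed = 1) {
  single <- !is.list(candidates)
  if (single) candidates <- list(features = as.matrix(candidates))
  tr <- split$train_ids
  te <- split$test_ids
  stopifnot(length(intersect(tr, te)) == 0L, length(tr) > 0L,
            length(te) > 0L)
  cand_train <- lapply(candidates, function(X) X[tr, , drop = FALSE])
  sel <- cv_select(cand_train, y[tr], folds = folds, repeats = repeats,
                   alphas = alphas, seed = seed)
  Xfull <- candidates[[sel$name]]
  r <- fit_evaluate(Xfull[tr, , drop = FALSE], y[tr],
                    Xfull[te, , drop = FALSE], y[te], sel$alpha)
  structure(
    list(feature_source = feature_source,
         chosen_layer = if (single) NULL else sel$name,
         chosen_alpha = sel$alpha,
         test_r = as.numeric(r),
         zero_variance = isTRUE(attr(r, "zero_variance")),
         cv_table = sel$cv_table),
    class = "encoding_result"
  )
}

#' Test-set predictions for a fitted encoding configuration
#'
#' Refits at the chosen penalty on the full training split and returns the
#' held-out predictions (used by the permutation tests, which rescore fixed
#' predictions under shuffled ratings).
#'
#' @inheritParams fit_evaluate
#' @return Length-`nrow(X_test)` numeric vector of predictions.
#' @export
ridge_predictions <- function(X_train, y_train, X_test, alpha) {
  mx <- zscore_fit(X_train)
  Xs <- zscore_apply(mx, X_train)
  Xt <- zscore_apply(mx, X_test)
  my <- zscore_fit(matrix(y_train, ncol = 1L))
  ys <- drop(zscore_apply(my, matrix(y_train, ncol = 1L)))
  drop(Xt %*% ridge_solve(Xs, ys, alpha))
}
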