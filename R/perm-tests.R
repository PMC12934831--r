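# floored permutation p-value: never exactly zero, minimum 1/n_perm
perm_pvalue <- function(count, n_perm) max(count, 1L) / n_perm

perm_result <- function(statistic_name, observed, null_draws, tails,
                        n_perm, seed) {
  count <- switch(tails,
    two = sum(abs(null_draws) >= abs(observed)),
    one = sum(null_draws >= observed)
  )
  structure(
    list(statistic_name = statistic_name,
         observed = observed,
         null_draws = null_draws,
         p_value = perm_pvalue(count, length(null_draws)),
         tails = tails,
         n_perm = as.integer(n_perm),
         seed = as.integer(seed)),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic_name))
  cat(sprintf("  observed = %.4f, p = %.4g (%s-tailed, %d permutations)\n",
              x$observed, x$p_value, x$tails, x$n_perm))
  invisible(x)
}

# matrix of shuffled columns of v (n x n_perm), seeded
shuffle_matrix <- function(v, n_perm, exact = FALSE) {
  n <- length(v)
  if (exact) {
    idx <- all_permutations(n)
    return(matrix(v[t(idx)], n, nrow(idx)))
  }
  vapply(seq_len(n_perm), function(i) v[sample.int(n)], numeric(n))
}

# all n! permutations of 1..n (rows); only for small n
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# correlations of each column of M with vector y, with NA -> 0
cor_cols <- function(M, y) {
  r <- suppressWarnings(drop(stats::cor(M, y)))
  r[!is.finite(r)] <- 0
  r
}

#' Permutation test: model population versus a single feature set
#'
#' Tests whether a population of models (e.g. vision network embeddings)
#' and a single feature set predict the held-out ratings differently.  The
#' statistic is the mean test correlation of the population minus the test
#' correlation of the single predictor.  The null shuffles the held-out
#' ratings and rescores every fixed prediction vector; two-tailed.
#'
#' @param model_preds n_test x n_models matrix of test-set predictions
#'   (one column per model).
#' @param single_pred Length-n_test prediction vector of the single
#'   feature set.
#' @param y_test Held-out ratings.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return A `perm_test` object.
#' @export
perm_group_vs_single <- function(model_preds, single_pred, y_test,
                                 n_perm = 5000L, seed = 1) {
  model_preds <- as.matrix(model_preds)
  if (nrow(model_preds) != length(y_test) ||
      length(single_pred) != length(y_test)) {
    stop("prediction vectors not aligned with y_test", call. = FALSE)
  }
  obs <- mean(cor_cols(model_preds, y_test)) -
    as.numeric(pearson_r(single_pred, y_test))
  null <- with_seed(seed, {
    Yp <- shuffle_matrix(y_test, n_perm)
    R <- suppressWarnings(stats::cor(cbind(model_preds, single_pred), Yp))
    R[!is.finite(R)] <- 0
    m <- nrow(R) - 1L
    colMeans(R[seq_len(m), , drop = FALSE]) - R[m + 1L, ]
  })
  perm_result("mean(model r) - single r", obs, null, "two", n_perm, seed)
}

#' Paired permutation test of a per-model improvement
#'
#' Tests whether combined models outperform their feature-alone versions.
#' The statistic is the mean paired difference in test correlations; the
#' null swaps each pair's two scores independently with probability 1/2
#' (equivalently, flips the sign of each difference).  One-tailed.
#'
#' @param r_alone,r_combined Equal-length vectors of per-model test
#'   correlations.
#' @param n_perm Number of permutations (default 5000); ignored when
#'   `exact = TRUE`.
#' @param seed Integer seed.
#' @param exact If `TRUE`, enumerate all 2^m sign patterns (m <= 20).
#' @return A `perm_test` object.
#' @export
perm_paired_improvement <- function(r_alone, r_combined, n_perm = 5000L,
                                    seed = 1, exact = FALSE) {
  if (length(r_alone) != length(r_combined)) {
    stop("paired score vectors have different lengths", call. = FALSE)
  }
  d <- r_combined - r_alone
  m <- length(d)
  obs <- mean(d)
  null <- if (exact) {
    if (m > 20L) stop("exact enumeration limited to m <= 20", call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    drop(signs %*% d) / m
  } else {
    with_seed(seed, {
      S <- matrix(sample(c(-1, 1), m * n_perm, replace = TRUE), m, n_perm)
      drop(crossprod(S, d)) / m
    })
  }
  perm_result("mean paired improvement", obs, null, "one",
              length(null), seed)
}

#' Permutation test of a correlation between two model-level score vectors
#'
#' Tests the correlation between per-model scores (e.g. pose-feature
#' decoding r versus rating-prediction r).  The null shuffles `scores_x`.
#'
#' @param scores_x,scores_y Equal-length numeric vectors (length >= 3).
#' @param n_perm Number of permutations (default 5000); ignored when
#'   `exact = TRUE`.
#' @param tails `"two"` (default) or `"one"`.
#' @param seed Integer seed.
#' @param exact If `TRUE`, enumerate all permutations (length <= 8).
#' @return A `perm_test` object.
#' @export
perm_correlation <- function(scores_x, scores_y, n_perm = 5000L,
                             tails = c("two", "one"), seed = 1,
                             exact = FALSE) {
  tails <- match.arg(tails)
  if (length(scores_x) != length(scores_y) || length(scores_x) < 3L) {
    stop("score vectors must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(scores_x) == 0 || stats::sd(scores_y) == 0) {
    stop("zero variance in a score vector", call. = FALSE)
  }
  obs <- stats::cor(scores_x, scores_y)
  null <- with_seed(seed, {
    Xp <- shuffle_matrix(scores_x, n_perm, exact = exact)
    cor_cols(Xp, scores_y)
  })
  perm_result("score correlation", obs, null, tails, length(null), seed)
}

#' Permutation test of a difference between two score correlations
#'
#' Tests whether per-model 3D pose scores track a reference score vector
#' (e.g. rating-prediction performance) more strongly than 2D pose scores:
#' the statistic is `cor(scores_3d, ref) - cor(scores_2d, ref)`.  The null
#' independently shuffles both pose score vectors across models;
#' one-tailed.
#'
#' @param scores_3d,scores_2d,scores_ref Equal-length numeric vectors.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return A `perm_test` object.
#' @export
perm_corr_difference <- function(scores_3d, scores_2d, scores_ref,
                                 n_perm = 5000L, seed = 1) {
  m <- length(scores_ref)
  if (length(scores_3d) != m || length(scores_2d) != m) {
    stop("score vectors have different lengths", call. = FALSE)
  }
  if (stats::sd(scores_3d) == 0 || stats::sd(scores_2d) == 0 ||
      stats::sd(scores_ref) == 0) {
    stop("zero variance in a score vector", call. = FALSE)
  }
  obs <- stats::cor(scores_3d, scores_ref) - stats::cor(scores_2d, scores_ref)
  null <- with_seed(seed, {
    P3 <- shuffle_matrix(scores_3d, n_perm)
    P2 <- shuffle_matrix(scores_2d, n_perm)
    cor_cols(P3, scores_ref) - cor_cols(P2, scores_ref)
  })
  perm_result("delta r (3D - 2D)", obs, null, "one", n_perm, seed)
}
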