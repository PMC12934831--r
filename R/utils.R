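#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# L2 norm of a vector
vnorm <- function(v) sqrt(sum(v^2))

# normalize to unit length; errors on (near-)zero input
unitize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n < tol) {
    stop("cannot normalize a zero (or non-finite) vector", call. = FALSE)
  }
  v / n
}

# cross product of two 3-vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix taking the +z axis onto a unit direction
#'
#' Minimal (geodesic) rotation mapping (0, 0, 1) onto `d`.  The antipodal
#' case d = (0, 0, -1) is resolved as a half-turn about the vertical axis.
#'
#' @param d Unit 3-vector.
#' @return A 3x3 rotation matrix `R` with `R %*% c(0, 0, 1) == d`.
#' @keywords internal
rotation_from_z <- function(d) {
  d <- unitize(d)
  z <- c(0, 0, 1)
  v <- cross3(z, d)
  s2 <- sum(v^2)
  cth <- sum(z * d)
  if (s2 < 1e-18) {
    if (cth > 0) return(diag(3))
    return(diag(c(-1, 1, -1)))  # 180 degrees about y
  }
  vx <- matrix(c(0, v[3], -v[2],
                 -v[3], 0, v[1],
                 v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s2)
}

# derive a stage seed from a run seed; keeps results < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}
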