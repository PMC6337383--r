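# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squared / plain Euclidean cross-distance matrices
#'
#' @param a,b numeric matrices with 3 columns (rows are points, Angstrom).
#' @return matrix of pairwise distances, `nrow(a)` x `nrow(b)`.
#' @keywords internal
#' @noRd
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Angle at vertex `b` formed by points a-b-c, in degrees
#' @noRd
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Run an expression with a temporary RNG seed, restoring global state
#'
#' All generator randomness flows through this helper so that the generators
#' neither depend on nor disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a sub-seed (stays below 2^31) from a master seed and a stream tag
#' @noRd
sub_seed <- function(seed, tag) {
  (as.integer(seed) * 1103L + sum(utf8ToInt(tag)) * 7L) %% 2147483629L
}

# 3D rotation matrix from axis (unit) and angle (radians), Rodrigues form.
rotation_matrix <- function(axis, theta) {
  a <- unit(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_rotation <- function() {
  # uniform via QR of a Gaussian matrix, determinant fixed to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
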