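#' @useDynLib cryofep, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var quantile runif rnorm sd splinefun setNames
#' @importFrom utils read.csv write.csv
NULL

# Numerically stable log(sum(exp(x))); tolerates -Inf entries.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Atomic write: serialize to a temp file in the destination directory,
# then rename, so interrupted runs never leave truncated outputs.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not move temporary file onto '%s'", path)
  invisible(path)
}

#' Quaternion utilities
#'
#' Quaternions are length-4 numeric vectors `(w, x, y, z)` of unit norm;
#' `q` and `-q` encode the same rotation (antipodal identification).
#'
#' @param q,q1,q2 unit quaternions `(w, x, y, z)`.
#' @return `quat_to_rotmat` returns the 3x3 rotation matrix;
#'   `quat_multiply` the composed quaternion `q1 * q2`;
#'   `quat_geodesic` the rotation angle (radians, in `[0, pi]`) between the
#'   two rotations, with antipodal pairs identified.
#' @keywords internal
#' @export
quat_to_rotmat <- function(q) {
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-9) stopf("quaternion must have unit norm (got %g)", n)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quat_to_rotmat
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; v1 <- q1[2:4]; w2 <- q2[1]; v2 <- q2[2:4]
  c(w1 * w2 - sum(v1 * v2),
    w1 * v2 + w2 * v1 + c(
      v1[2] * v2[3] - v1[3] * v2[2],
      v1[3] * v2[1] - v1[1] * v2[3],
      v1[1] * v2[2] - v1[2] * v2[1]
    ))
}

#' @rdname quat_to_rotmat
#' @export
quat_geodesic <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d)
}

# Canonical sign: first non-negligible component positive (antipodal pairs
# identified on the projective space of rotations).
quat_canonical <- function(q) {
  for (k in 1:4) {
    if (abs(q[k]) > 1e-12) return(if (q[k] < 0) -q else q)
  }
  q
}

# One uniformly distributed rotation quaternion from three U(0,1) deviates
# (Shoemake's subgroup-algorithm map).
shoemake_quaternion <- function(u) {
  a <- sqrt(1 - u[1]); b <- sqrt(u[1])
  c(a * sin(2 * pi * u[2]), a * cos(2 * pi * u[2]),
    b * sin(2 * pi * u[3]), b * cos(2 * pi * u[3]))
}

#' Draw uniform random rotations
#'
#' Samples quaternions uniformly on SO(3) using the subgroup-algorithm map
#' from three uniform deviates, consuming the current R RNG stream.
#'
#' @param n number of rotations.
#' @return an `n x 4` matrix of unit quaternions.
#' @export
random_quaternions <- function(n) {
  u <- matrix(runif(3 * n), ncol = 3)
  t(apply(u, 1, shoemake_quaternion))
}

# Halton low-discrepancy sequence in [0,1)^d (bases 2,3,5,...).
halton_sequence <- function(n, d, shift = rep(0, d)) {
  bases <- c(2, 3, 5, 7, 11, 13)[seq_len(d)]
  out <- matrix(0, n, d)
  for (j in seq_len(d)) {
    b <- bases[j]
    for (i in seq_len(n)) {
      f <- 1; r <- 0; k <- i
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      out[i, j] <- (r + shift[j]) %% 1
    }
  }
  out
}

# RMSD between two B x 3 coordinate sets after optimal superposition
# (Kabsch, via SVD of the cross-covariance with a determinant correction).
# Implemented directly because it must stay finite for identical, planar and
# otherwise rank-deficient bead sets, which trip the usual least-squares
# fitting routines.
rmsd_fitted <- function(a, b) {
  ca <- sweep(a, 2, colMeans(a))
  cb <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(cb, ca))
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((ca - cb %*% r)^2)))
}
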