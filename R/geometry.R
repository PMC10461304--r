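# Small dense-3D helpers shared across the package. All coordinates are in
# nm, times in ps, masses in amu, so 1 amu nm^2 ps^-2 == 1 kJ/mol.

#' Cross product of two 3-vectors
#' @param a,b numeric length-3 vectors.
#' @return numeric length-3 vector `a x b`.
#' @keywords internal
#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product of two n x 3 matrices.
cross_rows <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

vec_norm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Rotation matrix about an axis (Rodrigues form)
#'
#' @param axis numeric length-3, need not be normalized.
#' @param angle rotation angle in radians.
#' @return 3x3 proper rotation matrix.
#' @examples
#' rotation_about_axis(c(0, 0, 1), pi / 2)
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unit_vector(axis)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Moore-Penrose pseudo-inverse via SVD; used only for degenerate inertia.
pinv3 <- function(M, tol = 1e-12) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Convert angular rates between the generator (1/ns) and internal (1/ps) units
#'
#' Generator-facing rates (prescribed angular velocities, shear rates) are
#' quoted per nanosecond, matching how shear-rate axes are labelled in the
#' field; all internal kinematics use the amu/nm/ps system, so angular
#' velocities returned by the analysis functions are per picosecond.
#'
#' @param x numeric scalar or vector.
#' @return rescaled numeric.
#' @export
per_ns_to_per_ps <- function(x) x * 1e-3

#' @rdname per_ns_to_per_ps
#' @export
per_ps_to_per_ns <- function(x) x * 1e3
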