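# Core containers: a static bead structure, a single trajectory frame, and an
# ordered trajectory. Plain lists with S3 classes, in the style of `ape`'s
# phylo objects: cheap to build in tests, validated at the constructor.

#' Bead structure
#'
#' A static set of beads: positions (nm), masses (amu) and optional labels.
#' This is the reference ("equilibrium") configuration consumed by the Eckart
#' machinery and the elastic-network builder. The default bead mass is 72 amu,
#' the conventional coarse-grained 4-heavy-atom bead mass.
#'
#' @param positions numeric n x 3 matrix of coordinates in nm.
#' @param masses numeric vector of n positive masses in amu (default 72 each).
#' @param labels optional character vector of n bead labels.
#' @return an object of class `bead_structure` with fields `positions`,
#'   `masses`, `labels`, `n`.
#' @examples
#' s <- bead_structure(rbind(c(0, 0, 0), c(0.35, 0, 0)))
#' s$n
#' @export
bead_structure <- function(positions, masses = NULL, labels = NULL) {
  positions <- as_coord_matrix(positions, "positions")
  n <- nrow(positions)
  if (n < 1L) stop("a structure needs at least one bead", call. = FALSE)
  if (is.null(masses)) masses <- rep(72, n)
  masses <- as.numeric(masses)
  if (length(masses) != n) stop("masses length must match bead count", call. = FALSE)
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be finite and positive", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length must match bead count", call. = FALSE)
  }
  structure(list(positions = positions, masses = masses, labels = labels, n = n),
            class = "bead_structure")
}

#' Single trajectory frame
#'
#' @param time frame time in ps.
#' @param positions numeric n x 3 matrix (nm).
#' @param velocities optional numeric n x 3 matrix (nm/ps).
#' @return an object of class `traj_frame`.
#' @export
traj_frame <- function(time, positions, velocities = NULL) {
  positions <- as_coord_matrix(positions, "positions")
  if (!is.null(velocities)) {
    velocities <- as_coord_matrix(velocities, "velocities")
    if (nrow(velocities) != nrow(positions))
      stop("velocities must match positions in bead count", call. = FALSE)
  }
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time))
    stop("time must be a finite scalar (ps)", call. = FALSE)
  structure(list(time = as.numeric(time), positions = positions,
                 velocities = velocities),
            class = "traj_frame")
}

#' Bead trajectory
#'
#' An ordered list of frames over a fixed [bead_structure()]. Frame times must
#' be strictly increasing and, when `dt` is given, uniformly spaced.
#'
#' @param structure a [bead_structure()].
#' @param frames list of [traj_frame()] objects.
#' @param dt nominal frame spacing in ps, or `NULL` for non-uniform series.
#' @param motion optional ground-truth motion description (a list), recorded
#'   by the synthetic generators and serialized as a JSON sidecar.
#' @return an object of class `bead_trajectory`.
#' @export
bead_trajectory <- function(structure, frames, dt = NULL, motion = NULL) {
  stopifnot(inherits(structure, "bead_structure"))
  if (length(frames) < 1L) stop("a trajectory needs at least one frame", call. = FALSE)
  for (f in frames) {
    if (!inherits(f, "traj_frame")) stop("frames must be traj_frame objects", call. = FALSE)
    if (nrow(f$positions) != structure$n)
      stop("frame bead count differs from structure", call. = FALSE)
  }
  times <- vapply(frames, function(f) f$time, numeric(1L))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  if (!is.null(dt)) {
    dt <- as.numeric(dt)
    if (dt <= 0) stop("dt must be positive", call. = FALSE)
    if (length(times) > 1L && max(abs(diff(times) - dt)) > 1e-9 * dt)
      stop("frame times are not uniform at the stated dt", call. = FALSE)
  }
  has_vel <- all(vapply(frames, function(f) !is.null(f$velocities), logical(1L)))
  structure(list(structure = structure, frames = frames, dt = dt,
                 times = times, has_velocities = has_vel, motion = motion),
            class = "bead_trajectory")
}

#' @export
print.bead_structure <- function(x, ...) {
  cat(sprintf("bead_structure: %d beads, total mass %.1f amu\n", x$n, sum(x$masses)))
  invisible(x)
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf("bead_trajectory: %d beads, %d frames, t = [%g, %g] ps, velocities: %s\n",
              x$structure$n, length(x$frames), x$times[1L],
              x$times[length(x$times)], x$has_velocities))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a [bead_trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

as_coord_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  if (!is.matrix(x) || ncol(x) != 3L)
    stop(sprintf("%s must be an n x 3 numeric matrix", what), call. = FALSE)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop(sprintf("%s contain non-finite values", what), call. = FALSE)
  dimnames(x) <- NULL
  x
}

# Positions of `structure` relative to its mass-weighted centroid.
reference_displacements <- function(structure) {
  w <- structure$masses / sum(structure$masses)
  com <- colSums(structure$positions * w)
  sweep(structure$positions, 2L, com)
}
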