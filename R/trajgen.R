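# Synthetic trajectory generators with analytically known motion content.
# Velocities are always generated in closed form (never finite-differenced),
# so the prescribed angular velocity, the zero vibrational angular momentum of
# the breathing mode, etc., hold to machine precision and serve as ground
# truth for the Eckart-frame analysis. Rates (omega, gamma_dot) are taken in
# 1/ns; internal kinematics are nm/ps.

#' Rigid-rotor trajectory
#'
#' Rotates the structure rigidly about its center of mass at a constant
#' prescribed angular velocity; the center of mass stays at rest. Velocities
#' are exactly `omega x (r - r_cm)`.
#'
#' @param structure a [bead_structure()]; its positions are the reference.
#' @param omega numeric length-3 angular velocity in 1/ns.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing in ps (> 0).
#' @return a [bead_trajectory()] with a `motion` ground-truth record.
#' @examples
#' s <- bead_structure(rbind(c(0.3, 0, 0), c(-0.3, 0, 0),
#'                           c(0, 0.3, 0), c(0, 0, 0.3)))
#' tr <- make_rigid_rotor(s, omega = c(0, 0, 5), n_frames = 10, dt = 0.02)
#' @export
make_rigid_rotor <- function(structure, omega, n_frames, dt) {
  stopifnot(inherits(structure, "bead_structure"))
  check_grid(n_frames, dt)
  omega <- as.numeric(omega)
  if (length(omega) != 3L || any(!is.finite(omega)))
    stop("omega must be a finite 3-vector (1/ns)", call. = FALSE)
  w <- per_ns_to_per_ps(omega)              # rad/ps
  speed <- vec_norm(w)
  crel <- reference_displacements(structure)
  com <- colSums(structure$positions * structure$masses) / sum(structure$masses)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    t_k <- (k - 1L) * dt
    R <- if (speed > 0) rotation_about_axis(w, speed * t_k) else diag(3L)
    d <- crel %*% t(R)
    v <- cross_rows(matrix(w, nrow(d), 3L, byrow = TRUE), d)
    frames[[k]] <- traj_frame(t_k, sweep(d, 2L, com, "+"), v)
  }
  bead_trajectory(structure, frames, dt = dt,
                  motion = list(kind = "rigid_rotor", omega_per_ns = omega))
}

#' Breathing-mode trajectory (vibration without angular momentum)
#'
#' Scales all displacements from the center of mass by
#' `1 + amplitude * sin(2 pi frequency t)`. Velocities are purely radial, so
#' the total angular momentum of every frame is exactly zero: this is the
#' canonical angular-momentum-free vibration.
#'
#' @inheritParams make_rigid_rotor
#' @param amplitude dimensionless radial amplitude, `0 <= amplitude < 1`
#'   (1 would invert the structure through its center).
#' @param frequency mode frequency in 1/ps (cycles per ps).
#' @export
make_breathing <- function(structure, amplitude, frequency, n_frames, dt) {
  stopifnot(inherits(structure, "bead_structure"))
  check_grid(n_frames, dt)
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1): >= 1 inverts the structure", call. = FALSE)
  if (frequency < 0) stop("frequency must be >= 0", call. = FALSE)
  crel <- reference_displacements(structure)
  com <- colSums(structure$positions * structure$masses) / sum(structure$masses)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    t_k <- (k - 1L) * dt
    s <- 1 + amplitude * sin(2 * pi * frequency * t_k)
    sdot <- amplitude * 2 * pi * frequency * cos(2 * pi * frequency * t_k)
    frames[[k]] <- traj_frame(t_k, sweep(s * crel, 2L, com, "+"), sdot * crel)
  }
  bead_trajectory(structure, frames, dt = dt,
                  motion = list(kind = "breathing", amplitude = amplitude,
                                frequency_per_ps = frequency))
}

#' Twist-mode trajectory (vibration carrying angular momentum)
#'
#' The two halves of the bead set (split by the sign of the coordinate along
#' `axis` through the center of mass) counter-oscillate azimuthally:
#' `theta_half(t) = +/- twist_amplitude * sin(2 pi frequency t)`. The net
#' time-averaged rotation is zero, but the instantaneous total angular
#' momentum is generally nonzero - vibrational angular momentum. Beads lying
#' on the dividing plane are assigned to neither half and stay put.
#'
#' @inheritParams make_rigid_rotor
#' @param twist_amplitude peak twist angle in rad (>= 0).
#' @param frequency mode frequency in 1/ps.
#' @param axis twist axis (length-3, nonzero), through the center of mass.
#' @export
make_twist <- function(structure, twist_amplitude, frequency,
                       axis = c(0, 0, 1), n_frames, dt) {
  stopifnot(inherits(structure, "bead_structure"))
  check_grid(n_frames, dt)
  if (structure$n < 2L) stop("twist needs at least 2 beads", call. = FALSE)
  if (twist_amplitude < 0) stop("twist_amplitude must be >= 0", call. = FALSE)
  if (frequency < 0) stop("frequency must be >= 0", call. = FALSE)
  u <- unit_vector(as.numeric(axis))
  crel <- reference_displacements(structure)
  com <- colSums(structure$positions * structure$masses) / sum(structure$masses)
  proj <- drop(crel %*% u)
  side <- sign(proj)
  side[abs(proj) < 1e-12] <- 0
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    t_k <- (k - 1L) * dt
    th <- twist_amplitude * sin(2 * pi * frequency * t_k)
    thdot <- twist_amplitude * 2 * pi * frequency * cos(2 * pi * frequency * t_k)
    pos <- crel
    for (s in c(-1, 1)) {
      idx <- side == s
      if (any(idx)) pos[idx, ] <- crel[idx, , drop = FALSE] %*% t(rotation_about_axis(u, s * th))
    }
    # v = thetadot * (axis x d) per bead, signed by half
    vel <- cross_rows(matrix(u, structure$n, 3L, byrow = TRUE), pos) * (side * thdot)
    frames[[k]] <- traj_frame(t_k, sweep(pos, 2L, com, "+"), vel)
  }
  bead_trajectory(structure, frames, dt = dt,
                  motion = list(kind = "twist", twist_amplitude = twist_amplitude,
                                frequency_per_ps = frequency, axis = u))
}

#' Spherically symmetric bead cloud in a linear shear profile
#'
#' Builds a bead cloud centered at the origin with velocities sampled from the
#' linear shear profile `v1 = gamma_dot * x2` (flow along x1, gradient along
#' x2). With `lattice = TRUE` the positions are every point of a cubic lattice
#' inside the sphere, a set exactly closed under coordinate permutations and
#' sign flips, so the second moments obey `sum(m x1^2) == sum(m x2^2)` exactly
#' and the Einstein sphere limit `|omega_3| = gamma_dot / 2` is analytic
#' rather than statistical. The lattice may contain slightly more beads than
#' requested (complete symmetry shells are never truncated).
#'
#' @param n_beads minimum number of beads (>= 4).
#' @param radius cloud radius in nm.
#' @param gamma_dot shear rate in 1/ns.
#' @param lattice logical; exact symmetric lattice (default) or a seeded
#'   random uniform ball (symmetric only in distribution).
#' @param seed RNG seed, used only when `lattice = FALSE`.
#' @param mass bead mass in amu.
#' @return list with elements `structure` ([bead_structure()]) and `frame`
#'   ([traj_frame()] at t = 0 with the shear velocities).
#' @examples
#' cloud <- make_shear_cloud(50, radius = 2, gamma_dot = 10)
#' w <- apparent_angular_velocity(cloud$frame, cloud$structure)
#' per_ps_to_per_ns(w)   # ~ (0, 0, -5): |omega3| = gamma_dot / 2
#' @export
make_shear_cloud <- function(n_beads, radius, gamma_dot, lattice = TRUE,
                             seed = 1L, mass = 72) {
  if (n_beads < 4L) stop("n_beads must be >= 4", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (lattice) {
    m <- 1L
    repeat {
      g <- seq.int(-m, m)
      pts <- as.matrix(expand.grid(x1 = g, x2 = g, x3 = g))
      pts <- pts[rowSums(pts^2) <= m^2, , drop = FALSE]
      if (nrow(pts) >= n_beads) break
      m <- m + 1L
    }
    pos <- pts * (radius / m)
  } else {
    pos <- with_seed(seed, {
      r <- radius * stats::runif(n_beads)^(1 / 3)
      u <- matrix(stats::rnorm(3L * n_beads), n_beads, 3L)
      u <- u / sqrt(rowSums(u^2))
      u * r
    })
  }
  dimnames(pos) <- NULL
  gd <- per_ns_to_per_ps(gamma_dot)
  vel <- cbind(gd * pos[, 2L], 0, 0)
  st <- bead_structure(pos, masses = rep(mass, nrow(pos)))
  list(structure = st, frame = traj_frame(0, pos, vel))
}

#' Superpose synthetic motions
#'
#' Adds the displacement and velocity fields of several trajectories built on
#' the identical structure and time grid, plus an optional uniform
#' center-of-mass drift. Displacements are taken about the shared reference,
#' so `compose_motions(list(x))` returns `x` (up to the drift).
#'
#' @param parts list of [bead_trajectory()] objects sharing structure and grid.
#' @param com_velocity uniform drift velocity in nm/ps added to every bead.
#' @return a [bead_trajectory()]; `motion` records the parts' ground truths.
#' @export
compose_motions <- function(parts, com_velocity = c(0, 0, 0)) {
  if (length(parts) < 1L) stop("need at least one trajectory", call. = FALSE)
  base <- parts[[1L]]
  for (p in parts) {
    stopifnot(inherits(p, "bead_trajectory"))
    if (!isTRUE(all.equal(p$structure$positions, base$structure$positions)) ||
        !isTRUE(all.equal(p$structure$masses, base$structure$masses)))
      stop("all parts must share an identical structure", call. = FALSE)
    if (length(p$times) != length(base$times) ||
        max(abs(p$times - base$times)) > 1e-12)
      stop("all parts must share an identical time grid", call. = FALSE)
    if (!p$has_velocities) stop("all parts must carry velocities", call. = FALSE)
  }
  com_velocity <- as.numeric(com_velocity)
  ref <- base$structure$positions
  frames <- vector("list", length(base$times))
  for (k in seq_along(base$times)) {
    t_k <- base$times[k]
    pos <- ref
    vel <- matrix(0, nrow(ref), 3L)
    for (p in parts) {
      pos <- pos + (p$frames[[k]]$positions - ref)
      vel <- vel + p$frames[[k]]$velocities
    }
    pos <- pos + matrix(com_velocity * t_k, nrow(ref), 3L, byrow = TRUE)
    vel <- vel + matrix(com_velocity, nrow(ref), 3L, byrow = TRUE)
    frames[[k]] <- traj_frame(t_k, pos, vel)
  }
  bead_trajectory(base$structure, frames, dt = base$dt,
                  motion = list(kind = "composite",
                                parts = lapply(parts, function(p) p$motion),
                                com_velocity = com_velocity))
}

#' Compact self-avoiding toy chain
#'
#' Builds a compact self-avoiding bead chain with fixed consecutive spacing,
#' for elastic-network and observable tests. Growth is biased back toward the
#' centroid so the chain stays globular; a step is rejected when it comes
#' closer than `0.9 * bond_length` to any non-adjacent bead.
#'
#' @param n_beads chain length (>= 3).
#' @param bond_length consecutive bead spacing in nm.
#' @param seed RNG seed; fixed seed gives a bit-identical chain.
#' @param mass bead mass in amu.
#' @return a [bead_structure()].
#' @export
make_toy_protein <- function(n_beads, bond_length = 0.35, seed = 1L, mass = 72) {
  if (n_beads < 3L) stop("n_beads must be >= 3", call. = FALSE)
  if (bond_length <= 0) stop("bond_length must be positive", call. = FALSE)
  min_sep <- 0.9 * bond_length
  with_seed(seed, {
    for (attempt in seq_len(50L)) {
      pos <- matrix(0, n_beads, 3L)
      pos[2L, ] <- c(bond_length, 0, 0)
      ok <- TRUE
      for (i in seq.int(3L, n_beads)) {
        placed <- FALSE
        centroid <- colMeans(pos[seq_len(i - 1L), , drop = FALSE])
        for (try in seq_len(200L)) {
          dir <- stats::rnorm(3L)
          pull <- centroid - pos[i - 1L, ]
          if (vec_norm(pull) > 0) dir <- dir + 1.5 * pull / max(vec_norm(pull), bond_length)
          cand <- pos[i - 1L, ] + bond_length * unit_vector(dir)
          prev <- pos[seq_len(i - 2L), , drop = FALSE]
          if (nrow(prev) == 0L ||
              min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= min_sep) {
            pos[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(bead_structure(pos, masses = rep(mass, n_beads),
                                    labels = sprintf("BB%d", seq_len(n_beads))))
    }
    stop("could not pack a self-avoiding chain; loosen bond_length", call. = FALSE)
  })
}

check_grid <- function(n_frames, dt) {
  if (!is.numeric(n_frames) || n_frames < 2L)
    stop("n_frames must be >= 2", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("dt must be positive (ps)", call. = FALSE)
  invisible(TRUE)
}
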