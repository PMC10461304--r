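# Shared fixtures, all built in code. Units: nm, ps, amu.

# regular tetrahedron, edge ~0.49 nm, unit masses
tetrahedron <- function(mass = 1) {
  p <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 0.175
  bead_structure(p, masses = rep(mass, 4))
}

# Twist-symmetric bead set: each half is C2-symmetric about the twist axis
# (pairs p, Rz(pi) p) and the lower half mirrors the upper, so the
# counter-twisting halves have equal axis inertia and their angular momenta
# cancel exactly at every instant.
twist_symmetric_structure <- function(n_base = 4, seed = 11) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base <- cbind(stats::runif(n_base, -0.5, 0.5),
                stats::runif(n_base, -0.5, 0.5),
                stats::runif(n_base, 0.1, 0.6))
  top <- rbind(base, cbind(-base[, 1], -base[, 2], base[, 3]))
  bot <- cbind(top[, 1], top[, 2], -top[, 3])
  bead_structure(rbind(top, bot), masses = rep(72, 4L * n_base))
}

vec3_norm <- function(v) sqrt(sum(v^2))

# standard composite fixture: rigid rotation about x3 plus a twist
rigid_twist_composite <- function(structure, omega3 = 5, amplitude = 0.2,
                                  frequency = 0.02, n_frames = 100, dt = 1) {
  compose_motions(list(
    make_rigid_rotor(structure, c(0, 0, omega3), n_frames, dt),
    make_twist(structure, amplitude, frequency, axis = c(0, 0, 1),
               n_frames = n_frames, dt = dt)))
}

expect_vector_equal <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(abs(actual - expected)), tol)
}
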