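# Synthetic generators: ground-truth kinematics, symmetry, determinism.

test_that("rigid rotor kinematics are exact", {
  s <- tetrahedron()
  tr <- make_rigid_rotor(s, omega = c(0, 0, 5), n_frames = 25, dt = 0.02)
  w <- per_ns_to_per_ps(c(0, 0, 5))
  com0 <- colSums(s$positions * s$masses) / sum(s$masses)
  for (k in c(1L, 10L, 25L)) {
    f <- tr$frames[[k]]
    com <- center_of_mass(f, s)
    expect_vector_equal(com$position, com0)
    expect_vector_equal(com$velocity, c(0, 0, 0))
    d <- sweep(f$positions, 2, com$position)
    # v = omega x d, bead by bead
    vref <- t(apply(d, 1, function(di) c(w[2] * di[3] - w[3] * di[2],
                                         w[3] * di[1] - w[1] * di[3],
                                         w[1] * di[2] - w[2] * di[1])))
    expect_vector_equal(f$velocities, vref)
    # bead speed = |omega| * axis distance (per-bead arithmetic oracle)
    expect_vector_equal(sqrt(rowSums(f$velocities^2)),
                        vec3_norm(w) * sqrt(d[, 1]^2 + d[, 2]^2))
  }
  # single bead: rotation fixes the point
  s1 <- bead_structure(matrix(c(0.2, 0.1, -0.3), 1, 3), masses = 5)
  tr1 <- make_rigid_rotor(s1, c(3, -2, 5), n_frames = 5, dt = 0.1)
  for (f in tr1$frames) {
    expect_vector_equal(f$positions, s1$positions)
    expect_vector_equal(f$velocities, c(0, 0, 0))
  }
  expect_error(make_rigid_rotor(s, c(0, 0, 5), n_frames = 10, dt = -1), "dt")
})

test_that("breathing mode is angular-momentum free and scales Rg", {
  s <- make_toy_protein(20, seed = 3)
  tr <- make_breathing(s, amplitude = 0.1, frequency = 0.05,
                       n_frames = 40, dt = 0.5)
  for (f in tr$frames) {
    L <- angular_momentum(f, s)
    expect_lt(vec3_norm(L), 1e-12)
  }
  # max Rg = (1 + a) Rg0: frame grid hits sin = 1 at t = 5 ps (k = 11)
  rg <- rg_timeseries(tr)$rg
  rg0 <- gyration_tensor(traj_frame(0, s$positions), s)$rg
  expect_equal(max(rg), 1.1 * rg0, tolerance = 1e-10)
  # amplitude 0 -> static
  tr0 <- make_breathing(s, 0, 0.05, n_frames = 5, dt = 0.5)
  for (f in tr0$frames) expect_vector_equal(f$positions, tr0$frames[[1]]$positions)
  expect_error(make_breathing(s, 1.0, 0.05, 5, 0.5), "invert")
})

test_that("twist halves carry cancelling or net angular momentum as built", {
  sym <- twist_symmetric_structure()
  tr <- make_twist(sym, 0.3, 0.02, axis = c(0, 0, 1), n_frames = 30, dt = 1)
  for (k in c(2L, 14L, 27L))  # includes a velocity extremum at t = 0
    expect_lt(vec3_norm(angular_momentum(tr$frames[[k]], sym)), 1e-12)
  # unequal halves: |L| > 0 at twist-velocity extrema (t = multiples of period)
  s <- make_toy_protein(20, seed = 3)
  tru <- make_twist(s, 0.3, 0.02, axis = c(0, 0, 1), n_frames = 30, dt = 1)
  expect_gt(vec3_norm(angular_momentum(tru$frames[[1]], s)), 1e-6)
  # amplitude 0 -> static
  tr0 <- make_twist(s, 0, 0.02, n_frames = 4, dt = 1)
  for (f in tr0$frames) expect_vector_equal(f$positions, tr0$frames[[1]]$positions)
  expect_error(make_twist(bead_structure(matrix(0, 1, 3)), 0.1, 0.02,
                          n_frames = 4, dt = 1), "2 beads")
})

test_that("shear cloud lattice is exactly symmetric with the linear profile", {
  cl <- make_shear_cloud(60, radius = 2, gamma_dot = 10)
  pos <- cl$structure$positions
  m <- cl$structure$masses
  expect_gte(nrow(pos), 60)
  expect_identical(sum(m * pos[, 1]^2), sum(m * pos[, 2]^2))
  expect_identical(sum(m * pos[, 2]^2), sum(m * pos[, 3]^2))
  expect_vector_equal(colSums(m * pos), c(0, 0, 0))
  gd <- per_ns_to_per_ps(10)
  expect_vector_equal(cl$frame$velocities,
                      cbind(gd * pos[, 2], 0, 0))
  # gamma_dot = 0 -> all velocities zero
  cl0 <- make_shear_cloud(10, 1, 0)
  expect_vector_equal(cl0$frame$velocities, matrix(0, nrow(cl0$structure$positions), 3))
  # random cloud is seeded-reproducible
  a <- make_shear_cloud(50, 1, 5, lattice = FALSE, seed = 9)
  b <- make_shear_cloud(50, 1, 5, lattice = FALSE, seed = 9)
  expect_identical(a$structure$positions, b$structure$positions)
})

test_that("compose superposes fields and records ground truth", {
  s <- tetrahedron()
  rig <- make_rigid_rotor(s, c(0, 0, 5), n_frames = 12, dt = 0.5)
  expect_equal(compose_motions(list(rig))$frames[[7]]$positions,
               rig$frames[[7]]$positions, tolerance = 1e-14)
  bre <- make_breathing(s, 0.1, 0.05, n_frames = 12, dt = 0.5)
  comp <- compose_motions(list(rig, bre), com_velocity = c(0.01, 0, -0.02))
  # total KE reference is always the direct sum
  f <- comp$frames[[9]]
  direct <- 0.5 * sum(s$masses * rowSums(f$velocities^2))
  expect_equal(kinetic_lab(f, s)$T_total, direct, tolerance = 1e-14)
  expect_identical(comp$motion$kind, "composite")
  # mismatched grids refused
  short <- make_rigid_rotor(s, c(0, 0, 5), n_frames = 11, dt = 0.5)
  expect_error(compose_motions(list(rig, short)), "time grid")
})

test_that("toy protein chain is self-avoiding, spaced, deterministic", {
  s <- make_toy_protein(76, bond_length = 0.35, seed = 42)
  expect_identical(s$positions, make_toy_protein(76, bond_length = 0.35, seed = 42)$positions)
  consec <- sqrt(rowSums((s$positions[-1, ] - s$positions[-76, ])^2))
  expect_vector_equal(consec, rep(0.35, 75), tol = 1e-10)
  dmat <- as.matrix(stats::dist(s$positions))
  expect_gte(min(dmat[upper.tri(dmat)]), 0.9 * 0.35)
  s3 <- make_toy_protein(3, bond_length = 0.35, seed = 1)
  expect_equal(sqrt(sum((s3$positions[2, ] - s3$positions[1, ])^2)), 0.35,
               tolerance = 1e-12)
})

test_that("generators with a fixed seed are bit-reproducible and RNG-clean", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(make_toy_protein(10, seed = 5))
  invisible(make_shear_cloud(20, 1, 5, lattice = FALSE, seed = 5))
  after <- stats::runif(1)
  expect_identical(before, after)   # global RNG stream untouched
})
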