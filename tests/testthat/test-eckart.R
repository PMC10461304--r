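# Laboratory and Eckart rotation machinery.

test_that("center of mass, inertia and angular momentum match hand oracles", {
  # masses 1 and 3 at x = 0 and 1 -> COM at 0.75
  s <- bead_structure(rbind(c(0, 0, 0), c(1, 0, 0)), masses = c(1, 3))
  f <- traj_frame(0, s$positions, rbind(c(0.2, 0, 0), c(0.2, 0, 0)))
  com <- center_of_mass(f, s)
  expect_equal(com$position, c(0.75, 0, 0), tolerance = 1e-14)
  expect_equal(com$velocity, c(0.2, 0, 0), tolerance = 1e-14)
  # pair of unit masses at +-(1,0,0): J = diag(0, 2, 2)
  s2 <- bead_structure(rbind(c(1, 0, 0), c(-1, 0, 0)), masses = c(1, 1))
  f2 <- traj_frame(0, s2$positions)
  expect_vector_equal(inertia_tensor(f2, s2), diag(c(0, 2, 2)))
  # pure COM drift has zero angular momentum
  fd <- traj_frame(0, s2$positions, rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_vector_equal(angular_momentum(fd, s2), c(0, 0, 0))
  # PSD inertia on a generic frame
  s3 <- make_toy_protein(15, seed = 2)
  expect_gte(min(eigen(inertia_tensor(traj_frame(0, s3$positions), s3),
                       symmetric = TRUE)$values), 0)
})

test_that("apparent angular velocity is exact on rigid rotors and flags degeneracy", {
  s <- make_toy_protein(12, seed = 4)
  tr <- make_rigid_rotor(s, c(1.5, -2, 5), n_frames = 10, dt = 0.1)
  w <- per_ns_to_per_ps(c(1.5, -2, 5))
  for (k in c(1L, 6L, 10L)) {
    om <- apparent_angular_velocity(tr$frames[[k]], s)
    expect_lt(vec3_norm(om - w) / vec3_norm(w), 1e-10)
    expect_false(attr(om, "degenerate"))
  }
  # breathing frame: L = 0 -> omega = 0
  bre <- make_breathing(s, 0.2, 0.05, n_frames = 6, dt = 1)
  expect_vector_equal(apparent_angular_velocity(bre$frames[[4]], s), c(0, 0, 0))
  # collinear beads: degenerate inertia, pseudo-inverse flagged
  sl <- bead_structure(cbind(c(0, 0.5, 1), 0, 0), masses = rep(1, 3))
  fl <- traj_frame(0, sl$positions, matrix(0, 3, 3))
  oml <- apparent_angular_velocity(fl, sl)
  expect_true(attr(oml, "degenerate"))
})

test_that("shear cloud recovers the Einstein sphere limit analytically", {
  cl <- make_shear_cloud(80, radius = 2, gamma_dot = 10)
  om <- apparent_angular_velocity(cl$frame, cl$structure)
  gd <- per_ns_to_per_ps(10)
  expect_equal(abs(om[3]) / gd, 0.5, tolerance = 1e-12)
  expect_lt(abs(om[1]), 1e-15)
  expect_lt(abs(om[2]), 1e-15)
  expect_lt(om[3], 0)   # with flow v1 = gd * x2 the rotation is clockwise
})

test_that("eckart_rotation recovers known rotations and satisfies the condition", {
  s <- make_toy_protein(20, seed = 6)
  f0 <- traj_frame(0, s$positions)
  expect_vector_equal(eckart_rotation(f0, s)$rotation, diag(3), tol = 1e-10)
  R0 <- rotation_about_axis(c(2, -1, 0.5), 1.1)
  cref <- s$positions - matrix(colMeans(s$positions), s$n, 3, byrow = TRUE)
  f1 <- traj_frame(0, cref %*% t(R0) + matrix(c(1, 2, 3), s$n, 3, byrow = TRUE))
  er <- eckart_rotation(f1, s)
  expect_vector_equal(er$rotation, R0, tol = 1e-10)
  expect_lt(er$residual, 1e-9)
  # small random displacements: residual still at round-off
  set.seed(8)
  f2 <- traj_frame(0, s$positions + matrix(rnorm(3 * s$n, sd = 0.02), s$n, 3))
  er2 <- eckart_rotation(f2, s)
  expect_lt(er2$residual, 1e-9)
  expect_equal(det(er2$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(er2$rotation) - diag(3))), 1e-10)
  expect_error(eckart_rotation(
    traj_frame(0, cbind(0:2, 0, 0)),
    bead_structure(cbind(0:2, 0, 0), masses = rep(1, 3))), "collinear")
})

test_that("Eckart state: rigid and breathing limits are exact", {
  s <- make_toy_protein(20, seed = 6)
  tr <- make_rigid_rotor(s, c(0, 0, 5), n_frames = 20, dt = 1)
  w <- per_ns_to_per_ps(c(0, 0, 5))
  for (k in c(2L, 11L, 20L)) {
    st <- eckart_state(tr$frames[[k]], s)
    expect_lt(vec3_norm(st$Omega - w) / vec3_norm(w), 1e-10)
    expect_lt(max(abs(st$delta_v)), 1e-13)
    expect_lt(st$eckart_residual, 1e-9)
  }
  bre <- make_breathing(s, 0.15, 0.05, n_frames = 20, dt = 0.5)
  for (k in c(3L, 12L)) {
    st <- eckart_state(bre$frames[[k]], s)
    expect_lt(vec3_norm(st$Omega), 1e-12)
    expect_lt(max(abs(st$v_ang)), 1e-12)
  }
})

test_that("Omega agrees with a finite-difference rotation-history oracle", {
  # the oracle differentiates the Eckart rotation over time (skew of
  # Rdot R^T) and never touches the J' linear system
  s <- make_toy_protein(20, seed = 6)
  t_eval <- 10        # compare at the same physical time for both grids
  err <- sapply(c(0.5, 0.25), function(dt) {
    k <- as.integer(round(t_eval / dt)) + 1L
    comp <- rigid_twist_composite(s, amplitude = 0.2, n_frames = k + 2L,
                                  dt = dt)
    Rm <- eckart_rotation(comp$frames[[k - 1L]], s)$rotation
    R0 <- eckart_rotation(comp$frames[[k]], s)$rotation
    Rp <- eckart_rotation(comp$frames[[k + 1L]], s)$rotation
    S <- (Rp %*% t(R0) - Rm %*% t(R0)) / (2 * dt)
    om_fd <- c(S[3, 2] - S[2, 3], S[1, 3] - S[3, 1], S[2, 1] - S[1, 2]) / 2
    vec3_norm(eckart_state(comp$frames[[k]], s)$Omega - om_fd)
  })
  expect_lt(err[2], err[1])              # O(dt^2) convergence direction
  expect_lt(err[2] / err[1], 0.5)
  expect_lt(err[2], 1e-5)
})

test_that("Eckart rotation minimizes the leading Coriolis coupling", {
  s <- make_toy_protein(20, seed = 6)
  comp <- rigid_twist_composite(s, n_frames = 60, dt = 1)
  set.seed(31)
  for (k in c(7L, 25L, 48L)) {
    f <- comp$frames[[k]]
    base <- coriolis_coupling(f, s)
    expect_lt(base, 1e-10)
    R0 <- eckart_rotation(f, s)$rotation
    vals <- replicate(100, {
      Rp <- rotation_about_axis(rnorm(3), runif(1, 0, 5 * pi / 180)) %*% R0
      coriolis_coupling(f, s, rotation = Rp)
    })
    expect_true(all(vals >= base))
  }
})

test_that("frame-convention invariance: global rotation maps omega and Omega", {
  s <- make_toy_protein(15, seed = 9)
  comp <- rigid_twist_composite(s, n_frames = 10, dt = 1)
  Q <- rotation_about_axis(c(1, 1, -2), 0.8)
  k <- 6L
  f <- comp$frames[[k]]
  fQ <- traj_frame(f$time, f$positions %*% t(Q), f$velocities %*% t(Q))
  sQ <- bead_structure(s$positions %*% t(Q), masses = s$masses)
  st <- eckart_state(f, s)
  stQ <- eckart_state(fQ, sQ)
  expect_vector_equal(stQ$omega_lab, drop(Q %*% st$omega_lab), tol = 1e-12)
  expect_vector_equal(stQ$Omega, drop(Q %*% st$Omega), tol = 1e-12)
})

test_that("finite-difference velocities behave as documented", {
  s <- tetrahedron()
  # linear drift: exact
  frames <- lapply(0:4, function(k)
    traj_frame(k * 0.5, s$positions + matrix(c(0.1, -0.2, 0.3) * k * 0.5,
                                             4, 3, byrow = TRUE)))
  tr <- finite_difference_velocities(bead_trajectory(s, frames, dt = 0.5))
  expect_true(tr$has_velocities)
  for (f in tr$frames)
    expect_vector_equal(f$velocities,
                        matrix(c(0.1, -0.2, 0.3), 4, 3, byrow = TRUE), tol = 1e-12)
  # rigid rotor: O(dt^2) error, ratio ~ 4 when dt halves
  s2 <- make_toy_protein(10, seed = 5)
  err <- sapply(c(0.4, 0.2), function(dt) {
    tr2 <- make_rigid_rotor(s2, c(0, 0, 50), n_frames = 9, dt = dt)
    fd <- finite_difference_velocities(
      bead_trajectory(s2, lapply(tr2$frames, function(f)
        traj_frame(f$time, f$positions)), dt = dt))
    max(abs(fd$frames[[5]]$velocities - tr2$frames[[5]]$velocities))
  })
  expect_equal(err[1] / err[2], 4, tolerance = 0.1)
  expect_error(finite_difference_velocities(
    bead_trajectory(s, frames[1:2], dt = 0.5)), ">= 3 frames")
})

test_that("analyze_rotation emits the per-frame table with re-referencing", {
  s <- make_toy_protein(12, seed = 10)
  tr <- make_rigid_rotor(s, c(0, 0, 8), n_frames = 12, dt = 0.5)
  tab <- analyze_rotation(tr)
  expect_identical(nrow(tab), 12L)
  expect_vector_equal(tab$Omega3, rep(per_ns_to_per_ps(8), 12), tol = 1e-12)
  tab2 <- analyze_rotation(tr, rereference_every = 4L)
  expect_vector_equal(tab2$Omega3, tab$Omega3, tol = 1e-10)
})
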