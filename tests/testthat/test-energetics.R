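# Kinetic-energy decompositions and their closures.

test_that("unit identity and single-bead limit", {
  s <- bead_structure(matrix(0, 1, 3), masses = 1)
  f <- traj_frame(0, s$positions, matrix(c(1, 0, 0), 1, 3))
  kl <- kinetic_lab(f, s)
  expect_equal(kl$T_total, 0.5, tolerance = 1e-14)   # amu nm^2/ps^2 == kJ/mol
  expect_equal(kl$T_trans, 0.5, tolerance = 1e-14)
  expect_equal(kl$T_rot_lab, 0, tolerance = 1e-14)
  expect_equal(kl$T_vib_lab, 0, tolerance = 1e-14)
})

test_that("pure-motion limits split cleanly in both frames", {
  s <- make_toy_protein(18, seed = 12)
  rig <- make_rigid_rotor(s, c(0, 0, 5), n_frames = 8, dt = 1)
  f <- rig$frames[[5]]
  kl <- kinetic_lab(f, s)
  ke <- kinetic_eckart(f, s, reference = s)
  expect_equal(kl$T_vib_lab, 0, tolerance = 1e-12 * kl$T_total)
  expect_equal(kl$T_rot_lab, kl$T_total, tolerance = 1e-12)
  expect_equal(ke$T_vib_nonang + ke$T_vib_ang + abs(ke$T_cori), 0,
               tolerance = 1e-12 * kl$T_total)
  bre <- make_breathing(s, 0.15, 0.05, n_frames = 8, dt = 1)
  fb <- bre$frames[[2]]
  klb <- kinetic_lab(fb, s)
  keb <- kinetic_eckart(fb, s, reference = s)
  expect_equal(klb$T_rot_lab, 0, tolerance = 1e-12 * klb$T_total)
  expect_equal(klb$T_vib_lab, klb$T_total, tolerance = 1e-12)
  expect_equal(keb$T_rot_eck + keb$T_vib_ang + abs(keb$T_cori), 0,
               tolerance = 1e-12 * klb$T_total)
  expect_equal(keb$T_vib_nonang, keb$T_total, tolerance = 1e-12)
})

test_that("double closure and frame relations hold on composite fixtures", {
  s <- make_toy_protein(18, seed = 12)
  comp <- compose_motions(
    list(make_rigid_rotor(s, c(0, 0, 5), n_frames = 30, dt = 1),
         make_twist(s, 0.25, 0.02, axis = c(0, 0, 1), n_frames = 30, dt = 1),
         make_breathing(s, 0.08, 0.04, n_frames = 30, dt = 1)),
    com_velocity = c(0.02, -0.01, 0.005))
  en <- decompose_trajectory(comp)
  lab_sum <- en$T_trans + en$T_rot_lab + en$T_vib_lab
  eck_sum <- en$T_trans + en$T_rot_eck + en$T_vib_nonang + en$T_vib_ang + en$T_cori
  expect_lt(max(abs(lab_sum - en$T_total) / en$T_total), 1e-10)
  expect_lt(max(abs(eck_sum - en$T_total) / en$T_total), 1e-10)
  # Eq-level relations, frame by frame
  for (k in c(3L, 17L, 30L)) {
    f <- comp$frames[[k]]
    st <- eckart_state(f, s)
    rel <- frame_relations(kinetic_lab(f, s),
                           kinetic_eckart(f, s, state = st))
    expect_true(rel$pass)
  }
  # T_vib_ang > 0 once the twist has displaced the beads (at t = 0 the
  # configuration equals the reference, where lab and Eckart coincide and
  # the angular-vibration term is exactly zero)
  expect_lt(en$T_vib_ang[1], 1e-15)
  expect_gt(max(en$T_vib_ang), 1e-7)
})

test_that("T_cori vanishes on rigid and breathing fixtures, grows with twist", {
  s <- make_toy_protein(18, seed = 12)
  rigid_en <- decompose_trajectory(make_rigid_rotor(s, c(0, 0, 5), 10, 1))
  expect_lt(max(abs(rigid_en$T_cori)), 1e-12)
  breath_en <- decompose_trajectory(make_breathing(s, 0.1, 0.05, 10, 1))
  expect_lt(max(abs(breath_en$T_cori)), 1e-12)
  coris <- sapply(c(0.1, 0.2, 0.3), function(a) {
    comp <- rigid_twist_composite(s, amplitude = a, n_frames = 50, dt = 1)
    mean(abs(decompose_trajectory(comp)$T_cori))
  })
  expect_true(all(diff(coris) > 0))
})

test_that("twist amplitude drives T_vib_ang and the lab-Eckart gap monotonically", {
  s <- make_toy_protein(18, seed = 12)
  res <- t(sapply(c(0.1, 0.2, 0.3), function(a) {
    comp <- rigid_twist_composite(s, amplitude = a, n_frames = 100, dt = 1)
    en <- decompose_trajectory(comp)
    rot <- analyze_rotation(comp)
    c(vib = mean(en$T_vib_ang), gap = mean(abs(rot$omega3 - rot$Omega3)))
  }))
  expect_true(all(diff(res[, "vib"]) > 0))
  expect_true(all(diff(res[, "gap"]) > 0))
})

test_that("Galilean invariance: uniform drift changes T_trans only", {
  s <- make_toy_protein(18, seed = 12)
  base <- rigid_twist_composite(s, n_frames = 10, dt = 1)
  drift <- compose_motions(list(base), com_velocity = c(0.3, -0.2, 0.1))
  en0 <- decompose_trajectory(base)
  en1 <- decompose_trajectory(drift)
  for (col in c("T_rot_lab", "T_vib_lab", "T_rot_eck", "T_vib_nonang",
                "T_vib_ang", "T_cori"))
    expect_vector_equal(en1[[col]], en0[[col]], tol = 1e-10)
  expect_gt(min(en1$T_trans - en0$T_trans), 0)
})

test_that("timeseries_stats: means, fractions, block SE", {
  # constant series
  rec <- data.frame(time = 1:10, T_total = 2, T_trans = 0.5,
                    T_rot_lab = 1, T_vib_lab = 0.5)
  st <- timeseries_stats(rec, block_length = 2)
  expect_equal(unname(st$se["T_total"]), 0)
  expect_equal(unname(st$mean["T_rot_lab"]), 1)
  expect_equal(unname(st$fraction_of_total["T_trans"]), 0.25)
  # fractions of a real decomposition close to 1 per frame
  s <- make_toy_protein(15, seed = 13)
  en <- decompose_trajectory(rigid_twist_composite(s, n_frames = 20, dt = 1))
  fr <- (en$T_trans + en$T_rot_eck + en$T_vib_nonang + en$T_vib_ang + en$T_cori) /
    en$T_total
  expect_vector_equal(fr, rep(1, nrow(en)), tol = 1e-12)
  # iid noise: block SE ~ sd/sqrt(N) within 20%
  set.seed(99)
  x <- rnorm(4000)
  rec2 <- data.frame(time = seq_along(x), T_total = x)
  st2 <- timeseries_stats(rec2, block_length = 1)
  expect_equal(unname(st2$se["T_total"]), sd(x) / sqrt(length(x)),
               tolerance = 0.2)
  expect_error(timeseries_stats(rec, block_length = 50), "block_length")
})
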