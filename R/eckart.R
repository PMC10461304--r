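# Laboratory-frame (apparent) and Eckart-frame rotation analysis.
#
# Conventions. d_a = r_a - r_cm are lab displacements; the reference
# configuration c_a is the input structure taken about its own center of mass.
# The Eckart rotation R maps reference axes to the lab, d_a ~ R c_a, and is
# the mass-weighted RMSD-minimizing proper rotation (quaternion eigenvector
# method), which satisfies the Eckart condition sum_a m_a c_a x rho_a = 0
# with rho_a = R^T d_a - c_a. The Eckart angular velocity Omega follows from
# the time derivative of that condition:
#     J' Omega' = sum_a m_a c_a x (R^T (v_a - v_cm)),
#     J'        = sum_a m_a [ (c_a . (c_a + rho_a)) I - (c_a + rho_a) c_a^T ],
# with Omega = R Omega' (J' is not symmetric in general). The vibrational
# velocity in the Eckart frame is Delta v_a = (v_a - v_cm) - Omega x d_a,
# split as Delta v = v_tilde + u where v_tilde = (v - v_cm) - omega x d is
# the angular-momentum-free residual of the lab decomposition and
# u = (omega - Omega) x d carries all the vibrational angular momentum.

#' Center of mass of a frame
#'
#' @param frame a [traj_frame()].
#' @param structure the matching [bead_structure()] (supplies masses).
#' @return list with `position` (nm) and `velocity` (nm/ps, `NULL` when the
#'   frame has no velocities).
#' @export
center_of_mass <- function(frame, structure) {
  check_frame_structure(frame, structure)
  w <- structure$masses / sum(structure$masses)
  pos <- colSums(frame$positions * w)
  vel <- if (!is.null(frame$velocities)) colSums(frame$velocities * w) else NULL
  list(position = pos, velocity = vel)
}

#' Moment-of-inertia tensor
#'
#' `J = sum_a m_a [ |d_a|^2 I - d_a d_a^T ]` with `d_a = r_a - r_cm`;
#' symmetric positive semidefinite, in amu nm^2.
#'
#' @inheritParams center_of_mass
#' @return 3x3 numeric matrix.
#' @export
inertia_tensor <- function(frame, structure) {
  check_frame_structure(frame, structure)
  d <- sweep(frame$positions, 2L, center_of_mass(frame, structure)$position)
  m <- structure$masses
  sum(m * rowSums(d^2)) * diag(3L) - crossprod(d * sqrt(m))
}

#' Angular momentum about the center of mass
#'
#' `L = sum_a m_a (r_a - r_cm) x (v_a - v_cm)`, in amu nm^2 / ps.
#'
#' @inheritParams center_of_mass
#' @return numeric length-3 vector.
#' @export
angular_momentum <- function(frame, structure) {
  check_frame_structure(frame, structure, need_velocities = TRUE)
  com <- center_of_mass(frame, structure)
  d <- sweep(frame$positions, 2L, com$position)
  dv <- sweep(frame$velocities, 2L, com$velocity)
  colSums(structure$masses * cross_rows(d, dv))
}

#' Apparent (laboratory-frame) angular velocity
#'
#' Solves `J omega = L`. This "apparent" angular velocity absorbs every source
#' of angular momentum, including vibrations that carry it; only for a rigid
#' body is it the rotation rate of the body. For a degenerate (collinear)
#' inertia tensor the system is solved by pseudo-inverse and flagged via the
#' `degenerate` attribute.
#'
#' @inheritParams center_of_mass
#' @return numeric length-3 vector in 1/ps, with attribute `degenerate`
#'   (logical).
#' @export
apparent_angular_velocity <- function(frame, structure) {
  J <- inertia_tensor(frame, structure)
  L <- angular_momentum(frame, structure)
  solve_inertia(J, L)
}

#' Full laboratory rotation state
#'
#' @inheritParams center_of_mass
#' @return list with `com`, `com_velocity`, `inertia`, `angular_momentum`,
#'   `omega` (1/ps) and `degenerate`.
#' @export
lab_rotation_state <- function(frame, structure) {
  check_frame_structure(frame, structure, need_velocities = TRUE)
  com <- center_of_mass(frame, structure)
  J <- inertia_tensor(frame, structure)
  L <- angular_momentum(frame, structure)
  omega <- solve_inertia(J, L)
  list(com = com$position, com_velocity = com$velocity, inertia = J,
       angular_momentum = L, omega = as.numeric(omega),
       degenerate = attr(omega, "degenerate"))
}

#' Eckart rotation by mass-weighted quaternion superposition
#'
#' Finds the proper rotation `R` minimizing the mass-weighted RMSD between the
#' frame displacements and the reference configuration (largest-eigenvalue
#' quaternion of the 4x4 Kearsley form). That rotation satisfies the Eckart
#' condition; the residual `|sum_a m_a c_a x rho_a|` is reported and should be
#' at round-off level.
#'
#' @param frame a [traj_frame()].
#' @param reference reference [bead_structure()] (the minimized structure in
#'   the intended workflow; any fixed configuration works).
#' @return list with `rotation` (3x3, maps reference axes to lab),
#'   `residual` (amu nm^2), and `degenerate` (TRUE when the optimal rotation
#'   is not unique at working precision, e.g. collinear references).
#' @export
eckart_rotation <- function(frame, reference) {
  check_frame_structure(frame, reference)
  if (reference$n < 3L)
    stop("eckart_rotation needs >= 3 beads", call. = FALSE)
  cref <- reference_displacements(reference)
  if (qr(cref)$rank < 2L)
    stop("collinear reference configuration: Eckart frame undefined", call. = FALSE)
  com <- center_of_mass(frame, reference)$position
  d <- sweep(frame$positions, 2L, com)
  m <- reference$masses
  K <- crossprod(cref * m, d)           # K = sum m c d^T
  FF <- kearsley_matrix(K)
  es <- eigen(FF, symmetric = TRUE)
  q <- es$vectors[, 1L]
  degenerate <- (es$values[1L] - es$values[2L]) <
    1e-9 * max(abs(es$values[1L]), 1)
  R <- quaternion_to_matrix(q)
  rho <- d %*% R - cref                 # rows rho_a = R^T d_a - c_a
  residual <- vec_norm(colSums(m * cross_rows(cref, rho)))
  list(rotation = R, residual = residual, degenerate = degenerate)
}

#' Eckart-frame state of a single frame
#'
#' Builds the corotating-frame displacements, the Eckart angular velocity
#' `Omega`, and the vibrational velocity split (see the conventions at the top
#' of this file's source).
#'
#' @inheritParams eckart_rotation
#' @return list of class `eckart_state` with fields `rotation`, `rho` (n x 3,
#'   corotating-frame displacements), `eckart_inertia` (J', amu nm^2),
#'   `Omega` (1/ps, lab components), `omega_lab` (1/ps), `delta_v`,
#'   `v_nonang`, `v_ang` (n x 3, nm/ps, lab components), `eckart_residual`,
#'   `com`, `com_velocity`, `inertia`, `angular_momentum`, `degenerate`.
#' @export
eckart_state <- function(frame, reference) {
  check_frame_structure(frame, reference, need_velocities = TRUE)
  rot <- eckart_rotation(frame, reference)
  lab <- lab_rotation_state(frame, reference)
  core <- eckart_frame_core(frame, reference, rotation = rot$rotation)
  v_nonang <- core$dv -
    cross_rows(matrix(lab$omega, nrow(core$d), 3L, byrow = TRUE), core$d)
  v_ang <- core$delta_v - v_nonang                   # (omega - Omega) x d
  structure(list(rotation = core$R, reference = reference, rho = core$rho,
                 eckart_inertia = core$Jp, Omega = core$Omega,
                 omega_lab = lab$omega,
                 delta_v = core$delta_v, v_nonang = v_nonang, v_ang = v_ang,
                 eckart_residual = rot$residual, com = lab$com,
                 com_velocity = lab$com_velocity, inertia = lab$inertia,
                 angular_momentum = lab$angular_momentum,
                 degenerate = rot$degenerate || core$degenerate ||
                   isTRUE(lab$degenerate)),
            class = "eckart_state")
}

# Shared Eckart-frame solve for a given (or the optimal) attachment rotation:
# rho, J', Omega from the differentiated Eckart-like condition, and the
# vibrational velocities Delta v in lab components.
eckart_frame_core <- function(frame, reference, rotation = NULL) {
  if (is.null(rotation)) rotation <- eckart_rotation(frame, reference)$rotation
  cref <- reference_displacements(reference)
  m <- reference$masses
  com <- center_of_mass(frame, reference)
  d <- sweep(frame$positions, 2L, com$position)
  dv <- sweep(frame$velocities, 2L, com$velocity)
  R <- rotation
  rho <- d %*% R - cref
  dprime <- cref + rho                               # rows R^T d_a
  Jp <- sum(m * rowSums(cref * dprime)) * diag(3L) -
    crossprod(dprime * m, cref)                      # J' (not symmetric)
  rhs <- colSums(m * cross_rows(cref, dv %*% R))
  sv <- svd(Jp)
  degenerate <- min(sv$d) < 1e-10 * max(sv$d, .Machine$double.eps)
  Omega_prime <- if (degenerate) drop(pinv3(Jp) %*% rhs) else solve(Jp, rhs)
  Omega <- drop(R %*% Omega_prime)
  delta_v <- dv - cross_rows(matrix(Omega, nrow(d), 3L, byrow = TRUE), d)
  list(R = R, d = d, dv = dv, rho = rho, Jp = Jp, Omega = Omega,
       delta_v = delta_v, degenerate = degenerate)
}

#' Coriolis coupling of a frame for an arbitrary frame rotation
#'
#' Measures the rotation-vibration (Coriolis) coupling when the corotating
#' frame is attached with an arbitrary rotation `rotation` instead of the
#' Eckart one.
#'
#' `what = "condition"` (default) returns the magnitude of the leading
#' coupling term `|sum_a m_a c_a x rhodot_a|` (amu nm^2/ps), where
#' `rhodot_a = rotation^T (v_a - v_cm - Omega x d_a)` are the vibrational
#' velocities seen in the candidate frame. A static reorientation of the
#' frame does not change its angular velocity, so `Omega` is held at the
#' Eckart value. This is the coupling term the Eckart conditions are chosen
#' to annihilate: it is exactly zero at the Eckart rotation and positive for
#' any other attachment, which makes "any other frame gives a larger
#' Coriolis coupling" a testable statement.
#'
#' `what = "energy"` returns the signed coupling energy
#' `Omega~ . sum_a m_a d_a x Delta v~_a` (kJ/mol), with the frame angular
#' velocity `Omega~` re-solved from the differentiated Eckart-like condition
#' at the candidate rotation. This is the term entering the kinetic-energy
#' decomposition; it is second order in the vibrational displacements, and
#' at the Eckart rotation it is the residual coupling that cannot be removed
#' (it is stationary, not minimal, there - see the methods vignette).
#'
#' @inheritParams eckart_rotation
#' @param rotation 3x3 proper rotation mapping reference axes to lab;
#'   default: the Eckart rotation itself.
#' @param what `"condition"` (leading coupling magnitude, amu nm^2/ps) or
#'   `"energy"` (signed coupling energy, kJ/mol).
#' @return scalar; see `what`.
#' @export
coriolis_coupling <- function(frame, reference, rotation = NULL,
                              what = c("condition", "energy")) {
  what <- match.arg(what)
  check_frame_structure(frame, reference, need_velocities = TRUE)
  eck <- eckart_frame_core(frame, reference, rotation = NULL)
  if (is.null(rotation)) rotation <- eck$R
  cref <- reference_displacements(reference)
  m <- reference$masses
  if (what == "condition") {
    rhodot <- eck$delta_v %*% rotation     # rows: rotation^T (dv - Omega x d)
    return(vec_norm(colSums(m * cross_rows(cref, rhodot))))
  }
  cand <- eckart_frame_core(frame, reference, rotation = rotation)
  sum(cand$Omega * colSums(m * cross_rows(cand$d, cand$delta_v)))
}

#' Per-frame rotation analysis of a whole trajectory
#'
#' @param trajectory a [bead_trajectory()] with velocities (use
#'   [finite_difference_velocities()] first when absent).
#' @param reference reference [bead_structure()]; default: the trajectory's
#'   own structure.
#' @param rereference_every re-solve the reference every N frames using the
#'   instantaneous configuration (0 = never, the default). Provided because
#'   re-referencing was checked and found immaterial in the intended
#'   application; exposed for the same check here.
#' @return data.frame with columns `time`, `omega1..3` and `Omega1..3`
#'   (1/ps), `eckart_residual` (amu nm^2), `degenerate` (logical).
#' @export
analyze_rotation <- function(trajectory, reference = NULL,
                             rereference_every = 0L) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  if (!trajectory$has_velocities)
    stop("trajectory has no velocities; run finite_difference_velocities()",
         call. = FALSE)
  if (is.null(reference)) reference <- trajectory$structure
  ref <- reference
  out <- vector("list", n_frames(trajectory))
  for (k in seq_len(n_frames(trajectory))) {
    if (rereference_every > 0L && k > 1L &&
        (k - 1L) %% rereference_every == 0L) {
      ref <- bead_structure(trajectory$frames[[k]]$positions,
                            masses = reference$masses,
                            labels = reference$labels)
    }
    st <- eckart_state(trajectory$frames[[k]], ref)
    out[[k]] <- data.frame(time = trajectory$frames[[k]]$time,
                           omega1 = st$omega_lab[1L], omega2 = st$omega_lab[2L],
                           omega3 = st$omega_lab[3L], Omega1 = st$Omega[1L],
                           Omega2 = st$Omega[2L], Omega3 = st$Omega[3L],
                           eckart_residual = st$eckart_residual,
                           degenerate = st$degenerate)
  }
  do.call(rbind, out)
}

#' Finite-difference velocities for a velocity-free trajectory
#'
#' Central differences in the interior, one-sided at the ends; exact for
#' linear motion, O(dt^2) otherwise. A fallback for inputs without velocity
#' columns - synthetic generators always produce analytic velocities.
#'
#' @param trajectory a [bead_trajectory()] with >= 3 uniformly spaced frames.
#' @return the trajectory with velocities filled in and `has_velocities` set.
#' @export
finite_difference_velocities <- function(trajectory) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  nf <- n_frames(trajectory)
  if (nf < 3L) stop("need >= 3 frames for finite differences", call. = FALSE)
  dts <- diff(trajectory$times)
  if (max(dts) - min(dts) > 1e-9 * mean(dts))
    stop("finite differences need a uniform time grid", call. = FALSE)
  h <- mean(dts)
  P <- lapply(trajectory$frames, function(f) f$positions)
  frames <- vector("list", nf)
  for (k in seq_len(nf)) {
    v <- if (k == 1L) (P[[2L]] - P[[1L]]) / h
         else if (k == nf) (P[[nf]] - P[[nf - 1L]]) / h
         else (P[[k + 1L]] - P[[k - 1L]]) / (2 * h)
    frames[[k]] <- traj_frame(trajectory$times[k], P[[k]], v)
  }
  bead_trajectory(trajectory$structure, frames, dt = trajectory$dt,
                  motion = trajectory$motion)
}

# ---- internals ----

solve_inertia <- function(J, L) {
  sv <- svd(J)
  degenerate <- min(sv$d) < 1e-10 * max(sv$d, .Machine$double.eps)
  omega <- if (degenerate) drop(pinv3(J) %*% L) else solve(J, L)
  structure(as.numeric(omega), degenerate = degenerate)
}

# Kearsley 4x4 form for the correlation matrix K = sum m c d^T; its largest
# eigenvalue's quaternion gives the proper rotation maximizing
# sum m (R c) . d, i.e. minimizing the mass-weighted RMSD.
kearsley_matrix <- function(K) {
  matrix(c(
    K[1,1] + K[2,2] + K[3,3], K[2,3] - K[3,2], K[3,1] - K[1,3], K[1,2] - K[2,1],
    K[2,3] - K[3,2], K[1,1] - K[2,2] - K[3,3], K[1,2] + K[2,1], K[1,3] + K[3,1],
    K[3,1] - K[1,3], K[1,2] + K[2,1], -K[1,1] + K[2,2] - K[3,3], K[2,3] + K[3,2],
    K[1,2] - K[2,1], K[1,3] + K[3,1], K[2,3] + K[3,2], -K[1,1] - K[2,2] + K[3,3]),
    4L, 4L, byrow = TRUE)
}

quaternion_to_matrix <- function(q) {
  q <- q / vec_norm(q)
  q0 <- q[1L]; q1 <- q[2L]; q2 <- q[3L]; q3 <- q[4L]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2),
    3L, 3L, byrow = TRUE)
}

check_frame_structure <- function(frame, structure, need_velocities = FALSE) {
  stopifnot(inherits(frame, "traj_frame"), inherits(structure, "bead_structure"))
  if (nrow(frame$positions) != structure$n)
    stop("frame and structure bead counts differ", call. = FALSE)
  if (need_velocities && is.null(frame$velocities))
    stop("frame carries no velocities", call. = FALSE)
  invisible(TRUE)
}
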