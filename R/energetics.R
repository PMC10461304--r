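# Kinetic-energy decomposition in the laboratory and Eckart frames.
# Energies are in kJ/mol via the amu nm^2 ps^-2 identity. The laboratory
# split is T = T_trans + T_rot^lab + T_vib^lab with T_rot^lab built from the
# apparent angular velocity; because omega absorbs all angular momentum the
# lab Coriolis cross term vanishes identically. The Eckart split has five
# terms; the vibration carrying angular momentum and the (possibly negative)
# Coriolis coupling together with the Eckart rotational term recompose the
# lab rotational term.

#' Laboratory-frame kinetic-energy decomposition
#'
#' `T_trans = M |v_cm|^2 / 2`, `T_rot_lab = omega^T J omega / 2`, and
#' `T_vib_lab = T_total - T_trans - T_rot_lab`. The residual-velocity form
#' `sum m |v_tilde|^2 / 2` is computed as a cross-check; a relative
#' discrepancy above 1e-8 raises a warning (it would indicate a broken
#' inertia solve, e.g. a degenerate bead set). The laboratory Coriolis term
#' `omega . sum m d x v_tilde` is evaluated and reported; it is zero by
#' construction up to solver round-off.
#'
#' @inheritParams center_of_mass
#' @param lab_state optional precomputed [lab_rotation_state()].
#' @return list with `time`, `T_total`, `T_trans`, `T_rot_lab`, `T_vib_lab`,
#'   `T_cori_lab` (diagnostic, ~0) - all kJ/mol.
#' @export
kinetic_lab <- function(frame, structure, lab_state = NULL) {
  check_frame_structure(frame, structure, need_velocities = TRUE)
  if (is.null(lab_state)) lab_state <- lab_rotation_state(frame, structure)
  m <- structure$masses
  T_total <- 0.5 * sum(m * rowSums(frame$velocities^2))
  T_trans <- 0.5 * sum(m) * sum(lab_state$com_velocity^2)
  T_rot <- 0.5 * sum(lab_state$omega * (lab_state$inertia %*% lab_state$omega))
  d <- sweep(frame$positions, 2L, lab_state$com)
  dv <- sweep(frame$velocities, 2L, lab_state$com_velocity)
  vt <- dv - cross_rows(matrix(lab_state$omega, nrow(d), 3L, byrow = TRUE), d)
  T_vib_direct <- 0.5 * sum(m * rowSums(vt^2))
  T_vib <- T_total - T_trans - T_rot
  if (abs(T_vib - T_vib_direct) > 1e-8 * max(T_total, .Machine$double.eps))
    warning("lab vibrational energy: residual and direct forms disagree; ",
            "degenerate inertia?", call. = FALSE)
  T_cori_lab <- sum(lab_state$omega * colSums(m * cross_rows(d, vt)))
  list(time = frame$time, T_total = T_total, T_trans = T_trans,
       T_rot_lab = T_rot, T_vib_lab = T_vib, T_cori_lab = T_cori_lab)
}

#' Eckart-frame kinetic-energy decomposition
#'
#' Five terms: `T_trans`; `T_rot_eck = Omega^T J Omega / 2` with the
#' instantaneous inertia tensor; `T_vib_nonang = sum m |v_tilde|^2 / 2` from
#' the angular-momentum-free vibrational velocities; `T_vib_ang =
#' sum m |u|^2 / 2` from the vibrational velocities carrying angular
#' momentum; and the signed Coriolis coupling
#' `T_cori = Omega . sum m d x Delta v`. The five terms sum to the direct
#' total `sum m |v|^2 / 2`.
#'
#' @inheritParams center_of_mass
#' @param state an [eckart_state()] for this frame (computed when `NULL`,
#'   using `reference`).
#' @param reference reference structure, used only when `state` is `NULL`.
#' @return list with `time`, `T_total`, `T_trans`, `T_rot_eck`,
#'   `T_vib_nonang`, `T_vib_ang`, `T_cori` - all kJ/mol.
#' @export
kinetic_eckart <- function(frame, structure, state = NULL, reference = NULL) {
  check_frame_structure(frame, structure, need_velocities = TRUE)
  if (is.null(state)) {
    if (is.null(reference)) reference <- structure
    state <- eckart_state(frame, reference)
  }
  m <- structure$masses
  T_total <- 0.5 * sum(m * rowSums(frame$velocities^2))
  T_trans <- 0.5 * sum(m) * sum(state$com_velocity^2)
  T_rot <- 0.5 * sum(state$Omega * (state$inertia %*% state$Omega))
  T_vib_nonang <- 0.5 * sum(m * rowSums(state$v_nonang^2))
  T_vib_ang <- 0.5 * sum(m * rowSums(state$v_ang^2))
  d <- sweep(frame$positions, 2L, state$com)
  T_cori <- sum(state$Omega * colSums(m * cross_rows(d, state$delta_v)))
  list(time = frame$time, T_total = T_total, T_trans = T_trans,
       T_rot_eck = T_rot, T_vib_nonang = T_vib_nonang,
       T_vib_ang = T_vib_ang, T_cori = T_cori)
}

#' Inter-frame kinetic-energy relations
#'
#' Checks the identities linking the two decompositions of the same frame:
#' the vibrational energies without angular momentum agree across frames
#' (`T_vib_lab = T_vib_nonang`), and the lab rotational energy recomposes
#' from the Eckart rotational, angular-vibrational and Coriolis terms
#' (`T_rot_lab = T_rot_eck + T_vib_ang + T_cori`). Totals agree trivially.
#'
#' @param lab_part output of [kinetic_lab()].
#' @param eckart_part output of [kinetic_eckart()] for the same frame.
#' @return list with absolute residuals `vib_residual`, `rot_residual`,
#'   `total_residual` and logical `pass` at `tol * T_total`.
#' @param tol relative tolerance (default 1e-10).
#' @export
frame_relations <- function(lab_part, eckart_part, tol = 1e-10) {
  if (!isTRUE(all.equal(lab_part$time, eckart_part$time)))
    stop("decompositions come from different frames", call. = FALSE)
  vib_res <- abs(lab_part$T_vib_lab - eckart_part$T_vib_nonang)
  rot_res <- abs(lab_part$T_rot_lab -
                 (eckart_part$T_rot_eck + eckart_part$T_vib_ang +
                  eckart_part$T_cori))
  tot_res <- abs(lab_part$T_total - eckart_part$T_total)
  scale <- max(lab_part$T_total, .Machine$double.eps)
  list(vib_residual = vib_res, rot_residual = rot_res,
       total_residual = tot_res,
       pass = max(vib_res, rot_res, tot_res) < tol * scale)
}

#' Per-frame energy decomposition of a trajectory
#'
#' Runs both decompositions on every frame against a common reference.
#'
#' @inheritParams analyze_rotation
#' @return data.frame with one row per frame: `time`, `T_total`, `T_trans`,
#'   `T_rot_lab`, `T_vib_lab`, `T_rot_eck`, `T_vib_nonang`, `T_vib_ang`,
#'   `T_cori` (kJ/mol).
#' @export
decompose_trajectory <- function(trajectory, reference = NULL) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  if (!trajectory$has_velocities)
    stop("trajectory has no velocities", call. = FALSE)
  if (is.null(reference)) reference <- trajectory$structure
  rows <- lapply(trajectory$frames, function(f) {
    st <- eckart_state(f, reference)
    lab <- kinetic_lab(f, trajectory$structure,
                       lab_state = list(com = st$com,
                                        com_velocity = st$com_velocity,
                                        inertia = st$inertia,
                                        angular_momentum = st$angular_momentum,
                                        omega = st$omega_lab))
    eck <- kinetic_eckart(f, trajectory$structure, state = st)
    data.frame(time = f$time, T_total = lab$T_total, T_trans = lab$T_trans,
               T_rot_lab = lab$T_rot_lab, T_vib_lab = lab$T_vib_lab,
               T_rot_eck = eck$T_rot_eck, T_vib_nonang = eck$T_vib_nonang,
               T_vib_ang = eck$T_vib_ang, T_cori = eck$T_cori)
  })
  do.call(rbind, rows)
}

#' Time-series statistics for an energy decomposition
#'
#' Means, block-averaged standard errors, and mean fractional contributions
#' for each energy component. Fractions are per-frame component / T_total
#' (signed for the Coriolis term), reported both with and without the
#' translational term in the denominator, since either normalization is
#' defensible for "relative contributions".
#'
#' @param records data.frame from [decompose_trajectory()].
#' @param block_length frames per block for the standard error (default 50;
#'   blocks shorter than the series are required).
#' @return list with `mean`, `se`, `fraction_of_total`,
#'   `fraction_of_internal` (named numeric vectors) and `n_frames`,
#'   `block_length`.
#' @export
timeseries_stats <- function(records, block_length = 50L) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  block_length <- as.integer(block_length)
  if (block_length < 1L || block_length > nrow(records))
    stop("block_length must be in [1, n_frames]", call. = FALSE)
  comps <- setdiff(names(records), "time")
  mu <- vapply(records[comps], mean, numeric(1L))
  se <- vapply(records[comps], function(x) block_se(x, block_length), numeric(1L))
  tot <- records$T_total
  frac_tot <- vapply(records[comps], function(x) mean(x / tot), numeric(1L))
  internal <- tot - records$T_trans
  frac_int <- vapply(records[comps],
                     function(x) mean(ifelse(internal > 0, x / internal, NA_real_)),
                     numeric(1L))
  list(mean = mu, se = se, fraction_of_total = frac_tot,
       fraction_of_internal = frac_int,
       n_frames = nrow(records), block_length = block_length)
}

# Standard error from non-overlapping block means; trailing partial block
# dropped. With block_length 1 this is sd/sqrt(N).
block_se <- function(x, block_length) {
  nb <- length(x) %/% block_length
  if (nb < 2L) return(NA_real_)
  means <- vapply(seq_len(nb), function(b)
    mean(x[((b - 1L) * block_length + 1L):(b * block_length)]), numeric(1L))
  stats::sd(means) / sqrt(nb)
}
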