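# Conformational observables: gyration tensor and radius of gyration, RMSD,
# RMSF, and shear-normalized gyration diagonals. Axes follow the shear
# convention: x1 flow, x2 gradient, x3 vorticity.

#' Gyration tensor and radius of gyration
#'
#' `G_{mu nu} = sum_a w_a (r_a - r_cm)_mu (r_a - r_cm)_nu / sum_a w_a` with
#' `w_a` the bead masses (default) or 1; `rg = sqrt(trace G)`. The centering
#' uses the same weights as the averaging.
#'
#' @inheritParams center_of_mass
#' @param mass_weighted logical; mass-weight the tensor (default `TRUE`).
#'   With equal bead masses both variants coincide.
#' @return list with `tensor` (3x3, nm^2) and `rg` (nm).
#' @examples
#' s <- bead_structure(rbind(c(0.5, 0, 0), c(-0.5, 0, 0)), masses = c(1, 1))
#' gyration_tensor(traj_frame(0, s$positions), s)$rg   # 0.5
#' @export
gyration_tensor <- function(frame, structure, mass_weighted = TRUE) {
  check_frame_structure(frame, structure)
  w <- if (mass_weighted) structure$masses else rep(1, structure$n)
  w <- w / sum(w)
  com <- colSums(frame$positions * w)
  d <- sweep(frame$positions, 2L, com)
  G <- crossprod(d * sqrt(w))
  list(tensor = G, rg = sqrt(sum(diag(G))))
}

#' Radius-of-gyration time series
#'
#' @param trajectory a [bead_trajectory()].
#' @inheritParams gyration_tensor
#' @return data.frame with `time`, `rg` (nm) and the six distinct gyration
#'   tensor entries `G11, G22, G33, G12, G13, G23` (nm^2); attributes
#'   `mean_rg` and `se_rg` (plain sd/sqrt(N)) are attached.
#' @export
rg_timeseries <- function(trajectory, mass_weighted = TRUE) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  rows <- lapply(trajectory$frames, function(f) {
    g <- gyration_tensor(f, trajectory$structure, mass_weighted)
    data.frame(time = f$time, rg = g$rg,
               G11 = g$tensor[1L, 1L], G22 = g$tensor[2L, 2L],
               G33 = g$tensor[3L, 3L], G12 = g$tensor[1L, 2L],
               G13 = g$tensor[1L, 3L], G23 = g$tensor[2L, 3L])
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_rg") <- mean(out$rg)
  attr(out, "se_rg") <- stats::sd(out$rg) / sqrt(nrow(out))
  out
}

#' Shear-normalized gyration diagonals
#'
#' `<G_ii> / <G_ii(gamma_dot = 0)>` for i = 1..3. Under shear the flow
#' component rises above 1 (stretching along the flow) and the gradient
#' component falls below 1 (compression along the gradient).
#'
#' @param trajectory sheared-trajectory [bead_trajectory()].
#' @param reference_trajectory zero-shear reference trajectory.
#' @inheritParams gyration_tensor
#' @return numeric length-3 vector of dimensionless ratios.
#' @export
normalized_diagonals <- function(trajectory, reference_trajectory,
                                 mass_weighted = TRUE) {
  g <- rg_timeseries(trajectory, mass_weighted)
  g0 <- rg_timeseries(reference_trajectory, mass_weighted)
  num <- colMeans(g[, c("G11", "G22", "G33")])
  den <- colMeans(g0[, c("G11", "G22", "G33")])
  if (any(den <= 0)) stop("zero-shear reference has a zero diagonal", call. = FALSE)
  as.numeric(num / den)
}

#' Mass-weighted RMSD between a frame and a reference
#'
#' `sqrt( sum m |r_a - ref_a|^2 / sum m )`, optionally after removing the
#' centers of mass and applying the optimal (Eckart) rotation.
#'
#' @inheritParams eckart_rotation
#' @param superpose logical; superpose before measuring (default `TRUE`).
#' @param mass_weighted logical; mass weights in the average (default `TRUE`).
#' @return scalar RMSD in nm.
#' @export
rmsd <- function(frame, reference, superpose = TRUE, mass_weighted = TRUE) {
  check_frame_structure(frame, reference)
  w <- if (mass_weighted) reference$masses else rep(1, reference$n)
  w <- w / sum(w)
  if (superpose) {
    # both sets in their COM frames, rotation undone
    d <- superpose_frame(frame, reference) - reference_displacements(reference)
  } else {
    # raw coordinates, no alignment of any kind
    d <- frame$positions - reference$positions
  }
  sqrt(sum(w * rowSums(d^2)))
}

#' Per-bead root-mean-square fluctuation
#'
#' Fluctuation of each bead about its time-mean position. With
#' `superpose = TRUE` (default) every frame is first superposed onto the
#' reference (COM removal + optimal rotation), so rigid translation and
#' rotation contribute nothing.
#'
#' @param trajectory a [bead_trajectory()] with >= 2 frames.
#' @param reference reference [bead_structure()]; default: the trajectory's
#'   structure.
#' @param superpose logical (default `TRUE`).
#' @return numeric vector of per-bead RMSF values in nm.
#' @export
rmsf <- function(trajectory, reference = NULL, superpose = TRUE) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  if (n_frames(trajectory) < 2L) stop("rmsf needs >= 2 frames", call. = FALSE)
  if (is.null(reference)) reference <- trajectory$structure
  coords <- lapply(trajectory$frames, function(f) {
    if (superpose) superpose_frame(f, reference) else f$positions
  })
  nb <- reference$n
  mean_pos <- Reduce(`+`, coords) / length(coords)
  ssq <- Reduce(`+`, lapply(coords, function(p) rowSums((p - mean_pos)^2)))
  sqrt(ssq / length(coords))
}

# Frame coordinates expressed in the reference body frame: COM removed and
# the Eckart (optimal-superposition) rotation undone.
superpose_frame <- function(frame, reference) {
  com <- center_of_mass(frame, reference)$position
  R <- eckart_rotation(frame, reference)$rotation
  sweep(frame$positions, 2L, com) %*% R
}
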