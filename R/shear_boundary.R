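# Open-boundary (OBMD) shear formulas and DPD thermostat weights, as pure
# functions: the momentum-flux tensor of the imposed linear shear profile
# v1 = gamma_dot * x2, the buffer momentum balance yielding the external
# buffer force, its distribution over buffer particles, the DPD weight pair,
# and the buffer particle-number feedback. No particle insertion and no
# integration of equations of motion - these are the formulas a boundary
# driver would call, testable in isolation. All quantities are taken in one
# consistent unit system chosen by the caller (the package convention is
# amu / nm / ps, where pressure is kJ mol^-1 nm^-3).

#' Shear-boundary parameter set
#'
#' @param gamma_dot shear rate.
#' @param p pressure (normal load).
#' @param eta dynamic viscosity.
#' @param zeta bulk viscosity (carried for the isotropic stress term
#'   `pi = -zeta div v`, which vanishes for the divergence-free linear shear
#'   profile and enters none of the implemented components).
#' @param rho mass density.
#' @param n unit normal of the buffer-ROI interface, pointing into the ROI.
#' @param t unit vector along the flow; must be orthogonal to `n`.
#' @param area interface area.
#' @param D spatial dimension (default 3).
#' @return validated list of class `shear_params`.
#' @export
shear_params <- function(gamma_dot, p, eta, zeta = 0, rho,
                         n = c(0, 1, 0), t = c(1, 0, 0), area = 1, D = 3L) {
  n <- unit_vector(as.numeric(n))
  t <- unit_vector(as.numeric(t))
  if (abs(sum(n * t)) > 1e-10)
    stop("n and t must be orthogonal", call. = FALSE)
  if (area <= 0) stop("area must be positive", call. = FALSE)
  structure(list(gamma_dot = gamma_dot, p = p, eta = eta, zeta = zeta,
                 rho = rho, n = n, t = t, area = area, D = as.integer(D)),
            class = "shear_params")
}

#' Momentum-flux tensor of the imposed shear profile
#'
#' For the linear profile `v1 = gamma_dot * x2` under a constant normal load
#' `p`: `J11 = rho gamma_dot^2 x2^2 + p`, `J12 = J21 = -eta gamma_dot`,
#' `J22 = J33 = p`, all remaining off-diagonals zero. With `gamma_dot = 0` it
#' reduces to the constant-load form `p I`.
#'
#' @param params a [shear_params()].
#' @param x2 coordinate along the gradient (open) direction.
#' @return 3x3 numeric matrix.
#' @export
momentum_flux_tensor <- function(params, x2 = 0) {
  stopifnot(inherits(params, "shear_params"))
  J <- diag(c(params$rho * params$gamma_dot^2 * x2^2 + params$p,
              params$p, params$p))
  J[1L, 2L] <- J[2L, 1L] <- -params$eta * params$gamma_dot
  J
}

#' External buffer force from the momentum balance
#'
#' `F_ext = A (J22 n + J12 t) - sum_i' Delta(m v)_i' / dt`, where the flux
#' contribution uses the shear-geometry contraction `J^P . n = J22 n + J12 t`
#' and `Delta(m v)` is the momentum of each particle inserted (+) or deleted
#' (-) during the step. With zero shear and no exchange the force is the pure
#' normal load `p A n`; with zero flux it balances the exchanged momentum.
#'
#' @param params a [shear_params()].
#' @param flux 3x3 momentum-flux tensor (default: computed from `params` at
#'   `x2 = 0`).
#' @param exchanged_momentum matrix with one signed `Delta(m v)` row per
#'   inserted/deleted particle (or a single 3-vector); `NULL` for none.
#' @param dt time step over which the exchange happened.
#' @return numeric length-3 force vector.
#' @export
boundary_force <- function(params, flux = NULL, exchanged_momentum = NULL,
                           dt = 1) {
  stopifnot(inherits(params, "shear_params"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(flux)) flux <- momentum_flux_tensor(params, x2 = 0)
  Fv <- params$area * (flux[2L, 2L] * params$n + flux[1L, 2L] * params$t)
  if (!is.null(exchanged_momentum)) {
    dmv <- as_coord_matrix(exchanged_momentum, "exchanged_momentum")
    Fv <- Fv - colSums(dmv) / dt
  }
  Fv
}

#' Distribute the external buffer force over buffer particles
#'
#' Per-particle force `g_par_i (F . n) n + g_perp_i (F . t) t` (plus the same
#' `g_par` weighting for any residual component along `n x t`, so the sum is
#' conserved for arbitrary `F`). Weights are normalized to sum to 1, making
#' the per-particle forces sum to `F_ext` exactly regardless of the weighting
#' profile.
#'
#' @param F_ext total external force (length-3).
#' @param params a [shear_params()].
#' @param buffer_positions matrix of buffer particle positions (n x 3).
#' @param g_parallel,g_perp weighting spec for the normal / tangential parts:
#'   `"uniform"`, a numeric vector of per-particle weights, or a function of
#'   the position matrix returning one.
#' @return n x 3 matrix of per-particle forces.
#' @export
distribute_buffer_force <- function(F_ext, params, buffer_positions,
                                    g_parallel = "uniform",
                                    g_perp = "uniform") {
  stopifnot(inherits(params, "shear_params"))
  pos <- as_coord_matrix(buffer_positions, "buffer_positions")
  np <- nrow(pos)
  if (np < 1L) stop("buffer is empty", call. = FALSE)
  wpar <- normalize_weights(g_parallel, pos)
  wperp <- normalize_weights(g_perp, pos)
  b <- cross3(params$n, params$t)
  Fn <- sum(F_ext * params$n)
  Ft <- sum(F_ext * params$t)
  Fb <- sum(F_ext * b)
  outer(wpar, Fn * params$n) + outer(wperp, Ft * params$t) +
    outer(wpar, Fb * b)
}

#' DPD thermostat weight functions
#'
#' The standard dissipative/random weight pair:
#' `omega_R(r) = 1 - r/r_c` for `r < r_c` (0 beyond the cutoff) and
#' `omega_D = omega_R^2`, which is exactly the fluctuation-dissipation
#' constraint linking the dissipative and random forces.
#'
#' @param r interparticle distance(s), >= 0 (vectorized).
#' @param r_c cutoff radius, > 0.
#' @return list with numeric vectors `omega_D` and `omega_R`.
#' @examples
#' w <- dpd_weights(c(0, 0.5, 1), r_c = 1)
#' all.equal(w$omega_D, w$omega_R^2)
#' @export
dpd_weights <- function(r, r_c) {
  if (any(r < 0)) stop("r must be >= 0", call. = FALSE)
  if (r_c <= 0) stop("r_c must be positive", call. = FALSE)
  wR <- pmax(0, 1 - r / r_c)
  list(omega_D = wR^2, omega_R = wR)
}

#' Buffer occupation state
#'
#' @param N_B current particle count in the buffer.
#' @param N_target desired mean count `<N_B>`.
#' @param dt time step.
#' @param tau_B buffer relaxation time (> 0, typically ~100 dt).
#' @return validated list of class `buffer_state`.
#' @export
buffer_state <- function(N_B, N_target, dt, tau_B) {
  if (N_B < 0 || N_target < 0) stop("counts must be >= 0", call. = FALSE)
  if (tau_B <= 0) stop("tau_B must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(list(N_B = N_B, N_target = N_target, dt = dt, tau_B = tau_B),
            class = "buffer_state")
}

#' Buffer feedback step
#'
#' `Delta N_B = (dt / tau_B) (<N_B> - N_B)`: negative when the buffer is
#' overfull (deletion regime), positive when underfull (insertion regime).
#' For `dt < tau_B` the update is a contraction toward the target.
#'
#' @param state a [buffer_state()].
#' @return scalar `Delta N_B` (generally fractional).
#' @export
buffer_feedback <- function(state) {
  stopifnot(inherits(state, "buffer_state"))
  (state$dt / state$tau_B) * (state$N_target - state$N_B)
}

normalize_weights <- function(spec, pos) {
  np <- nrow(pos)
  w <- if (is.character(spec) && identical(spec, "uniform")) rep(1, np)
       else if (is.function(spec)) spec(pos)
       else as.numeric(spec)
  if (length(w) != np) stop("weighting spec must yield one weight per particle",
                            call. = FALSE)
  s <- sum(w)
  if (abs(s) < .Machine$double.eps)
    stop("weights sum to zero", call. = FALSE)
  w / s
}
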