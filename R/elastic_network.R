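# Breakable elastic network (EN). Harmonic bonds are built between bead
# pairs whose reference separation falls inside a distance window (defaults
# 0.5-0.9 nm, force constant 550 kJ mol^-1 nm^-2, the standard CG backbone
# EN parameters). Each bond gets an irreversible break cutoff R_c = 1.35 r0:
# the first sampled frame in which the instantaneous length exceeds R_c
# breaks the bond for good; the pair is then handed off to the nonbonded
# bookkeeping (no potential evaluated here) and contributes nothing to the
# harmonic energy.

#' Build an elastic network from a structure
#'
#' One harmonic bond per bead pair with
#' `lower <= |r_i - r_j| <= upper`; the observed distance becomes the bond's
#' equilibrium length `r0`.
#'
#' @param structure a [bead_structure()].
#' @param lower,upper elastic bond cutoffs in nm (defaults 0.5 and 0.9).
#' @param k force constant in kJ mol^-1 nm^-2 (default 550).
#' @param selection optional integer vector of bead indices the EN is
#'   restricted to (e.g. backbone beads); default: all beads.
#' @return object of class `elastic_network`: a list with `bonds` (data.frame
#'   `i, j, k, r0, Rc, intact, break_time`), `lower`, `upper`, `n_beads`.
#' @export
build_en <- function(structure, lower = 0.5, upper = 0.9, k = 550,
                     selection = NULL) {
  stopifnot(inherits(structure, "bead_structure"))
  if (structure$n < 2L) stop("need >= 2 beads to build an EN", call. = FALSE)
  if (lower >= upper) stop("lower must be < upper", call. = FALSE)
  sel <- if (is.null(selection)) seq_len(structure$n) else sort(unique(as.integer(selection)))
  if (any(sel < 1L | sel > structure$n)) stop("selection out of range", call. = FALSE)
  pos <- structure$positions
  pairs <- utils::combn(sel, 2L)
  dd <- sqrt(rowSums((pos[pairs[1L, ], , drop = FALSE] -
                      pos[pairs[2L, ], , drop = FALSE])^2))
  keep <- which(dd >= lower & dd <= upper)
  bonds <- data.frame(i = as.integer(pairs[1L, keep]),
                      j = as.integer(pairs[2L, keep]),
                      k = rep(as.numeric(k), length(keep)),
                      r0 = dd[keep], Rc = rep(NA_real_, length(keep)),
                      intact = rep(TRUE, length(keep)),
                      break_time = rep(NA_real_, length(keep)))
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  structure(list(bonds = bonds, lower = lower, upper = upper,
                 n_beads = structure$n), class = "elastic_network")
}

#' Assign irreversible break cutoffs
#'
#' Sets `Rc = multiplier * r0` for every bond. The default multiplier 1.35 is
#' calibrated so that an equilibrium (zero-shear) trajectory conserves the
#' network.
#'
#' @param network an [build_en()] network.
#' @param multiplier break cutoff as a multiple of `r0`; must exceed 1.
#' @return the network with cutoffs assigned.
#' @export
assign_break_cutoffs <- function(network, multiplier = 1.35) {
  stopifnot(inherits(network, "elastic_network"))
  if (multiplier <= 1) stop("multiplier must be > 1 (Rc > r0)", call. = FALSE)
  network$bonds$Rc <- multiplier * network$bonds$r0
  network$multiplier <- multiplier
  network
}

#' Apply irreversible bond breaking along a trajectory
#'
#' Scans frames in order; a bond whose instantaneous length first exceeds its
#' `Rc` is marked broken at that frame's time and never re-forms, even if the
#' distance later drops below the cutoff.
#'
#' @param network an [assign_break_cutoffs()] network.
#' @param trajectory a [bead_trajectory()] over the same beads.
#' @return list with `network` (updated), `events` (data.frame `bond, i, j,
#'   time, length`), `intact_count` (data.frame `time, intact`).
#' @export
apply_breaking <- function(network, trajectory) {
  stopifnot(inherits(network, "elastic_network"),
            inherits(trajectory, "bead_trajectory"))
  b <- network$bonds
  if (nrow(b) > 0L && any(is.na(b$Rc)))
    stop("assign break cutoffs before applying breaking", call. = FALSE)
  if (nrow(b) > 0L && max(b$j) > trajectory$structure$n)
    stop("bond bead index out of range for this trajectory", call. = FALSE)
  events <- list()
  counts <- integer(n_frames(trajectory))
  for (fk in seq_len(n_frames(trajectory))) {
    fr <- trajectory$frames[[fk]]
    if (nrow(b) > 0L) {
      len <- sqrt(rowSums((fr$positions[b$i, , drop = FALSE] -
                           fr$positions[b$j, , drop = FALSE])^2))
      newly <- which(b$intact & len > b$Rc)
      if (length(newly)) {
        b$intact[newly] <- FALSE
        b$break_time[newly] <- fr$time
        events[[length(events) + 1L]] <-
          data.frame(bond = newly, i = b$i[newly], j = b$j[newly],
                     time = fr$time, length = len[newly])
      }
    }
    counts[fk] <- sum(b$intact)  # integer: logical sum
  }
  network$bonds <- b
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(bond = integer(), i = integer(), j = integer(),
                        time = numeric(), length = numeric())
  list(network = network,
       events = ev,
       intact_count = data.frame(time = trajectory$times, intact = counts))
}

#' Harmonic energy of the intact network in a frame
#'
#' `sum over intact bonds of k (r - r0)^2 / 2` in kJ/mol; broken bonds
#' contribute nothing.
#'
#' @param network an `elastic_network`.
#' @param frame a [traj_frame()].
#' @return scalar energy in kJ/mol.
#' @export
harmonic_energy <- function(network, frame) {
  stopifnot(inherits(network, "elastic_network"), inherits(frame, "traj_frame"))
  b <- network$bonds[network$bonds$intact, , drop = FALSE]
  if (nrow(b) == 0L) return(0)
  len <- sqrt(rowSums((frame$positions[b$i, , drop = FALSE] -
                       frame$positions[b$j, , drop = FALSE])^2))
  sum(0.5 * b$k * (len - b$r0)^2)
}

#' Serialize an elastic network
#'
#' `write_en_json()` writes the full bond table (including break state) as
#' JSON; `write_en_table()` writes a GROMACS-style bonded-term text table
#' (`i j funct r0 k`, 1-based indices, funct 1).
#'
#' @param network an `elastic_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_en_json <- function(network, path) {
  jsonlite::write_json(
    list(lower = network$lower, upper = network$upper,
         multiplier = network$multiplier, bonds = network$bonds),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_en_json
#' @export
write_en_table <- function(network, path) {
  b <- network$bonds
  lines <- c("[ bonds ]", "; i  j  funct  r0(nm)  k(kJ/mol/nm^2)",
             sprintf("%6d %6d %4d %12.6f %12.3f", b$i, b$j, 1L, b$r0, b$k))
  writeLines(lines, path)
  invisible(path)
}
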