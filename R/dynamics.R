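# R-facing layer over the compiled Langevin engine.
#
# The integrator is BAOAB Langevin at kT = 1, friction 1/time, dt = 0.01
# intrinsic time units; the protocol time unit tau corresponds to 500
# integration steps. Chain bonds are classic Kremer-Grest FENE+WCA springs
# (k = 30 kT/sigma^2, maximum extension 1.5 sigma). Shell, tether and
# crosslink bonds are harmonic springs (k = 30 kT/sigma^2) with a per-bond
# rest length — the shell rest geometry is half the build spacing, which
# pre-tensions the membrane so the composite relaxes near the target volume
# fraction, and tether/crosslink rests equal their assignment distances, so
# installing them is jolt-free — plus a WCA core
# and a hard stability error at 8 sigma extension (bonds are permanent;
# working extensions stay far below the guard).
# Non-bonded pairs: WCA (repulsive classes) or truncated-shifted 12-6 wells
# (attractive class pairs, cutoff 2.5 sigma).

BOND_R0 <- c(chain = 1.5, shell = 8.0, tether = 8.0, crosslink = 8.0)
BOND_STYLE <- c(chain = 0L, shell = 1L, tether = 1L, crosslink = 1L)

bond_r0_of <- function(bonds) {
  if (nrow(bonds) == 0) return(numeric(0))
  unname(BOND_R0[bonds$type])
}

bond_style_of <- function(bonds) {
  if (nrow(bonds) == 0) return(integer(0))
  unname(BOND_STYLE[bonds$type])
}

bond_rest_of <- function(bonds) {
  if (nrow(bonds) == 0) return(numeric(0))
  if (is.null(bonds$rest)) return(rep(0, nrow(bonds)))
  ifelse(is.na(bonds$rest), 0, bonds$rest)
}

default_engine_opts <- function(n_steps, seed, dt = 0.01, friction = 1,
                                temperature = 1, record_every = 0L,
                                series_every = TAU_STEPS, max_disp = 0,
                                init_velocities = TRUE, init_kT = temperature,
                                energies = FALSE, fene_k = 30,
                                rc_attr = ATTRACT_CUTOFF, skin = 0.4) {
  list(n_steps = as.integer(n_steps), dt = dt, friction = friction,
       temperature = temperature, seed = as.double(seed),
       record_every = as.integer(record_every),
       series_every = as.integer(series_every), max_disp = max_disp,
       init_velocities = init_velocities, init_kT = init_kT,
       energies = energies, fene_k = fene_k,
       rc_attr = rc_attr, skin = skin)
}

bond_matrix <- function(bonds) {
  if (nrow(bonds) == 0) return(matrix(integer(0), 0, 2))
  cbind(as.integer(bonds$i), as.integer(bonds$j))
}

run_engine <- function(positions, class_code, bonds, interaction, opts,
                       protocol = list(type = "none")) {
  cpp_run(positions, as.integer(class_code), bond_matrix(bonds),
          bond_r0_of(bonds), bond_style_of(bonds), bond_rest_of(bonds),
          unclass(interaction)[seq_len(5), seq_len(5)], sigma_of(interaction),
          opts, protocol)
}

#' Create a simulation state
#'
#' Bundles an equilibrated (or in-progress) nucleus with an interaction
#' matrix and integrator settings; all stochastic dynamics derive from
#' `seed`, so identical seeds and inputs give bitwise-identical trajectories.
#'
#' @param nucleus An `nm_nucleus` model.
#' @param interaction An `nm_interaction` matrix
#'   (default [default_interaction()]).
#' @param dt Integration time step (intrinsic units, default 0.01).
#' @param friction Langevin friction (inverse time, default 1).
#' @param temperature Thermal energy kT (default 1).
#' @param seed Integer seed for the thermostat noise.
#' @return An `nm_state` object.
#' @export
sim_state <- function(nucleus, interaction = default_interaction(),
                      dt = 0.01, friction = 1, temperature = 1, seed = 1L) {
  stopifnot(inherits(nucleus, "nm_nucleus"))
  check_interaction(interaction)
  structure(
    list(nucleus = nucleus, interaction = interaction, dt = dt,
         friction = friction, temperature = temperature, seed = seed,
         step_count = 0L),
    class = "nm_state")
}

#' Run Langevin dynamics
#'
#' Advances the state by `n_steps` integration steps, optionally under a
#' protocol (moving pulling anchors or compression plates), recording
#' coordinate snapshots every `record_every` steps and scalar series every
#' `series_every` steps. Topology (classes, bonds) is immutable during a run.
#'
#' @param state An `nm_state`.
#' @param n_steps Number of integration steps (0 records only the initial
#'   snapshot).
#' @param record_every Snapshot cadence in steps (0: initial/final only).
#' @param series_every Scalar-series cadence in steps (default one tau).
#' @param protocol `list(type = "none")`, or a stretch/compression protocol
#'   as built internally by [stretch()] / [compress()].
#' @param energies Record kinetic/potential energy series.
#' @param max_disp Per-step displacement cap in sigma (0 = off); used for
#'   soft starts where overlapping initial coordinates would otherwise
#'   generate unbounded core forces.
#' @return An `nm_trajectory`: list with `frames` (coordinate matrices),
#'   `frame_steps`, `series` (tibble), the final `state`, and run metadata.
#' @export
run_dynamics <- function(state, n_steps, record_every = 0L,
                         series_every = TAU_STEPS,
                         protocol = list(type = "none"),
                         energies = FALSE, max_disp = 0) {
  stopifnot(inherits(state, "nm_state"))
  nuc <- state$nucleus
  opts <- default_engine_opts(
    n_steps, seed = state$seed, dt = state$dt, friction = state$friction,
    temperature = state$temperature, record_every = record_every,
    series_every = series_every, energies = energies, max_disp = max_disp)
  res <- run_engine(nuc$positions, nuc$class_code, nuc$bonds,
                    state$interaction, opts, protocol)
  nuc$positions <- res$positions
  state$nucleus <- nuc
  state$step_count <- state$step_count + as.integer(n_steps)
  state$seed <- derive_seed(state$seed, "continue")  # fresh stream next run
  series <- tibble::as_tibble(
    Filter(function(v) length(v) > 0, res$series))
  structure(
    list(frames = res$frames, frame_steps = res$frame_steps, series = series,
         state = state, protocol = protocol,
         params = list(dt = state$dt, friction = state$friction,
                       temperature = state$temperature, n_steps = n_steps,
                       record_every = record_every,
                       series_every = series_every, seed = opts$seed)),
    class = "nm_trajectory")
}

#' Advance a state by a single integration step
#'
#' @inheritParams run_dynamics
#' @return The advanced `nm_state`.
#' @export
langevin_step <- function(state, protocol = list(type = "none")) {
  run_dynamics(state, n_steps = 1L, series_every = 1L,
               protocol = protocol)$state
}

#' Non-bonded forces on every subunit
#'
#' Computes class-dependent pair forces (WCA cores plus truncated 12-6 wells)
#' through the neighbor-list production path; brute-force \eqn{O(N^2)}
#' summation over the same potentials is available as an independent check
#' via `brute = TRUE`.
#'
#' @param state An `nm_state`.
#' @param brute Use the direct all-pairs reference path.
#' @return N x 3 matrix of forces (kT/sigma).
#' @export
pair_forces <- function(state, brute = FALSE) {
  nuc <- state$nucleus
  emat <- unclass(state$interaction)[1:5, 1:5]
  smat <- sigma_of(state$interaction)
  if (!brute) {
    return(cpp_pair_forces(nuc$positions, as.integer(nuc$class_code),
                           bond_matrix(nuc$bonds), emat, smat,
                           ATTRACT_CUTOFF))
  }
  brute_pair_forces(nuc$positions, nuc$class_code, nuc$bonds, emat, smat)
}

# Direct O(N^2) pair-force reference (no neighbor structure); pure R.
brute_pair_forces <- function(pos, class_code, bonds, emat,
                              smat = matrix(1, 5, 5)) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  bonded <- matrix(FALSE, n, n)
  if (nrow(bonds) > 0) {
    bonded[cbind(bonds$i, bonds$j)] <- TRUE
    bonded[cbind(bonds$j, bonds$i)] <- TRUE
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (bonded[i, j]) next
      dr <- pos[i, ] - pos[j, ]
      r2 <- sum(dr^2)
      eps <- emat[class_code[i], class_code[j]]
      s <- smat[class_code[i], class_code[j]]
      rc2 <- if (eps > 0) ATTRACT_CUTOFF^2 else REPEL_CUTOFF^2 * s^2
      if (r2 >= rc2) next
      e <- if (eps > 0) eps else 1
      sr2 <- s^2 / r2
      sr6 <- sr2^3
      fmag <- 24 * e * (2 * sr6^2 - sr6) / r2
      f[i, ] <- f[i, ] + fmag * dr
      f[j, ] <- f[j, ] - fmag * dr
    }
  }
  f
}

#' Bonded (finite-extensible) forces on every subunit
#'
#' FENE spring plus WCA core for every chain, shell, tether and crosslink
#' bond; the force diverges as extension approaches the maximum (1.5 sigma)
#' and a bond at or beyond it raises a stability error naming the bond.
#'
#' @param state An `nm_state`.
#' @return N x 3 matrix of forces (kT/sigma).
#' @export
bond_forces <- function(state) {
  nuc <- state$nucleus
  cpp_bond_forces(nuc$positions, bond_matrix(nuc$bonds), 30,
                  bond_r0_of(nuc$bonds), bond_style_of(nuc$bonds),
                  bond_rest_of(nuc$bonds))
}

#' Total potential energy of a state
#'
#' @param state An `nm_state`.
#' @return Scalar potential energy (kT).
#' @export
potential_energy <- function(state) {
  nuc <- state$nucleus
  cpp_potential_energy(nuc$positions, as.integer(nuc$class_code),
                       bond_matrix(nuc$bonds),
                       unclass(state$interaction)[1:5, 1:5],
                       sigma_of(state$interaction),
                       ATTRACT_CUTOFF, 30, bond_r0_of(nuc$bonds),
                       bond_style_of(nuc$bonds), bond_rest_of(nuc$bonds))
}

#' @export
print.nm_trajectory <- function(x, ...) {
  cat(sprintf("<nm_trajectory> %d frames, %d series rows, %d steps (%s protocol)\n",
              length(x$frames), nrow(x$series), x$params$n_steps,
              x$protocol$type))
  invisible(x)
}

#' @export
print.nm_state <- function(x, ...) {
  cat(sprintf("<nm_state> %d subunits, step count %d, kT = %g, dt = %g\n",
              nrow(x$nucleus$positions), x$step_count, x$temperature, x$dt))
  invisible(x)
}
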