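# Langevin / NVE dynamics, force evaluation and minimization on top of the
# compiled core.

#' Simulation parameters
#'
#' @param dt timestep, fs.
#' @param friction Langevin friction, ps^-1; 0 gives NVE (velocity Verlet,
#'   to which the BAOAB update reduces exactly).
#' @param temperature thermostat temperature, K.
#' @param nlEvery neighbor-list rebuild interval, steps (a safety rebuild
#'   also triggers whenever any bead moved more than skin/2 since the last
#'   build).
#' @param skin neighbor-list skin, A.
#' @param seed integer seed; all run randomness derives from it and it is
#'   recorded in the trajectory.
#' @param outStride frame output interval, steps.
#' @param cap maximum per-bead displacement per step, A; NA disables
#'   capping (displacement-capped integration mirrors LAMMPS nve/limit).
#' @return a [SimParams-class]
#' @export
simParams <- function(dt = 10, friction = 1, temperature = 300,
                      nlEvery = 10L, skin = 4, seed = 1L,
                      outStride = 1000L, cap = NA_real_) {
  new("SimParams", dt = dt, friction = friction, temperature = temperature,
      nlEvery = as.integer(nlEvery), skin = skin, seed = as.integer(seed),
      outStride = as.integer(outStride), cap = as.numeric(cap))
}

#' Forces and energy terms of a configuration
#'
#' Direct (all-pairs) evaluation of the implemented energy: harmonic bonds,
#' Ashbaugh-Hatch pair terms with a 3 sigma cutoff, and Debye-Hueckel
#' electrostatics. Bonded (1-2) neighbors and pairs internal to a rigid
#' group are excluded from the nonbonded terms. Forces are the exact
#' negative gradient of the returned energy.
#'
#' @param topology a [Topology-class]
#' @param coords beads x 3 coordinate matrix, A
#' @param ff a [ForceField-class]
#' @param sasa optional per-bead SASA scale factors ([sasaScaleFactors()])
#' @param bondKScale multiplier on the bond constant (used by the
#'   compaction-relaxation protocol)
#' @return list(forces, eBond, eAH, eDH, eTotal)
#' @export
computeForces <- function(topology, coords, ff, sasa = NULL,
                          bondKScale = 1) {
  res <- cpp_forces_energy(as.matrix(coords), .sysList(topology, ff, sasa),
                           bondKScale)
  list(forces = res$forces, eBond = res$e_bond, eAH = res$e_ah,
       eDH = res$e_dh, eTotal = res$e_total)
}

#' Run Langevin (or NVE) dynamics
#'
#' BAOAB-discretized Langevin integration of flexible beads plus rigid
#' groups (net force and torque about each group's center of mass;
#' orientation by quaternion update, so internal geometry is preserved to
#' machine precision). Velocities are initialized from Maxwell-Boltzmann
#' at the run temperature unless supplied. Deterministic given the seed.
#'
#' @param topology a [Topology-class]
#' @param coords starting coordinates, beads x 3, A
#' @param ff a [ForceField-class]
#' @param params a [SimParams-class]
#' @param nsteps number of steps
#' @param sasa optional per-bead SASA scale factors
#' @param extForce optional constant external force, beads x 3,
#'   kcal/(mol A)
#' @param vel optional starting velocities (A/fs) for continuations
#' @param bondKScale multiplier on the bond constant
#' @return a [Trajectory-class]; the final coordinates and velocities are
#'   attached as attributes `finalCoords` and `finalVel` for continuations.
#'   An uncapped per-step displacement above 10 A aborts with an error
#'   carrying the last good coordinates (`lastCoords` on the condition).
#' @export
runDynamics <- function(topology, coords, ff, params, nsteps,
                        sasa = NULL, extForce = NULL, vel = NULL,
                        bondKScale = 1) {
  stopifnot(is(params, "SimParams"))
  sys <- .sysList(topology, ff, sasa)
  cap <- if (is.na(params@cap)) -1 else params@cap
  res <- cpp_run(as.matrix(coords), sys, as.integer(nsteps), params@dt,
                 params@friction, params@temperature, params@outStride,
                 params@nlEvery, params@skin, params@seed, cap,
                 ext_force = if (is.null(extForce)) NULL else as.matrix(extForce),
                 vel0 = if (is.null(vel)) NULL else as.matrix(vel),
                 bondKScale = bondKScale)
  nf <- res$n_frames
  if (res$blowup) {
    last <- if (nf >= 1) res$coords[, , nf, drop = TRUE] else coords
    cond <- structure(class = c("cgphosBlowup", "error", "condition"),
                      list(message = paste0(
                        "integration blow-up (displacement > 10 A/step) at step ",
                        res$blowup_step,
                        "; last good frame attached as `lastCoords`"),
                        call = sys.call(), lastCoords = last))
    stop(cond)
  }
  keep <- seq_len(nf)
  timeNs <- res$steps[keep] * params@dt * 1e-6
  new("Trajectory",
      coords = res$coords[, , keep, drop = FALSE],
      timeNs = timeNs,
      energies = data.frame(step = res$steps[keep], time = timeNs,
                            bond = res$e_bond[keep], ah = res$e_ah[keep],
                            dh = res$e_dh[keep], kinetic = res$kinetic[keep],
                            temperature = res$temperature[keep]),
      params = params, topology = topology) -> traj
  attr(traj, "finalCoords") <- res$final_coords
  attr(traj, "finalVel") <- res$final_vel
  attr(traj, "dof") <- res$dof
  traj
}

#' Minimize the potential energy
#'
#' FIRE descent on the flexible beads (rigid groups held fixed), with a
#' per-step displacement clamp for robustness from poor starting points.
#'
#' @param topology a [Topology-class]
#' @param coords starting coordinates
#' @param ff a [ForceField-class]
#' @param tol convergence threshold on the maximum force component,
#'   kcal/(mol A)
#' @param maxIter iteration budget; non-convergence returns the best
#'   coordinates with a warning
#' @param sasa optional per-bead SASA scale factors
#' @param bondKScale multiplier on the bond constant
#' @return list(coords, converged, fmax, iterations, energy)
#' @export
minimizeEnergy <- function(topology, coords, ff, tol = 1e-8,
                           maxIter = 200000L, sasa = NULL, bondKScale = 1) {
  res <- cpp_minimize(as.matrix(coords), .sysList(topology, ff, sasa),
                      tol, as.integer(maxIter), bondKScale)
  if (!res$converged)
    warning("minimization did not converge (max force ",
            format(res$fmax, digits = 3), ")")
  res
}
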