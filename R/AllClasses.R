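#' @import methods
NULL

#' ForceField: residue parameters and pair-interaction tables
#'
#' Holds the per-residue parameters (mass, charge, van der Waals diameter
#' sigma, hydropathy lambda) of a coarse-grained alpha-carbon model, the
#' derived type-pair tables (sigma_ij, lambda_ij, epsilon_ij), the
#' Debye-Hueckel electrostatics constants, and the harmonic bond constants.
#' Construct with [loadForceField()].
#'
#' @slot model "HPS" or "KH-D".
#' @slot residues data.frame with columns code, mass, charge, sigma, lambda.
#' @slot pairSigma,pairLambda,pairEpsilon symmetric type-pair matrices,
#'   indexed by residue code. For HPS, epsilon is the constant 0.2 kcal/mol
#'   and lambda_ij the arithmetic mean of hydropathies; for KH-D, epsilon and
#'   the +-1 lambda sign come from the contact-energy mapping.
#' @slot elec list: debyeLength (A), dielectric, coulombConstant
#'   (kcal A / (mol e^2)), cutoff (A).
#' @slot bond list: r0 (A), K (kcal/(mol A^2)), convention U = K (r - r0)^2.
#' @slot phosphoCharge charge per phospho residue, -2 or -1.5 e.
#' @slot checksums named md5 sums of the parameter files the table was read
#'   from.
#' @export
setClass("ForceField", representation(
  model = "character",
  residues = "data.frame",
  pairSigma = "matrix",
  pairLambda = "matrix",
  pairEpsilon = "matrix",
  elec = "list",
  bond = "list",
  phosphoCharge = "numeric",
  checksums = "character"
))

setValidity("ForceField", function(object) {
  msgs <- character()
  r <- object@residues
  need <- c("code", "mass", "charge", "sigma", "lambda")
  if (!all(need %in% names(r))) msgs <- c(msgs, "residues table incomplete")
  else {
    if (any(r$sigma <= 0)) msgs <- c(msgs, "sigma must be > 0")
    if (any(r$mass <= 0)) msgs <- c(msgs, "mass must be > 0")
    if (object@model == "HPS" && any(r$lambda < 0 | r$lambda > 1))
      msgs <- c(msgs, "HPS hydropathies must lie in [0,1]")
  }
  if (!isSymmetric(unname(object@pairEpsilon)) ||
      !isSymmetric(unname(object@pairSigma)))
    msgs <- c(msgs, "pair tables must be symmetric")
  if (any(object@pairEpsilon < 0)) msgs <- c(msgs, "epsilon_ij must be >= 0")
  if (object@elec$debyeLength <= 0) msgs <- c(msgs, "Debye length must be > 0")
  if (object@elec$dielectric <= 0) msgs <- c(msgs, "dielectric must be > 0")
  if (object@bond$r0 <= 0 || object@bond$K <= 0)
    msgs <- c(msgs, "bond constants must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Topology: beads, bonds, rigid groups, phospho state
#'
#' The simulated object: residue beads grouped into chains, harmonic bonds
#' between sequence neighbors, rigid groups with reference coordinates, the
#' phosphorylation state, and the periodic cubic box. Construct with
#' [buildTopology()] from [chainFromSequence()] chains.
#'
#' @slot beads data.frame with columns code (residue code, may be pS/pT),
#'   resNum (canonical residue number, 1-based), chain (chain id).
#' @slot bonds integer matrix, two bead ids per row (sequence neighbors).
#' @slot rigid list of groups, each list(ids, refCoords, name); refCoords is
#'   an n x 3 matrix of reference coordinates in A.
#' @slot phosphoState label such as "DEPH", "KIN1", "SHK1", "POM1", "FULL".
#' @slot phosphoSites data.frame (site, chain) of applied phospho positions.
#' @slot box edge length of the periodic cubic box, A.
#' @export
setClass("Topology", representation(
  beads = "data.frame",
  bonds = "matrix",
  rigid = "list",
  phosphoState = "character",
  phosphoSites = "data.frame",
  box = "numeric"
))

setValidity("Topology", function(object) {
  msgs <- character()
  b <- object@beads
  if (!all(c("code", "resNum", "chain") %in% names(b)))
    msgs <- c(msgs, "beads table incomplete")
  n <- nrow(b)
  if (nrow(object@bonds) > 0) {
    if (any(object@bonds < 1 | object@bonds > n))
      msgs <- c(msgs, "bond refers to nonexistent bead")
    same <- b$chain[object@bonds[, 1]] == b$chain[object@bonds[, 2]]
    adj <- abs(b$resNum[object@bonds[, 1]] - b$resNum[object@bonds[, 2]]) == 1
    if (!all(same & adj))
      msgs <- c(msgs, "bonds must connect sequence neighbors")
  }
  rid <- integer(n)
  for (g in object@rigid) {
    if (length(g$ids) < 3) msgs <- c(msgs, "rigid group needs >= 3 beads")
    if (any(rid[g$ids] != 0))
      msgs <- c(msgs, "bead belongs to more than one rigid group")
    rid[g$ids] <- 1L
    if (!is.matrix(g$refCoords) || nrow(g$refCoords) != length(g$ids))
      msgs <- c(msgs, "rigid reference coordinates inconsistent")
  }
  for (ch in split(b$resNum, b$chain)) {
    if (any(diff(ch) <= 0))
      msgs <- c(msgs, "residue numbers must be strictly increasing per chain")
  }
  if (object@box <= 0) msgs <- c(msgs, "box edge must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' SimParams: integrator and thermostat configuration
#'
#' @slot dt timestep, fs.
#' @slot friction Langevin friction, ps^-1 (0 = NVE).
#' @slot temperature K.
#' @slot nlEvery neighbor-list rebuild interval, steps.
#' @slot skin neighbor-list skin, A.
#' @slot seed integer RNG seed, recorded in all outputs.
#' @slot outStride frame output interval, steps.
#' @slot cap optional maximum per-bead displacement per step, A (NA = off).
#' @export
setClass("SimParams", representation(
  dt = "numeric", friction = "numeric", temperature = "numeric",
  nlEvery = "integer", skin = "numeric", seed = "integer",
  outStride = "integer", cap = "numeric"
))

setValidity("SimParams", function(object) {
  msgs <- character()
  if (object@dt <= 0) msgs <- c(msgs, "dt must be > 0")
  if (object@friction < 0) msgs <- c(msgs, "friction must be >= 0")
  if (object@temperature < 0) msgs <- c(msgs, "temperature must be >= 0")
  if (object@nlEvery < 1) msgs <- c(msgs, "nlEvery must be >= 1")
  if (object@outStride < 1) msgs <- c(msgs, "outStride must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: time-ordered frames with energy bookkeeping
#'
#' @slot coords numeric array, beads x 3 x frames, A.
#' @slot timeNs frame times, ns.
#' @slot energies data.frame: step, time, bond, ah, dh, kinetic, temperature.
#' @slot params the [SimParams-class] the run used.
#' @slot topology the simulated [Topology-class].
#' @export
setClass("Trajectory", representation(
  coords = "array", timeNs = "numeric", energies = "data.frame",
  params = "SimParams", topology = "Topology"
))

#' ObservableSeries: a scalar per-frame time series
#'
#' @slot values observable values, one per frame.
#' @slot frameNs frame interval, ns.
#' @slot trimIndex number of leading frames excluded as unequilibrated.
#' @slot label,unit description of the observable.
#' @export
setClass("ObservableSeries", representation(
  values = "numeric", frameNs = "numeric", trimIndex = "integer",
  label = "character", unit = "character"
))

setValidity("ObservableSeries", function(object) {
  msgs <- character()
  if (any(!is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (object@trimIndex < 0 || object@trimIndex >= length(object@values))
    msgs <- c(msgs, "trim index must be < series length")
  if (length(msgs)) msgs else TRUE
})

## ------------------------------------------------------------------- show

setMethod("show", "ForceField", function(object) {
  cat("ForceField <", object@model, "> ", nrow(object@residues),
      " residue types, phospho charge ", object@phosphoCharge, "e\n",
      "  Debye length ", object@elec$debyeLength, " A, dielectric ",
      object@elec$dielectric, ", bond r0 ", object@bond$r0, " A, K ",
      object@bond$K, " kcal/(mol A^2)\n", sep = "")
})

setMethod("show", "Topology", function(object) {
  cat("Topology: ", nrow(object@beads), " beads in ",
      length(unique(object@beads$chain)), " chain(s), ",
      nrow(object@bonds), " bonds, ", length(object@rigid),
      " rigid group(s)\n  phospho state ", object@phosphoState, " (",
      nrow(object@phosphoSites), " site-applications), box ",
      object@box, " A\n", sep = "")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", dim(object@coords)[3], " frames of ",
      dim(object@coords)[1], " beads, ",
      round(max(object@timeNs), 3), " ns (seed ", object@params@seed,
      ")\n", sep = "")
})

setMethod("show", "ObservableSeries", function(object) {
  cat("ObservableSeries '", object@label, "' [", object@unit, "]: ",
      length(object@values), " frames @ ", object@frameNs,
      " ns, trim ", object@trimIndex, "\n", sep = "")
})

## ------------------------------------------------------------- accessors

#' Number of beads in a topology
#' @param topology a [Topology-class]
#' @return integer bead count
#' @export
nBeads <- function(topology) nrow(topology@beads)

#' Bead table of a topology
#' @param topology a [Topology-class]
#' @return data.frame with code, resNum, chain
#' @export
beads <- function(topology) topology@beads

#' Rigid-group list of a topology
#' @param topology a [Topology-class]
#' @return list of groups (ids, refCoords, name)
#' @export
rigidGroups <- function(topology) topology@rigid

#' Frame coordinates of a trajectory
#' @param traj a [Trajectory-class]
#' @param frame frame index (1-based)
#' @return beads x 3 coordinate matrix, A
#' @export
frameCoords <- function(traj, frame) traj@coords[, , frame, drop = TRUE]

#' Number of frames in a trajectory
#' @param traj a [Trajectory-class]
#' @return integer
#' @export
nFrames <- function(traj) dim(traj@coords)[3]

#' Energy log of a trajectory
#' @param traj a [Trajectory-class]
#' @return data.frame: step, time, bond, ah, dh, kinetic, temperature
#' @export
energyLog <- function(traj) traj@energies

#' Values of an observable series
#' @param x an [ObservableSeries-class] or numeric vector
#' @param trimmed drop the leading `trimIndex` frames?
#' @return numeric vector
#' @export
seriesValues <- function(x, trimmed = TRUE) {
  if (is.numeric(x)) return(x)
  stopifnot(is(x, "ObservableSeries"))
  if (trimmed && x@trimIndex > 0) x@values[-seq_len(x@trimIndex)] else x@values
}

#' Construct an ObservableSeries
#' @param values numeric per-frame values
#' @param frameNs frame interval in ns
#' @param label,unit description
#' @param trimIndex leading frames already excluded (default 0)
#' @return an [ObservableSeries-class]
#' @export
observableSeries <- function(values, frameNs, label = "observable",
                             unit = "A", trimIndex = 0L) {
  new("ObservableSeries", values = as.numeric(values),
      frameNs = frameNs, trimIndex = as.integer(trimIndex),
      label = label, unit = unit)
}
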