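# Initial configurations and the relaxation protocols.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.chainOnly <- function(topology) {
  if (length(topology@rigid) > 0)
    stop("initializer requires a fully flexible topology (no rigid groups)")
  if (length(unique(topology@beads$chain)) != 1)
    stop("initializer requires a single chain")
}

#' Straight-line initial configuration
#'
#' Places the beads of a single flexible chain collinearly on the x axis at
#' the given spacing, centered on the origin.
#'
#' @param topology a single-chain [Topology-class] without rigid groups
#' @param spacing bead spacing, A (the bond equilibrium length by default)
#' @return beads x 3 coordinate matrix
#' @export
initStraight <- function(topology, spacing = 3.81) {
  .chainOnly(topology)
  n <- nBeads(topology)
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  cbind(x = x, y = numeric(n), z = numeric(n))
}

#' Semi-relaxed initial configuration with a target radius of gyration
#'
#' Grows a self-avoiding random walk (step 3.81 A, hard core 3.0 A), then
#' rescales it isotropically about its center of mass so the mass-weighted
#' radius of gyration matches `targetRg` exactly. Deterministic given the
#' seed.
#'
#' @param topology a single-chain [Topology-class] without rigid groups
#' @param ff a [ForceField-class] (for bead masses)
#' @param targetRg target radius of gyration, A (default 65.3 A = 6.53 nm)
#' @param seed RNG seed
#' @param step,hardcore walk step length and excluded-volume diameter, A
#' @return beads x 3 coordinate matrix
#' @export
initSemiRelaxed <- function(topology, ff, targetRg = 65.3, seed = 1,
                            step = 3.81, hardcore = 3.0) {
  .chainOnly(topology)
  n <- nBeads(topology)
  lower <- 2.0 * n^(1 / 3) # collapsed-globule packing bound, A
  if (targetRg < lower)
    stop("target Rg ", targetRg, " A below the packing bound (",
         round(lower, 1), " A) for ", n, " beads")
  coords <- .withSeed(seed, {
    X <- matrix(0, n, 3)
    hc2 <- hardcore^2
    i <- 2L
    tries <- 0L
    while (i <= n) {
      u <- stats::rnorm(3)
      cand <- X[i - 1L, ] + step * u / sqrt(sum(u^2))
      prev <- X[seq_len(i - 2L), , drop = FALSE]
      ok <- i == 2L ||
        all(colSums((t(prev) - cand)^2) > hc2)
      if (ok) {
        X[i, ] <- cand
        i <- i + 1L
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > 500L) { # back up a step if boxed in
          i <- max(2L, i - 1L)
          tries <- 0L
        }
      }
    }
    X
  })
  m <- ff@residues[topology@beads$code, "mass"]
  com <- colSums(coords * m) / sum(m)
  centered <- sweep(coords, 2, com)
  rg <- sqrt(sum(m * rowSums(centered^2)) / sum(m))
  centered * (targetRg / rg)
}

.findGroup <- function(topology, name) {
  for (g in topology@rigid) if (g$name == name) return(g)
  NULL
}

# Per-chain anchor bead inside a rigid group: the group bead bonded to a
# flexible bead of that chain.
.anchors <- function(topology, grp) {
  rig <- grp$ids
  out <- list()
  for (k in seq_len(nrow(topology@bonds))) {
    i <- topology@bonds[k, 1]; j <- topology@bonds[k, 2]
    if (i %in% rig && !(j %in% rig))
      out[[length(out) + 1]] <- c(anchor = i, first = j)
    else if (j %in% rig && !(i %in% rig))
      out[[length(out) + 1]] <- c(anchor = j, first = i)
  }
  out
}

#' Dimer initial configuration with the IDR arms apart
#'
#' Places the core rigid group (named "FBAR") at its reference coordinates
#' centered on the origin; each IDR arm extends in a straight line away
#' from its anchor bead, in the direction from the rigid-group center
#' through the anchor, with 3.81 A spacing (the first arm bead 3.81 A from
#' its anchor). SH3-type rigid groups at arm ends are translated so their
#' anchor continues the line.
#'
#' @param topology a dimer [Topology-class] with an "FBAR" rigid group
#' @param spacing arm bead spacing, A
#' @return beads x 3 coordinate matrix
#' @export
initDimerApart <- function(topology, spacing = 3.81) {
  grp <- .findGroup(topology, "FBAR")
  if (is.null(grp)) stop("no rigid group named 'FBAR' in topology")
  n <- nBeads(topology)
  X <- matrix(NA_real_, n, 3)
  ref <- grp$refCoords
  ctr <- colMeans(ref)
  X[grp$ids, ] <- sweep(ref, 2, ctr) # F-BAR centered at origin
  b <- topology@beads
  rigidAll <- unlist(lapply(topology@rigid, `[[`, "ids"))
  for (a in .anchors(topology, grp)) {
    anchor <- a["anchor"]; first <- a["first"]
    dir <- X[anchor, ]
    dir <- dir / sqrt(sum(dir^2)) # from center through anchor
    ch <- b$chain[first]
    # flexible arm beads of this chain beyond the anchor, in sequence order
    armIds <- which(b$chain == ch & !(seq_len(n) %in% rigidAll) &
                      sign(b$resNum - b$resNum[anchor]) ==
                        sign(b$resNum[first] - b$resNum[anchor]))
    armIds <- armIds[order(abs(b$resNum[armIds] - b$resNum[anchor]))]
    for (k in seq_along(armIds))
      X[armIds[k], ] <- X[anchor, ] + k * spacing * dir
    # SH3-type group at the arm end, if any
    for (g in topology@rigid) {
      if (g$name == "FBAR") next
      if (!all(b$chain[g$ids] == ch)) next
      aa <- .anchors(topology, g)
      if (length(aa) == 0) next
      ganchor <- aa[[1]]["anchor"]
      last <- X[armIds[length(armIds)], ]
      want <- last + spacing * dir
      ra <- g$refCoords[match(ganchor, g$ids), ]
      rel <- sweep(g$refCoords, 2, ra)
      # rotate so the group extends outward along the arm direction
      u <- colMeans(rel)
      un <- sqrt(sum(u^2))
      if (un > 1e-9) {
        u <- u / un
        v <- u + dir
        R <- if (sqrt(sum(v^2)) < 1e-9) -diag(3) # antiparallel: invert
             else 2 * (v %o% v) / sum(v * v) - diag(3) # reflect u -> dir
        rel <- rel %*% t(R)
      }
      X[g$ids, ] <- sweep(rel, 2, want, `+`)
    }
  }
  if (anyNA(X)) stop("beads left unplaced; is the dimer topology complete?")
  X
}

#' Compaction-relaxation protocol
#'
#' Mirrors the two-stage relaxation used to prepare dimer simulations:
#' (1) a run with the bond constant reduced 1000-fold while the box and the
#' flexible-bead coordinates are affinely shrunk by a factor of 10 (rigid
#' groups are translated with their centers of mass, not internally
#' scaled); (2) staged restoration of the bond constant over geometric
#' steps, each run displacement-capped.
#'
#' @param topology a [Topology-class]
#' @param coords starting coordinates
#' @param ff a [ForceField-class]
#' @param params a [SimParams-class]; its cap (default 0.1 A here) applies
#'   to every stage
#' @param nsStage duration of each stage, ns
#' @param kSchedule bond-constant multipliers of the staged restoration
#'   (fractions of the force-field K); the first entry is the shrink stage
#' @param shrink box/coordinate scale factor of stage 1
#' @return list(coords, topology) with the shrunken box
#' @export
compactionRelax <- function(topology, coords, ff, params,
                            nsStage = 10,
                            kSchedule = c(0.001, 0.01, 0.1, 1),
                            shrink = 0.1) {
  if (is.na(params@cap)) params@cap <- 0.1
  nstep <- max(1L, round(nsStage * 1e6 / params@dt))
  n <- nBeads(topology)
  rigidAll <- unlist(lapply(topology@rigid, `[[`, "ids"))
  flex <- setdiff(seq_len(n), rigidAll)
  X <- as.matrix(coords)
  # affine shrink about the box center (the origin); rigid groups are
  # translated with their centers of mass below, not internally scaled
  X[flex, ] <- X[flex, , drop = FALSE] * shrink
  for (g in topology@rigid) {
    com <- colMeans(X[g$ids, , drop = FALSE])
    X[g$ids, ] <- sweep(X[g$ids, , drop = FALSE], 2, com - com * shrink)
  }
  topology@box <- topology@box * shrink
  seed <- params@seed
  for (k in seq_along(kSchedule)) {
    params@seed <- as.integer(seed + k)
    traj <- runDynamics(topology, X, ff, params, nstep,
                        bondKScale = kSchedule[k])
    X <- attr(traj, "finalCoords")
  }
  list(coords = X, topology = topology)
}

.sh3Groups <- function(topology) {
  Filter(function(g) g$name != "FBAR", topology@rigid)
}

#' Forced-interaction dimer initial configuration
#'
#' From a relaxed "apart" configuration, applies a constant force to each
#' SH3-type rigid group directed toward the opposite side of the F-BAR
#' (along the axis joining the two IDR anchor points) until both SH3
#' centers of mass have crossed the midplane through the F-BAR center of
#' mass, then re-relaxes with the staged displacement-capped protocol.
#'
#' @param topology a dimer [Topology-class] with "FBAR" and two SH3-type
#'   rigid groups
#' @param coords relaxed "apart" coordinates
#' @param ff a [ForceField-class]
#' @param params a [SimParams-class]
#' @param forceMag force per SH3 bead, kcal/(mol A)
#' @param maxTimeNs abort if the midplane is not crossed within this time
#' @param relaxNs duration of each post-crossing relaxation stage, ns
#' @return coordinates with both SH3 groups on opposite sides from their
#'   start
#' @export
initDimerInteracting <- function(topology, coords, ff, params,
                                 forceMag = 0.5, maxTimeNs = 20,
                                 relaxNs = 1) {
  grp <- .findGroup(topology, "FBAR")
  if (is.null(grp)) stop("no rigid group named 'FBAR' in topology")
  sh3 <- .sh3Groups(topology)
  if (length(sh3) != 2) stop("need exactly two SH3-type rigid groups")
  anch <- .anchors(topology, grp)
  if (length(anch) != 2) stop("F-BAR must anchor exactly two arms")
  X <- as.matrix(coords)
  axis <- X[anch[[1]]["anchor"], ] - X[anch[[2]]["anchor"], ]
  axis <- axis / sqrt(sum(axis^2))
  fbarCom <- colMeans(X[grp$ids, , drop = FALSE])
  proj <- function(X, g)
    sum((colMeans(X[g$ids, , drop = FALSE]) - fbarCom) * axis)
  start <- vapply(sh3, function(g) proj(X, g), numeric(1))
  if (any(start == 0)) stop("SH3 starts on the midplane; cannot orient force")
  ext <- matrix(0, nBeads(topology), 3)
  for (k in 1:2)
    ext[sh3[[k]]$ids, ] <- matrix(-sign(start[k]) * forceMag * axis,
                                  length(sh3[[k]]$ids), 3, byrow = TRUE)
  chunk <- max(1L, round(0.2 * 1e6 / params@dt)) # 0.2 ns chunks
  elapsed <- 0
  vel <- NULL
  crossed <- FALSE
  seed <- params@seed
  it <- 0L
  while (elapsed < maxTimeNs) {
    it <- it + 1L
    params@seed <- as.integer(seed + 1000L + it)
    traj <- runDynamics(topology, X, ff, params, chunk, extForce = ext,
                        vel = vel)
    X <- attr(traj, "finalCoords")
    vel <- attr(traj, "finalVel")
    elapsed <- elapsed + chunk * params@dt * 1e-6
    now <- vapply(sh3, function(g) proj(X, g), numeric(1))
    if (all(sign(now) == -sign(start)) && all(abs(now) > 1)) {
      crossed <- TRUE
      break
    }
  }
  if (!crossed)
    stop("SH3 groups did not cross the F-BAR midplane within ", maxTimeNs,
         " ns; increase forceMag")
  if (is.na(params@cap)) params@cap <- 0.1
  nstep <- max(1L, round(relaxNs * 1e6 / params@dt))
  for (k in 1:3) {
    params@seed <- as.integer(seed + 2000L + k)
    traj <- runDynamics(topology, X, ff, params, nstep,
                        bondKScale = 10^(k - 3))
    X <- attr(traj, "finalCoords")
  }
  X
}
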